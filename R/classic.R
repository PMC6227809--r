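#' Hebbian (Hopfield) couplings
#'
#' \eqn{J_{ij} = \frac{1}{N}\sum_\mu \xi^\mu_i \xi^\mu_j} for \eqn{i \ne j},
#' zero diagonal, zero thresholds. Symmetric by construction.
#'
#' @param patterns A \code{\link{pattern_set}} in \code{-1/+1} coding.
#' @return A \code{\link{couplings}} object.
#' @examples
#' p <- iid_patterns(50, 3, seed = 1)
#' cp <- hebb_couplings(p)
#' isSymmetric(cp$J)
#' @export
hebb_couplings <- function(patterns) {
  if (patterns$convention != "pm1")
    stop("Hebb couplings are defined for +/-1 patterns", call. = FALSE)
  N <- ncol(patterns$xi)
  J <- crossprod(patterns$xi) / N
  diag(J) <- 0
  couplings(N, "pm1", J = J)
}

#' Generalized (covariance) Hebb couplings
#'
#' The covariance rule for correlated pattern ensembles:
#' \eqn{J_{ij} = \frac{1}{N a_v}\sum_\mu (\xi^\mu_i - a)(\xi^\mu_j - a)} with
#' \code{a} the known mean activity of the ensemble (the bias \code{b} for
#' \code{-1/+1} patterns, the coding level \code{f} for \code{0/1}) and
#' \eqn{a_v} the component variance (\eqn{1 - b^2}, resp. \eqn{f(1-f)}).
#' Unlike the delayed-matching rule this requires explicit knowledge of the
#' stimulus statistics. For \code{0/1} patterns the thresholds are set to the
#' midpoint \eqn{(1 - 2f)/2} of the signal levels so the current at a stored
#' pattern is centred; for \code{-1/+1} the centred currents already separate
#' at zero threshold.
#'
#' @param patterns A \code{\link{pattern_set}}.
#' @param a Known mean activity; defaults to the generator parameter recorded
#'   in the pattern set, falling back to the empirical mean.
#' @return A \code{\link{couplings}} object. Reduces exactly to
#'   \code{\link{hebb_couplings}} when \code{a = 0} in \code{-1/+1} coding.
#' @export
generalized_hebb_couplings <- function(patterns, a = NULL) {
  xi <- patterns$xi
  N <- ncol(xi)
  if (is.null(a)) {
    a <- if (patterns$convention == "pm1") patterns$meta$b else patterns$meta$f
    if (is.null(a)) a <- mean(xi)
  }
  v <- if (patterns$convention == "pm1") 1 - a^2 else a * (1 - a)
  if (v <= 0) stop("degenerate activity statistics", call. = FALSE)
  Jc <- crossprod(xi - a) / (N * v)
  diag(Jc) <- 0
  theta <- if (patterns$convention == "zero_one")
    rep((1 - 2 * a) / 2, N) else numeric(N)
  couplings(N, patterns$convention, J = Jc, theta = theta)
}

#' Storkey's online learning rule
#'
#' Adds one pattern to the couplings with
#' \deqn{\Delta J_{ij} = \frac{1}{N}\left(\xi_i \xi_j - \xi_i h_{ji} -
#'       h_{ij}\xi_j\right),\qquad
#'       h_{ij} = \sum_{k \ne i,j} J_{ik}\,\xi_k,}
#' where the partial local fields \eqn{h_{ij}} exclude the pre- and
#' post-synaptic units. The field terms penalize further growth of weights
#' onto memories that are already embedded with strong aligned fields, a
#' regularization built into the rule itself; symmetry of \code{J} is
#' preserved.
#'
#' @param coup A \code{\link{couplings}} object (\code{-1/+1}).
#' @param pattern Pattern vector to store.
#' @return The updated couplings.
#' @export
storkey_update <- function(coup, pattern) {
  if (coup$convention != "pm1")
    stop("Storkey's rule is defined for +/-1 patterns", call. = FALSE)
  N <- n_units(coup)
  if (length(pattern) != N) stop("pattern length mismatch", call. = FALSE)
  H <- drop(coup$J %*% pattern)             # full fields, no threshold
  # partial fields: h_ij = H_i - J_ij xi_j  (J_ii = 0 already)
  hij <- matrix(H, N, N) - coup$J * rep(pattern, each = N)
  dJ <- (tcrossprod(pattern) - t(hij) * pattern -
           hij * rep(pattern, each = N)) / N
  coup$J <- coup$J + mask_increment(dJ, coup)
  coup
}

#' Storkey couplings for a whole pattern set
#'
#' Applies \code{\link{storkey_update}} sequentially (online) to each pattern.
#'
#' @param patterns A \code{\link{pattern_set}} (\code{-1/+1}).
#' @return A \code{\link{couplings}} object.
#' @export
storkey_couplings <- function(patterns) {
  coup <- couplings(ncol(patterns$xi), "pm1")
  for (mu in seq_len(nrow(patterns$xi)))
    coup <- storkey_update(coup, patterns$xi[mu, ])
  coup
}
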