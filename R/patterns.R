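#' Pattern sets
#'
#' A pattern set holds M binary patterns of N components as an M x N matrix,
#' together with its coding convention and the generation parameters. The
#' storage load is \code{alpha = M / N}.
#'
#' @param xi M x N matrix of pattern components in the declared alphabet.
#' @param convention \code{"pm1"} or \code{"zero_one"}.
#' @param meta Named list of generation parameters.
#' @return An object of class \code{"dcm_patterns"}.
#' @export
pattern_set <- function(xi, convention = c("pm1", "zero_one"), meta = list()) {
  convention <- match.arg(convention)
  xi <- as.matrix(xi)
  alphabet <- if (convention == "pm1") c(-1, 1) else c(0, 1)
  if (!all(xi %in% alphabet))
    stop("pattern entries outside the declared alphabet", call. = FALSE)
  structure(list(xi = xi, convention = convention, meta = meta),
            class = "dcm_patterns")
}

#' @export
print.dcm_patterns <- function(x, ...) {
  cat(sprintf("%d %s patterns of %d units (alpha = %.3f)\n",
              nrow(x$xi), if (x$convention == "pm1") "+/-1" else "0/1",
              ncol(x$xi), nrow(x$xi) / ncol(x$xi)))
  invisible(x)
}

#' @export
dim.dcm_patterns <- function(x) dim(x$xi)

restore_seed <- function(seed) {
  if (is.null(seed)) return(invisible())
  set.seed(seed)
  invisible()
}

#' Independent unbiased binary patterns
#'
#' Each component is -1 or +1 with probability 1/2, independently.
#'
#' @param N Units per pattern.
#' @param M Number of patterns.
#' @param seed Optional seed; when given, the generator is a pure function of
#'   \code{(N, M, seed)}.
#' @return A \code{\link{pattern_set}}.
#' @examples
#' p <- iid_patterns(100, 10, seed = 1)
#' mean(p$xi)
#' @export
iid_patterns <- function(N, M, seed = NULL) {
  biased_patterns(N, M, b = 0, seed = seed)
}

#' Biased binary patterns
#'
#' Each component is +1 with probability \code{(1 + b) / 2} and -1 otherwise,
#' independently; \code{b = 0} recovers the unbiased ensemble and the mean
#' component value is \code{b}.
#'
#' @inheritParams iid_patterns
#' @param b Bias in \code{(-1, 1)}.
#' @export
biased_patterns <- function(N, M, b, seed = NULL) {
  if (N < 1 || M < 0) stop("`N` and `M` must be positive", call. = FALSE)
  if (abs(b) >= 1) stop("`b` must lie strictly inside (-1, 1)", call. = FALSE)
  restore_seed(seed)
  xi <- matrix(ifelse(stats::runif(M * N) < (1 + b) / 2, 1, -1), M, N)
  pattern_set(xi, "pm1", meta = list(b = b, seed = seed))
}

#' Sparse 0/1 patterns
#'
#' Each component is 1 with probability \code{f} (the coding level). With
#' \code{exact = TRUE} every pattern instead has exactly \code{round(f * N)}
#' active units at random positions; this removes the binomial fluctuations
#' of the per-pattern activity, which at network sizes of a few hundred units
#' are large enough to dominate a strict overlap criterion when an inhibitory
#' mechanism pins the network activity at \code{f}.
#'
#' @inheritParams iid_patterns
#' @param f Coding level in (0, 1).
#' @param exact If \code{TRUE}, fix the active count of every pattern at
#'   \code{round(f * N)}.
#' @export
sparse_patterns <- function(N, M, f, seed = NULL, exact = FALSE) {
  if (f <= 0 || f >= 1) stop("`f` must lie in (0, 1)", call. = FALSE)
  restore_seed(seed)
  if (exact) {
    k <- max(1L, round(f * N))
    xi <- matrix(0, M, N)
    for (mu in seq_len(M)) xi[mu, sample.int(N, k)] <- 1
  } else {
    xi <- matrix(as.numeric(stats::runif(M * N) < f), M, N)
  }
  pattern_set(xi, "zero_one", meta = list(f = f, seed = seed, exact = exact))
}

#' Patterns composed from a dictionary of sparse features
#'
#' Pre-generates a dictionary of \code{L} sparse 0/1 features (each unit
#' active with probability \code{f}); every pattern is the componentwise OR of
#' \code{F} features drawn uniformly without replacement. Shorter dictionaries
#' produce more correlated pattern sets; in the limit of an infinite
#' dictionary the patterns decorrelate. Activity is not renormalized after
#' superposition, so the expected coding level of a pattern is
#' \code{1 - (1 - f)^F}.
#'
#' @inheritParams sparse_patterns
#' @param L Dictionary length.
#' @param F Features superimposed per pattern; must not exceed \code{L}.
#' @export
dictionary_patterns <- function(N, M, L, F, f, seed = NULL) {
  if (F > L) stop("`F` must not exceed the dictionary length `L`", call. = FALSE)
  if (F < 1) stop("`F` must be >= 1", call. = FALSE)
  if (f <= 0 || f >= 1) stop("`f` must lie in (0, 1)", call. = FALSE)
  restore_seed(seed)
  dict <- matrix(as.numeric(stats::runif(L * N) < f), L, N)
  xi <- matrix(0, M, N)
  for (mu in seq_len(M)) {
    feats <- sample.int(L, F)
    xi[mu, ] <- as.numeric(colSums(dict[feats, , drop = FALSE]) > 0)
  }
  pattern_set(xi, "zero_one",
              meta = list(L = L, F = F, f = f, seed = seed, dictionary = dict))
}

#' Corrupt a pattern
#'
#' Flips exactly \code{round(chi * N)} randomly chosen components (sampled
#' without replacement), for either coding convention. Used to initialize
#' retrieval tests at a controlled Hamming distance from the memory.
#'
#' @param pattern Binary vector.
#' @param chi Corruption fraction in \code{[0, 1]}.
#' @param convention Coding of the pattern.
#' @param n_copies Number of independently corrupted copies; with
#'   \code{n_copies > 1} a matrix with one copy per column is returned.
#' @return A corrupted copy (vector), or an N x n_copies matrix.
#' @examples
#' xi <- rep(1, 10)
#' sum(corrupt(xi, 0.3, "pm1") != xi)
#' @export
corrupt <- function(pattern, chi, convention = c("pm1", "zero_one"),
                    n_copies = 1) {
  convention <- match.arg(convention)
  if (chi < 0 || chi > 1) stop("`chi` must lie in [0, 1]", call. = FALSE)
  N <- length(pattern)
  k <- round(chi * N)
  out <- matrix(pattern, N, n_copies)
  if (k > 0) {
    for (j in seq_len(n_copies)) {
      idx <- sample.int(N, k)
      out[idx, j] <- if (convention == "pm1") -out[idx, j] else 1 - out[idx, j]
    }
  }
  if (n_copies == 1L) drop(out) else out
}

#' Overlap between a state and a pattern
#'
#' For \code{-1/+1} coding the usual normalized dot product
#' \eqn{m = \frac{1}{N}\sum_i s_i \xi_i}. For \code{0/1} coding the
#' activity-centred overlap
#' \eqn{m = \frac{1}{N f (1-f)} \sum_i (s_i - f)(\xi_i - f)} with \code{f} the
#' pattern's coding level, which is 1 when \code{s} equals the pattern and
#' near 0 for uncorrelated or all-silent states. Accepts time-averaged
#' (non-binary) states.
#'
#' @param s State vector, or N x K matrix (one overlap per column).
#' @param pattern Reference pattern.
#' @param convention Coding convention.
#' @return Overlap value(s).
#' @export
pattern_overlap <- function(s, pattern, convention = c("pm1", "zero_one")) {
  convention <- match.arg(convention)
  s <- as.matrix(s)
  if (convention == "pm1") {
    drop(crossprod(s, pattern)) / length(pattern)
  } else {
    f <- mean(pattern)
    if (f == 0 || f == 1) stop("degenerate pattern: uniform activity", call. = FALSE)
    drop(crossprod(s - f, pattern - f)) / (length(pattern) * f * (1 - f))
  }
}
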