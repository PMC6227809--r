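#' Local fields of the network
#'
#' The total input current to each unit: the recurrent contribution
#' \code{J \%*\% s}, plus the external stimulus scaled by the field intensity
#' \code{lambda}, minus the local threshold.
#'
#' @param coup A \code{\link{couplings}} object.
#' @param s State vector of length N, or an N x K matrix of K states updated
#'   in parallel (independent replicas sharing the couplings).
#' @param stimulus Stimulus vector of length N, or \code{NULL} for none.
#'   Hidden units must have (and are given) zero stimulus.
#' @param lambda Field intensity multiplying the stimulus; may be negative
#'   (antagonist field).
#' @return Fields in the same shape as \code{s}.
#' @examples
#' cp <- couplings(4)
#' local_fields(cp, rep(1, 4), stimulus = c(1, -1, 1, -1), lambda = 2)
#' @export
local_fields <- function(coup, s, stimulus = NULL, lambda = 0) {
  s <- as.matrix(s)
  if (nrow(s) != n_units(coup))
    stop("state length does not match the number of units", call. = FALSE)
  h <- coup$J %*% s - coup$theta
  if (!is.null(stimulus) && lambda != 0) {
    if (length(stimulus) != n_units(coup))
      stop("stimulus length does not match the number of units", call. = FALSE)
    stimulus[coup$hidden] <- 0
    h <- h + lambda * stimulus
  }
  if (ncol(h) == 1L) drop(h) else h
}

# P(next state is "up") given fields, per convention.
# pm1:      P(+1) = exp(beta h) / (2 cosh(beta h)) = plogis(2 beta h)
# zero_one: P(1)  = plogis(beta h)
up_probability <- function(h, beta, convention) {
  if (convention == "pm1") stats::plogis(2 * beta * h) else stats::plogis(beta * h)
}

# hard-threshold update; ties at h == 0 keep the previous state
threshold_update <- function(h, s, convention) {
  up <- if (convention == "pm1") 1 else 1
  dn <- if (convention == "pm1") -1 else 0
  out <- s
  out[h > 0] <- up
  out[h < 0] <- dn
  out
}

#' One synchronous Glauber update
#'
#' All units draw their next state simultaneously and independently from the
#' sigmoid of their current local field. For \code{-1/+1} units the
#' probability of the up state is \eqn{e^{\beta h} / (2\cosh\beta h)}; for
#' \code{0/1} units it is the logistic sigmoid \eqn{1/(1 + e^{-\beta h})}. In
#' the deterministic limit the update is a hard threshold with ties keeping
#' the previous state.
#'
#' @inheritParams local_fields
#' @param params A \code{\link{dynamics_params}} object.
#' @param inhibition Optional \code{\link{inhibition_scheme}} applied to the
#'   fields before the update (0/1 networks).
#' @return The next state, same shape as \code{s}.
#' @examples
#' cp <- couplings(5)
#' set.seed(1)
#' glauber_step(cp, rep(1, 5), dynamics_params(beta = 1))
#' @export
glauber_step <- function(coup, s, params, stimulus = NULL, lambda = 0,
                         inhibition = NULL) {
  vec <- is.null(dim(s))
  s <- as.matrix(s)
  h <- coup$J %*% s - coup$theta
  if (!is.null(stimulus) && lambda != 0) {
    stimulus[coup$hidden] <- 0
    h <- h + lambda * stimulus
  }
  if (!is.null(inhibition))
    h <- apply_inhibition(s, coup, inhibition, h, params)
  if (!all(is.finite(h))) stop("non-finite local fields", call. = FALSE)
  if (params$deterministic) {
    out <- threshold_update(h, s, coup$convention)
  } else {
    p <- up_probability(h, params$beta, coup$convention)
    draw <- matrix(stats::runif(length(p)), nrow(p), ncol(p))
    up <- draw < p
    out <- matrix(if (coup$convention == "pm1") -1 else 0, nrow(p), ncol(p))
    out[up] <- 1
  }
  if (vec) drop(out) else out
}

#' Run the synchronous dynamics for several steps
#'
#' Iterates \code{\link{glauber_step}} from the given state. The state is
#' never reset internally; the final state is returned alongside the recorded
#' trajectory (if requested).
#'
#' @inheritParams glauber_step
#' @param n_steps Number of updates, at least 1.
#' @param record If \code{TRUE}, return the full trajectory as an
#'   \code{n_steps x N} matrix (vector states only).
#' @return A list with \code{state} (final state) and, when recording,
#'   \code{trajectory}.
#' @examples
#' cp <- couplings(4)
#' set.seed(1)
#' run_dynamics(cp, rep(1, 4), dynamics_params(beta = 1), n_steps = 5)$state
#' @export
run_dynamics <- function(coup, s, params, n_steps, stimulus = NULL,
                         lambda = 0, inhibition = NULL, record = FALSE) {
  if (n_steps < 1) stop("`n_steps` must be at least 1", call. = FALSE)
  traj <- if (record && is.null(dim(s)))
    matrix(NA_real_, n_steps, length(s)) else NULL
  for (t in seq_len(n_steps)) {
    s <- glauber_step(coup, s, params, stimulus, lambda, inhibition)
    if (!is.null(traj)) traj[t, ] <- s
  }
  out <- list(state = s)
  if (!is.null(traj)) out$trajectory <- traj
  out
}

#' Enumerate all fixed points of the deterministic dynamics
#'
#' Exhaustively scans all \code{2^N} states and returns those mapped to
#' themselves by the zero-temperature synchronous update (ties at zero field
#' keep the previous state, so a unit with zero field is always self-stable).
#' Intended as a small-network test oracle; refuses networks larger than
#' \code{max_units}.
#'
#' @param coup A \code{\link{couplings}} object.
#' @param max_units Refuse enumeration beyond this size (default 14).
#' @return A matrix with one fixed point per row (possibly zero rows).
#' @examples
#' xi <- c(1, -1, 1, -1)
#' cp <- hebb_couplings(pattern_set(matrix(xi, 1)))
#' nrow(enumerate_attractors(cp))
#' @export
enumerate_attractors <- function(coup, max_units = 14) {
  N <- n_units(coup)
  if (N > max_units)
    stop("refusing exhaustive enumeration for N > ", max_units, call. = FALSE)
  lv <- if (coup$convention == "pm1") c(-1, 1) else c(0, 1)
  grid <- as.matrix(expand.grid(rep(list(lv), N)))
  S <- t(grid)                               # N x 2^N
  H <- coup$J %*% S - coup$theta
  S2 <- threshold_update(H, S, coup$convention)
  fixed <- colSums(S2 == S) == N
  out <- t(S[, fixed, drop = FALSE])
  dimnames(out) <- NULL
  out
}
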