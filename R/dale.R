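#' Outgoing-sign labels for Dale's principle
#'
#' Assigns each unit an excitatory (+1) or inhibitory (-1) outgoing-sign
#' label. In the excitatory-inhibitory experiments shipped with the package
#' the modeled plastic population is all excitatory and the inhibitory
#' population is replaced by an effective feedback scheme
#' (\code{\link{inhibition_scheme}}); the mask is nevertheless general.
#'
#' @param N Number of units.
#' @param frac_inhibitory Fraction of inhibitory units (default 0: all
#'   excitatory).
#' @param seed Optional seed for the random placement of inhibitory units.
#' @return A length-N vector of +1/-1.
#' @export
dale_mask <- function(N, frac_inhibitory = 0, seed = NULL) {
  restore_seed(seed)
  mask <- rep(1, N)
  k <- round(frac_inhibitory * N)
  if (k > 0) mask[sample.int(N, k)] <- -1
  mask
}

#' Effective inhibitory feedback schemes
#'
#' Three mechanisms that hold the mean activity of a sparse 0/1 network near
#' the target coding level \code{f}, standing in for a separate (non-learned)
#' inhibitory sub-population:
#' \describe{
#'   \item{\code{global_feedback}}{subtracts \code{gain * (activity - f)}
#'     from every field, where the population activity is tracked by a global
#'     inhibitory variable with time constant \code{tau} steps (instantaneous
#'     strong feedback is unstable under synchronous updates, locking the
#'     network into an all-on/all-off limit cycle; the smoothed variable
#'     damps it). The stationary activity error is approximately
#'     \code{logit(f) / (beta * gain)}, so gains of order twenty suffice at
#'     moderate noise.}
#'   \item{\code{soft_wta}}{subtracts a common inhibition level chosen anew at
#'     every step so that the expected number of active units equals
#'     \code{N * f} (a soft winner-takes-all; in the deterministic limit
#'     exactly the \code{N * f} largest fields win).}
#'   \item{\code{adaptive_threshold}}{per-unit slow threshold dynamics: each
#'     unit tracks its own running activity with time constant \code{tau}
#'     steps and is penalized by \code{theta_gain * (running - f)}, pushing
#'     every unit's long-run activity toward \code{f}.}
#' }
#' All three prevent epileptic (all-on) and silent states.
#'
#' @param kind Scheme name.
#' @param target_activity Desired mean activity (pattern coding level f).
#' @param gain Feedback gain of \code{global_feedback}.
#' @param theta_gain Threshold gain of \code{adaptive_threshold}.
#' @param tau Activity-tracking time constant in steps; defaults to 10 for
#'   \code{global_feedback} (fast damping) and 40 for
#'   \code{adaptive_threshold} (slow per-unit estimates, whose sampling
#'   fluctuations otherwise bias the activity upward).
#' @return An object of class \code{"dcm_inhibition"}.
#' @examples
#' inhibition_scheme("global_feedback", target_activity = 0.1)
#' @export
inhibition_scheme <- function(kind = c("global_feedback", "soft_wta",
                                       "adaptive_threshold"),
                              target_activity, gain = 40, theta_gain = 40,
                              tau = NULL) {
  kind <- match.arg(kind)
  if (is.null(tau)) tau <- if (kind == "adaptive_threshold") 40 else 10
  if (target_activity <= 0 || target_activity >= 1)
    stop("`target_activity` must lie in (0, 1)", call. = FALSE)
  structure(list(kind = kind, target_activity = target_activity, gain = gain,
                 theta_gain = theta_gain, tau = tau, env = new.env()),
            class = "dcm_inhibition")
}

#' Reset the internal state of an inhibition scheme
#'
#' Only \code{adaptive_threshold} carries state (the per-unit running
#' activities); resetting restarts them at the target level.
#'
#' @param scheme An \code{\link{inhibition_scheme}}.
#' @return The scheme, with cleared state.
#' @export
reset_inhibition <- function(scheme) {
  rm(list = ls(scheme$env), envir = scheme$env)
  scheme
}

#' Apply an inhibitory feedback scheme to the local fields
#'
#' Called inside \code{\link{glauber_step}} when an inhibition scheme is
#' supplied; exposed for direct inspection. \code{s} and \code{h} may be
#' N x K matrices of parallel replicas.
#'
#' @param s Current state (pre-update).
#' @param coup Couplings (0/1 convention required).
#' @param scheme \code{\link{inhibition_scheme}}.
#' @param h Local fields before inhibition.
#' @param params \code{\link{dynamics_params}}.
#' @return Adjusted fields, same shape as \code{h}.
#' @export
apply_inhibition <- function(s, coup, scheme, h, params) {
  if (coup$convention != "zero_one")
    stop("inhibitory feedback schemes apply to 0/1 networks", call. = FALSE)
  s <- as.matrix(s); h <- as.matrix(h)
  N <- nrow(h); K <- ncol(h)
  f <- scheme$target_activity
  if (scheme$kind == "global_feedback") {
    a <- scheme$env$a
    if (is.null(a) || length(a) != K) a <- rep(f, K)
    a <- (1 - 1 / scheme$tau) * a + (1 / scheme$tau) * colMeans(s)
    scheme$env$a <- a
    h <- sweep(h, 2, scheme$gain * (a - f), `-`)
  } else if (scheme$kind == "soft_wta") {
    k <- max(1L, round(N * f))
    for (j in seq_len(K)) {
      hs <- sort(h[, j], decreasing = TRUE)
      if (params$deterministic) {
        inh <- if (k < N) (hs[k] + hs[k + 1]) / 2 else hs[N] - 1
      } else {
        target <- N * f
        fn <- function(I) sum(stats::plogis(params$beta * (h[, j] - I))) - target
        span <- 25 / params$beta + 1
        inh <- tryCatch(
          stats::uniroot(fn, c(min(h[, j]) - span, max(h[, j]) + span))$root,
          error = function(e) (hs[k] + hs[min(N, k + 1)]) / 2)
      }
      h[, j] <- h[, j] - inh
    }
  } else {  # adaptive_threshold
    a <- scheme$env$a
    if (is.null(a) || nrow(a) != N || ncol(a) != K)
      a <- matrix(f, N, K)
    a <- (1 - 1 / scheme$tau) * a + (1 / scheme$tau) * s
    scheme$env$a <- a
    h <- h - scheme$theta_gain * (a - f)
  }
  h
}
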