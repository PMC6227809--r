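#' Dynamics parameters for synchronous Glauber updates
#'
#' Bundles the inverse temperature \code{beta} controlling the dynamical noise
#' of the network with an explicit zero-temperature switch. At finite
#' \code{beta} every unit is updated stochastically from a sigmoid of its local
#' field; with \code{deterministic = TRUE} the sigmoid is replaced by a hard
#' threshold (the \code{beta} to infinity limit) and ties at exactly zero field
#' keep the unit's previous state.
#'
#' @param beta Inverse temperature, a finite positive number. Ignored by the
#'   update itself when \code{deterministic = TRUE} but still recorded.
#' @param deterministic Logical; if \code{TRUE} units are updated by
#'   thresholding their local field.
#' @return An object of class \code{"dcm_dynamics"}.
#' @examples
#' dynamics_params(beta = 3)
#' dynamics_params(deterministic = TRUE)
#' @export
dynamics_params <- function(beta = 3, deterministic = FALSE) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single finite positive number", call. = FALSE)
  structure(list(beta = beta, deterministic = isTRUE(deterministic)),
            class = "dcm_dynamics")
}

#' Staircase external-field protocol
#'
#' Describes the time course of the stimulus intensity during one pattern
#' presentation: an initial preparation period of \code{T_init} steps at the
#' full intensity \code{lambda0}, followed by windows of \code{2 * T} steps.
#' Each window records time-delayed correlations for \code{T} steps at the
#' current level \eqn{\lambda} and for \code{T} steps at the lower level
#' \eqn{\lambda - \delta\lambda}; the couplings are updated at the end of the
#' window, and the level then steps down until it reaches \code{lambda_min}.
#' The low phase of the final window is clipped at \code{lambda_min}, so the
#' lowest intensity at which correlations are recorded equals \code{lambda_min}
#' exactly.
#'
#' A window pair may be repeated up to \code{reps_per_level} times at the same
#' level before the field steps down. When \code{confine} is non-\code{NULL},
#' repetition stops early as soon as the mean activity of the low phase has an
#' overlap of at least \code{confine} with the presented pattern, i.e. as soon
#' as the freely relaxing network stays confined near the pattern at the lower
#' field. This adaptive repetition keeps the sampling from drifting into other
#' attractors (and consequently unlearning them) while the field descends.
#'
#' \code{lambda_min} may be positive, to keep a residual bias toward the
#' pattern during the last recordings (used in one-shot learning so that the
#' free phase cannot wander into, and erase, older memories), or negative, in
#' which case the network must resist an antagonist field and larger basins of
#' attraction are carved.
#'
#' @param lambda0 Initial field intensity (units of local field).
#' @param delta_lambda Step decrement of the staircase, positive.
#' @param T Number of dynamics steps per recording phase (half-window).
#' @param T_init Preparation steps at \code{lambda0} before the first window.
#' @param lambda_min Terminal intensity; may be negative (antagonist field) or
#'   positive (one-shot learning).
#' @param reps_per_level Maximum window-pair repetitions at each level.
#' @param confine Overlap threshold in \code{[0, 1]} for adaptive early exit
#'   from level repetitions, or \code{NULL} to always run
#'   \code{reps_per_level} pairs.
#' @param stimulus_center Value subtracted from the stimulus components of
#'   visible units before scaling by the field intensity. Zero (the default)
#'   presents the raw pattern. For 0/1 patterns without an inhibitory
#'   feedback mechanism, centring at the coding level (\code{f}) makes the
#'   field push inactive units down as well as active units up, which is
#'   required for the pattern to be imprinted at all: uncentred 0/1 stimuli
#'   leave the inactive units fluctuating at chance.
#' @return An object of class \code{"dcm_protocol"}.
#' @examples
#' field_protocol()
#' # one-shot variant: residual positive field, adaptive confinement reps
#' field_protocol(T = 60, lambda_min = 0.05, reps_per_level = 5, confine = 0.85)
#' @export
field_protocol <- function(lambda0 = 2, delta_lambda = 0.2, T = 20,
                           T_init = 40, lambda_min = 0, reps_per_level = 1,
                           confine = NULL, stimulus_center = 0) {
  if (T < 1) stop("`T` must be at least 1", call. = FALSE)
  if (delta_lambda <= 0) stop("`delta_lambda` must be positive", call. = FALSE)
  if (lambda0 < lambda_min)
    stop("`lambda0` must not be below `lambda_min`", call. = FALSE)
  if (reps_per_level < 1) stop("`reps_per_level` must be >= 1", call. = FALSE)
  if (!is.null(confine) && (confine < 0 || confine > 1))
    stop("`confine` must lie in [0, 1]", call. = FALSE)
  structure(list(lambda0 = lambda0, delta_lambda = delta_lambda,
                 T = as.integer(T), T_init = as.integer(T_init),
                 lambda_min = lambda_min,
                 reps_per_level = as.integer(reps_per_level),
                 confine = confine, stimulus_center = stimulus_center),
            class = "dcm_protocol")
}

#' Learning parameters
#'
#' @param eta Learning rate per coupling update (zero gives the identity
#'   update). The increment of a single
#'   window is a difference of normalized correlations (entries of order one),
#'   so the induced change of a local field is of order \code{eta * N}; keeping
#'   \code{eta * N} of order one (e.g. \code{eta = 1/N}) makes the per-window
#'   field change comparable to the staircase decrement and is the scale used
#'   by the higher-level training drivers.
#' @param l2_decay Multiplicative weight-decay coefficient applied to the
#'   couplings before each increment (\code{J <- (1 - l2_decay) * J}). Zero
#'   disables regularization; a small positive value gives the one-shot
#'   palimpsest regime its steady state.
#' @param update_theta Logical; update local thresholds from the single-site
#'   magnetization mismatch (mirror of the coupling rule). Thresholds matter
#'   for biased and sparse patterns; for unbiased \code{+/-1} patterns they
#'   stay near zero either way.
#' @return An object of class \code{"dcm_learning"}.
#' @examples
#' learning_params(eta = 1 / 200)
#' @export
learning_params <- function(eta, l2_decay = 0, update_theta = TRUE) {
  if (!is.numeric(eta) || eta < 0)
    stop("`eta` must be non-negative", call. = FALSE)
  if (l2_decay < 0 || l2_decay >= 1)
    stop("`l2_decay` must lie in [0, 1)", call. = FALSE)
  structure(list(eta = eta, l2_decay = l2_decay,
                 update_theta = isTRUE(update_theta)),
            class = "dcm_learning")
}

#' Corruption-and-retrieval storage criterion
#'
#' A pattern counts as stored when, over \code{n_trials} independent retrieval
#' attempts started from a copy of the pattern with a fraction \code{chi} of
#' randomly chosen components flipped, the fraction of successful attempts is
#' at least \code{success_rate_min}. One attempt relaxes the network for
#' \code{relax_steps} steps at zero field and then declares success when the
#' overlap with the pattern, averaged over a further \code{readout_steps}
#' steps, reaches \code{overlap_min}.
#'
#' \code{chi} operationalizes the basin width demanded of each memory; the
#' corruption flips exactly \code{round(chi * N)} components. Measured
#' capacities depend directly on \code{success_rate_min} and
#' \code{overlap_min}; the defaults (0.9 and 0.9) are deliberately strict.
#'
#' @param chi Corruption fraction in \code{[0, 1]}.
#' @param n_trials Retrieval attempts per pattern.
#' @param success_rate_min Minimum fraction of successful attempts.
#' @param relax_steps Relaxation steps before readout.
#' @param readout_steps Steps over which the overlap is time-averaged.
#' @param overlap_min Minimum time-averaged overlap for a successful attempt.
#' @return An object of class \code{"dcm_criterion"}.
#' @examples
#' retrieval_criterion(chi = 0.1)
#' @export
retrieval_criterion <- function(chi = 0.1, n_trials = 10,
                                success_rate_min = 0.9, relax_steps = 30,
                                readout_steps = 10, overlap_min = 0.9) {
  if (chi < 0 || chi > 1) stop("`chi` must lie in [0, 1]", call. = FALSE)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  stopifnot(success_rate_min >= 0, success_rate_min <= 1,
            overlap_min >= -1, overlap_min <= 1,
            relax_steps >= 0, readout_steps >= 1)
  structure(list(chi = chi, n_trials = as.integer(n_trials),
                 success_rate_min = success_rate_min,
                 relax_steps = as.integer(relax_steps),
                 readout_steps = as.integer(readout_steps),
                 overlap_min = overlap_min),
            class = "dcm_criterion")
}

#' @export
print.dcm_protocol <- function(x, ...) {
  cat(sprintf(
    "Staircase field protocol: lambda %.3g -> %.3g by %.3g, T = %d (T_init = %d)\n",
    x$lambda0, x$lambda_min, x$delta_lambda, x$T, x$T_init))
  if (x$reps_per_level > 1L)
    cat(sprintf("  up to %d window pairs per level%s\n", x$reps_per_level,
                if (!is.null(x$confine))
                  sprintf(", early exit at confinement overlap %.2f", x$confine)
                else ""))
  invisible(x)
}

#' @export
print.dcm_criterion <- function(x, ...) {
  cat(sprintf(
    "Retrieval criterion: chi = %.3g, %d trials, success rate >= %.2f, overlap >= %.2f\n",
    x$chi, x$n_trials, x$success_rate_min, x$overlap_min))
  invisible(x)
}
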