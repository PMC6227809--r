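#' Accumulate time-delayed correlations over a window
#'
#' Runs \code{T} synchronous updates at a fixed field intensity, accumulating
#' the delayed pairwise products \eqn{s_i(t+1) s_j(t)} over the T consecutive
#' step pairs and the single-site activities \eqn{s_i(t+1)} over the T visited
#' states. Returns the normalized averages together with the final state; the
#' network is never reset.
#'
#' @param coup A \code{\link{couplings}} object.
#' @param s Current state vector.
#' @param params \code{\link{dynamics_params}}.
#' @param stimulus Stimulus direction (zero on hidden units).
#' @param lambda Field intensity held fixed during the window.
#' @param T Window length in steps.
#' @param clamp Optional index vector of units frozen at their stimulus value
#'   throughout the window (the infinite-field limit on those units).
#' @param inhibition Optional \code{\link{inhibition_scheme}}.
#' @return An object of class \code{"dcm_corr"}: list with the N x N delayed
#'   correlation matrix \code{C}, magnetizations \code{m}, \code{n_samples},
#'   the field level \code{lambda}, and the final \code{state}.
#' @examples
#' cp <- couplings(6)
#' set.seed(1)
#' w <- accumulate_window(cp, rep(1, 6), dynamics_params(beta = 1),
#'                        stimulus = rep(1, 6), lambda = 1, T = 10)
#' range(w$C)
#' @export
accumulate_window <- function(coup, s, params, stimulus = NULL, lambda = 0,
                              T = 20, clamp = NULL, inhibition = NULL) {
  if (T < 1) stop("`T` must be at least 1", call. = FALSE)
  N <- n_units(coup)
  if (!is.null(clamp)) s[clamp] <- stimulus[clamp]
  C <- matrix(0, N, N)
  m <- numeric(N)
  for (t in seq_len(T)) {
    s2 <- glauber_step(coup, s, params, stimulus, lambda, inhibition)
    if (!is.null(clamp)) s2[clamp] <- stimulus[clamp]
    C <- C + tcrossprod(s2, s)
    m <- m + s2
    s <- s2
  }
  structure(list(C = C / T, m = m / T, n_samples = T, lambda = lambda,
                 state = s),
            class = "dcm_corr")
}

#' Delayed-correlations matching update
#'
#' The core plasticity rule: the couplings are incremented by the difference
#' of the time-delayed correlations recorded at two successive field levels,
#' \deqn{J_{ij} \leftarrow J_{ij} + \eta\,(\langle s_i' s_j\rangle_{\lambda} -
#'       \langle s_i' s_j\rangle_{\lambda - \delta\lambda}),}
#' and the thresholds by the opposite of the magnetization mismatch, so that
#' matched statistics are an exact fixed point of learning. When
#' \code{lp$l2_decay > 0} the couplings are multiplicatively decayed before
#' the increment. The diagonal, any structural zeros, and (if present) the
#' Dale sign constraint are enforced on the result.
#'
#' @param coup A \code{\link{couplings}} object.
#' @param corr_high,corr_low \code{"dcm_corr"} accumulators from the higher
#'   and lower field level of one window.
#' @param lp \code{\link{learning_params}}.
#' @return The updated couplings.
#' @export
dcm_update <- function(coup, corr_high, corr_low, lp) {
  if (!inherits(corr_high, "dcm_corr") || !inherits(corr_low, "dcm_corr"))
    stop("correlation accumulators must come from `accumulate_window()`",
         call. = FALSE)
  if (!all(dim(corr_high$C) == dim(coup$J)) ||
      !all(dim(corr_low$C) == dim(coup$J)))
    stop("accumulator size does not match the couplings", call. = FALSE)
  if (corr_high$lambda <= corr_low$lambda)
    stop("`corr_high` must be recorded at the higher field level", call. = FALSE)
  if (lp$l2_decay > 0) coup$J <- (1 - lp$l2_decay) * coup$J
  coup$J <- coup$J + mask_increment(lp$eta * (corr_high$C - corr_low$C), coup)
  if (lp$update_theta)
    coup$theta <- coup$theta - lp$eta * (corr_high$m - corr_low$m)
  if (!is.null(coup$sign_mask)) coup <- project_dale(coup)
  coup
}

# embed a visible-length pattern into a full stimulus vector (zeros on hidden)
full_stimulus <- function(coup, pattern) {
  N <- n_units(coup)
  if (length(pattern) == N) {
    stim <- pattern
    stim[coup$hidden] <- 0
  } else if (length(pattern) == length(coup$visible)) {
    stim <- numeric(N)
    stim[coup$visible] <- pattern
  } else {
    stop("pattern length matches neither the network nor its visible subset",
         call. = FALSE)
  }
  stim
}

random_state <- function(N, convention) {
  if (convention == "pm1") sample(c(-1, 1), N, replace = TRUE)
  else sample(c(0, 1), N, replace = TRUE)
}

#' Present one pattern with the staircase field protocol
#'
#' Runs the full DCM presentation of a single pattern: \code{T_init}
#' preparation steps at \code{lambda0}, then for each staircase level a window
#' pair (T steps at \eqn{\lambda}, T steps at the lower level) followed by a
#' \code{\link{dcm_update}}, repeating pairs at the same level up to
#' \code{protocol$reps_per_level} times (with early exit once the low phase
#' stays confined on the pattern, see \code{\link{field_protocol}}), until the
#' field reaches \code{lambda_min}. The network state is carried through and
#' never reset.
#'
#' @param coup A \code{\link{couplings}} object.
#' @param pattern Pattern vector (full length or visible-length for hidden
#'   architectures).
#' @param protocol \code{\link{field_protocol}}.
#' @param lp \code{\link{learning_params}}.
#' @param params \code{\link{dynamics_params}}.
#' @param state Current network state; a uniform random state is drawn when
#'   \code{NULL}.
#' @param inhibition Optional \code{\link{inhibition_scheme}}.
#' @return List with the updated \code{couplings}, the final \code{state},
#'   the number of window pairs \code{n_windows}, the total dynamics steps
#'   \code{n_steps}, and \code{window_log}, a data frame with one row per
#'   window (field level, mean absolute coupling change, low-phase overlap
#'   with the pattern).
#' @export
present_pattern <- function(coup, pattern, protocol, lp, params,
                            state = NULL, inhibition = NULL) {
  target <- full_stimulus(coup, pattern)
  stim <- target
  if (protocol$stimulus_center != 0)
    stim[coup$visible] <- stim[coup$visible] - protocol$stimulus_center
  N <- n_units(coup)
  if (is.null(state)) state <- random_state(N, coup$convention)
  n_steps <- 0L
  if (protocol$T_init > 0) {
    state <- run_dynamics(coup, state, params, protocol$T_init, stim,
                          protocol$lambda0, inhibition)$state
    n_steps <- n_steps + protocol$T_init
  }
  vis <- coup$visible
  lam <- protocol$lambda0
  log_lambda <- numeric(0); log_dj <- numeric(0); log_ov <- numeric(0)
  n_windows <- 0L
  while (lam > protocol$lambda_min + 1e-9) {
    lo <- max(lam - protocol$delta_lambda, protocol$lambda_min)
    for (rep in seq_len(protocol$reps_per_level)) {
      ch <- accumulate_window(coup, state, params, stim, lam, protocol$T,
                              inhibition = inhibition)
      cl <- accumulate_window(coup, ch$state, params, stim, lo, protocol$T,
                              inhibition = inhibition)
      state <- cl$state
      J_old <- coup$J
      coup <- dcm_update(coup, ch, cl, lp)
      n_windows <- n_windows + 1L
      n_steps <- n_steps + 2L * protocol$T
      ov <- pattern_overlap(cl$m[vis], target[vis], coup$convention)
      log_lambda <- c(log_lambda, lam)
      log_dj <- c(log_dj, mean(abs(coup$J - J_old)))
      log_ov <- c(log_ov, ov)
      if (!is.null(protocol$confine) && ov >= protocol$confine) break
    }
    lam <- lo
  }
  list(couplings = coup, state = state, n_windows = n_windows,
       n_steps = n_steps,
       window_log = data.frame(lambda = log_lambda, mean_abs_dJ = log_dj,
                               low_phase_overlap = log_ov))
}

#' Cyclic DCM training of a pattern set
#'
#' Presents all patterns in turn with \code{\link{present_pattern}}, cycling
#' through the whole set until every pattern passes the retrieval criterion or
#' \code{max_cycles} is exhausted. The network state persists across
#' presentations and cycles.
#'
#' @inheritParams present_pattern
#' @param patterns A \code{\link{pattern_set}}.
#' @param criterion \code{\link{retrieval_criterion}} used for the
#'   end-of-cycle storage check.
#' @param max_cycles Maximum number of full cycles.
#' @return List with \code{couplings}, \code{cycles_used}, logical
#'   \code{stored} per pattern after the last check, \code{converged}, and
#'   the final \code{state}.
#' @export
train_cyclic <- function(coup, patterns, protocol, lp, params, criterion,
                         max_cycles = 30, state = NULL, inhibition = NULL) {
  if (max_cycles < 1) stop("`max_cycles` must be >= 1", call. = FALSE)
  M <- nrow(patterns$xi)
  if (M == 0)
    return(list(couplings = coup, cycles_used = 0L,
                stored = logical(0), converged = TRUE, state = state))
  if (is.null(state)) state <- random_state(n_units(coup), coup$convention)
  stored <- rep(FALSE, M)
  cycles <- 0L
  for (cyc in seq_len(max_cycles)) {
    for (mu in seq_len(M)) {
      pr <- present_pattern(coup, patterns$xi[mu, ], protocol, lp, params,
                            state, inhibition)
      coup <- pr$couplings
      state <- pr$state
    }
    cycles <- cyc
    stored <- retrieval_test(coup, patterns, criterion, params, inhibition)
    if (all(stored)) break
  }
  list(couplings = coup, cycles_used = cycles, stored = stored,
       converged = all(stored), state = state)
}

#' Pseudo-likelihood (clamped-limit) update
#'
#' One stochastic gradient-ascent step on the log-pseudo-likelihood of a fully
#' visible \code{-1/+1} network evaluated at the clamped pattern:
#' \deqn{\Delta J_{ij} = \eta\,(\xi_i - \tanh\beta h_i(\xi))\,\xi_j, \qquad
#'       \Delta\theta_i = -\eta\,(\xi_i - \tanh\beta h_i(\xi)),}
#' with the fields computed from the clamped configuration at zero external
#' field. This is the infinite-field two-step limit of the delayed-matching
#' rule; in the zero-noise limit it reduces to the perceptron rule.
#'
#' @inheritParams present_pattern
#' @return The updated couplings.
#' @export
pseudolikelihood_update <- function(coup, pattern, lp, params) {
  if (length(coup$hidden) > 0)
    stop("pseudo-likelihood update requires a fully visible network",
         call. = FALSE)
  if (coup$convention != "pm1")
    stop("pseudo-likelihood update is defined for +/-1 units", call. = FALSE)
  if (length(pattern) != n_units(coup))
    stop("pattern length mismatch", call. = FALSE)
  h <- local_fields(coup, pattern)
  resid <- if (params$deterministic) pattern - threshold_update(h, pattern, "pm1")
           else pattern - tanh(params$beta * h)
  if (lp$l2_decay > 0) coup$J <- (1 - lp$l2_decay) * coup$J
  coup$J <- coup$J + mask_increment(lp$eta * tcrossprod(resid, pattern), coup)
  if (lp$update_theta) coup$theta <- coup$theta - lp$eta * resid
  if (!is.null(coup$sign_mask)) coup <- project_dale(coup)
  coup
}

#' Empirical log-pseudo-likelihood of patterns under the one-step dynamics
#'
#' Mean over patterns and units of
#' \eqn{\log P(s_i' = \xi_i \mid s = \xi)}, the conditional probability that
#' one synchronous update reproduces each pattern component from the clamped
#' pattern. Used as the objective that \code{\link{pseudolikelihood_update}}
#' ascends.
#'
#' @param coup \code{\link{couplings}} (fully visible, \code{pm1}).
#' @param patterns \code{\link{pattern_set}}.
#' @param params \code{\link{dynamics_params}}.
#' @return Average log-pseudo-likelihood (non-positive).
#' @export
log_pseudolikelihood <- function(coup, patterns, params) {
  tot <- 0
  M <- nrow(patterns$xi)
  for (mu in seq_len(M)) {
    xi <- patterns$xi[mu, ]
    h <- local_fields(coup, xi)
    tot <- tot + sum(stats::plogis(2 * params$beta * xi * h, log.p = TRUE))
  }
  tot / (M * ncol(patterns$xi))
}
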