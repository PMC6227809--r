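#' Restricted visible-hidden couplings
#'
#' Builds a couplings object for a bipartite (restricted) architecture:
#' synapses exist only between the visible and the hidden population, in both
#' directions and with independent weights (the two directions are not tied,
#' so the kinetic model may be asymmetric). Visible-visible and hidden-hidden
#' blocks are structural zeros preserved by every update.
#'
#' @param n_visible,n_hidden Population sizes.
#' @param convention Coding convention.
#' @return A \code{\link{couplings}} object with \code{visible} set to the
#'   first \code{n_visible} indices.
#' @examples
#' cp <- restricted_couplings(6, 2)
#' sum(cp$struct_mask)
#' @export
restricted_couplings <- function(n_visible, n_hidden,
                                 convention = c("pm1", "zero_one")) {
  convention <- match.arg(convention)
  N <- n_visible + n_hidden
  vis <- seq_len(n_visible)
  mask <- matrix(0, N, N)
  if (n_hidden > 0) {
    hid <- (n_visible + 1):N
    mask[vis, hid] <- 1
    mask[hid, vis] <- 1
  }
  couplings(N, convention, struct_mask = mask, visible = vis)
}

#' Clamped-limit contrastive update for hidden architectures
#'
#' The infinite-field limit of the delayed-matching rule on a restricted
#' architecture, estimated by sampling. Positive phase: the visible units are
#' clamped at the pattern while the hidden units are sampled (a burn-in
#' followed by \code{n_samples} recorded steps of delayed products). Negative
#' phase: a free chain is seeded at the pattern (visible part; hidden part
#' carried over from the positive phase), advanced \code{k_steps} steps with
#' no field, and its delayed products are recorded over \code{n_samples}
#' steps. The couplings move along the difference, restricted to the
#' structurally allowed blocks:
#' \eqn{\Delta J = \eta\,(C^{+} - C^{-})}. With \code{k_steps = 0} the
#' negative chain is not advanced, so its statistics are those of the seed
#' itself.
#'
#' @param coup \code{\link{restricted_couplings}}.
#' @param pattern Visible-length pattern.
#' @param lp \code{\link{learning_params}}.
#' @param params \code{\link{dynamics_params}}.
#' @param k_steps Free-chain steps before recording (the "k" of CD-k).
#' @param burn_in Clamped-phase steps discarded before recording.
#' @param n_samples Recorded steps per phase.
#' @param state Optional starting state.
#' @return List with updated \code{couplings} and final \code{state}.
#' @export
clamped_limit_update <- function(coup, pattern, lp, params, k_steps = 1,
                                 burn_in = 10, n_samples = 10, state = NULL) {
  if (is.null(coup$struct_mask))
    stop("`clamped_limit_update()` expects a restricted architecture",
         call. = FALSE)
  stim <- full_stimulus(coup, pattern)
  N <- n_units(coup)
  if (is.null(state)) state <- random_state(N, coup$convention)
  vis <- coup$visible
  # positive phase: visible clamped at the pattern
  state[vis] <- stim[vis]
  if (burn_in > 0) {
    for (t in seq_len(burn_in)) {
      state <- glauber_step(coup, state, params)
      state[vis] <- stim[vis]
    }
  }
  pos <- accumulate_window(coup, state, params, stimulus = stim, lambda = 0,
                           T = n_samples, clamp = vis)
  # negative phase: free chain seeded at the clamp
  s_neg <- pos$state
  s_neg[vis] <- stim[vis]
  if (k_steps > 0)
    s_neg <- run_dynamics(coup, s_neg, params, k_steps)$state
  neg <- accumulate_window(coup, s_neg, params, lambda = 0, T = n_samples)
  neg$lambda <- -1   # mark as the lower (free) phase
  pos$lambda <- 0
  coup <- dcm_update(coup, pos, neg, lp)
  list(couplings = coup, state = neg$state)
}

#' DCM training with hidden units
#'
#' Applies the staircase-field presentation (\code{\link{present_pattern}})
#' to a restricted visible-hidden architecture: the stimulus acts on the
#' visible units only, delayed correlations are accumulated over the full
#' state, and the updates touch only the structurally allowed blocks.
#'
#' @inheritParams train_cyclic
#' @param cycles Number of passes over the pattern set (no storage check:
#'   hidden-unit training targets the ensemble statistics, not attractor
#'   storage of individual patterns).
#' @return List with \code{couplings} and final \code{state}.
#' @export
dcm_hidden_train <- function(coup, patterns, protocol, lp, params,
                             cycles = 1, state = NULL) {
  if (is.null(state)) state <- random_state(n_units(coup), coup$convention)
  for (cyc in seq_len(cycles)) {
    for (mu in seq_len(nrow(patterns$xi))) {
      pr <- present_pattern(coup, patterns$xi[mu, ], protocol, lp, params,
                            state)
      coup <- pr$couplings
      state <- pr$state
    }
  }
  list(couplings = coup, state = state)
}

#' Sample visible configurations from the free dynamics
#'
#' Runs the free network (no external field) and records the visible part of
#' the state every \code{thin} steps after a burn-in: a generative sample of
#' the model's visible statistics.
#'
#' @param coup \code{\link{couplings}}.
#' @param params \code{\link{dynamics_params}}.
#' @param n_samples Number of recorded configurations.
#' @param burn_in Discarded initial steps.
#' @param thin Steps between recordings.
#' @param state Optional starting state.
#' @return Matrix with one visible configuration per row.
#' @export
sample_visible <- function(coup, params, n_samples, burn_in = 100, thin = 5,
                           state = NULL) {
  N <- n_units(coup)
  if (is.null(state)) state <- random_state(N, coup$convention)
  if (burn_in > 0) state <- run_dynamics(coup, state, params, burn_in)$state
  out <- matrix(NA_real_, n_samples, length(coup$visible))
  for (i in seq_len(n_samples)) {
    state <- run_dynamics(coup, state, params, thin)$state
    out[i, ] <- state[coup$visible]
  }
  out
}
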