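#' Corruption-and-retrieval storage test
#'
#' For every pattern, runs \code{criterion$n_trials} retrieval attempts: the
#' dynamics is initialized at the pattern with a fraction \code{chi} of
#' components flipped, relaxed at zero external field, and the overlap with
#' the pattern is time-averaged over a readout window. The pattern counts as
#' stored when the fraction of attempts reaching
#' \code{criterion$overlap_min} is at least \code{criterion$success_rate_min}.
#' Attempts for one pattern are simulated as parallel replicas.
#'
#' @param coup Trained \code{\link{couplings}}.
#' @param patterns \code{\link{pattern_set}} (full or visible-length
#'   patterns).
#' @param criterion \code{\link{retrieval_criterion}}.
#' @param params \code{\link{dynamics_params}}.
#' @param inhibition Optional \code{\link{inhibition_scheme}} active during
#'   retrieval.
#' @return Logical vector, one entry per pattern.
#' @export
retrieval_test <- function(coup, patterns, criterion, params,
                           inhibition = NULL) {
  M <- nrow(patterns$xi)
  vapply(seq_len(M), function(mu)
    retrieval_test_one(coup, patterns$xi[mu, ], criterion, params, inhibition),
    logical(1))
}

retrieval_test_one <- function(coup, pattern, criterion, params,
                               inhibition = NULL) {
  stim <- full_stimulus(coup, pattern)
  vis <- coup$visible
  target <- stim[vis]
  S <- corrupt(rep(target, length.out = length(vis)), criterion$chi,
               coup$convention, n_copies = criterion$n_trials)
  if (length(coup$hidden) > 0) {
    Sfull <- matrix(random_state(n_units(coup) * criterion$n_trials,
                                 coup$convention),
                    n_units(coup), criterion$n_trials)
    Sfull[vis, ] <- S
    S <- Sfull
  }
  if (!is.null(inhibition)) inhibition <- reset_inhibition(inhibition)
  for (t in seq_len(criterion$relax_steps))
    S <- glauber_step(coup, S, params, inhibition = inhibition)
  ov <- numeric(criterion$n_trials)
  for (t in seq_len(criterion$readout_steps)) {
    S <- glauber_step(coup, S, params, inhibition = inhibition)
    ov <- ov + pattern_overlap(as.matrix(S)[vis, , drop = FALSE], target,
                               coup$convention)
  }
  ov <- ov / criterion$readout_steps
  mean(ov >= criterion$overlap_min) >= criterion$success_rate_min
}

#' Single-step stability of a pattern
#'
#' The lax storage criterion used in online-rule comparisons: a pattern is
#' stable when one zero-temperature synchronous update maps it exactly onto
#' itself (every aligned local field non-negative, ties keeping the state).
#' Much less demanding than the corruption-and-retrieval criterion, which
#' additionally requires a finite basin and persistence under the stochastic
#' dynamics.
#'
#' @param coup \code{\link{couplings}}.
#' @param pattern Pattern vector (visible-length allowed).
#' @return Logical.
#' @export
one_step_stable <- function(coup, pattern) {
  stim <- full_stimulus(coup, pattern)
  vis <- coup$visible
  s <- stim
  h <- local_fields(coup, s)
  s2 <- threshold_update(h, s, coup$convention)
  all(s2[vis] == stim[vis])
}

#' Maximum storage load
#'
#' Estimates the largest storage load \eqn{\alpha = M / N} at which a
#' learning rule embeds a full pattern set so that every pattern passes the
#' retrieval criterion. For each repetition a fresh pattern set is generated
#' at each candidate \code{M} and the largest passing \code{M} is located by
#' integer bisection (storage success is treated as monotone in the load).
#'
#' @param rule One of \code{"hebb"}, \code{"covariance"}, \code{"storkey"},
#'   \code{"dcm"}, or a function \code{function(patterns) -> couplings}.
#' @param N Network size.
#' @param criterion \code{\link{retrieval_criterion}}.
#' @param params \code{\link{dynamics_params}}.
#' @param generator Pattern generator \code{function(N, M) -> pattern_set}.
#' @param protocol,lp,max_cycles DCM training controls (\code{rule = "dcm"});
#'   \code{lp} defaults to \code{learning_params(eta = 1/N)}.
#' @param alpha_range Search bracket for the load.
#' @param n_reps Independent repetitions averaged over.
#' @param inhibition Optional inhibition scheme (training and retrieval).
#' @return List with \code{alpha_max} (mean over repetitions) and
#'   \code{per_rep}.
#' @export
max_storage_load <- function(rule, N, criterion, params,
                             generator = function(N, M) iid_patterns(N, M),
                             protocol = NULL, lp = NULL, max_cycles = 30,
                             alpha_range = c(0.02, 0.5), n_reps = 3,
                             inhibition = NULL) {
  if (is.null(protocol)) protocol <- field_protocol()
  if (is.null(lp)) lp <- learning_params(eta = 1 / N)
  build <- build_rule(rule, protocol, lp, params, criterion, max_cycles,
                      inhibition)
  passes <- function(M) {
    pats <- generator(N, M)
    coup <- build(pats)
    if (is.null(coup)) return(FALSE)       # DCM failed to converge
    all(retrieval_test(coup, pats, criterion, params, inhibition))
  }
  per_rep <- vapply(seq_len(n_reps), function(r) {
    lo <- max(1L, round(alpha_range[1] * N))
    hi <- max(lo + 1L, round(alpha_range[2] * N))
    if (!passes(lo)) return(0)
    if (passes(hi)) return(hi / N)
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (passes(mid)) lo <- mid else hi <- mid
    }
    lo / N
  }, numeric(1))
  list(alpha_max = mean(per_rep), per_rep = per_rep)
}

build_rule <- function(rule, protocol, lp, params, criterion, max_cycles,
                       inhibition) {
  if (is.function(rule)) return(rule)
  switch(rule,
    hebb = function(pats) hebb_couplings(pats),
    covariance = function(pats) generalized_hebb_couplings(pats),
    storkey = function(pats) storkey_couplings(pats),
    dcm = function(pats) {
      coup <- couplings(ncol(pats$xi), pats$convention)
      fit <- train_cyclic(coup, pats, protocol, lp, params, criterion,
                          max_cycles, inhibition = inhibition)
      if (fit$converged) fit$couplings else NULL
    },
    stop("unknown rule: ", rule, call. = FALSE))
}

#' Census of spurious attractors
#'
#' Launches independent random walks of the free dynamics from uniformly
#' random initial states, reads out the time-averaged state over the last
#' \code{readout} steps, binarizes it, and collects the distinct terminal
#' states that are genuine fixed points of the zero-temperature dynamics but
#' do not match any stored pattern (nor, for \code{-1/+1} networks, a global
#' flip of one) within \code{match_overlap}. Limit cycles of the synchronous
#' dynamics binarize to non-fixed points and are excluded from the census
#' (reported separately).
#'
#' @param coup Trained \code{\link{couplings}}.
#' @param patterns The stored \code{\link{pattern_set}}.
#' @param n_walks Number of random walks.
#' @param walk_len Steps per walk (including the readout window).
#' @param params \code{\link{dynamics_params}}.
#' @param readout Steps averaged for the terminal readout.
#' @param match_overlap Overlap above which a terminal state counts as a
#'   stored memory.
#' @param batch Walks simulated simultaneously.
#' @return List with \code{n_spurious} (distinct spurious attractors),
#'   \code{spurious} (matrix, one per row), \code{n_matched} and
#'   \code{n_unconverged} walk counts.
#' @export
spurious_census <- function(coup, patterns, n_walks, walk_len, params,
                            readout = 20, match_overlap = 0.9, batch = 512) {
  N <- n_units(coup)
  if (n_walks < 1)
    return(list(n_spurious = 0L, spurious = matrix(0, 0, N),
                n_matched = 0L, n_unconverged = 0L))
  readout <- min(readout, walk_len)
  det <- dynamics_params(beta = params$beta, deterministic = TRUE)
  seen <- character(0)
  spurious <- list()
  n_matched <- 0L
  n_unconv <- 0L
  left <- n_walks
  while (left > 0) {
    K <- min(batch, left)
    left <- left - K
    S <- matrix(random_state(N * K, coup$convention), N, K)
    for (t in seq_len(walk_len - readout))
      S <- glauber_step(coup, S, params)
    acc <- matrix(0, N, K)
    for (t in seq_len(readout)) {
      S <- glauber_step(coup, S, params)
      acc <- acc + S
    }
    acc <- acc / readout
    B <- if (coup$convention == "pm1") ifelse(acc >= 0, 1, -1)
         else ifelse(acc >= 0.5, 1, 0)
    # genuine fixed points of the deterministic dynamics only
    fixed <- colSums(threshold_update(coup$J %*% B - coup$theta, B,
                                      coup$convention) == B) == N
    n_unconv <- n_unconv + sum(!fixed)
    if (!any(fixed)) next
    B <- B[, fixed, drop = FALSE]
    ov <- patterns$xi %*% B / N
    if (coup$convention == "pm1") {
      matched <- apply(abs(ov), 2, max) >= match_overlap
    } else {
      f <- rowMeans(patterns$xi)
      cov <- (patterns$xi - f) %*% B
      ovc <- sweep(cov, 1, N * f * (1 - f), `/`)
      matched <- apply(ovc, 2, max) >= match_overlap
    }
    n_matched <- n_matched + sum(matched)
    for (j in which(!matched)) {
      key <- paste(B[, j], collapse = "")
      if (!key %in% seen) {
        seen <- c(seen, key)
        spurious[[length(spurious) + 1L]] <- B[, j]
      }
    }
  }
  list(n_spurious = length(spurious),
       spurious = if (length(spurious)) do.call(rbind, spurious)
                  else matrix(0, 0, N),
       n_matched = n_matched, n_unconverged = n_unconv)
}

#' One-shot palimpsest capacity
#'
#' Presents a stream of fresh patterns, each learned once (repeating its
#' presentation at most \code{max_present} times until it passes the
#' retrieval criterion) and never seen again. With the one-shot protocol
#' (small positive terminal field, weight decay) the network enters a steady
#' state in which an old memory is lost whenever a new one is carved; the
#' palimpsest capacity is the steady-state number of still-retrievable
#' memories, averaged over the tail of the stream. The same runs are also
#' scored with the lax \code{\link{one_step_stable}} criterion.
#'
#' The couplings start from a weak random (glassy) background of scale
#' \code{J0_sd / sqrt(N)}, which removes the pathological cold-start regime
#' in which the very first memories are each other's only escape routes.
#'
#' @param N Network size.
#' @param n_stream Number of patterns presented (choose of order \code{N}
#'   to resolve the steady state).
#' @param params \code{\link{dynamics_params}}; default
#'   \code{dynamics_params(beta = 3)}.
#' @param protocol One-shot \code{\link{field_protocol}}; default
#'   \code{field_protocol(T = 60, lambda_min = 0.05, reps_per_level = 5,
#'   confine = 0.85)}.
#' @param lp \code{\link{learning_params}}; default
#'   \code{learning_params(eta = 3 / N, l2_decay = 0.001)}.
#' @param criterion \code{\link{retrieval_criterion}}.
#' @param max_present Presentation repetitions allowed per pattern.
#' @param J0_sd Scale of the initial random couplings.
#' @param tail_frac Final fraction of the stream over which capacities are
#'   averaged.
#' @param generator Pattern generator \code{function(N, M)}.
#' @return List with \code{capacity} and \code{capacity_per_neuron} (strict
#'   criterion), \code{onestep_capacity} and
#'   \code{onestep_capacity_per_neuron}, the final \code{couplings}, and a
#'   per-checkpoint data frame \code{tail_counts}.
#' @export
palimpsest_capacity <- function(N, n_stream, params = NULL, protocol = NULL,
                                lp = NULL, criterion = retrieval_criterion(),
                                max_present = 8, J0_sd = 0.3,
                                tail_frac = 0.45,
                                generator = function(N, M) iid_patterns(N, M)) {
  if (is.null(params)) params <- dynamics_params(beta = 3)
  if (is.null(protocol))
    protocol <- field_protocol(T = 60, lambda_min = 0.05,
                               reps_per_level = 5, confine = 0.85)
  if (is.null(lp)) lp <- learning_params(eta = 3 / N, l2_decay = 0.001)
  pats <- generator(N, n_stream)
  J0 <- matrix(stats::rnorm(N * N, 0, J0_sd / sqrt(N)), N, N)
  coup <- couplings(N, pats$convention, J = J0)
  state <- random_state(N, coup$convention)
  tail_start <- ceiling((1 - tail_frac) * n_stream)
  idx <- integer(0); strict <- integer(0); lax <- integer(0)
  reps_used <- integer(n_stream)
  for (mu in seq_len(n_stream)) {
    for (rep in seq_len(max_present)) {
      pr <- present_pattern(coup, pats$xi[mu, ], protocol, lp, params, state)
      coup <- pr$couplings
      state <- pr$state
      if (retrieval_test_one(coup, pats$xi[mu, ], criterion, params)) break
    }
    reps_used[mu] <- rep
    if (mu >= tail_start) {
      prev <- pattern_set(pats$xi[seq_len(mu), , drop = FALSE],
                          pats$convention)
      idx <- c(idx, mu)
      strict <- c(strict,
                  sum(retrieval_test(coup, prev, criterion, params)))
      lax <- c(lax, sum(vapply(seq_len(mu), function(v)
        one_step_stable(coup, pats$xi[v, ]), logical(1))))
    }
  }
  list(capacity = mean(strict), capacity_per_neuron = mean(strict) / N,
       onestep_capacity = mean(lax),
       onestep_capacity_per_neuron = mean(lax) / N,
       couplings = coup,
       tail_counts = data.frame(presented = idx, retrievable = strict,
                                one_step_stable = lax),
       reps_used = reps_used)
}
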