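test_that("restricted architectures keep forbidden blocks at zero", {
  rc <- restricted_couplings(6, 3)
  vis <- 1:6; hid <- 7:9
  expect_true(all(rc$struct_mask[vis, vis] == 0))
  expect_true(all(rc$struct_mask[hid, hid] == 0))
  expect_true(all(rc$struct_mask[vis, hid] == 1))
  pars <- dynamics_params(beta = 1)
  lp <- learning_params(eta = 0.1)
  xi <- iid_patterns(6, 1, seed = 1)$xi[1, ]
  set.seed(2)
  up <- clamped_limit_update(rc, xi, lp, pars)
  expect_true(all(up$couplings$J[rc$struct_mask == 0] == 0))
  expect_gt(sum(abs(up$couplings$J)), 0)
  # visible-visible update attempts are structurally impossible:
  # a network with no hidden units stays empty under the window protocol
  rc0 <- restricted_couplings(6, 0)
  set.seed(3)
  pr <- present_pattern(rc0, xi, field_protocol(T = 3, T_init = 2),
                        lp, pars)
  expect_identical(pr$couplings$J, rc0$J)
})

test_that("contrastive update has zero mean when phases match by construction", {
  # J = 0: positive-phase hidden units are unbiased coins, the negative chain
  # is seeded at the clamp; the expected increment vanishes
  set.seed(4)
  rc <- restricted_couplings(5, 3)
  pars <- dynamics_params(beta = 1)
  lp <- learning_params(eta = 1)           # raw correlation difference
  xi <- iid_patterns(5, 1, seed = 5)$xi[1, ]
  R <- 200
  acc <- matrix(0, 8, 8)
  for (r in seq_len(R)) {
    up <- clamped_limit_update(restricted_couplings(5, 3), xi, lp, pars,
                               k_steps = 0, burn_in = 5, n_samples = 4)
    acc <- acc + up$couplings$J
  }
  # mean increment per allowed synapse ~ N(0, sd/sqrt(R)); 4 sd tolerance
  expect_lt(max(abs(acc / R)), 4 * 0.5 / sqrt(4 * R) + 0.05)
})

test_that("expected contrastive increment matches the exact two-phase difference", {
  # tiny restricted network where both phases are exactly computable by
  # enumerating the Markov chain; Monte-Carlo mean of the update must agree
  nv <- 3; nh <- 2; N <- nv + nh
  set.seed(6)
  rc <- restricted_couplings(nv, nh)
  J <- matrix(0, N, N)
  J[1:nv, (nv + 1):N] <- rnorm(nv * nh, sd = 0.4)
  J[(nv + 1):N, 1:nv] <- rnorm(nv * nh, sd = 0.4)
  rc$J <- J
  beta <- 0.7
  pars <- dynamics_params(beta = beta)
  xi <- c(1, -1, 1)
  s0 <- c(xi, 1, -1)
  n_samp <- 3
  mexp <- function(s, clamped) {
    m <- tanh(beta * (drop(J %*% s)))
    if (clamped) m[1:nv] <- xi
    m
  }
  # exact positive phase: hidden chain with visible clamped, from s0
  hid_states <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  Cpos <- matrix(0, N, N); P <- c(0, 0, 0, 0)
  P[which(apply(hid_states, 1, function(h) all(h == s0[4:5])))] <- 1
  dist_end <- NULL
  for (t in seq_len(n_samp)) {
    Cstep <- matrix(0, N, N); Pn <- numeric(4)
    for (a in 1:4) {
      s <- c(xi, hid_states[a, ])
      m <- mexp(s, clamped = TRUE)
      Cstep <- Cstep + P[a] * tcrossprod(m, s)
      ph <- (1 + tanh(beta * drop(J %*% s)[4:5])) / 2
      for (b in 1:4)
        Pn[b] <- Pn[b] + P[a] *
          prod(ifelse(hid_states[b, ] == 1, ph, 1 - ph))
    }
    Cpos <- Cpos + Cstep / n_samp
    P <- Pn
  }
  # exact negative phase: free chain seeded at (xi, hidden from positive end)
  full_states <- as.matrix(expand.grid(rep(list(c(-1, 1)), N)))
  Pf <- numeric(2^N)
  for (a in 1:4) {
    s <- c(xi, hid_states[a, ])
    idx <- which(apply(full_states, 1, function(r) all(r == s)))
    Pf[idx] <- Pf[idx] + P[a]
  }
  step_free <- function(Pf) {
    Pn <- numeric(2^N)
    for (a in which(Pf > 0)) {
      pu <- (1 + tanh(beta * drop(J %*% full_states[a, ]))) / 2
      for (b in seq_len(2^N))
        Pn[b] <- Pn[b] + Pf[a] *
          prod(ifelse(full_states[b, ] == 1, pu, 1 - pu))
    }
    Pn
  }
  Pf <- step_free(Pf)                      # k_steps = 1
  Cneg <- matrix(0, N, N)
  for (t in seq_len(n_samp)) {
    Cstep <- matrix(0, N, N)
    for (a in which(Pf > 0)) {
      s <- full_states[a, ]
      Cstep <- Cstep + Pf[a] * tcrossprod(mexp(s, FALSE), s)
    }
    Cneg <- Cneg + Cstep / n_samp
    Pf <- step_free(Pf)
  }
  exact <- (Cpos - Cneg) * rc$struct_mask
  # Monte-Carlo estimate through the implementation
  R <- 400
  lp <- learning_params(eta = 1, update_theta = FALSE)
  acc <- matrix(0, N, N)
  set.seed(7)
  for (r in seq_len(R)) {
    up <- clamped_limit_update(rc, xi, lp, pars, k_steps = 1, burn_in = 0,
                               n_samples = n_samp, state = s0)
    acc <- acc + (up$couplings$J - rc$J)
  }
  mc <- acc / R
  se <- 1 / sqrt(n_samp * R)               # product terms bounded by 1
  expect_lt(max(abs(mc - exact)[rc$struct_mask == 1]), 5 * se + 0.02)
})

test_that("hidden-unit training shapes the visible statistics toward the ensemble", {
  set.seed(31)
  nv <- 30; nh <- 4
  proto_mat <- matrix(sample(c(-1, 1), 2 * nv, replace = TRUE), 2, nv)
  pats <- pattern_set(proto_mat[rep(1:2, 10), ], "pm1")
  pars <- dynamics_params(beta = 2)
  lp <- learning_params(eta = 2 / (nv + nh))
  proto_ov <- function(S) mean(apply(abs(S %*% t(proto_mat)) / nv, 1, max))
  cp0 <- restricted_couplings(nv, nh)
  s_before <- sample_visible(cp0, pars, 150)
  fit <- dcm_hidden_train(cp0, pats, field_protocol(T = 20), lp, pars,
                          cycles = 3)
  s_after <- sample_visible(fit$couplings, pars, 150)
  expect_gt(proto_ov(s_after), proto_ov(s_before) + 0.2)
  # free samples' pairwise correlations move toward the ensemble's
  ens <- crossprod(pats$xi) / nrow(pats$xi)
  dist <- function(S) norm(crossprod(S) / nrow(S) - ens, "F")
  expect_lt(dist(s_after), dist(s_before))
  expect_true(all(fit$couplings$J[cp0$struct_mask == 0] == 0))
})
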