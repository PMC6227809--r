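test_that("window accumulators average delayed products correctly", {
  N <- 12
  pars <- dynamics_params(beta = 2)
  xi <- iid_patterns(N, 1, seed = 1)$xi[1, ]
  cp <- couplings(N)
  # clamped trajectory: correlations are exactly the pattern outer product
  w <- accumulate_window(cp, xi, pars, stimulus = xi, lambda = 0, T = 7,
                         clamp = seq_len(N))
  expect_equal(w$C, tcrossprod(xi))
  expect_equal(w$m, xi)
  expect_equal(w$n_samples, 7)
  # T = 1: a single outer product of consecutive states
  set.seed(4)
  s0 <- sample(c(-1, 1), N, replace = TRUE)
  set.seed(5)
  w1 <- accumulate_window(cp, s0, pars, T = 1)
  set.seed(5)
  s1 <- glauber_step(cp, s0, pars)
  expect_equal(w1$C, tcrossprod(s1, s0))
  # free fair-coin units decorrelate: entries vanish like 1/sqrt(T)
  set.seed(6)
  wf <- accumulate_window(cp, s0, pars, T = 400)
  expect_lt(max(abs(wf$C)), 4 / sqrt(400))
})

test_that("matched correlations are an exact fixed point of the update", {
  N <- 10
  set.seed(2)
  J <- matrix(rnorm(N * N, sd = 0.1), N); diag(J) <- 0
  cp <- couplings(N, J = J, theta = rnorm(N, sd = 0.1))
  pars <- dynamics_params(beta = 2)
  set.seed(3)
  w1 <- accumulate_window(cp, rep(1, N), pars, T = 5)
  w2 <- w1
  w2$lambda <- -0.5           # lower level, identical statistics
  lp <- learning_params(eta = 0.1)
  out <- dcm_update(cp, w1, w2, lp)
  expect_identical(out$J, cp$J)
  expect_identical(out$theta, cp$theta)
  # eta = 0 is the identity even for mismatched accumulators
  set.seed(9)
  w3 <- accumulate_window(cp, rep(-1, N), pars, T = 5)
  w3$lambda <- -0.5
  out0 <- dcm_update(cp, w1, w3, learning_params(eta = 0))
  expect_identical(out0$J, cp$J)
  # sign contract: positive correlation difference potentiates
  outp <- dcm_update(cp, w1, w3, lp)
  dC <- w1$C - w3$C; diag(dC) <- 0
  expect_true(all(sign(outp$J - cp$J)[dC != 0] == sign(dC)[dC != 0]))
  # weight decay is applied multiplicatively before the increment
  lpd <- learning_params(eta = 0.1, l2_decay = 0.02)
  outd <- dcm_update(cp, w1, w3, lpd)
  ref <- 0.98 * cp$J + 0.1 * dC
  expect_equal(outd$J, ref)
})

test_that("a degenerate staircase presents without updating", {
  N <- 20
  cp <- couplings(N)
  proto <- field_protocol(lambda0 = 1, lambda_min = 1, T_init = 5)
  xi <- iid_patterns(N, 1, seed = 3)$xi[1, ]
  set.seed(1)
  pr <- present_pattern(cp, xi, proto, learning_params(eta = 0.1),
                        dynamics_params(beta = 2))
  expect_equal(pr$n_windows, 0)
  expect_identical(pr$couplings$J, cp$J)
  expect_equal(pr$n_steps, 5)
})

test_that("presentation bookkeeping counts preparation and window steps", {
  N <- 30
  proto <- field_protocol(lambda0 = 1, delta_lambda = 0.25, T = 7, T_init = 13)
  xi <- iid_patterns(N, 1, seed = 4)$xi[1, ]
  set.seed(2)
  pr <- present_pattern(couplings(N), xi, proto, learning_params(eta = 1 / N),
                        dynamics_params(beta = 5))
  expect_equal(pr$n_windows, 4)              # 1 -> 0.75 -> 0.5 -> 0.25 -> 0
  expect_equal(pr$n_steps, 13 + 2 * 7 * 4)
  expect_equal(nrow(pr$window_log), 4)
})

test_that("one staircase presentation stores a single pattern", {
  N <- 100
  xi <- iid_patterns(N, 1, seed = 5)$xi[1, ]
  pars <- dynamics_params(beta = 10)
  set.seed(6)
  pr <- present_pattern(couplings(N), xi, field_protocol(),
                        learning_params(eta = 1 / N), pars)
  expect_true(dcmnet:::retrieval_test_one(pr$couplings, xi, quick_criterion(),
                                          pars))
  # learned couplings are asymmetric (unlike the Hebbian baselines)
  J <- pr$couplings$J
  expect_gt(sum(abs(J - t(J))), 0)
})

test_that("cyclic training stores an extensive set and is seed-deterministic", {
  N <- 80
  pats <- iid_patterns(N, 6, seed = 7)
  pars <- dynamics_params(beta = 10)
  crit <- quick_criterion()
  lp <- learning_params(eta = 1 / N)
  set.seed(8)
  fit <- train_cyclic(couplings(N), pats, field_protocol(), lp, pars, crit,
                      max_cycles = 15)
  expect_true(fit$converged)
  set.seed(8)
  fit2 <- train_cyclic(couplings(N), pats, field_protocol(), lp, pars, crit,
                       max_cycles = 15)
  expect_identical(fit$couplings$J, fit2$couplings$J)
  # empty pattern set: nothing happens
  empty <- pattern_set(matrix(numeric(0), 0, N))
  fit0 <- train_cyclic(couplings(N), empty, field_protocol(), lp, pars, crit)
  expect_equal(fit0$cycles_used, 0)
  expect_identical(fit0$couplings$J, couplings(N)$J)
})

test_that("pseudo-likelihood update reduces to Hebb at zero couplings", {
  N <- 15
  xi <- iid_patterns(N, 1, seed = 9)$xi[1, ]
  lp <- learning_params(eta = 0.05)
  out <- pseudolikelihood_update(couplings(N), xi, lp, dynamics_params(beta = 2))
  ref <- 0.05 * tcrossprod(xi); diag(ref) <- 0
  expect_equal(out$J, ref)             # tanh(0) = 0: pure Hebbian step
  expect_equal(out$theta, -0.05 * xi)
  # saturated margins give a vanishing update
  strong <- couplings(N, J = 3 * tcrossprod(xi) / N - diag(3 / N, N))
  out2 <- pseudolikelihood_update(strong, xi, lp, dynamics_params(beta = 20))
  expect_lt(max(abs(out2$J - strong$J)), 1e-10)
})

test_that("zero-noise pseudo-likelihood limit is bit-equivalent to the perceptron rule", {
  N <- 25
  set.seed(10)
  J <- matrix(rnorm(N * N, sd = 0.2), N); diag(J) <- 0
  theta <- rnorm(N, sd = 0.1)
  lp <- learning_params(eta = 0.05)
  det <- dynamics_params(beta = 4, deterministic = TRUE)
  pats <- iid_patterns(N, 4, seed = 11)
  cp <- couplings(N, J = J, theta = theta)
  Jp <- J; tp <- theta
  for (mu in 1:4) {
    cp <- pseudolikelihood_update(cp, pats$xi[mu, ], lp, det)
    # independent oracle (factor 2 of the error term carried explicitly)
    or <- perceptron_step(Jp, tp, pats$xi[mu, ], eta = 0.05)
    Jp <- or$J; tp <- or$theta
  }
  expect_identical(cp$J, Jp)
  expect_identical(cp$theta, tp)
})

test_that("repeated pseudo-likelihood steps ascend the objective", {
  N <- 10
  pats <- iid_patterns(N, 3, seed = 12)
  pars <- dynamics_params(beta = 1)
  lp <- learning_params(eta = 0.05)
  cp <- couplings(N)
  ll0 <- log_pseudolikelihood(cp, pats, pars)
  for (it in 1:30) for (mu in 1:3)
    cp <- pseudolikelihood_update(cp, pats$xi[mu, ], lp, pars)
  expect_gt(log_pseudolikelihood(cp, pats, pars), ll0)
})
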