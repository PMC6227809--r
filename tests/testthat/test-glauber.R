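test_that("local fields combine recurrent input, stimulus and thresholds", {
  N <- 6
  xi <- c(1, -1, 1, -1, 1, -1)
  # no couplings: field is the scaled stimulus
  cp <- couplings(N)
  expect_equal(local_fields(cp, rep(1, N), stimulus = xi, lambda = 2), 2 * xi)
  # direct sum of recurrent contributions
  cp2 <- couplings(2, J = matrix(c(0, 1, 1, 0), 2))
  expect_equal(local_fields(cp2, c(1, 1)), c(1, 1))
  # thresholds equal to the recurrent input cancel it exactly
  set.seed(1)
  J <- matrix(rnorm(N * N), N); diag(J) <- 0
  s <- sample(c(-1, 1), N, replace = TRUE)
  cp3 <- couplings(N, J = J, theta = drop(J %*% s))
  expect_equal(local_fields(cp3, s), rep(0, N))
  expect_error(local_fields(cp, rep(1, 3)), "state length")
})

test_that("update probabilities follow the closed-form sigmoid", {
  # pm1: P(+1) = e^{beta h} / (2 cosh(beta h)); zero field is exactly 1/2
  expect_equal(dcmnet:::up_probability(0, beta = 7, "pm1"), 0.5)
  expect_equal(dcmnet:::up_probability(1, beta = 1, "pm1"),
               exp(1) / (exp(1) + exp(-1)), tolerance = 1e-12)
  expect_equal(dcmnet:::up_probability(1, beta = 1, "pm1"), 0.88080,
               tolerance = 1e-4)
  # normalization is exact: P(+1) + P(-1) = 1, even at saturating fields
  hs <- seq(-30, 30, length.out = 101)
  expect_equal(dcmnet:::up_probability(hs, 2, "pm1") +
                 dcmnet:::up_probability(-hs, 2, "pm1"), rep(1, 101))
  # strictly increasing in h (away from double-precision saturation)
  h <- seq(-4, 4, length.out = 101)
  p <- dcmnet:::up_probability(h, 2, "pm1")
  expect_true(all(diff(p) > 0))
  expect_true(all(dcmnet:::up_probability(1, c(1, 2, 4), "pm1") ==
                    cummax(dcmnet:::up_probability(1, c(1, 2, 4), "pm1"))))
  # 0/1 convention: logistic sigmoid of beta h
  expect_equal(dcmnet:::up_probability(2, beta = 1.5, "zero_one"),
               plogis(3))
  # extreme fields neither overflow nor leave [0, 1]
  expect_equal(dcmnet:::up_probability(c(-1e6, 1e6), 10, "pm1"), c(0, 1))
})

test_that("empirical single-step frequencies match the analytic sigmoid", {
  set.seed(42)
  N <- 2000
  beta <- 1.3
  h0 <- 0.4
  cp <- couplings(N, theta = rep(-h0, N))    # uniform field h0 via thresholds
  s <- glauber_step(cp, rep(1, N), dynamics_params(beta = beta))
  p_hat <- mean(s == 1)
  p <- dcmnet:::up_probability(h0, beta, "pm1")
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / N))
})

test_that("deterministic limit thresholds fields and keeps state on ties", {
  cp <- couplings(3, theta = c(-1, 1, 0))    # fields: +1, -1, 0
  det <- dynamics_params(beta = 5, deterministic = TRUE)
  s <- c(-1, 1, -1)
  expect_equal(glauber_step(cp, s, det), c(1, -1, -1))
  s2 <- c(-1, 1, 1)
  expect_equal(glauber_step(cp, s2, det)[3], 1)   # tie keeps previous state
})

test_that("trajectories are reproducible and respect fixed points", {
  set.seed(3)
  N <- 40
  pats <- iid_patterns(N, 1, seed = 9)
  cp <- hebb_couplings(pats)
  det <- dynamics_params(beta = 1, deterministic = TRUE)
  # a stored pattern is a fixed point: the trajectory is constant
  tr <- run_dynamics(cp, pats$xi[1, ], det, n_steps = 5, record = TRUE)
  expect_true(all(apply(tr$trajectory, 1, identical, y = pats$xi[1, ])))
  # same seed gives bit-identical stochastic trajectories
  pars <- dynamics_params(beta = 1)
  set.seed(11); t1 <- run_dynamics(cp, pats$xi[1, ], pars, 20, record = TRUE)
  set.seed(11); t2 <- run_dynamics(cp, pats$xi[1, ], pars, 20, record = TRUE)
  expect_identical(t1$trajectory, t2$trajectory)
  expect_error(run_dynamics(cp, pats$xi[1, ], pars, 0), "n_steps")
})

test_that("exhaustive fixed-point enumeration finds memories and mixtures", {
  # degenerate network: zero fields everywhere, tie rule fixes every state
  expect_equal(nrow(enumerate_attractors(couplings(4))), 16)
  # one Hebbian pattern: the pattern and its flip are fixed points
  p1 <- iid_patterns(8, 1, seed = 2)
  fx <- enumerate_attractors(hebb_couplings(p1))
  has_state <- function(fx, s) any(apply(fx, 1, function(r) all(r == s)))
  expect_true(has_state(fx, p1$xi[1, ]))
  expect_true(has_state(fx, -p1$xi[1, ]))
  # three patterns: the symmetric mixture appears among the fixed points
  p3 <- iid_patterns(12, 3, seed = 2)
  fx3 <- enumerate_attractors(hebb_couplings(p3))
  mix <- sign(colSums(p3$xi))
  expect_true(has_state(fx3, mix))
  expect_error(enumerate_attractors(couplings(20)), "refusing")
})

test_that("long-run state distribution matches the exact Markov chain", {
  # N = 3 units: build the 8-state transition matrix explicitly and compare
  # its stationary distribution with empirical occupation frequencies
  set.seed(8)
  N <- 3
  J <- matrix(rnorm(9, sd = 0.6), 3); diag(J) <- 0
  cp <- couplings(N, J = J, theta = rnorm(3, sd = 0.2))
  beta <- 1
  states <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  P <- matrix(0, 8, 8)
  for (a in 1:8) {
    p_up <- dcmnet:::up_probability(local_fields(cp, states[a, ]), beta, "pm1")
    for (b in 1:8)
      P[a, b] <- prod(ifelse(states[b, ] == 1, p_up, 1 - p_up))
  }
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  # empirical occupation over a long run
  pars <- dynamics_params(beta = beta)
  s <- states[1, ]
  counts <- numeric(8)
  key <- function(s) sum((s + 1) / 2 * c(1, 2, 4)) + 1
  for (t in 1:30000) {
    s <- glauber_step(cp, s, pars)
    counts[key(s)] <- counts[key(s)] + 1
  }
  expect_lt(max(abs(counts / 30000 - stat)), 0.02)
})
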