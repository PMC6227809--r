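# shared fixtures: built in code, deterministic via explicit seeds

quick_criterion <- function(chi = 0.1, n_trials = 5, success_rate_min = 0.8) {
  retrieval_criterion(chi = chi, n_trials = n_trials,
                      success_rate_min = success_rate_min)
}

# deterministic zero-temperature update of a raw state vector
det_step <- function(coup, s) {
  h <- local_fields(coup, s)
  out <- s
  out[h > 0] <- 1
  out[h < 0] <- if (coup$convention == "pm1") -1 else 0
  out
}

# direct perceptron rule: independent oracle for the zero-noise limit of the
# pseudo-likelihood update (error-driven Hebbian increments)
perceptron_step <- function(J, theta, xi, eta) {
  h <- drop(J %*% xi) - theta
  pred <- ifelse(h > 0, 1, ifelse(h < 0, -1, xi))
  err <- xi - pred                       # 0 or +/-2 on error units
  dJ <- eta * tcrossprod(err, xi)
  diag(dJ) <- 0
  list(J = J + dJ, theta = theta - eta * err)
}
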