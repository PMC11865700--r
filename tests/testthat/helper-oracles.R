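# Independent brute-force oracles, deliberately coded in the most literal
# form (explicit products/sums over risk sets), separate from the package's
# vectorized implementations.

# Product-form negative log partial likelihood (Breslow for ties):
# for every event i, a factor exp(eta_i) / sum_{l: t_l >= t_i} exp(eta_l).
oracle_cox_nll <- function(beta, time, delta, X) {
  eta <- drop(as.matrix(X) %*% beta)
  nll <- 0
  for (i in seq_along(time)) {
    if (delta[i] == 1) {
      risk <- which(time >= time[i])
      nll <- nll - (eta[i] - log(sum(exp(eta[risk]))))
    }
  }
  nll
}

# Central finite differences of the oracle NLL.
oracle_cox_gradient <- function(beta, time, delta, X, h = 1e-6) {
  vapply(seq_along(beta), function(j) {
    e <- numeric(length(beta)); e[j] <- h
    (oracle_cox_nll(beta + e, time, delta, X) -
       oracle_cox_nll(beta - e, time, delta, X)) / (2 * h)
  }, numeric(1))
}

# Small random single-cause survival instance (exponential times + censoring).
random_surv_instance <- function(n = 30, p = 3, seed = NULL,
                                 beta = NULL, tie_prob = 0) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) beta <- rnorm(p, sd = 0.5)
  tt <- -log(runif(n)) / (0.3 * exp(drop(X %*% beta)))
  cc <- -log(runif(n)) / 0.2
  time <- pmin(tt, cc)
  if (tie_prob > 0) time <- round(time, 1) + 0.05  # induce ties, keep > 0
  status <- as.integer(tt <= cc)
  list(time = time, status = status, X = X, beta_gen = beta,
       data = survival_dataset(time, status, X),
       view = cause_view(survival_dataset(time, status, X), 1))
}

# Small competing-risks instance with effects on both causes.
random_cr_instance <- function(n = 120, p = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  b1 <- c(1, 0.5, rep(0, p - 2))
  b2 <- c(1, 0, -0.5, rep(0, p - 3))
  t1 <- -log(runif(n)) / (0.2 * exp(drop(X %*% b1)))
  t2 <- -log(runif(n)) / (0.2 * exp(drop(X %*% b2)))
  cc <- -log(runif(n)) / 0.1
  time <- pmin(t1, t2, cc)
  status <- ifelse(t1 <= t2 & t1 <= cc, 1L, ifelse(t2 <= cc, 2L, 0L))
  list(data = survival_dataset(time, status, X), beta1 = b1, beta2 = b2)
}

# Eq.-4 weights computed literally, for cross-checking weight_vector().
oracle_weights <- function(z, theta) {
  sapply(seq_along(z), function(j)
    sum(exp(z * theta)) / (length(z) * exp(z[j] * theta)))
}
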