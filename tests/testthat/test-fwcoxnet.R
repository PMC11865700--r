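make_fw_instance <- function(seed = 1, n = 150, p = 20) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(1, -0.8, 0.6, rep(0, p - 3))
  tt <- -log(runif(n)) / (0.25 * exp(drop(X %*% beta)))
  cc <- -log(runif(n)) / 0.15
  ds <- survival_dataset(pmin(tt, cc), as.integer(tt <= cc), X)
  list(view = cause_view(ds, 1), X = X, beta = beta)
}

test_that("zero prior scores collapse to the plain elastic net fit", {
  inst <- make_fw_instance(2)
  cfg <- penalty_config(nfolds = 5, seed = 42)
  plain <- fit_fwcoxnet(inst$view, inst$X, z = NULL, config = cfg)
  zed <- fit_fwcoxnet(inst$view, inst$X, z = rep(0, 20), config = cfg)
  expect_equal(zed$beta, plain$beta, tolerance = 1e-6)
  expect_identical(zed$lambda_selected, plain$lambda_selected)
  expect_identical(zed$folds, plain$folds)
})

test_that("cross-validated fit is deterministic given a seed", {
  inst <- make_fw_instance(3)
  cfg <- penalty_config(nfolds = 5, seed = 7)
  z <- abs(inst$beta)
  f1 <- fit_fwcoxnet(inst$view, inst$X, z = z, config = cfg)
  f2 <- fit_fwcoxnet(inst$view, inst$X, z = z, config = cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$cv_loglik, f2$cv_loglik)
  expect_identical(f1$theta, f2$theta)
})

test_that("objective trace is nonincreasing over alternations", {
  inst <- make_fw_instance(4)
  cfg <- penalty_config(nfolds = 5, seed = 1)
  z <- abs(inst$beta) + abs(rnorm(20, sd = 0.05))
  fit <- fit_fwcoxnet(inst$view, inst$X, z = z, config = cfg)
  tr <- fit$objective_trace
  expect_gte(length(tr), 1)
  if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-8))
})

test_that("selected solution satisfies KKT at the tilted weights", {
  inst <- make_fw_instance(5)
  cfg <- penalty_config(nfolds = 5, seed = 3)
  z_raw <- abs(inst$beta)
  fit <- fit_fwcoxnet(inst$view, inst$X, z = z_raw, config = cfg)
  w <- weight_vector(z_raw / max(z_raw), fit$theta)$w
  viol <- kkt_residuals(fit$beta, inst$view, inst$X, cfg$alpha,
                        fit$lambda_selected, w)
  expect_lt(max(viol), 1e-4)
})

test_that("informative prior scores recover true features more often", {
  # single-cause replicates; z = |true beta| versus no prior information
  hits_z <- hits_0 <- integer(0)
  for (s in 1:15) {
    set.seed(6000 + s)
    n <- 150; p <- 40
    X <- matrix(rnorm(n * p), n, p)
    beta <- c(rep(0.7, 5), rep(0, p - 5))
    tt <- -log(runif(n)) / (0.2 * exp(drop(X %*% beta)))
    cc <- -log(runif(n)) / 0.15
    ds <- survival_dataset(pmin(tt, cc), as.integer(tt <= cc), X)
    v <- cause_view(ds, 1)
    cfg <- penalty_config(nfolds = 5, seed = s)
    fz <- fit_fwcoxnet(v, X, z = abs(beta), config = cfg)
    f0 <- fit_fwcoxnet(v, X, z = NULL, config = cfg)
    hits_z <- c(hits_z, sum(fz$beta[1:5] != 0))
    hits_0 <- c(hits_0, sum(f0$beta[1:5] != 0))
  }
  expect_gte(sum(hits_z), sum(hits_0))
  expect_gte(mean(hits_z), 4)  # true set nearly always recovered with prior
})

test_that("all-censored cause yields a null fit with a warning", {
  ds <- survival_dataset(1:20, rep(c(0, 2), 10), matrix(rnorm(40), 20, 2))
  expect_warning(fit <- fit_fwcoxnet(cause_view(ds, 1), ds$X), "censored")
  expect_true(all(fit$beta == 0))
  expect_true(fit$null_fit)
})

test_that("too few events for the requested folds is an error", {
  set.seed(1)
  ds <- survival_dataset(rexp(30) + 0.1, c(rep(1, 3), rep(0, 27)),
                         matrix(rnorm(60), 30, 2))
  expect_error(fit_fwcoxnet(cause_view(ds, 1), ds$X,
                            config = penalty_config(nfolds = 10)),
               "fewer events")
})

test_that("cv_partial_loglik matches a hand evaluation at beta = 0", {
  # with beta = 0 each fold contributes NLL_train - NLL_full, i.e. minus the
  # difference of summed log risk-set sizes
  ds <- survival_dataset(c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 1),
                         matrix(rnorm(5), 5, 1))
  v <- cause_view(ds, 1)
  folds <- c(1, 2, 1, 2, 1)
  B <- matrix(0, 1, 1)
  hand <- 0
  for (f in 1:2) {
    tr <- folds != f
    nll_full <- oracle_cox_nll(0, ds$time, v$delta, ds$X)
    nll_tr <- oracle_cox_nll(0, ds$time[tr], v$delta[tr],
                             ds$X[tr, , drop = FALSE])
    hand <- hand - (nll_full - nll_tr)
  }
  expect_equal(cv_partial_loglik(v, ds$X, list(B, B), folds), hand,
               tolerance = 1e-10)
})

test_that("raising a feature's score tends to keep it selected", {
  # monotonicity probe at fixed lambda and nonnegative theta: raising z_j
  # while holding the others fixed should not remove feature j. Because the
  # weights are coupled through the normalizer this is a tendency, not a
  # theorem, so violations are reported as findings rather than failures.
  inst <- make_fw_instance(10)
  w0 <- rep(1, 20)
  lam <- lambda_path(inst$view, inst$X, 1, w0, n_lambda = 10)[5]
  violations <- 0L
  checks <- 0L
  for (s in 1:10) {
    set.seed(8000 + s)
    z <- abs(rnorm(20))
    theta <- runif(1, 0, 3)
    b_lo <- solve_beta(inst$view, inst$X, 1, lam, weight_vector(z, theta)$w)
    j <- sample(which(b_lo != 0), 1)
    z_hi <- z
    z_hi[j] <- z_hi[j] + 1
    b_hi <- solve_beta(inst$view, inst$X, 1, lam, weight_vector(z_hi, theta)$w)
    checks <- checks + 1L
    if (b_hi[j] == 0) violations <- violations + 1L
  }
  if (violations > 0)
    message(sprintf("monotone-selection probe: %d/%d violations", violations,
                    checks))
  expect_identical(checks, 10L)
})

test_that("stratified folds always contain events of the cause", {
  set.seed(99)
  delta <- c(rep(1, 12), rep(0, 88))
  for (s in 1:10) {
    folds <- coopnet:::assign_folds(delta, nfolds = 5, stratify = TRUE)
    per_fold <- vapply(1:5, function(f) sum(delta[folds == f]), numeric(1))
    expect_true(all(per_fold >= 1))
  }
})
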