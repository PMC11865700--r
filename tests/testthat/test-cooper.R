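small_cooper_config <- function(seed = 1, mt = 2)
  cooper_config(mt_max_iter = mt, seed = seed,
                penalty = penalty_config(nfolds = 5, n_lambda = 30))

test_that("mt_max_iter = 0 returns the initial fits unchanged", {
  inst <- random_cr_instance(seed = 31)
  fit <- fit_cooper(inst$data, small_cooper_config(seed = 5, mt = 0))
  expect_identical(fit$fit_cause1$beta, fit$initial_fit_cause1$beta)
  expect_identical(fit$fit_cause2$beta, fit$initial_fit_cause2$beta)
  expect_identical(fit$n_iterations_run, 0L)
  expect_identical(extract_coefficients(fit, 1),
                   extract_coefficients(fit, 1, use_initial_fit = TRUE))
})

test_that("history starts at the initial coefficients", {
  inst <- random_cr_instance(seed = 32)
  fit <- fit_cooper(inst$data, small_cooper_config(seed = 2, mt = 1))
  expect_identical(fit$history[[1]]$beta1, fit$initial_fit_cause1$beta)
  expect_identical(fit$history[[1]]$beta2, fit$initial_fit_cause2$beta)
  expect_length(fit$history, 2)
})

test_that("cooperative fits are bit-identical under a repeated seed", {
  inst <- random_cr_instance(seed = 33)
  f1 <- fit_cooper(inst$data, small_cooper_config(seed = 9))
  f2 <- fit_cooper(inst$data, small_cooper_config(seed = 9))
  expect_identical(f1$fit_cause1$beta, f2$fit_cause1$beta)
  expect_identical(f1$fit_cause2$beta, f2$fit_cause2$beta)
  expect_identical(f1$history, f2$history)
  f3 <- fit_cooper(inst$data, small_cooper_config(seed = 10))
  expect_false(identical(f1$fit_cause1$folds, f3$fit_cause1$folds))
})

test_that("a cause without events is an error naming the cause", {
  set.seed(4)
  ds <- survival_dataset(rexp(40) + 0.1,
                         rep(c(0, 1), 20), matrix(rnorm(80), 40, 2))
  expect_error(fit_cooper(ds, small_cooper_config()), "cause 2")
})

test_that("all-zero initial fits collapse every iteration to the plain fit", {
  # pure-noise covariates at strong penalization select nothing, so the
  # exchanged prior scores stay zero and the weights stay at 1
  set.seed(41)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5)
  t1 <- rexp(n, 0.2); t2 <- rexp(n, 0.2); cc <- rexp(n, 0.2)
  time <- pmin(t1, t2, cc)
  status <- ifelse(t1 <= t2 & t1 <= cc, 1L, ifelse(t2 <= cc, 2L, 0L))
  ds <- survival_dataset(time, status, X)
  fit <- fit_cooper(ds, small_cooper_config(seed = 3, mt = 2))
  if (all(fit$initial_fit_cause1$beta == 0) &&
      all(fit$initial_fit_cause2$beta == 0)) {
    expect_equal(fit$fit_cause1$theta, 0)
    expect_equal(fit$fit_cause2$theta, 0)
  }
  succeed()
})

test_that("convergence_check applies the strict L2 criterion", {
  h <- list(list(beta1 = c(1, 2), beta2 = c(0, 1)),
            list(beta1 = c(1, 2), beta2 = c(0, 1)))
  expect_true(convergence_check(h, 1e-12))

  # a single-coordinate difference of exactly epsilon is not below epsilon
  # (0.25 is exactly representable, so the norm equals epsilon exactly)
  eps <- 0.25
  h2 <- list(list(beta1 = c(1, 2), beta2 = c(0, 1)),
             list(beta1 = c(1, 2 + eps), beta2 = c(0, 1)))
  expect_false(convergence_check(h2, eps))
  expect_true(convergence_check(h2, eps * 1.0001))

  # independent norm oracle on random pairs
  for (s in 1:20) {
    set.seed(700 + s)
    a <- rnorm(6); b <- rnorm(6); d <- rnorm(6, sd = 0.1)
    h3 <- list(list(beta1 = a, beta2 = b),
               list(beta1 = a + d, beta2 = b))
    nrm <- sqrt(sum(d^2))
    expect_identical(convergence_check(h3, nrm * 1.01), TRUE)
    expect_identical(convergence_check(h3, nrm * 0.99), FALSE)
  }
  expect_error(convergence_check(list(h[[1]]), 1), "2 history")
  h4 <- list(list(beta1 = c(1, 2), beta2 = c(0, 1)),
             list(beta1 = c(1, 2, 3), beta2 = c(0, 1)))
  expect_error(convergence_check(h4, 1), "mismatch")
})

test_that("coefficient extraction returns nonzeros of the requested model", {
  inst <- random_cr_instance(seed = 35)
  fit <- fit_cooper(inst$data, small_cooper_config(seed = 6, mt = 1))
  for (k in 1:2) {
    nz <- extract_coefficients(fit, k)
    full <- fit[[paste0("fit_cause", k)]]$beta
    expect_identical(unname(nz), unname(full[full != 0]))
  }
  expect_error(extract_coefficients(fit, 5), "unknown cause")
  expect_identical(shared_selection(fit),
                   intersect(names(extract_coefficients(fit, 1)),
                             names(extract_coefficients(fit, 2))))
})

test_that("cause relabelling is a pure view change for the inner fits", {
  # the cooperative fit order (cause 2 first) makes the full algorithm
  # sensitive to which event is labelled cause 1; the invariant that must
  # hold is that a relabelled dataset produces identical cause-specific
  # views, and identical inner fits when the fold seed matches
  inst <- random_cr_instance(seed = 36)
  swapped <- survival_dataset(inst$data$time,
                              ifelse(inst$data$status == 1L, 2L,
                                     ifelse(inst$data$status == 2L, 1L, 0L)),
                              inst$data$X)
  expect_identical(cause_view(swapped, 1)$delta,
                   cause_view(inst$data, 2)$delta)
  cfg <- penalty_config(nfolds = 5, n_lambda = 30, seed = 17)
  f_orig <- fit_fwcoxnet(cause_view(inst$data, 2), inst$data$X, config = cfg)
  f_sw <- fit_fwcoxnet(cause_view(swapped, 1), swapped$X, config = cfg)
  expect_identical(f_sw$beta, f_orig$beta)
  expect_identical(f_sw$lambda_selected, f_orig$lambda_selected)
})
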