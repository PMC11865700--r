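#' Proof-of-concept simulation scenarios
#'
#' Four low-dimensional, high-signal competing-risks scenarios with n = 1000
#' and p = 14 (three potentially informative covariates uniform on [-3, 3],
#' eleven standard-normal noise covariates):
#' \describe{
#'   \item{A}{x1 has effect 1 on both cause-specific hazards; both causes
#'     have prevalence about 35\%. Shared information to exploit.}
#'   \item{B}{x1 affects only cause 1 and x2 only cause 2 (effect 1 each);
#'     prevalences as in A. No shared information.}
#'   \item{C}{x1 has effect 1 on cause 1 and 0.25 on cause 2; cause 1 is
#'     common (about 55\%) and cause 2 rare (about 7\%).}
#'   \item{D}{x1, x2, x3 have effects 1, 0.75, -0.5 on both hazards;
#'     prevalences as in C.}
#' }
#'
#' @param id One of "A", "B", "C", "D".
#' @param n Number of observations (default 1000).
#' @return Object of class \code{poc_scenario} with true coefficient vectors
#'   and target status prevalences.
#' @export
poc_scenario <- function(id = c("A", "B", "C", "D"), n = 1000) {
  id <- match.arg(id)
  p <- 14L
  b1 <- numeric(p)
  b2 <- numeric(p)
  symmetric <- id %in% c("A", "B")  # A: shared effect; B: swap x1/x2 + causes
  if (id == "A") {
    b1[1] <- 1; b2[1] <- 1
    targets <- c(cause1 = 0.35, cause2 = 0.35)
  } else if (id == "B") {
    b1[1] <- 1; b2[2] <- 1
    targets <- c(cause1 = 0.35, cause2 = 0.35)
  } else if (id == "C") {
    b1[1] <- 1; b2[1] <- 0.25
    targets <- c(cause1 = 0.55, cause2 = 0.07)
  } else {
    b1[1:3] <- c(1, 0.75, -0.5); b2[1:3] <- c(1, 0.75, -0.5)
    targets <- c(cause1 = 0.55, cause2 = 0.07)
  }
  structure(list(id = id, n = as.integer(n), p = p, beta1 = b1, beta2 = b2,
                 target_prevalence = targets, symmetric = symmetric),
            class = "poc_scenario")
}

# Draw the covariate matrix of the proof-of-concept design.
poc_covariates <- function(n, p = 14L) {
  X <- cbind(matrix(runif(n * 3L, -3, 3), n, 3L),
             matrix(rnorm(n * (p - 3L)), n, p - 3L))
  colnames(X) <- paste0("x", seq_len(p))
  X
}

#' Calibrate baseline rates of a proof-of-concept scenario
#'
#' The scenarios state target status prevalences but constant cause-specific
#' baseline hazards and a censoring rate must be chosen to attain them. With
#' exponential latent times, the probability that cause k is observed for a
#' subject with rates \eqn{r_1, r_2, c} is \eqn{r_k / (r_1 + r_2 + c)}; its
#' population value is estimated by Monte Carlo over the covariate
#' distribution (fixed internal seed) and the baseline log-rates are found by
#' derivative-free minimization of the squared prevalence error at a fixed
#' censoring rate of 0.1. Scenarios whose construction is symmetric under
#' swapping the two causes (A and B) are solved on the one-dimensional
#' diagonal \eqn{h_{01} = h_{02}}, so equal targets yield exactly equal rates.
#'
#' @param scenario A \code{\link{poc_scenario}}.
#' @param n_eval Monte-Carlo draws per objective evaluation (default 50000).
#' @param tol Maximum absolute prevalence error accepted, as a proportion
#'   (default 0.015).
#' @return List with \code{h01}, \code{h02}, \code{censor_rate} and the
#'   \code{achieved} prevalences (censored, cause 1, cause 2). Errors if the
#'   targets cannot be met within \code{tol}.
#' @export
calibrate_poc <- function(scenario, n_eval = 50000, tol = 0.015) {
  stopifnot(inherits(scenario, "poc_scenario"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(872634L)
  X <- poc_covariates(n_eval, scenario$p)
  e1 <- exp(drop(X[, 1:3] %*% scenario$beta1[1:3]))
  e2 <- exp(drop(X[, 1:3] %*% scenario$beta2[1:3]))
  cr <- 0.1
  tg <- scenario$target_prevalence
  props <- function(h01, h02) {
    r1 <- h01 * e1
    r2 <- h02 * e2
    tot <- r1 + r2 + cr
    c(mean(cr / tot), mean(r1 / tot), mean(r2 / tot))
  }
  if (isTRUE(scenario$symmetric) && tg[1] == tg[2]) {
    obj <- function(lh) {
      pr <- props(exp(lh), exp(lh))
      (pr[2] - tg[1])^2 + (pr[3] - tg[2])^2
    }
    opt <- optimize(obj, c(-8, 4))
    h01 <- h02 <- exp(opt$minimum)
  } else {
    obj <- function(lh) {
      pr <- props(exp(lh[1]), exp(lh[2]))
      (pr[2] - tg[1])^2 + (pr[3] - tg[2])^2
    }
    opt <- stats::optim(c(log(cr), log(cr)), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    h01 <- exp(opt$par[1])
    h02 <- exp(opt$par[2])
  }
  achieved <- props(h01, h02)
  names(achieved) <- c("censored", "cause1", "cause2")
  err <- max(abs(achieved[2:3] - tg))
  if (err > tol)
    stop(sprintf(paste0("calibration failed for scenario %s: achieved ",
                        "(%.3f, %.3f) vs targets (%.3f, %.3f)"),
                 scenario$id, achieved[2], achieved[3], tg[1], tg[2]))
  list(h01 = h01, h02 = h02, censor_rate = cr, achieved = achieved)
}

# Baseline rates precomputed with calibrate_poc() at its defaults; a test
# verifies they reproduce the target prevalences. Regenerate with
#   lapply(setNames(nm = c("A","B","C","D")),
#          function(s) calibrate_poc(poc_scenario(s))[c("h01","h02","censor_rate")])
#' Cached baseline-rate calibration of a proof-of-concept scenario
#'
#' @param id Scenario id ("A".."D").
#' @return List with \code{h01}, \code{h02}, \code{censor_rate}.
#' @export
poc_calibration <- function(id) {
  out <- poc_calibration_cache[[match.arg(id, c("A", "B", "C", "D"))]]
  out
}

poc_calibration_cache <- list(
  A = list(h01 = 0.19639171, h02 = 0.19639171, censor_rate = 0.1),
  B = list(h01 = 0.09050468, h02 = 0.09050468, censor_rate = 0.1),
  C = list(h01 = 0.17215786, h02 = 0.02370224, censor_rate = 0.1),
  D = list(h01 = 0.22201537, h02 = 0.02825649, censor_rate = 0.1)
)

#' Generate a proof-of-concept competing-risks dataset
#'
#' Covariates as described in \code{\link{poc_scenario}}; constant
#' cause-specific hazards \eqn{h_k(t \mid x) = h_{0k} \exp(x^T \beta_k)}
#' realized through exponential latent event times plus independent
#' exponential censoring, with baseline rates calibrated to the scenario's
#' target prevalences (cached; see \code{\link{calibrate_poc}}).
#'
#' @param scenario A \code{\link{poc_scenario}} (or a scenario id string).
#' @param seed Integer seed.
#' @param calibration Optional list with \code{h01}, \code{h02},
#'   \code{censor_rate} overriding the cached calibration.
#' @return A \code{simulated_dataset} (see \code{\link{gen_highdim_dataset}}).
#' @export
gen_poc_dataset <- function(scenario, seed = 1L, calibration = NULL) {
  if (is.character(scenario)) scenario <- poc_scenario(scenario)
  stopifnot(inherits(scenario, "poc_scenario"))
  if (is.null(calibration)) calibration <- poc_calibration_cache[[scenario$id]]
  set.seed(seed)
  X <- poc_covariates(scenario$n, scenario$p)
  eta1 <- drop(X %*% scenario$beta1)
  eta2 <- drop(X %*% scenario$beta2)
  lt <- latent_competing_times(calibration$h01 * exp(eta1),
                               calibration$h02 * exp(eta2),
                               calibration$censor_rate)
  structure(list(data = survival_dataset(lt$time, lt$status, X),
                 beta1_true = scenario$beta1, beta2_true = scenario$beta2,
                 block_label = c(rep("signal", 3), rep("noise", scenario$p - 3)),
                 scenario = scenario, calibration = calibration),
            class = "simulated_dataset")
}
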