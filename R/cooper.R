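#' Settings for the cooperative competing-risks fit
#'
#' @param mt_max_iter Maximum number of outer alternations between the two
#'   cause-specific models (>= 0; 0 returns the initial plain elastic-net
#'   fits unchanged).
#' @param epsilon Stopping threshold: the alternation ends when the L2 norm
#'   of the change in both causes' coefficient vectors falls below it.
#' @param penalty A \code{\link{penalty_config}} shared by both causes.
#' @param seed Integer seed governing fold assignment in every inner fit.
#' @return Object of class \code{cooper_config}.
#' @export
cooper_config <- function(mt_max_iter = 3, epsilon = 1e-8,
                          penalty = penalty_config(), seed = 1L) {
  stopifnot(mt_max_iter >= 0, epsilon > 0,
            inherits(penalty, "penalty_config"))
  structure(list(mt_max_iter = as.integer(mt_max_iter), epsilon = epsilon,
                 penalty = penalty, seed = as.integer(seed)),
            class = "cooper_config")
}

#' Cooperative penalized regression for two competing events
#'
#' Fits two cause-specific Cox elastic nets that iteratively exchange
#' information. Step 1 fits a plain cross-validated elastic net for each
#' cause (events of the other cause treated as censored) at the penalty
#' maximizing the cross-validated partial log-likelihood. Step 2 alternates:
#' the cause-2 model is refit with the cause-1 model's absolute coefficients
#' as prior relevance scores, then the cause-1 model is refit with the new
#' cause-2 magnitudes, until the coefficient change of both causes drops
#' below \code{epsilon} or \code{mt_max_iter} iterations are reached.
#' Coefficients shrunk to zero for one cause thus raise the penalty on the
#' same feature for the other cause, while shared effects protect each other
#' from shrinkage.
#'
#' @param data A \code{\link{survival_dataset}} with events of both causes.
#' @param config A \code{\link{cooper_config}}.
#' @return Object of class \code{cooper_fit}: final fits \code{fit_cause1},
#'   \code{fit_cause2}; plain elastic-net \code{initial_fit_cause1},
#'   \code{initial_fit_cause2}; \code{history} (per-iteration coefficient
#'   pairs, entry 1 = initial fits); \code{n_iterations_run};
#'   \code{converged}; \code{delta_norms} (per-iteration L2 coefficient
#'   changes).
#' @export
fit_cooper <- function(data, config = cooper_config()) {
  stopifnot(inherits(data, "survival_dataset"),
            inherits(config, "cooper_config"))
  for (k in 1:2) {
    if (sum(data$status == k) == 0)
      stop("no events of cause ", k, "; cannot fit cause-specific models")
  }
  view1 <- cause_view(data, 1)
  view2 <- cause_view(data, 2)
  X <- data$X
  pen <- config$penalty
  pen$seed <- NULL  # seeding handled here so inner fits draw fresh folds
  set.seed(config$seed)

  init1 <- fit_fwcoxnet(view1, X, z = NULL, config = pen)
  init2 <- fit_fwcoxnet(view2, X, z = NULL, config = pen)
  fit1 <- init1
  fit2 <- init2
  history <- list(list(beta1 = init1$beta, beta2 = init2$beta))
  delta_norms <- NULL
  converged <- FALSE
  n_run <- 0L

  if (config$mt_max_iter > 0) {
    for (j in seq_len(config$mt_max_iter)) {
      # order as printed: cause 2 first, informed by cause 1's magnitudes
      fit2 <- tryCatch(
        fit_fwcoxnet(view2, X, z = abs(fit1$beta), config = pen),
        error = function(e) stop("inner fit failed (iteration ", j,
                                 ", cause 2): ", conditionMessage(e)))
      fit1 <- tryCatch(
        fit_fwcoxnet(view1, X, z = abs(fit2$beta), config = pen),
        error = function(e) stop("inner fit failed (iteration ", j,
                                 ", cause 1): ", conditionMessage(e)))
      history[[j + 1L]] <- list(beta1 = fit1$beta, beta2 = fit2$beta)
      n_run <- j
      d1 <- sqrt(sum((history[[j + 1L]]$beta1 - history[[j]]$beta1)^2))
      d2 <- sqrt(sum((history[[j + 1L]]$beta2 - history[[j]]$beta2)^2))
      delta_norms <- rbind(delta_norms, c(cause1 = d1, cause2 = d2))
      if (convergence_check(history, config$epsilon)) {
        converged <- TRUE
        break
      }
    }
  }
  structure(list(fit_cause1 = fit1, fit_cause2 = fit2,
                 initial_fit_cause1 = init1, initial_fit_cause2 = init2,
                 history = history, n_iterations_run = n_run,
                 converged = converged, delta_norms = delta_norms,
                 config = config),
            class = "cooper_fit")
}

#' Convergence of the cooperative alternation
#'
#' TRUE iff the L2 norm of the difference between the last two coefficient
#' vectors is strictly below \code{epsilon} for both causes.
#'
#' @param history List of per-iteration \code{list(beta1, beta2)} entries
#'   (at least 2).
#' @param epsilon Positive threshold.
#' @return Logical flag.
#' @export
convergence_check <- function(history, epsilon) {
  stopifnot(epsilon > 0)
  m <- length(history)
  if (m < 2) stop("need at least 2 history entries")
  a <- history[[m - 1L]]
  b <- history[[m]]
  for (nm in c("beta1", "beta2")) {
    if (length(a[[nm]]) != length(b[[nm]]))
      stop("coefficient length mismatch in history for ", nm)
  }
  d1 <- sqrt(sum((b$beta1 - a$beta1)^2))
  d2 <- sqrt(sum((b$beta2 - a$beta2)^2))
  d1 < epsilon && d2 < epsilon
}

#' Extract nonzero coefficients from a cooperative fit
#'
#' @param fit A \code{\link{fit_cooper}} result.
#' @param cause Which cause-specific model, 1 or 2.
#' @param use_initial_fit Return the step-1 plain elastic-net coefficients
#'   (the Coxnet baseline) instead of the final cooperative fit.
#' @return Named numeric vector of nonzero coefficients (empty if none).
#' @export
extract_coefficients <- function(fit, cause, use_initial_fit = FALSE) {
  stopifnot(inherits(fit, "cooper_fit"))
  if (!(cause %in% c(1, 2))) stop("unknown cause code: ", cause)
  slot <- if (use_initial_fit) paste0("initial_fit_cause", cause)
          else paste0("fit_cause", cause)
  beta <- fit[[slot]]$beta
  beta[beta != 0]
}

#' @export
coef.cooper_fit <- function(object, cause = 1, use_initial_fit = FALSE, ...) {
  extract_coefficients(object, cause, use_initial_fit)
}

#' Features selected by both cause-specific models
#'
#' @inheritParams extract_coefficients
#' @return Character vector of feature names with nonzero coefficients in
#'   both causes' models.
#' @export
shared_selection <- function(fit, use_initial_fit = FALSE) {
  intersect(names(extract_coefficients(fit, 1, use_initial_fit)),
            names(extract_coefficients(fit, 2, use_initial_fit)))
}

#' @export
print.cooper_fit <- function(x, ...) {
  cat(sprintf("cooper_fit: %d iterations run, converged = %s\n",
              x$n_iterations_run, x$converged))
  for (k in 1:2) {
    cat(sprintf("  cause %d: %d nonzero (initial %d)\n", k,
                length(extract_coefficients(x, k)),
                length(extract_coefficients(x, k, use_initial_fit = TRUE))))
  }
  cat(sprintf("  shared selection: %d features\n",
              length(shared_selection(x))))
  invisible(x)
}
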