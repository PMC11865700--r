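#' Penalty and cross-validation settings
#'
#' @param alpha Elastic-net mixing parameter in [0, 1]; 1 = lasso (pure
#'   l1, the variable-selection setting), 0 = ridge.
#' @param nfolds Number of cross-validation folds (>= 2).
#' @param stratify_by_status Assign folds separately within events and
#'   non-events of the cause, so every fold contains events. Recommended for
#'   small samples or rare events.
#' @param n_lambda Length of the penalty path.
#' @param lambda_min_ratio Smallest/largest penalty ratio; default 0.05 when
#'   n < p, 0.0001 otherwise. In the p > n lasso regime the cross-validated
#'   partial likelihood peaks well above this point and collapses below it
#'   as the fit saturates, so a longer path only adds cost.
#' @param t_init Initial learning rate of the theta line search.
#' @param thresh Convergence tolerance for the alternating beta/theta
#'   optimization (relative objective change).
#' @param seed Optional integer; when given, fold assignment is drawn from
#'   this seed inside the fit.
#' @return Object of class \code{penalty_config}.
#' @export
penalty_config <- function(alpha = 1, nfolds = 10, stratify_by_status = FALSE,
                           n_lambda = 50, lambda_min_ratio = NULL,
                           t_init = 100, thresh = 1e-7, seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, nfolds >= 2, n_lambda >= 2,
            t_init > 0, thresh > 0)
  structure(list(alpha = alpha, nfolds = as.integer(nfolds),
                 stratify_by_status = isTRUE(stratify_by_status),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 t_init = t_init, thresh = thresh, seed = seed),
            class = "penalty_config")
}

# Fold assignment; stratified splits events and non-events proportionally.
# A held-out fold with zero events is re-drawn (stratified) or an error
# (unstratified).
assign_folds <- function(delta, nfolds, stratify) {
  n <- length(delta)
  for (try in 1:100) {
    folds <- integer(n)
    if (stratify) {
      for (grp in list(which(delta == 1), which(delta == 0))) {
        if (length(grp))
          folds[grp] <- sample(rep_len(seq_len(nfolds), length(grp)))
      }
    } else {
      folds <- sample(rep_len(seq_len(nfolds), n))
    }
    empty <- any(vapply(seq_len(nfolds),
                        function(f) sum(delta[folds == f]) == 0, logical(1)))
    if (!empty) return(folds)
    if (!stratify)
      stop("a cross-validation fold contains no events; ",
           "use stratify_by_status or fewer folds")
  }
  stop("could not construct folds with events in every fold")
}

#' Cross-validated partial log-likelihood (Verweij-Van Houwelingen)
#'
#' For each fold, the contribution of the held-out observations is the
#' difference between the full-data negative log partial likelihood at the
#' coefficients trained without the fold and the training-data value at the
#' same coefficients; contributions are summed over folds and negated so that
#' larger is better.
#'
#' @inheritParams cox_nll
#' @param beta_per_fold List (one element per fold) of p x L coefficient
#'   matrices on the input covariate scale, trained with the fold held out.
#' @param folds Integer fold assignment of each observation.
#' @return Numeric vector of length L (per-penalty-level CV log-likelihood).
#'   Penalty levels with a non-finite contribution are set to \code{-Inf} and
#'   flagged with a warning, excluding them from selection.
#' @export
cv_partial_loglik <- function(view, X, beta_per_fold, folds) {
  X <- as.matrix(X)
  nfolds <- length(beta_per_fold)
  if (nfolds < 2) stop("need at least 2 folds")
  if (length(folds) != nrow(X) || !setequal(unique(folds), seq_len(nfolds)))
    stop("folds must partition the observations into length(beta_per_fold) folds")
  L <- ncol(beta_per_fold[[1]])
  cvl <- numeric(L)
  to_full <- time_order(view$time)
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    to_tr <- time_order(view$time[tr])
    Eta <- X %*% beta_per_fold[[f]]  # linear predictors once per fold
    nll_full <- drop(cpp_cox_nll_multi(Eta, to_full$ord, to_full$firsts,
                                       to_full$lasts, view$delta))
    nll_tr <- drop(cpp_cox_nll_multi(Eta[tr, , drop = FALSE], to_tr$ord,
                                     to_tr$firsts, to_tr$lasts, view$delta[tr]))
    cvl <- cvl - (nll_full - nll_tr)
  }
  bad <- !is.finite(cvl)
  if (any(bad)) {
    warning(sum(bad), " penalty level(s) gave non-finite CV contributions; excluded")
    cvl[bad] <- -Inf
  }
  cvl
}

# One pathwise solver call; returns coefficients on the input scale and the
# number of penalty levels actually fitted before deviance-based early
# stopping (dev.ratio > 0.99 or fractional deviance gain < 1e-5, the
# pathwise-solver convention). When theta_fixed is given (fold refits), the
# per-lambda tilt is taken as fixed instead of alternating.
fw_path_fit <- function(view, X, z, config, lambda, theta_fixed = NULL) {
  std <- standardize_X(X)
  to <- time_order(view$time)
  alternate <- !is.null(z) && is.null(theta_fixed)
  fit <- cpp_cox_path(std$Xs, view$delta, to$ord, to$firsts, to$lasts,
                      config$alpha, lambda, rep(1, ncol(X)),
                      if (is.null(z)) numeric(0) else z, alternate,
                      0, config$t_init, 50, config$thresh,
                      25L, 25L, 1e-7, 1e-7, 1000L,
                      numeric(ncol(X)), 0.99, 1e-5,
                      if (is.null(theta_fixed)) numeric(0) else theta_fixed)
  fit$beta_orig <- fit$beta / std$scale
  fit
}

#' Fit a feature-weighted Cox elastic net with cross-validated penalty
#'
#' Fits one cause-specific Cox model along a decreasing penalty path. When
#' prior relevance scores \code{z} are supplied, the fit alternates between
#' the coefficient step (IRLS + coordinate descent at the current penalty
#' factors) and the scalar theta step that tilts the penalty factors toward
#' high-scoring features, until the relative objective change falls below
#' \code{config$thresh} (at most 25 alternations per penalty level). Without
#' \code{z} the fit is a plain Cox elastic net. The penalty level is chosen
#' by the cross-validated partial log-likelihood (the maximizing value,
#' "lambda.min"); cross-validation folds re-estimate coefficients with the
#' tilt theta(lambda) frozen at its full-data path values, i.e. lambda is
#' cross-validated given theta.
#'
#' @inheritParams cox_nll
#' @param z Optional nonnegative prior relevance scores (length p), e.g.
#'   absolute coefficients of a related model. Internally rescaled to unit
#'   maximum; \code{NULL} or all-zero scores give the plain elastic net.
#' @param config A \code{\link{penalty_config}}.
#' @return Object of class \code{fwcoxnet_fit} with elements \code{beta}
#'   (named coefficients at the selected penalty, input scale), \code{theta},
#'   \code{lambda_selected}, \code{lambda} (path), \code{cv_loglik},
#'   \code{objective_trace} (per-alternation objective at the selected
#'   penalty), \code{beta_path}, \code{theta_path}, \code{folds} and
#'   \code{cause}.
#' @export
fit_fwcoxnet <- function(view, X, z = NULL, config = penalty_config()) {
  stopifnot(inherits(view, "cause_view"), inherits(config, "penalty_config"))
  X <- as.matrix(X)
  p <- ncol(X)
  fnames <- colnames(X)
  if (is.null(fnames)) fnames <- paste0("x", seq_len(p))
  n_events <- sum(view$delta)
  if (n_events == 0) {
    warning("all observations censored for cause ", view$cause,
            "; returning null fit")
    beta <- setNames(numeric(p), fnames)
    return(structure(list(beta = beta, theta = 0, lambda_selected = NA_real_,
                          lambda = NA_real_, cv_loglik = NA_real_,
                          objective_trace = numeric(0),
                          beta_path = NULL, theta_path = NULL,
                          folds = NULL, cause = view$cause, null_fit = TRUE),
                     class = "fwcoxnet_fit"))
  }
  if (n_events < config$nfolds)
    stop("cause ", view$cause, " has fewer events (", n_events,
         ") than cross-validation folds (", config$nfolds, ")")
  if (!is.null(z)) {
    z <- as.numeric(z)
    if (length(z) != p) stop("z must have one entry per feature")
    if (anyNA(z) || any(!is.finite(z)) || any(z < 0))
      stop("z must be finite and nonnegative")
    if (max(z) > 0) z <- z / max(z) else z <- NULL  # unit (max-abs) scale
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  lambda <- lambda_path(view, X, config$alpha, rep(1, p),
                        n_lambda = config$n_lambda,
                        lambda_min_ratio = config$lambda_min_ratio)
  folds <- assign_folds(view$delta, config$nfolds, config$stratify_by_status)

  # full-data path first: the alternation estimates the tilt theta(lambda);
  # folds then re-estimate coefficients at that tilt, cross-validating lambda
  # given theta (the usual pathwise treatment of secondary hyperparameters)
  full <- fw_path_fit(view, X, z, config, lambda)
  L_eff <- full$n_lambda_used
  lambda <- lambda[seq_len(L_eff)]
  theta_full <- full$theta[seq_len(L_eff)]
  beta_per_fold <- vector("list", config$nfolds)
  for (f in seq_len(config$nfolds)) {
    tr <- folds != f
    view_tr <- structure(list(time = view$time[tr], delta = view$delta[tr],
                              cause = view$cause), class = "cause_view")
    ffit <- fw_path_fit(view_tr, X[tr, , drop = FALSE], z, config, lambda,
                        theta_fixed = if (is.null(z)) NULL else theta_full)
    beta_per_fold[[f]] <- ffit$beta_orig[, seq_len(ffit$n_lambda_used), drop = FALSE]
    L_eff <- min(L_eff, ffit$n_lambda_used)
  }
  # restrict selection to penalty levels fitted in every fold and the full
  # path (early stopping may truncate them at different points)
  lambda <- lambda[seq_len(L_eff)]
  beta_per_fold <- lapply(beta_per_fold,
                          function(B) B[, seq_len(L_eff), drop = FALSE])
  cvl <- cv_partial_loglik(view, X, beta_per_fold, folds)
  i_min <- which.max(cvl)
  beta <- setNames(full$beta_orig[, i_min], fnames)
  structure(list(beta = beta, theta = full$theta[i_min],
                 lambda_selected = lambda[i_min], lambda = lambda,
                 cv_loglik = cvl,
                 objective_trace = full$trace[[i_min]],
                 beta_path = full$beta_orig[, seq_len(L_eff), drop = FALSE],
                 theta_path = full$theta[seq_len(L_eff)],
                 folds = folds, cause = view$cause, alpha = config$alpha,
                 null_fit = FALSE),
            class = "fwcoxnet_fit")
}

#' @export
print.fwcoxnet_fit <- function(x, ...) {
  cat(sprintf("fwcoxnet_fit (cause %d): %d nonzero of %d coefficients\n",
              x$cause, sum(x$beta != 0), length(x$beta)))
  if (!isTRUE(x$null_fit))
    cat(sprintf("  lambda.min = %.5g, theta = %.4g\n",
                x$lambda_selected, x$theta))
  invisible(x)
}

#' @export
coef.fwcoxnet_fit <- function(object, ...) object$beta
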