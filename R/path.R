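# Internal: center/scale columns (population sd, 1/n) for penalty fairness.
# Constant columns get scale 1 and can never enter the model.
standardize_X <- function(X) {
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  scl <- sqrt(colSums(Xc^2) / n)
  scl[scl < 1e-12] <- 1
  list(Xs = sweep(Xc, 2L, scl, "/"), center = ctr, scale = scl)
}

# Full objective on the standardized scale: NLL/n + lambda * weighted penalty.
fw_objective <- function(beta, view, X, alpha, lambda, w) {
  cox_nll(beta, view, X) / nrow(as.matrix(X)) +
    lambda * sum(w * (alpha * abs(beta) + 0.5 * (1 - alpha) * beta^2))
}

#' Penalty path for a feature-weighted Cox elastic net
#'
#' Decreasing log-spaced sequence of penalty levels. The largest value is the
#' smallest penalty at which all coefficients are zero:
#' \eqn{\lambda_{max} = \max_j |g_j| / (\alpha w_j)} with \eqn{g} the gradient
#' of the mean negative log partial likelihood at \eqn{\beta = 0} on
#' standardized covariates.
#'
#' @inheritParams cox_nll
#' @param alpha Elastic-net mixing parameter. For \code{alpha = 0} the
#'   maximum is unbounded; the conventional surrogate (computed as if
#'   \code{alpha = 0.001}) is used and a message is emitted.
#' @param w A \code{\link{weight_vector}} (or plain positive vector) of
#'   penalty factors.
#' @param n_lambda Path length (default 100).
#' @param lambda_min_ratio Smallest/largest penalty ratio; defaults to 0.05
#'   when n < p, 0.0001 otherwise.
#' @param standardize Standardize covariates before computing the gradient
#'   (default TRUE, matching the fitting functions).
#' @return Strictly decreasing positive vector of length \code{n_lambda}.
#' @export
lambda_path <- function(view, X, alpha, w, n_lambda = 100,
                        lambda_min_ratio = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  if (inherits(w, "weight_vector")) w <- w$w
  if (sum(view$delta) == 0) stop("no events of the requested cause")
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (nrow(X) < ncol(X)) 0.05 else 1e-4
  a <- alpha
  if (a <= 0) {
    message("alpha = 0: lambda_max undefined; using alpha = 0.001 surrogate")
    a <- 0.001
  }
  Xs <- if (standardize) standardize_X(X)$Xs else X
  g0 <- cox_gradient(numeric(ncol(X)), view, Xs) / nrow(X)
  lmax <- max(abs(g0) / (a * w))
  if (!is.finite(lmax) || lmax <= 0) stop("degenerate lambda path")
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Solve the feature-weighted Cox elastic net at fixed penalty factors
#'
#' Minimizes \code{NLL/n + lambda * sum_j w_j (alpha |beta_j| +
#' (1-alpha)/2 beta_j^2)} for fixed penalty factors \code{w} by iteratively
#' reweighted least squares around cyclic coordinate descent with soft
#' thresholding. Covariates are standardized internally; coefficients are
#' returned on the input scale.
#'
#' @inheritParams lambda_path
#' @param lambda Nonnegative penalty level.
#' @param beta_init Warm-start coefficients on the input scale (default 0).
#' @param thresh Convergence tolerance (relative objective change).
#' @return Coefficient vector on the input scale. Attribute \code{converged}
#'   is FALSE (with a warning) if iteration limits were reached.
#' @export
solve_beta <- function(view, X, alpha, lambda, w, beta_init = NULL,
                       thresh = 1e-9) {
  X <- as.matrix(X)
  if (inherits(w, "weight_vector")) w <- w$w
  if (lambda < 0) stop("lambda must be nonnegative")
  if (any(w <= 0)) stop("penalty factors must be positive")
  p <- ncol(X)
  if (is.null(beta_init)) beta_init <- numeric(p)
  if (sum(view$delta) == 0) {
    warning("no events of the requested cause; returning null fit")
    return(structure(numeric(p), converged = TRUE))
  }
  std <- standardize_X(X)
  to <- time_order(view$time)
  fit <- cpp_cox_path(std$Xs, view$delta, to$ord, to$firsts, to$lasts,
                      alpha, lambda, w, numeric(0), FALSE, 0, 100, 50,
                      thresh, 1L, 100L, thresh, thresh * 10, 10000L,
                      beta_init * std$scale, 2, 0, numeric(0))
  beta <- drop(fit$beta) / std$scale
  names(beta) <- colnames(X)
  structure(beta, converged = fit$n_irls_maxed == 0)
}

#' Karush-Kuhn-Tucker residuals of a penalized Cox solution
#'
#' For each zero coefficient, the amount by which the mean-scale partial
#' likelihood gradient exceeds the l1 threshold \eqn{\lambda \alpha w_j}; for
#' each nonzero coefficient, the absolute violation of the stationarity
#' condition. Computed on the standardized covariate scale used by the
#' solvers. Useful for verifying optimality of returned solutions.
#'
#' @inheritParams solve_beta
#' @param beta Coefficients on the input scale.
#' @return Numeric vector of nonnegative violations (length p).
#' @export
kkt_residuals <- function(beta, view, X, alpha, lambda, w) {
  X <- as.matrix(X)
  if (inherits(w, "weight_vector")) w <- w$w
  std <- standardize_X(X)
  bs <- beta * std$scale
  g <- cox_gradient(bs, view, std$Xs) / nrow(X)
  viol <- numeric(length(beta))
  nz <- bs != 0
  viol[!nz] <- pmax(0, abs(g[!nz]) - lambda * alpha * w[!nz])
  viol[nz] <- abs(g[nz] + lambda * (1 - alpha) * w[nz] * bs[nz] +
                    lambda * alpha * w[nz] * sign(bs[nz]))
  viol
}
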