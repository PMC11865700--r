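#' Feature-weighted penalty factors
#'
#' Softmax-like transform of prior relevance scores into per-feature penalty
#' factors: \eqn{w_j(\theta) = \sum_l \exp(z_l \theta) / (p \exp(z_j \theta))}.
#' Features with larger score \eqn{z_j \theta} receive smaller penalty
#' factors. At \eqn{\theta = 0} all factors are 1 and the penalty collapses to
#' the ordinary elastic net. The factors satisfy the harmonic-mean identity
#' \eqn{\sum_j 1 / w_j = p}.
#'
#' @param z Nonnegative, finite prior relevance scores (length p). In the
#'   cooperative algorithm these are the complementary model's absolute
#'   coefficients.
#' @param theta Scalar tilt parameter.
#' @return Object of class \code{weight_vector}: list with positive factors
#'   \code{w} and the \code{theta} used. Overflow is guarded by subtracting
#'   the maximum score before exponentiation.
#' @export
weight_vector <- function(z, theta) {
  z <- as.numeric(z)
  if (anyNA(z) || any(!is.finite(z))) stop("z must be finite")
  if (length(theta) != 1L || !is.finite(theta)) stop("theta must be a finite scalar")
  w <- drop(cpp_theta_weights(z, theta))
  structure(list(w = w, theta = theta), class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("weight_vector: p = %d, theta = %.4g, range [%.4g, %.4g]\n",
              length(x$w), x$theta, min(x$w), max(x$w)))
  invisible(x)
}

#' Optimize the penalty tilt parameter theta at fixed coefficients
#'
#' With \code{beta} held fixed, the partial-likelihood term of the
#' feature-weighted objective does not involve \eqn{\theta}, so the step
#' minimizes the penalty \eqn{\lambda \sum_j w_j(\theta) (\alpha |\beta_j| +
#' (1-\alpha)/2\, \beta_j^2)} over the scalar \eqn{\theta}. Gradient descent
#' with backtracking line search starts at step size \code{t_init} and stops
#' when the relative objective decrease falls below \code{thresh}; if the
#' first gradient step stalls, a golden-section search over the clipped
#' interval takes over (the log of the penalty is convex in \eqn{\theta}, so
#' the minimum is global). The returned \eqn{\theta} never increases the
#' objective relative to \code{theta_init}.
#'
#' @inheritParams cox_nll
#' @param z Prior relevance scores, assumed on unit (max-abs) scale.
#' @param alpha Elastic-net mixing parameter in [0, 1].
#' @param lambda Penalty level.
#' @param theta_init Starting value.
#' @param t_init Initial learning rate of the backtracking search.
#' @param thresh Relative-decrease stopping tolerance.
#' @param theta_clip Bound of the search interval.
#' @return Scalar theta.
#' @export
update_theta <- function(view, X, beta, z, alpha, lambda,
                         theta_init = 0, t_init = 100, thresh = 1e-7,
                         theta_clip = 50) {
  z <- as.numeric(z)
  if (anyNA(z) || any(!is.finite(z))) stop("z must be finite")
  cpen <- alpha * abs(beta) + 0.5 * (1 - alpha) * beta^2
  const_term <- cox_nll(beta, view, X) / nrow(as.matrix(X))
  if (!is.finite(const_term)) {
    warning("non-finite objective in theta step; resetting theta to 0")
    return(0)
  }
  cpp_theta_step(z, cpen, lambda, theta_init, t_init, thresh, theta_clip,
                 const_term)
}
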