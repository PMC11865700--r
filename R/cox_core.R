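#' Negative Cox log partial likelihood
#'
#' Sum-scale negative log partial likelihood of a cause-specific Cox model,
#' with the Breslow convention when tied event times occur. Observations with
#' an event of the competing cause count as censored (see
#' \code{\link{cause_view}}). Returns 0 when the view contains no events.
#'
#' @param beta Coefficient vector of length \code{ncol(X)}.
#' @param view A \code{\link{cause_view}}.
#' @param X Covariate matrix.
#' @return Nonnegative scalar.
#' @export
cox_nll <- function(beta, view, X) {
  cc <- cox_check_inputs(beta, view, X)
  if (sum(view$delta) == 0) return(0)
  cw <- cpp_cox_working(cc$eta, cc$to$ord, cc$to$firsts, cc$to$lasts, view$delta)
  cw$nll
}

#' Gradient of the negative Cox log partial likelihood
#'
#' Exact gradient of \code{\link{cox_nll}} with respect to \code{beta}
#' (sum scale).
#'
#' @inheritParams cox_nll
#' @return Numeric vector of length \code{ncol(X)}.
#' @export
cox_gradient <- function(beta, view, X) {
  cc <- cox_check_inputs(beta, view, X)
  if (sum(view$delta) == 0) return(numeric(ncol(X)))
  cw <- cpp_cox_working(cc$eta, cc$to$ord, cc$to$firsts, cc$to$lasts, view$delta)
  drop(crossprod(X, cw$g_eta))
}

#' Quadratic (IRLS) approximation of the Cox partial likelihood
#'
#' Working weights and responses such that one penalized weighted
#' least-squares step on them equals one Newton-type step on the negative log
#' partial likelihood. The Hessian is approximated by its diagonal, the
#' convention of pathwise penalized-Cox solvers; callers pair it with step
#' halving.
#'
#' @inheritParams cox_nll
#' @return Object of class \code{cox_quadratic}: list with
#'   \code{working_response}, \code{working_weight} (nonnegative),
#'   \code{linear_predictor} and logical \code{degenerate} (TRUE when all
#'   weights vanish, e.g. no events: caller should fall back to a null fit).
#' @export
cox_quadratic <- function(beta, view, X) {
  cc <- cox_check_inputs(beta, view, X)
  n <- nrow(X)
  if (sum(view$delta) == 0) {
    return(structure(list(working_response = cc$eta,
                          working_weight = numeric(n),
                          linear_predictor = cc$eta, degenerate = TRUE),
                     class = "cox_quadratic"))
  }
  cw <- cpp_cox_working(cc$eta, cc$to$ord, cc$to$firsts, cc$to$lasts, view$delta)
  w <- drop(cw$w)
  g <- drop(cw$g_eta)
  z <- cc$eta
  ok <- w > 1e-10
  z[ok] <- cc$eta[ok] - g[ok] / w[ok]
  w[!ok] <- 0
  structure(list(working_response = z, working_weight = w,
                 linear_predictor = cc$eta, degenerate = !any(ok)),
            class = "cox_quadratic")
}

cox_check_inputs <- function(beta, view, X) {
  stopifnot(inherits(view, "cause_view"))
  X <- as.matrix(X)
  if (nrow(X) != length(view$time))
    stop("X and view have mismatched numbers of observations")
  if (length(beta) != ncol(X))
    stop("beta must have one entry per column of X")
  if (anyNA(beta) || any(!is.finite(beta))) stop("beta must be finite")
  if (anyNA(X) || any(!is.finite(X))) stop("X must be finite")
  eta <- drop(X %*% beta)
  list(eta = eta, to = time_order(view$time))
}
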