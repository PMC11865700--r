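#' Specify one correlated covariate block
#'
#' @param name Block label (carried through to evaluation output).
#' @param size Number of covariates in the block.
#' @param rho Pairwise within-block correlation, in [0, 1).
#' @param effects_cause1,effects_cause2 Per-feature effects on the cause-1
#'   and cause-2 log hazards, applied to the first features of the block;
#'   unlisted features have effect 0. Length at most \code{size}.
#' @return Object of class \code{block_spec}.
#' @export
block_spec <- function(name, size, rho, effects_cause1 = numeric(0),
                       effects_cause2 = numeric(0)) {
  stopifnot(size >= 1, rho >= 0, rho < 1,
            length(effects_cause1) <= size, length(effects_cause2) <= size)
  structure(list(name = name, size = as.integer(size), rho = rho,
                 effects_cause1 = effects_cause1,
                 effects_cause2 = effects_cause2),
            class = "block_spec")
}

# The five-block genomics layout: shared, reversed, and disjoint effects of
# magnitude 0.5 (four informative features per block), plus correlated noise.
default_highdim_blocks <- function() {
  list(
    block_spec("B1",   250, 0.50, rep(0.5, 4),  rep(0.5, 4)),
    block_spec("B2",   250, 0.35, rep(0.5, 4),  rep(-0.5, 4)),
    block_spec("B3.1", 250, 0.05, rep(-0.5, 4), numeric(0)),
    block_spec("B3.2", 250, 0.05, numeric(0),   rep(0.5, 4)),
    block_spec("B4",   500, 0.32, numeric(0),   numeric(0))
  )
}

#' Configuration of the high-dimensional competing-risks generator
#'
#' Defaults emulate a gene-expression-like design: n = 400 observations,
#' p = 5000 standard-normal covariates in correlated blocks, 12 informative
#' features per cause with effects of magnitude 0.5, exponential latent event
#' and censoring times with baseline hazards 0.1.
#'
#' @param n Number of observations.
#' @param blocks List of \code{\link{block_spec}} objects.
#' @param n_uncorrelated_noise Count of additional i.i.d. standard-normal
#'   noise covariates.
#' @param baseline_hazard Baseline hazard of both causes' latent exponential
#'   event times.
#' @param censoring_hazard Hazard of the independent exponential censoring
#'   time.
#' @param seed Integer seed.
#' @return Object of class \code{highdim_config}.
#' @export
highdim_config <- function(n = 400, blocks = default_highdim_blocks(),
                           n_uncorrelated_noise = 3500,
                           baseline_hazard = 0.1, censoring_hazard = 0.1,
                           seed = 1L) {
  stopifnot(n >= 2, baseline_hazard > 0, censoring_hazard > 0,
            n_uncorrelated_noise >= 0)
  for (b in blocks) stopifnot(inherits(b, "block_spec"))
  structure(list(n = as.integer(n), blocks = blocks,
                 n_uncorrelated_noise = as.integer(n_uncorrelated_noise),
                 baseline_hazard = baseline_hazard,
                 censoring_hazard = censoring_hazard,
                 seed = as.integer(seed)),
            class = "highdim_config")
}

#' Generate block-correlated standard-normal covariates
#'
#' Within a block, \eqn{x_j = \sqrt{\rho} f + \sqrt{1-\rho}\, e_j} with one
#' shared standard-normal factor \eqn{f} per block and independent
#' standard-normal \eqn{e_j}, giving exact pairwise correlation \eqn{\rho}
#' and standard-normal marginals. Noise features are i.i.d. standard normal.
#'
#' @param n Number of observations.
#' @param blocks List of \code{\link{block_spec}}s.
#' @param n_noise Number of uncorrelated noise covariates appended.
#' @param seed Optional seed (uses the current RNG stream when NULL).
#' @return List with \code{X} (n x p matrix) and \code{block_label}
#'   (per-feature label; noise features labelled "noise").
#' @export
gen_block_covariates <- function(n, blocks, n_noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- vector("list", length(blocks) + (n_noise > 0))
  labels <- character(0)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    f <- rnorm(n)
    E <- matrix(rnorm(n * b$size), n, b$size)
    cols[[i]] <- sqrt(b$rho) * f + sqrt(1 - b$rho) * E
    labels <- c(labels, rep(b$name, b$size))
  }
  if (n_noise > 0) {
    cols[[length(blocks) + 1L]] <- matrix(rnorm(n * n_noise), n, n_noise)
    labels <- c(labels, rep("noise", n_noise))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  list(X = X, block_label = labels)
}

# Latent-failure-time construction shared by both generators: exponential
# latent event times per cause plus independent exponential censoring; the
# minimum determines the observed time and status.
latent_competing_times <- function(rate1, rate2, rate_c) {
  n <- length(rate1)
  t1 <- -log(runif(n)) / rate1
  t2 <- -log(runif(n)) / rate2
  cc <- -log(runif(n)) / rate_c
  time <- pmin(t1, t2, cc)
  # argmin of the three latent times; ties (probability zero in continuous
  # time) break toward the lower cause index
  status <- ifelse(t1 <= t2 & t1 <= cc, 1L, ifelse(t2 <= cc, 2L, 0L))
  list(time = time, status = as.integer(status))
}

#' Generate a high-dimensional competing-risks dataset with ground truth
#'
#' Covariates follow the block-correlation layout of \code{config}; latent
#' event times are \eqn{T_{ik} = -\log(U_{ik}) / (\lambda \exp(x_i^T
#' \beta_k))} for causes k = 1, 2 with independent standard-uniform draws,
#' censoring \eqn{C_i = -\log(U_{Ci}) / \lambda_C}; the observed time is the
#' minimum of the three and the status records which won (0 = censoring).
#' At defaults this yields roughly 30\% cause-1 events, 40\% cause-2 events
#' and 30\% censoring.
#'
#' @param config A \code{\link{highdim_config}}.
#' @return Object of class \code{simulated_dataset}: list with \code{data}
#'   (a \code{\link{survival_dataset}}), true coefficient vectors
#'   \code{beta1_true}, \code{beta2_true}, and \code{block_label}.
#' @export
gen_highdim_dataset <- function(config = highdim_config()) {
  stopifnot(inherits(config, "highdim_config"))
  set.seed(config$seed)
  gen <- gen_block_covariates(config$n, config$blocks,
                              config$n_uncorrelated_noise)
  p <- ncol(gen$X)
  beta1 <- numeric(p)
  beta2 <- numeric(p)
  offset <- 0L
  for (b in config$blocks) {
    if (length(b$effects_cause1))
      beta1[offset + seq_along(b$effects_cause1)] <- b$effects_cause1
    if (length(b$effects_cause2))
      beta2[offset + seq_along(b$effects_cause2)] <- b$effects_cause2
    offset <- offset + b$size
  }
  nz1 <- which(beta1 != 0)
  nz2 <- which(beta2 != 0)
  eta1 <- if (length(nz1)) drop(gen$X[, nz1, drop = FALSE] %*% beta1[nz1]) else numeric(config$n)
  eta2 <- if (length(nz2)) drop(gen$X[, nz2, drop = FALSE] %*% beta2[nz2]) else numeric(config$n)
  lt <- latent_competing_times(config$baseline_hazard * exp(eta1),
                               config$baseline_hazard * exp(eta2),
                               config$censoring_hazard)
  structure(list(data = survival_dataset(lt$time, lt$status, gen$X),
                 beta1_true = beta1, beta2_true = beta2,
                 block_label = gen$block_label, config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset with ground truth\n")
  print(x$data)
  cat(sprintf("  true nonzero: %d (cause 1), %d (cause 2)\n",
              sum(x$beta1_true != 0), sum(x$beta2_true != 0)))
  invisible(x)
}
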