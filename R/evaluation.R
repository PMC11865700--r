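#' Per-block confusion counts of a variable selection
#'
#' A feature counts as selected iff its estimated coefficient (or a logical
#' selection flag) is nonzero; it counts as a positive iff the true effect of
#' the requested cause is nonzero. Counts are computed separately within each
#' covariate block of the generating design.
#'
#' @param beta_hat Numeric coefficient vector (nonzero = selected) or logical
#'   selection vector, length p.
#' @param truth A \code{simulated_dataset} with ground-truth effects and
#'   block labels.
#' @param cause Which cause's true effects define positives (1 or 2).
#' @return data.frame with one row per block: \code{cause}, \code{block},
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn}, \code{block_size}.
#' @export
classify_selection <- function(beta_hat, truth, cause) {
  stopifnot(inherits(truth, "simulated_dataset"), cause %in% c(1, 2))
  labels <- truth$block_label
  if (is.null(labels)) stop("truth carries no block labels")
  if (length(beta_hat) != length(labels))
    stop("beta_hat length does not match the number of features")
  sel <- if (is.logical(beta_hat)) beta_hat else beta_hat != 0
  bt <- if (cause == 1) truth$beta1_true else truth$beta2_true
  pos <- bt != 0
  blocks <- unique(labels)
  out <- lapply(blocks, function(b) {
    i <- labels == b
    data.frame(cause = cause, block = b,
               tp = sum(sel[i] & pos[i]), fp = sum(sel[i] & !pos[i]),
               tn = sum(!sel[i] & !pos[i]), fn = sum(!sel[i] & pos[i]),
               block_size = sum(i))
  })
  do.call(rbind, out)
}

#' Selection metrics from confusion counts
#'
#' PPV = TP/(TP+FP), FPR = FP/(FP+TN), TPR = TP/(TP+FN),
#' F1 = 2 PPV TPR / (PPV + TPR). PPV, TPR and F1 are reported as \code{NA}
#' (not applicable, not an error) in blocks without true positives for the
#' cause; PPV is also \code{NA} when nothing was selected.
#'
#' @param counts data.frame as returned by \code{\link{classify_selection}}.
#' @return The input with columns \code{ppv}, \code{fpr}, \code{tpr},
#'   \code{f1} appended.
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  has_pos <- (tp + fn) > 0
  ppv <- ifelse(has_pos & (tp + fp) > 0, tp / (tp + fp), NA_real_)
  fpr <- ifelse((fp + tn) > 0, fp / (fp + tn), NA_real_)
  tpr <- ifelse(has_pos, tp / (tp + fn), NA_real_)
  f1 <- ifelse(has_pos & !is.na(ppv) & (ppv + tpr) > 0,
               2 * ppv * tpr / (ppv + tpr), NA_real_)
  f1[has_pos & !is.na(ppv) & (ppv + tpr) == 0] <- 0
  counts$ppv <- ppv
  counts$fpr <- fpr
  counts$tpr <- tpr
  counts$f1 <- f1
  counts
}

#' Coefficient estimation error
#'
#' Elementwise true-minus-estimated coefficients,
#' \eqn{\beta_j - \hat\beta_j}.
#'
#' @param beta_hat Estimated coefficients.
#' @param beta_true True coefficients (same length).
#' @return Numeric vector of per-feature errors.
#' @export
coefficient_bias <- function(beta_hat, beta_true) {
  if (length(beta_hat) != length(beta_true))
    stop("coefficient vectors have different lengths")
  as.numeric(beta_true) - as.numeric(beta_hat)
}

#' Threshold a variable-importance vector into a selection
#'
#' A feature is selected iff its importance exceeds the absolute value of
#' the smallest importance, \eqn{v_j > |\min v|}: negative importances are
#' treated as pure noise and their magnitude sets the noise floor. This is
#' the rule used to turn permutation-importance vectors (e.g. from random
#' survival forests) into selections comparable with coefficient-based
#' methods.
#'
#' @param v Numeric importance vector.
#' @return Logical selection vector.
#' @export
threshold_importance <- function(v) {
  stopifnot(is.numeric(v), length(v) > 0)
  v > abs(min(v))
}

#' Replicated variable-selection benchmark
#'
#' Repeats the simulate-fit-score cycle: replicate r draws a dataset with
#' seed \code{base_seed + r}, fits the cooperative model once, and scores
#' each requested method's selection per cause and covariate block. The
#' built-in methods are \code{"cooper"} (final cooperative fits) and
#' \code{"coxnet"} (the initial plain elastic-net fits of the same run, so
#' one fit serves both). External methods can be supplied as adapter
#' functions \code{function(dataset) list(cause1=, cause2=, type=)} returning
#' per-cause coefficient (\code{type = "coefficient"}) or importance
#' (\code{type = "importance"}) vectors; importances are thresholded with
#' \code{\link{threshold_importance}} before classification.
#'
#' @param design "highdim" or "poc".
#' @param methods Character vector among "cooper", "coxnet" and the names of
#'   \code{adapters}.
#' @param n_replicates Number of replications.
#' @param base_seed Integer; replicate r uses seed \code{base_seed + r}.
#' @param data_config A \code{\link{highdim_config}} (its seed is overridden
#'   per replicate) for \code{design = "highdim"}, or a
#'   \code{\link{poc_scenario}} for \code{design = "poc"}.
#' @param fit_config A \code{\link{cooper_config}}; its seed is overridden
#'   per replicate.
#' @param adapters Named list of external adapter functions.
#' @return Object of class \code{benchmark_result}: \code{results} (long
#'   data.frame: replicate, seed, method, cause, block, confusion counts and
#'   metrics), \code{aggregates} (median/quartiles/IQR per method, cause,
#'   block and metric) and \code{failures} (per-method failed replicate
#'   counts).
#' @export
run_benchmark <- function(design = c("highdim", "poc"),
                          methods = c("cooper", "coxnet"),
                          n_replicates = 10, base_seed = 1,
                          data_config = NULL,
                          fit_config = cooper_config(),
                          adapters = list()) {
  design <- match.arg(design)
  stopifnot(length(methods) >= 1)
  known <- c("cooper", "coxnet", names(adapters))
  if (!all(methods %in% known))
    stop("unknown methods: ", paste(setdiff(methods, known), collapse = ", "))
  need_cooper <- any(methods %in% c("cooper", "coxnet"))
  rows <- list()
  failures <- setNames(integer(length(methods)), methods)
  for (r in seq_len(n_replicates)) {
    seed_r <- base_seed + r
    sim <- if (design == "highdim") {
      cfg <- if (is.null(data_config)) highdim_config() else data_config
      cfg$seed <- seed_r
      gen_highdim_dataset(cfg)
    } else {
      sc <- if (is.null(data_config)) poc_scenario("A") else data_config
      gen_poc_dataset(sc, seed = seed_r)
    }
    cfit <- NULL
    if (need_cooper) {
      fc <- fit_config
      fc$seed <- seed_r
      cfit <- tryCatch(fit_cooper(sim$data, fc), error = function(e) e)
    }
    for (m in methods) {
      sel <- tryCatch({
        if (m %in% c("cooper", "coxnet")) {
          if (inherits(cfit, "error")) stop(conditionMessage(cfit))
          init <- m == "coxnet"
          list(cause1 = fit_beta_vector(cfit, 1, init),
               cause2 = fit_beta_vector(cfit, 2, init))
        } else {
          out <- adapters[[m]](sim$data)
          if (identical(out$type, "importance"))
            list(cause1 = threshold_importance(out$cause1),
                 cause2 = threshold_importance(out$cause2))
          else list(cause1 = out$cause1, cause2 = out$cause2)
        }
      }, error = function(e) e)
      if (inherits(sel, "error")) {
        failures[m] <- failures[m] + 1L
        next
      }
      for (k in 1:2) {
        sc <- compute_metrics(classify_selection(sel[[paste0("cause", k)]],
                                                 sim, k))
        sc <- cbind(data.frame(replicate = r, seed = seed_r, method = m), sc)
        rows[[length(rows) + 1L]] <- sc
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(results = results,
                 aggregates = if (is.null(results)) NULL
                              else aggregate_benchmark(results),
                 failures = failures, design = design),
            class = "benchmark_result")
}

fit_beta_vector <- function(cfit, cause, use_initial_fit) {
  slot <- if (use_initial_fit) paste0("initial_fit_cause", cause)
          else paste0("fit_cause", cause)
  unname(cfit[[slot]]$beta)
}

#' Aggregate benchmark rows into median and quartiles
#'
#' Quantiles use the default linear-interpolation definition (type 7); the
#' IQR is reported both as q75 - q25 and through the quartile pair.
#'
#' @param results Long data.frame as in \code{\link{run_benchmark}}.
#' @return data.frame with one row per method, cause, block and metric.
#' @export
aggregate_benchmark <- function(results) {
  metrics <- c("ppv", "fpr", "tpr", "f1")
  keys <- unique(results[, c("method", "cause", "block")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- results[results$method == keys$method[i] &
                     results$cause == keys$cause[i] &
                     results$block == keys$block[i], ]
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        method = keys$method[i], cause = keys$cause[i],
        block = keys$block[i], metric = m, n = length(v),
        median = q[2], q25 = q[1], q75 = q[3], iqr = q[3] - q[1])
    }
  }
  do.call(rbind, out)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result (%s design): %d replicates scored\n",
              x$design,
              if (is.null(x$results)) 0L else length(unique(x$results$replicate))))
  if (is.null(x$results)) {
    cat("  no successful replicates\n")
    return(invisible(x))
  }
  if (any(x$failures > 0)) {
    cat("  failures:\n")
    for (m in names(x$failures)[x$failures > 0])
      cat(sprintf("    %s: %d\n", m, x$failures[m]))
  }
  print(x$aggregates[x$aggregates$metric %in% c("ppv", "fpr"), ],
        row.names = FALSE)
  invisible(x)
}
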