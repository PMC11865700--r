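#' Construct a competing-risks survival dataset
#'
#' Bundles follow-up times, an event-status code and a covariate matrix into
#' the container used throughout the package. Status uses the convention
#' 0 = censored, 1 = event of cause 1, 2 = event of cause 2.
#'
#' @param time Numeric vector of strictly positive follow-up times.
#' @param status Integer vector with values in \{0, 1, 2\}.
#' @param X Numeric matrix (n rows, p columns) of covariates; no missing
#'   values allowed.
#' @param feature_names Optional character vector of p feature labels;
#'   defaults to the column names of \code{X} or \code{x1..xp}.
#' @return An object of class \code{survival_dataset}: a list with elements
#'   \code{time}, \code{status}, \code{X}, \code{feature_names}.
#' @export
survival_dataset <- function(time, status, X, feature_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  time <- as.numeric(time)
  status <- as.integer(status)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 observations")
  if (length(time) != n || length(status) != n)
    stop("time, status and X must have matching lengths")
  if (anyNA(time) || any(!is.finite(time)) || any(time <= 0))
    stop("all times must be strictly positive and finite")
  bad <- which(!(status %in% 0:2))
  if (length(bad))
    stop("status must be 0, 1 or 2; offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (anyNA(X) || any(!is.finite(X)))
    stop("covariate matrix contains missing or non-finite values")
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X)))
  }
  if (length(feature_names) != ncol(X))
    stop("feature_names must have one entry per column of X")
  colnames(X) <- feature_names
  structure(list(time = time, status = status, X = X,
                 feature_names = feature_names),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  tab <- table(factor(x$status, levels = 0:2))
  cat(sprintf("survival_dataset: n = %d, p = %d\n", length(x$time), ncol(x$X)))
  cat(sprintf("  status: %d censored, %d cause 1, %d cause 2\n",
              tab[[1]], tab[[2]], tab[[3]]))
  invisible(x)
}

#' Cause-specific view of a competing-risks dataset
#'
#' Recodes the status for a single cause: events of the competing cause are
#' treated as censored, yielding the binary indicator used by cause-specific
#' Cox models.
#'
#' @param data A \code{\link{survival_dataset}}.
#' @param cause Which event type, 1 or 2.
#' @return Object of class \code{cause_view}: list with \code{time},
#'   \code{delta} (binary indicator of the requested cause) and \code{cause}.
#' @export
cause_view <- function(data, cause) {
  stopifnot(inherits(data, "survival_dataset"))
  if (!(cause %in% c(1L, 2L))) stop("cause must be 1 or 2")
  structure(list(time = data$time,
                 delta = as.numeric(data$status == cause),
                 cause = as.integer(cause)),
            class = "cause_view")
}

#' @export
print.cause_view <- function(x, ...) {
  cat(sprintf("cause_view: cause %d, %d events / %d observations\n",
              x$cause, sum(x$delta), length(x$delta)))
  invisible(x)
}

# Sorting/tie bookkeeping shared by all partial-likelihood code: 0-based order
# of ascending time plus, per sorted position, the first and last sorted
# positions carrying the same time (Breslow tie groups).
time_order <- function(time) {
  ord <- order(time)
  ts <- time[ord]
  n <- length(ts)
  firsts <- match(ts, ts)                 # first index of each tie group
  lasts <- n + 1L - rev(match(rev(ts), rev(ts)))
  list(ord = ord - 1L, firsts = firsts - 1L, lasts = lasts - 1L)
}

#' Read a competing-risks dataset from CSV
#'
#' Expects a header with columns \code{time} and \code{status} followed by
#' one column per feature. Status codes are validated against \{0, 1, 2\}.
#'
#' @param path Path to a CSV file.
#' @return A \code{\link{survival_dataset}} with feature order preserved.
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("time", "status")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns 'time' and 'status'")
  feat <- setdiff(names(df), need)
  if (!length(feat)) stop("CSV contains no feature columns")
  bad <- which(!(df$status %in% 0:2))
  if (length(bad))
    stop("invalid status codes (must be 0/1/2) in rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad_t <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_t))
    stop("non-positive or missing times in rows: ",
         paste(utils::head(bad_t, 5L), collapse = ", "))
  X <- as.matrix(df[, feat, drop = FALSE])
  if (anyNA(X))
    stop("missing covariate values in rows: ",
         paste(utils::head(which(rowSums(is.na(X)) > 0), 5L), collapse = ", "))
  survival_dataset(df$time, df$status, X, feature_names = feat)
}

#' Write a competing-risks dataset to CSV
#'
#' Inverse of \code{\link{read_survival_csv}}.
#'
#' @param data A \code{\link{survival_dataset}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_survival_csv <- function(data, path) {
  stopifnot(inherits(data, "survival_dataset"))
  df <- data.frame(time = data$time, status = data$status, check.names = FALSE)
  df <- cbind(df, as.data.frame(data$X, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
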