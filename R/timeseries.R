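#' Multivariate abundance time series
#'
#' Container for a set of named, equally sampled time series (one column per
#' species or variable). This is the universal input of the network-inference
#' functions: every estimator and simulator in the package consumes or
#' produces a `time_series_set`.
#'
#' @param values numeric matrix (or data frame of numerics), one column per
#'   variable, one row per time point. All values must be finite.
#' @param names character vector of unique variable labels; defaults to the
#'   column names of `values` (or `V1`, `V2`, ... when absent).
#' @param dt_label optional free-text annotation of the sampling interval
#'   (e.g. `"biweekly"`); purely descriptive.
#'
#' @return An object of class `time_series_set`: a list with elements
#'   `values` (matrix with column names), `names`, and `dt_label`.
#' @export
time_series_set <- function(values, names = NULL, dt_label = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    oif_error("`values` must be a numeric matrix", "oifnet_bad_input")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    oif_error(sprintf("non-finite value at row %d, column %d", bad[1], bad[2]),
              "oifnet_bad_input")
  }
  if (is.null(names)) {
    names <- colnames(values)
    if (is.null(names)) names <- paste0("V", seq_len(ncol(values)))
  }
  if (length(names) != ncol(values)) {
    oif_error("`names` length must equal the number of columns",
              "oifnet_bad_input")
  }
  if (anyDuplicated(names)) {
    oif_error(sprintf("duplicate variable names: %s",
                      paste(unique(names[duplicated(names)]), collapse = ", ")),
              "oifnet_bad_input")
  }
  colnames(values) <- names
  structure(list(values = values, names = names, dt_label = dt_label),
            class = "time_series_set")
}

#' @export
print.time_series_set <- function(x, ...) {
  cat(sprintf("time_series_set: %d time points x %d variables\n",
              nrow(x$values), ncol(x$values)))
  cat("  variables:", paste(utils::head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) "..." else "", "\n")
  if (!is.null(x$dt_label)) cat("  sampling:", x$dt_label, "\n")
  invisible(x)
}

#' @export
as.matrix.time_series_set <- function(x, ...) x$values

#' Number of time points in a time series set
#' @param ts a `time_series_set`
#' @return integer
#' @export
n_points <- function(ts) nrow(as_time_series_set(ts)$values)

#' Number of variables in a time series set
#' @param ts a `time_series_set`
#' @return integer
#' @export
n_series <- function(ts) ncol(as_time_series_set(ts)$values)

#' Coerce to a time series set
#'
#' Accepts a `time_series_set` (returned unchanged), or a numeric matrix /
#' data frame that is wrapped via [time_series_set()].
#'
#' @param x object to coerce
#' @return a `time_series_set`
#' @export
as_time_series_set <- function(x) {
  if (inherits(x, "time_series_set")) return(x)
  time_series_set(x)
}

# package-level error helper: every condition carries a distinct class so
# tests and callers can catch specific failure modes
oif_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "oifnet_error")))
}
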