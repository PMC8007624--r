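#' Fit an optimal-information-flow interaction network
#'
#' The main entry point of the package: infers the directed predictive-
#' causality network of a multispecies time-series panel. For the
#' information-flow methods the source-target delay is first optimized
#' (globally or per pair) by maximizing mutual information, transfer entropy
#' is then evaluated at the optimal delay, and the resulting matrix is
#' min-max normalized for presentation and diversity analysis.
#'
#' @param x a [time_series_set()], or a numeric matrix / data frame with one
#'   column per species.
#' @param method `"te"` (transfer entropy, the optimal-information-flow
#'   score), `"mi"`, `"corr"`, or `"ccm"` (cross-map skill).
#' @param config an [estimator_config()].
#' @param delay_policy `"global_mi"` (default), `"fixed"` or `"per_pair"`;
#'   see [infer_interaction_matrix()].
#' @param u_range candidate delays for the delay search.
#' @param normalize keep the raw matrix alongside a min-max normalized one
#'   (default `TRUE`).
#' @param ... further arguments passed to [infer_interaction_matrix()]
#'   (embedding settings for `"ccm"`, bias correction for `"te"`).
#' @return An object of class `oif`, with components `matrix` (raw
#'   [interaction_matrix()]), `normalized` (normalized matrix or `NULL`),
#'   `method`, `config`, `delays`, `species`, `n` (time points).
#'   Supports `print()`, `summary()`, `coef()` (normalized scores) and
#'   `plot()`.
#' @examples
#' ts <- simulate_coupled_logistic(beta_yx = 0.8, n_steps = 400)
#' fit <- oif(ts, method = "te")
#' fit
#' coef(fit)
#' @export
oif <- function(x, method = c("te", "mi", "corr", "ccm"),
                config = estimator_config(),
                delay_policy = c("global_mi", "fixed", "per_pair"),
                u_range = 1:10, normalize = TRUE, ...) {
  method <- match.arg(method)
  delay_policy <- match.arg(delay_policy)
  ts <- as_time_series_set(x)
  m <- infer_interaction_matrix(ts, method = method, config = config,
                                delay_policy = delay_policy,
                                u_range = u_range, ...)
  norm <- if (normalize) suppressWarnings(normalize_matrix(m)) else NULL
  structure(list(matrix = m, normalized = norm, method = method,
                 config = config, delays = m$delays, species = ts$names,
                 n = nrow(ts$values)),
            class = "oif")
}

#' @export
print.oif <- function(x, ...) {
  cat(sprintf("oif network (%s): %d species, %d time points\n",
              x$method, length(x$species), x$n))
  if (!is.null(x$delays) && length(x$delays) == 1) {
    cat(sprintf("  global delay u = %d\n", x$delays))
  }
  off <- x$matrix$values[row(x$matrix$values) != col(x$matrix$values)]
  cat(sprintf("  raw score range: [%.4g, %.4g]\n", min(off), max(off)))
  invisible(x)
}

#' @export
summary.oif <- function(object, n_top = 10L, ...) {
  v <- if (!is.null(object$normalized)) object$normalized$values else
    object$matrix$values
  off <- which(row(v) != col(v), arr.ind = TRUE)
  ord <- order(v[off], decreasing = TRUE)
  top <- utils::head(ord, n_top)
  links <- data.frame(
    source = object$species[off[top, 1]],
    target = object$species[off[top, 2]],
    score = v[off[top, ]])
  out <- list(method = object$method, species = object$species,
              n = object$n, delays = object$delays, top_links = links,
              score_summary = summary(v[off]))
  class(out) <- "summary.oif"
  out
}

#' @export
print.summary.oif <- function(x, ...) {
  cat(sprintf("oif network summary (%s): %d species, %d time points\n",
              x$method, length(x$species), x$n))
  cat("strongest directed interactions:\n")
  print(x$top_links, row.names = FALSE)
  invisible(x)
}

#' @export
coef.oif <- function(object, normalized = TRUE, ...) {
  if (normalized && !is.null(object$normalized)) {
    object$normalized$values
  } else {
    object$matrix$values
  }
}

#' @export
plot.oif <- function(x, main = NULL, ...) {
  v <- coef(x)
  S <- nrow(v)
  graphics::image(seq_len(S), seq_len(S), t(v[S:1, , drop = FALSE]),
                  axes = FALSE, xlab = "target", ylab = "source",
                  main = if (is.null(main))
                    sprintf("%s interaction matrix", x$method) else main,
                  ...)
  graphics::axis(1, at = seq_len(S), labels = colnames(v), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(S), labels = rev(rownames(v)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}
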