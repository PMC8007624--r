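#' Construct an interaction matrix object
#'
#' @param values S x S numeric matrix of directed scores, entry (i, j) =
#'   score of the directed interaction i -> j; the diagonal is forced to 0.
#' @param method which estimator produced the scores.
#' @param species_names labels (defaults to the matrix dimnames).
#' @param normalized whether the off-diagonal entries are min-max scaled to
#'   \[0, 1\].
#' @param delays delay(s) used: a single global u or an S x S matrix.
#' @return An object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(values, method = c("te", "mi", "corr", "ccm"),
                               species_names = NULL, normalized = FALSE,
                               delays = NULL) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    oif_error("interaction matrix must be square", "oifnet_bad_input")
  }
  if (is.null(species_names)) {
    species_names <- rownames(values)
    if (is.null(species_names)) {
      species_names <- sprintf("sp%02d", seq_len(nrow(values)))
    }
  }
  dimnames(values) <- list(species_names, species_names)
  diag(values) <- 0
  structure(list(values = values, method = method,
                 species_names = species_names, normalized = normalized,
                 delays = delays),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix (%s%s): %d species\n", x$method,
              if (x$normalized) ", normalized" else "",
              nrow(x$values)))
  off <- x$values[row(x$values) != col(x$values)]
  cat(sprintf("  off-diagonal range: [%.4g, %.4g]\n",
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.matrix.interaction_matrix <- function(x, ...) x$values

#' Infer the directed pairwise interaction matrix of a community
#'
#' Fills every ordered species pair (i, j), i != j, with a directed
#' predictive-causality score: transfer entropy (`"te"`), mutual information
#' (`"mi"`, symmetric), linear correlation (`"corr"`, symmetric), or
#' cross-map skill (`"ccm"`, where entry (i, j) is the skill of estimating
#' species i from the shadow manifold of species j — the cross-mapping
#' convention for "i forces j").
#'
#' The time delay of the information estimators is set by `delay_policy`:
#' a global delay maximizing the mean MI across all pairs (`"global_mi"`,
#' the default), the fixed `config$u` (`"fixed"`), or a per-pair
#' MI-optimal delay (`"per_pair"`).
#'
#' Pairs involving a zero-variance (e.g. entirely absent) species score 0
#' with a warning rather than failing: species with many zeros are expected
#' to carry low information flow.
#'
#' @param ts a [time_series_set()] (or coercible matrix) with >= 2 species.
#' @param method `"te"`, `"mi"`, `"corr"` or `"ccm"`.
#' @param config an [estimator_config()].
#' @param delay_policy `"global_mi"`, `"fixed"` or `"per_pair"`.
#' @param u_range candidate delays scanned by the delay policies.
#' @param E,tau,theiler embedding settings for `method = "ccm"`.
#' @param bias_correction,n_shuffle,shuffle_seed optional shuffled-source
#'   baseline correction for `method = "te"` (see [transfer_entropy()]).
#' @return An [interaction_matrix()].
#' @export
infer_interaction_matrix <- function(ts, method = c("te", "mi", "corr", "ccm"),
                                     config = estimator_config(),
                                     delay_policy = c("global_mi", "fixed",
                                                      "per_pair"),
                                     u_range = 1:10,
                                     E = 3L, tau = 1L, theiler = 0L,
                                     bias_correction = c("none", "shuffle"),
                                     n_shuffle = 2L, shuffle_seed = NULL) {
  method <- match.arg(method)
  delay_policy <- match.arg(delay_policy)
  bias_correction <- match.arg(bias_correction)
  ts <- as_time_series_set(ts)
  m <- ts$values
  S <- ncol(m)
  if (S < 2) oif_error("need at least 2 species", "oifnet_bad_input")
  ok <- apply(m, 2, stats::sd) > 0
  if (any(!ok)) {
    warning(sprintf("zero-variance species scored 0: %s",
                    paste(ts$names[!ok], collapse = ", ")),
            call. = FALSE)
  }
  M <- matrix(0, S, S)
  delays <- NULL
  # resolve the working delay(s) for the information estimators
  if (method %in% c("te", "mi")) {
    if (delay_policy == "fixed") {
      delays <- config$u
    } else if (delay_policy == "global_mi") {
      delays <- global_mi_delay(ts, u_range = u_range, config = config)
    } else {
      delays <- matrix(NA_integer_, S, S)
    }
  }
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i == j) next
      if (!ok[i] || !ok[j]) { M[i, j] <- 0; next }
      M[i, j] <- tryCatch({
        switch(method,
          corr = pearson_corr(m[, i], m[, j]),
          mi = {
            u <- resolve_u(delay_policy, delays, i, j, m, u_range, config)
            if (delay_policy == "per_pair") delays[i, j] <- u
            mutual_information(m[, i], m[, j], u = u, config = config)
          },
          te = {
            u <- resolve_u(delay_policy, delays, i, j, m, u_range, config)
            if (delay_policy == "per_pair") delays[i, j] <- u
            cfg <- config; cfg$u <- as.integer(u)
            transfer_entropy(m[, i], m[, j], config = cfg,
                             bias_correction = bias_correction,
                             n_shuffle = n_shuffle,
                             shuffle_seed = if (is.null(shuffle_seed)) NULL
                                            else shuffle_seed + i * 137L + j)
          },
          ccm = simplex_cross_map(
            embed_series(m[, j], E = E, tau = tau), m[, i],
            theiler = theiler)$rho)
      }, oifnet_error = function(e) 0)
    }
  }
  interaction_matrix(M, method = if (method == "ccm") "ccm" else method,
                     species_names = ts$names, normalized = FALSE,
                     delays = delays)
}

#' Global MI-optimal delay of a community
#'
#' The delay maximizing the mean mutual-information profile across all
#' ordered species pairs — a single community-level optimum used when
#' per-pair delay selection is too unstable or too costly.
#'
#' @param ts a [time_series_set()].
#' @param u_range candidate positive delays.
#' @param config an [estimator_config()].
#' @return the selected integer delay.
#' @export
global_mi_delay <- function(ts, u_range = 1:10,
                            config = estimator_config()) {
  ts <- as_time_series_set(ts)
  m <- ts$values
  S <- ncol(m)
  ok <- apply(m, 2, stats::sd) > 0
  mi_sum <- rep(0, length(u_range)); mi_n <- rep(0, length(u_range))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j || !ok[i] || !ok[j]) next
    ds <- tryCatch(optimal_delay(m[, i], m[, j], u_range = u_range,
                                 config = config),
                   oifnet_error = function(e) NULL)
    if (is.null(ds)) next
    fin <- is.finite(ds$mi_profile)
    mi_sum[fin] <- mi_sum[fin] + ds$mi_profile[fin]
    mi_n[fin] <- mi_n[fin] + 1
  }
  if (all(mi_n == 0)) {
    oif_error("delay search failed for every pair",
              "oifnet_estimation_failed")
  }
  u_range[which.max(mi_sum / pmax(mi_n, 1))]
}

resolve_u <- function(delay_policy, delays, i, j, m, u_range, config) {
  if (delay_policy == "per_pair") {
    optimal_delay(m[, i], m[, j], u_range = u_range, config = config)$u_star
  } else if (delay_policy == "global_mi") {
    delays
  } else {
    config$u
  }
}

#' Min-max normalize an interaction matrix
#'
#' Floors negative off-diagonal scores at 0 (cross-map skill can be
#' negative; interaction magnitudes are presented on a \[0, 1\] scale),
#' then rescales the off-diagonal entries so the maximum is 1. An all-equal
#' matrix maps to all zeros with a warning.
#'
#' @param m an [interaction_matrix()].
#' @return the normalized [interaction_matrix()].
#' @export
normalize_matrix <- function(m) {
  stopifnot(inherits(m, "interaction_matrix"))
  v <- m$values
  off <- row(v) != col(v)
  vals <- v[off]
  if (all(!is.finite(vals))) {
    oif_error("no finite off-diagonal entries", "oifnet_bad_input")
  }
  vals[vals < 0] <- 0
  lo <- min(vals, na.rm = TRUE); hi <- max(vals, na.rm = TRUE)
  if (hi > lo) {
    vals <- (vals - lo) / (hi - lo)
  } else {
    warning("all off-diagonal entries equal; normalized matrix is all-zero",
            call. = FALSE)
    vals[] <- 0
  }
  v[off] <- vals
  diag(v) <- 0
  out <- m
  out$values <- v
  out$normalized <- TRUE
  out
}

#' Time-resolved dynamical interaction networks
#'
#' Infers one interaction matrix per time window at resolution `g` (the
#' minimum number of samples used for an inference): expanding windows
#' \[1..t\] for t = g, g + step, ..., n (the incremental scheme, default) or
#' sliding windows of fixed length `g`. A window whose inference fails
#' yields a missing (`NULL`) entry rather than an error.
#'
#' @param ts a [time_series_set()].
#' @param method,config,... forwarded to [infer_interaction_matrix()].
#' @param g window resolution in samples (default 30).
#' @param window_mode `"expanding"` or `"sliding"`.
#' @param step spacing between consecutive window endpoints (default 1).
#' @param normalize if `TRUE` (default) each matrix is min-max normalized.
#' @return An object of class `dynamical_networks`: list with `matrices`
#'   (list of [interaction_matrix()] or `NULL`), `windows` (data frame with
#'   `start`, `end`), `g`, `window_mode`, `method`.
#' @export
dynamical_networks <- function(ts, method = "te",
                               config = estimator_config(),
                               g = 30L, window_mode = c("expanding",
                                                        "sliding"),
                               step = 1L, normalize = TRUE,
                               delay_policy = c("global_mi", "fixed",
                                                "per_pair"),
                               u_range = 1:10, ...) {
  window_mode <- match.arg(window_mode)
  delay_policy <- match.arg(delay_policy)
  ts <- as_time_series_set(ts)
  n <- nrow(ts$values)
  g <- as.integer(g); step <- as.integer(step)
  if (n < g) oif_error("series shorter than the resolution g",
                       "oifnet_insufficient_data")
  if (g < 30L) {
    warning("resolution g below 30 samples is under the minimum-data rule",
            call. = FALSE)
  }
  ends <- seq(g, n, by = step)
  starts <- if (window_mode == "expanding") rep(1L, length(ends)) else
    ends - g + 1L
  # short windows cannot satisfy the 30-vector floor once the delay is
  # folded in; relax the floor inside windows (warned once above if g < 30)
  wconf <- config
  wconf$min_samples <- 2L
  # the community-level delay is resolved once on the full series, so every
  # window is inferred at the same u
  if (method %in% c("te", "mi") && delay_policy == "global_mi") {
    wconf$u <- as.integer(suppressWarnings(
      global_mi_delay(ts, u_range = u_range, config = wconf)))
    delay_policy <- "fixed"
  }
  mats <- vector("list", length(ends))
  failed <- 0L
  for (w in seq_along(ends)) {
    sub <- ts$values[starts[w]:ends[w], , drop = FALSE]
    mats[[w]] <- tryCatch({
      m <- suppressWarnings(
        infer_interaction_matrix(sub, method = method, config = wconf,
                                 delay_policy = delay_policy,
                                 u_range = u_range, ...))
      if (normalize) suppressWarnings(normalize_matrix(m)) else m
    }, oifnet_error = function(e) { failed <<- failed + 1L; NULL })
  }
  if (failed > 0) {
    warning(sprintf("%d of %d windows failed and are missing", failed,
                    length(ends)), call. = FALSE)
  }
  structure(list(matrices = mats,
                 windows = data.frame(start = starts, end = ends),
                 g = g, window_mode = window_mode, method = method),
            class = "dynamical_networks")
}

#' @export
print.dynamical_networks <- function(x, ...) {
  cat(sprintf("dynamical_networks: %d %s windows (g=%d, method=%s)\n",
              nrow(x$windows), x$window_mode, x$g, x$method))
  invisible(x)
}

#' Taxonomic alpha-diversity in a time window
#'
#' Counts the species with at least one strictly positive abundance inside
#' the window (observed species richness).
#'
#' @param ts a [time_series_set()].
#' @param window integer vector `c(start, end)` (defaults to the full
#'   series).
#' @return integer count in \[0, S\].
#' @export
taxonomic_alpha <- function(ts, window = NULL) {
  ts <- as_time_series_set(ts)
  n <- nrow(ts$values)
  if (is.null(window)) window <- c(1L, n)
  if (window[1] < 1 || window[2] > n || window[1] > window[2]) {
    oif_error("invalid or empty window", "oifnet_bad_input")
  }
  sub <- ts$values[window[1]:window[2], , drop = FALSE]
  sum(apply(sub, 2, function(v) any(v > 0)))
}

#' Effective alpha-diversity of a thresholded interaction network
#'
#' Counts the model-inferred interacting species: those with at least one
#' incident directed link (incoming or outgoing, configurable) whose
#' normalized score is at or above the threshold.
#'
#' @param m a normalized [interaction_matrix()].
#' @param theta threshold in \[0, 1\].
#' @param rule `"either"` (default), `"in"` or `"out"`: which incident links
#'   make a species count.
#' @return integer count in \[0, S\].
#' @export
effective_alpha <- function(m, theta, rule = c("either", "in", "out")) {
  rule <- match.arg(rule)
  stopifnot(inherits(m, "interaction_matrix"))
  if (!m$normalized) {
    oif_error("effective alpha requires a normalized matrix",
              "oifnet_bad_input")
  }
  if (theta < 0 || theta > 1) {
    oif_error("`theta` must lie in [0, 1]", "oifnet_bad_config")
  }
  v <- m$values
  inc <- (v >= theta & theta > 0) | (theta == 0 & v > 0)
  diag(inc) <- FALSE
  hit <- switch(rule,
                either = rowSums(inc) + colSums(inc) > 0,
                out = rowSums(inc) > 0,
                `in` = colSums(inc) > 0)
  sum(hit)
}

#' Effective and taxonomic alpha-diversity series of a dynamical network
#'
#' @param networks a [dynamical_networks()] object.
#' @param ts the [time_series_set()] the networks were inferred from.
#' @param theta interaction threshold applied to every window.
#' @param rule incidence rule, see [effective_alpha()].
#' @return A data frame with columns `time` (window end), `alpha_eff`,
#'   `alpha_tax`, `theta`; missing windows carry `NA`.
#' @export
alpha_diversity_series <- function(networks, ts, theta,
                                   rule = c("either", "in", "out")) {
  rule <- match.arg(rule)
  stopifnot(inherits(networks, "dynamical_networks"))
  ts <- as_time_series_set(ts)
  w <- networks$windows
  a_eff <- vapply(seq_len(nrow(w)), function(i) {
    m <- networks$matrices[[i]]
    if (is.null(m)) NA_real_ else effective_alpha(m, theta, rule = rule)
  }, numeric(1))
  a_tax <- vapply(seq_len(nrow(w)), function(i) {
    taxonomic_alpha(ts, c(w$start[i], w$end[i]))
  }, numeric(1))
  data.frame(time = w$end, alpha_eff = a_eff, alpha_tax = a_tax,
             theta = theta)
}

#' Optimize the interaction threshold against taxonomic diversity
#'
#' Scans a threshold grid; for each threshold the effective alpha-diversity
#' series of the dynamical networks is scored against the taxonomic
#' alpha-diversity series of the same windows, by Pearson correlation or by
#' plug-in mutual information of the two (integer) count series. The
#' threshold maximizing the score is selected (smallest on ties). A
#' degenerate (constant) series scores -Inf under correlation and 0 under
#' MI.
#'
#' @param networks a [dynamical_networks()] with at least 5 non-missing
#'   windows.
#' @param ts the underlying [time_series_set()].
#' @param theta_grid thresholds covering \[0, 1\]; must contain 0.2 and 0.3
#'   (the optimal thresholds reported for cross-map skill and transfer
#'   entropy).
#' @param criterion `"corr"` or `"mi"`.
#' @param rule incidence rule, see [effective_alpha()].
#' @return An object of class `threshold_search`: list with `theta_star`,
#'   `criterion`, `score_curve`, `theta_grid`, `alpha` (the diversity series
#'   at `theta_star`).
#' @export
optimize_threshold <- function(networks, ts,
                               theta_grid = seq(0, 1, by = 0.05),
                               criterion = c("corr", "mi"),
                               rule = c("either", "in", "out")) {
  criterion <- match.arg(criterion)
  rule <- match.arg(rule)
  stopifnot(inherits(networks, "dynamical_networks"))
  theta_grid <- sort(unique(theta_grid))
  has <- function(v) any(abs(theta_grid - v) < 1e-9)
  if (min(theta_grid) > 1e-9 || max(theta_grid) < 1 - 1e-9 ||
      !has(0.2) || !has(0.3)) {
    oif_error("`theta_grid` must cover [0, 1] and contain 0.2 and 0.3",
              "oifnet_bad_config")
  }
  n_ok <- sum(!vapply(networks$matrices, is.null, logical(1)))
  if (n_ok < 5) {
    oif_error("need at least 5 non-missing windows", "oifnet_bad_input")
  }
  ts <- as_time_series_set(ts)
  a_tax <- alpha_diversity_series(networks, ts, theta = 0,
                                  rule = rule)$alpha_tax
  scores <- vapply(theta_grid, function(th) {
    a_eff <- alpha_diversity_series(networks, ts, theta = th,
                                    rule = rule)$alpha_eff
    keep <- is.finite(a_eff) & is.finite(a_tax)
    ae <- a_eff[keep]; at <- a_tax[keep]
    if (criterion == "corr") {
      if (stats::sd(ae) == 0 || stats::sd(at) == 0) return(-Inf)
      stats::cor(ae, at)
    } else {
      if (stats::sd(ae) == 0 || stats::sd(at) == 0) return(0)
      symbol_mi(as.integer(ae), as.integer(at), log_base = 2)
    }
  }, numeric(1))
  theta_star <- theta_grid[which.max(scores)]   # first max = smallest theta
  structure(list(theta_star = theta_star, criterion = criterion,
                 score_curve = stats::setNames(scores, theta_grid),
                 theta_grid = theta_grid,
                 alpha = alpha_diversity_series(networks, ts,
                                                theta = theta_star,
                                                rule = rule)),
            class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("threshold_search (%s): theta* = %.2f (score %.4f)\n",
              x$criterion, x$theta_star,
              x$score_curve[as.character(x$theta_star)]))
  invisible(x)
}
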