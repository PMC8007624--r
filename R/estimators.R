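#' Configuration of the information-theoretic estimators
#'
#' Bundles the tuning parameters shared by the probability-density,
#' mutual-information and transfer-entropy estimators.
#'
#' @param r kernel/bin width in standardized (z-score) units. The default
#'   0.25 is the calibrated width used for ecological abundance series.
#' @param k Markov order of the target's own history (default 1: the next
#'   state depends on the current state only).
#' @param l Markov order of the source history (default 1).
#' @param u source-target time delay in samples (default 1).
#' @param log_base base of the logarithm: 2 for bits (default), `exp(1)` for
#'   nats.
#' @param estimator_kind `"histogram"` for a fixed grid of width `r` anchored
#'   at 0 (admits an exact brute-force oracle), or `"kernel"` for the
#'   box-kernel (step-kernel) estimator with max-norm radius `r`.
#' @param standardize if `TRUE` (default) each series is z-scored before
#'   binning, making `r` scale-free.
#' @param min_samples minimum number of usable paired sample vectors
#'   (default 30, the minimum-data rule shared with the network-inference
#'   resolution `g`).
#'
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(r = 0.25, k = 1L, l = 1L, u = 1L, log_base = 2,
                             estimator_kind = c("histogram", "kernel"),
                             standardize = TRUE, min_samples = 30L) {
  estimator_kind <- match.arg(estimator_kind)
  if (!is.numeric(r) || length(r) != 1 || r <= 0) {
    oif_error("`r` must be a positive number", "oifnet_bad_config")
  }
  k <- as.integer(k); l <- as.integer(l); u <- as.integer(u)
  if (k < 1L || l < 1L) oif_error("`k` and `l` must be >= 1", "oifnet_bad_config")
  if (u < 0L) oif_error("`u` must be >= 0", "oifnet_bad_config")
  if (!log_base %in% c(2, exp(1)) && !(is.numeric(log_base) && log_base > 1)) {
    oif_error("`log_base` must be a number > 1", "oifnet_bad_config")
  }
  structure(list(r = r, k = k, l = l, u = u, log_base = log_base,
                 estimator_kind = estimator_kind, standardize = standardize,
                 min_samples = as.integer(min_samples)),
            class = "estimator_config")
}

#' Standardize a series to zero mean and unit standard deviation
#'
#' @param x numeric vector with at least 2 points and nonzero variance.
#' @return the z-scored series.
#' @export
standardize_series <- function(x) {
  if (length(x) < 2) oif_error("need at least 2 points", "oifnet_bad_input")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    oif_error("zero-variance (constant) series", "oifnet_zero_variance")
  }
  (x - mean(x)) / s
}

# map a series onto integer bin indices of a fixed grid of width r anchored
# at 0 (bin m covers [m*r, (m+1)*r))
discretize_series <- function(x, r, standardize = TRUE) {
  if (standardize) x <- standardize_series(x)
  as.integer(floor(x / r))
}

#' Joint probability estimate on binned or kernel support
#'
#' Estimates the (joint) probability distribution of a set of points, either
#' on a fixed grid of equal-width bins anchored at 0 (`"histogram"`) or by
#' the box-kernel rule, where the probability mass at each sample point is
#' the fraction of samples within max-norm radius `r` (`"kernel"`).
#'
#' @param samples numeric matrix, one row per observation, one column per
#'   dimension (a vector is treated as one-dimensional). Samples are used as
#'   given; standardize beforehand if a scale-free width is wanted.
#' @param r positive bin width / kernel radius.
#' @param kind `"histogram"` or `"kernel"`.
#' @return An object of class `pdf_estimate`: list with `support` (matrix of
#'   bin indices for the histogram, sample coordinates for the kernel),
#'   `probabilities`, `dims` and `kind`. Histogram probabilities sum to 1;
#'   kernel values are pointwise masses in (0, 1].
#' @export
joint_pdf <- function(samples, r = 0.25, kind = c("histogram", "kernel")) {
  kind <- match.arg(kind)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (nrow(samples) < 1) oif_error("empty sample set", "oifnet_bad_input")
  if (r <= 0) oif_error("`r` must be positive", "oifnet_bad_config")
  n <- nrow(samples); d <- ncol(samples)
  if (kind == "histogram") {
    bins <- floor(samples / r)
    key <- apply(bins, 1, paste, collapse = "|")
    tab <- table(key)
    sup <- do.call(rbind, lapply(strsplit(names(tab), "|", fixed = TRUE),
                                 as.numeric))
    p <- as.numeric(tab) / n
  } else {
    # pointwise box-kernel mass: fraction of samples in the max-norm r-ball
    p <- vapply(seq_len(n), function(i) {
      within <- rep(TRUE, n)
      for (j in seq_len(d)) {
        within <- within & abs(samples[, j] - samples[i, j]) <= r
      }
      sum(within) / n
    }, numeric(1))
    sup <- samples
  }
  structure(list(support = sup, probabilities = p, dims = d, kind = kind,
                 r = r, n = n),
            class = "pdf_estimate")
}

#' Pearson linear correlation between two series
#'
#' The linear, non-lagged correlation
#' \deqn{\mathrm{corr}(X,Y)=\frac{\sum_t (x_t-\bar X)(y_t-\bar Y)}
#'   {\sqrt{\sum_t (x_t-\bar X)^2 \sum_t (y_t-\bar Y)^2}}.}
#'
#' @param x,y equal-length numeric series, both nonconstant.
#' @return correlation in \[-1, 1\].
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) {
    oif_error("series must have equal length", "oifnet_bad_input")
  }
  if (length(x) < 2) oif_error("need at least 2 points", "oifnet_bad_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    oif_error("zero-variance (constant) series", "oifnet_zero_variance")
  }
  stats::cor(x, y)
}

# lag-align two series so that x(t-u) is paired with y(t); u = 0 pairs
# contemporaneous values
lag_pairs <- function(x, y, u) {
  n <- length(x)
  if (u == 0) return(list(x = x, y = y))
  if (u >= n) oif_error("delay exceeds series length", "oifnet_insufficient_data")
  list(x = x[seq_len(n - u)], y = y[(1 + u):n])
}

# plug-in MI (chosen base) from two integer symbol sequences; 0 log 0 = 0
symbol_mi <- function(a, b, log_base = 2) {
  jt <- table(a, b) / length(a)
  px <- rowSums(jt); py <- colSums(jt)
  terms <- jt * log(jt / outer(px, py), base = log_base)
  terms[jt == 0] <- 0
  sum(terms)
}

#' Mutual information between two series at a time delay
#'
#' Plug-in mutual information \eqn{MI(X(t-u); Y(t))} on binned or box-kernel
#' probability estimates. The first series is shifted `u` samples into the
#' past relative to the second; `u = 0` gives the symmetric contemporaneous
#' MI.
#'
#' @param x source series (shifted backwards by `u`).
#' @param y target series.
#' @param u non-negative integer delay in samples.
#' @param config an [estimator_config()].
#' @return MI in units of `config$log_base` (bits by default), >= 0 up to
#'   numerical slack.
#' @export
mutual_information <- function(x, y, u = 0L, config = estimator_config()) {
  u <- as.integer(u)
  if (u < 0) oif_error("`u` must be >= 0", "oifnet_bad_config")
  if (length(x) != length(y)) {
    oif_error("series must have equal length", "oifnet_bad_input")
  }
  if (length(x) - u < config$min_samples) {
    oif_error(sprintf(
      "only %d paired points after shifting by u=%d (need >= %d)",
      length(x) - u, u, config$min_samples), "oifnet_insufficient_data")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    oif_error("zero-variance (constant) series", "oifnet_zero_variance")
  }
  if (config$estimator_kind == "histogram") {
    sx <- discretize_series(x, config$r, config$standardize)
    sy <- discretize_series(y, config$r, config$standardize)
    p <- lag_pairs(sx, sy, u)
    symbol_mi(p$x, p$y, config$log_base)
  } else {
    zx <- if (config$standardize) standardize_series(x) else x
    zy <- if (config$standardize) standardize_series(y) else y
    p <- lag_pairs(zx, zy, u)
    kernel_mi_counts(p$x, p$y, config$r) / log(config$log_base)
  }
}

# build the lag-aligned (target now, target past block, source past block)
# design for TE; returns a list of integer/numeric matrices
te_design <- function(source, target, u, k, l) {
  n <- length(target)
  t0 <- (u + max(k, l)):n
  if (length(t0) < 1 || t0[1] < 1) {
    oif_error("series too short for the requested (u, k, l)",
              "oifnet_insufficient_data")
  }
  list(
    now = target[t0],
    target_past = vapply(seq_len(k), function(j) target[t0 - u - (j - 1)],
                         numeric(length(t0))),
    source_past = vapply(seq_len(l), function(j) source[t0 - u - (j - 1)],
                         numeric(length(t0))),
    n_vectors = length(t0)
  )
}

# plug-in TE from the binned design via frequency tables; 0 log 0 = 0 terms
# never arise because only occupied cells are enumerated
histogram_te <- function(now, target_past, source_past, log_base) {
  key <- function(m) {
    if (is.matrix(m)) apply(m, 1, paste, collapse = ",") else as.character(m)
  }
  a <- as.character(now); b <- key(target_past); cc <- key(source_past)
  N <- length(a)
  n_abc <- table(paste(a, b, cc, sep = "|"))
  n_ab <- table(paste(a, b, sep = "|"))
  n_bc <- table(paste(b, cc, sep = "|"))
  n_b <- table(b)
  parts <- strsplit(names(n_abc), "|", fixed = TRUE)
  aa <- vapply(parts, `[`, "", 1)
  bb <- vapply(parts, `[`, "", 2)
  ccp <- vapply(parts, `[`, "", 3)
  num <- as.numeric(n_abc) * as.numeric(n_b[bb])
  den <- as.numeric(n_ab[paste(aa, bb, sep = "|")]) *
    as.numeric(n_bc[paste(bb, ccp, sep = "|")])
  sum(as.numeric(n_abc) / N * log(num / den, base = log_base))
}

#' Transfer entropy from a source to a target series
#'
#' Plug-in transfer entropy
#' \deqn{TE_{S \to T}^{(k,l)} = \sum p(T_t, T_{t-u}^{(k)}, S_{t-u}^{(l)})
#'   \log \frac{p(T_t \mid T_{t-u}^{(k)}, S_{t-u}^{(l)})}
#'             {p(T_t \mid T_{t-u}^{(k)})}}
#' on binned (`"histogram"`) or box-kernel (`"kernel"`) probability
#' estimates. The histogram kind supports arbitrary Markov orders `k`, `l`;
#' the kernel kind implements the memoryless case `k = l = 1`.
#'
#' An optional shuffled-source baseline correction ("effective" transfer
#' entropy) subtracts the mean TE obtained after permuting the source series,
#' removing the finite-sample bias shared by all pairs of a panel. It is a
#' bias correction, not a significance test.
#'
#' @param source,target equal-length numeric series.
#' @param config an [estimator_config()]; `config$u` must be >= 1.
#' @param bias_correction `"none"` (default) or `"shuffle"`.
#' @param n_shuffle number of source permutations averaged for the baseline.
#' @param shuffle_seed integer seed making the baseline reproducible.
#' @return TE in units of `config$log_base`, >= 0 up to numerical slack
#'   (the corrected version can be negative).
#' @export
transfer_entropy <- function(source, target, config = estimator_config(),
                             bias_correction = c("none", "shuffle"),
                             n_shuffle = 2L, shuffle_seed = NULL) {
  bias_correction <- match.arg(bias_correction)
  if (length(source) != length(target)) {
    oif_error("series must have equal length", "oifnet_bad_input")
  }
  if (config$u < 1L) oif_error("TE requires `u` >= 1", "oifnet_bad_config")
  n_vec <- length(target) - config$u - max(config$k, config$l) + 1L
  if (n_vec < config$min_samples) {
    oif_error(sprintf("only %d sample vectors (need >= %d)", n_vec,
                      config$min_samples), "oifnet_insufficient_data")
  }
  if (stats::sd(source) == 0 || stats::sd(target) == 0) {
    oif_error("zero-variance (constant) series", "oifnet_zero_variance")
  }
  raw <- te_once(source, target, config)
  if (bias_correction == "none") return(raw)
  if (!is.null(shuffle_seed)) set.seed(as.integer(shuffle_seed))
  baseline <- mean(vapply(seq_len(n_shuffle), function(i) {
    te_once(sample(source), target, config)
  }, numeric(1)))
  raw - baseline
}

te_once <- function(source, target, config) {
  if (config$estimator_kind == "histogram") {
    s <- discretize_series(source, config$r, config$standardize)
    x <- discretize_series(target, config$r, config$standardize)
    d <- te_design(s, x, config$u, config$k, config$l)
    histogram_te(d$now, d$target_past, d$source_past, config$log_base)
  } else {
    if (config$k != 1L || config$l != 1L) {
      oif_error("kernel TE implements k = l = 1 only", "oifnet_bad_config")
    }
    zs <- if (config$standardize) standardize_series(source) else source
    zt <- if (config$standardize) standardize_series(target) else target
    d <- te_design(zs, zt, config$u, 1L, 1L)
    kernel_te_counts(d$now, d$target_past[, 1], d$source_past[, 1],
                     config$r) / log(config$log_base)
  }
}

#' Exact brute-force transfer-entropy oracle on symbol sequences
#'
#' Independent reference implementation of the plug-in transfer entropy for
#' pre-discretized integer sequences: enumerates every observed
#' (target-now, target-past, source-past) tuple, accumulates exact empirical
#' frequencies in hash environments, and evaluates the defining sum term by
#' term. Used to validate [transfer_entropy()] with histogram binning.
#'
#' @param source_symbols,target_symbols equal-length integer vectors.
#' @param u positive delay; `k`, `l` Markov orders.
#' @param log_base base of the logarithm (default 2).
#' @return the plug-in TE.
#' @export
plugin_te_oracle <- function(source_symbols, target_symbols, u = 1L,
                             k = 1L, l = 1L, log_base = 2) {
  if (length(source_symbols) != length(target_symbols)) {
    oif_error("length mismatch", "oifnet_bad_input")
  }
  u <- as.integer(u); k <- as.integer(k); l <- as.integer(l)
  n <- length(target_symbols)
  t0 <- (u + max(k, l)):n
  count <- function() new.env(hash = TRUE, parent = emptyenv())
  inc <- function(env, key) {
    assign(key, (if (exists(key, envir = env)) get(key, envir = env) else 0) + 1,
           envir = env)
  }
  e_abc <- count(); e_ab <- count(); e_bc <- count(); e_b <- count()
  keys <- character(length(t0))
  for (idx in seq_along(t0)) {
    t <- t0[idx]
    a <- target_symbols[t]
    b <- paste(target_symbols[t - u - seq_len(k) + 1], collapse = ",")
    cc <- paste(source_symbols[t - u - seq_len(l) + 1], collapse = ",")
    k_abc <- paste(a, b, cc, sep = "|")
    inc(e_abc, k_abc)
    inc(e_ab, paste(a, b, sep = "|"))
    inc(e_bc, paste(b, cc, sep = "|"))
    inc(e_b, b)
    keys[idx] <- k_abc
  }
  N <- length(t0)
  total <- 0
  for (key in ls(e_abc)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    n_abc <- get(key, envir = e_abc)
    n_ab <- get(paste(parts[1], parts[2], sep = "|"), envir = e_ab)
    n_bc <- get(paste(parts[2], parts[3], sep = "|"), envir = e_bc)
    n_b <- get(parts[2], envir = e_b)
    total <- total + n_abc / N * log((n_abc * n_b) / (n_ab * n_bc),
                                     base = log_base)
  }
  total
}

#' Select the time delay maximizing mutual information
#'
#' Scans a set of candidate delays, computes \eqn{MI(X(t-u); Y(t))} for each,
#' and selects the delay with the maximum MI (the smallest candidate on
#' ties). The associated information distance \eqn{d = e^{-MI}} (MI in nats)
#' is returned per candidate.
#'
#' @param x source series (its past is scanned).
#' @param y target series.
#' @param u_range non-empty set of positive integer candidate delays.
#' @param config an [estimator_config()].
#' @return An object of class `delay_search`: list with `u_star`,
#'   `mi_profile` (in `config$log_base` units), `distance_profile`,
#'   `u_range`.
#' @export
optimal_delay <- function(x, y, u_range = 1:10,
                          config = estimator_config()) {
  u_range <- as.integer(u_range)
  if (length(u_range) < 1 || any(u_range < 1)) {
    oif_error("`u_range` must be a non-empty set of positive delays",
              "oifnet_bad_config")
  }
  mi <- vapply(u_range, function(u) {
    tryCatch(mutual_information(x, y, u = u, config = config),
             oifnet_error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(mi))) {
    oif_error("mutual information failed for every candidate delay",
              "oifnet_estimation_failed")
  }
  mi_nats <- mi * log(config$log_base)
  u_star <- u_range[which.max(replace(mi, is.na(mi), -Inf))]
  structure(list(u_star = u_star, u_range = u_range, mi_profile = mi,
                 distance_profile = exp(-mi_nats), log_base = config$log_base),
            class = "delay_search")
}

#' @export
print.delay_search <- function(x, ...) {
  cat(sprintf("delay search over u in {%s}: u* = %d (MI = %.4f)\n",
              paste(range(x$u_range), collapse = ".."), x$u_star,
              x$mi_profile[match(x$u_star, x$u_range)]))
  invisible(x)
}

#' Information distance from a mutual information value
#'
#' \eqn{d(X, Y) = e^{-MI}} with MI in nats; a metric-like dissimilarity in
#' (0, 1]: independent variables are at distance 1, strongly informative
#' pairs approach 0.
#'
#' @param mi_nats non-negative MI in nats.
#' @return distance in (0, 1].
#' @export
info_distance <- function(mi_nats) {
  if (any(mi_nats < 0)) oif_error("MI must be >= 0", "oifnet_bad_input")
  exp(-mi_nats)
}

#' Parameters of a bivariate first-order Gaussian autoregression
#'
#' @param A 2x2 coefficient matrix with spectral radius < 1.
#' @param noise_cov 2x2 symmetric positive-definite innovation covariance.
#' @param n number of samples to simulate.
#' @param seed integer seed.
#' @return An object of class `var_params`.
#' @export
var_params <- function(A, noise_cov = diag(2), n = 1000L, seed = 1L) {
  A <- as.matrix(A); noise_cov <- as.matrix(noise_cov)
  if (!all(dim(A) == c(2, 2)) || !all(dim(noise_cov) == c(2, 2))) {
    oif_error("`A` and `noise_cov` must be 2x2", "oifnet_bad_config")
  }
  if (max(abs(eigen(A, only.values = TRUE)$values)) >= 1) {
    oif_error("`A` must have spectral radius < 1 (stationarity)",
              "oifnet_nonstationary")
  }
  if (max(abs(noise_cov - t(noise_cov))) > 1e-12 ||
      any(eigen(noise_cov, only.values = TRUE)$values <= 0)) {
    oif_error("`noise_cov` must be symmetric positive-definite",
              "oifnet_bad_config")
  }
  structure(list(A = A, noise_cov = noise_cov, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "var_params")
}

# stationary covariance of Z_t = A Z_{t-1} + eps via the discrete Lyapunov
# equation Sigma = A Sigma A' + Q, solved exactly through vectorization
stationary_covariance <- function(A, Q) {
  matrix(solve(diag(4) - kronecker(A, A), as.vector(Q)), 2, 2)
}

#' Closed-form transfer entropy of a Gaussian VAR(1)
#'
#' For Gaussian autoregressive processes transfer entropy coincides with
#' Granger causality: \eqn{TE = \tfrac12 \log(\sigma^2_{restricted} /
#' \sigma^2_{full})}, where the full innovation variance conditions the
#' target on both lagged components and the restricted one on the target's
#' own past only. Both variances follow analytically from the stationary
#' solution of the discrete Lyapunov equation.
#'
#' @param params a [var_params()] (variable 1 is "x", variable 2 is "y").
#' @param direction `"x_to_y"` or `"y_to_x"`.
#' @param log_base 2 for bits (default), `exp(1)` for nats.
#' @return the transfer entropy.
#' @export
analytic_gaussian_te <- function(params, direction = c("x_to_y", "y_to_x"),
                                 log_base = 2) {
  direction <- match.arg(direction)
  stopifnot(inherits(params, "var_params"))
  tgt <- if (direction == "x_to_y") 2L else 1L
  A <- params$A; Q <- params$noise_cov
  Sigma <- stationary_covariance(A, Q)
  Gamma1 <- A %*% Sigma                       # Cov(Z_t, Z_{t-1})
  # full model: regression on both lagged components recovers the VAR row,
  # leaving exactly the innovation variance
  s2_full <- Q[tgt, tgt]
  # restricted model: target regressed on its own past only
  s2_restricted <- Sigma[tgt, tgt] - Gamma1[tgt, tgt]^2 / Sigma[tgt, tgt]
  0.5 * log(s2_restricted / s2_full, base = log_base)
}

#' Convert an information value between logarithm bases
#'
#' @param value information value.
#' @param from,to source and destination bases (e.g. 2 and `exp(1)`).
#' @return the converted value; bits = nats / ln 2 exactly.
#' @export
convert_info_units <- function(value, from = 2, to = exp(1)) {
  value * log(from) / log(to)
}
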