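#' Parameters of the coupled logistic two-species model
#'
#' The benchmark system of two diffusively coupled logistic maps
#' \deqn{X(t+1) = X(t)\,[r_x - r_x X(t) - \beta_{xy} Y(t)]}
#' \deqn{Y(t+1) = Y(t)\,[r_y - r_y Y(t) - \beta_{yx} X(t)]}
#' where \eqn{\beta_{xy}} is the strength of the effect of Y on X and
#' \eqn{\beta_{yx}} that of X on Y. With \eqn{\beta_{xy} = 0} the system is
#' unidirectional (X drives Y). Defaults are the standard chaotic benchmark
#' values \eqn{r_x = 3.8, r_y = 3.5, x_0 = 0.4, y_0 = 0.2}.
#'
#' @param beta_xy,beta_yx coupling strengths in \[0, 1\].
#' @param r_x,r_y intrinsic growth rates.
#' @param x0,y0 initial states in (0, 1).
#' @param n_steps total number of iterates to generate (including the
#'   initial state).
#' @param transient number of initial steps to discard (default 0).
#' @return An object of class `coupled_logistic_params`.
#' @export
coupled_logistic_params <- function(beta_xy = 0, beta_yx = 0,
                                    r_x = 3.8, r_y = 3.5,
                                    x0 = 0.4, y0 = 0.2,
                                    n_steps = 1000L, transient = 0L) {
  if (beta_xy < 0 || beta_xy > 1 || beta_yx < 0 || beta_yx > 1) {
    oif_error("couplings must lie in [0, 1]", "oifnet_bad_config")
  }
  n_steps <- as.integer(n_steps); transient <- as.integer(transient)
  if (n_steps <= transient || transient < 0) {
    oif_error("need n_steps > transient >= 0", "oifnet_bad_config")
  }
  structure(list(beta_xy = beta_xy, beta_yx = beta_yx, r_x = r_x, r_y = r_y,
                 x0 = x0, y0 = y0, n_steps = n_steps, transient = transient),
            class = "coupled_logistic_params")
}

#' Simulate the coupled logistic two-species model
#'
#' Deterministically iterates the coupled logistic map (see
#' [coupled_logistic_params()]). No noise is added and no clipping is
#' applied: trajectories leaving \[-0.5, 1.5\] abort with a divergence error
#' (optionally, `floor_at_zero` clamps negative states at 0 instead).
#'
#' @param params a [coupled_logistic_params()]; alternatively pass the
#'   parameters through `...`.
#' @param floor_at_zero if `TRUE`, negative iterates are set to 0 rather than
#'   trapped by the divergence check.
#' @param ... parameters forwarded to [coupled_logistic_params()] when
#'   `params` is missing.
#' @return A [time_series_set()] with columns `X` and `Y` of length
#'   `n_steps - transient`; parameters attached as attribute `"params"`.
#' @export
simulate_coupled_logistic <- function(params = NULL, floor_at_zero = FALSE,
                                      ...) {
  if (is.null(params)) params <- coupled_logistic_params(...)
  stopifnot(inherits(params, "coupled_logistic_params"))
  if (params$x0 == 0 || params$y0 == 0) {
    oif_error("zero initial state is absorbing (the map fixes 0)",
              "oifnet_degenerate_dynamics")
  }
  n <- params$n_steps
  x <- numeric(n); y <- numeric(n)
  x[1] <- params$x0; y[1] <- params$y0
  for (t in seq_len(n - 1)) {
    x[t + 1] <- x[t] * (params$r_x - params$r_x * x[t] - params$beta_xy * y[t])
    y[t + 1] <- y[t] * (params$r_y - params$r_y * y[t] - params$beta_yx * x[t])
    if (floor_at_zero) {
      x[t + 1] <- max(x[t + 1], 0); y[t + 1] <- max(y[t + 1], 0)
    }
    if (!is.finite(x[t + 1]) || !is.finite(y[t + 1]) ||
        x[t + 1] < -0.5 || x[t + 1] > 1.5 ||
        y[t + 1] < -0.5 || y[t + 1] > 1.5) {
      oif_error(sprintf("trajectory diverged at step %d", t + 1),
                "oifnet_divergent_dynamics")
    }
    if (x[t + 1] == 0 && y[t + 1] == 0) {
      oif_error(sprintf("both species absorbed at 0 at step %d", t + 1),
                "oifnet_degenerate_dynamics")
    }
  }
  keep <- (params$transient + 1):n
  out <- time_series_set(cbind(X = x[keep], Y = y[keep]))
  attr(out, "params") <- params
  out
}

#' Parameters of the synthetic multispecies community
#'
#' Generator emulating a biweekly multispecies census: a minority of
#' always-present, strongly interacting species with chaotic intrinsic
#' dynamics (multiplicative logistic updates coupled through the directed
#' matrix `B`, generalizing the two-species map), shared sinusoidal seasonal
#' forcing on the growth rates, lognormal observation noise, and a set of
#' rare species observed sporadically (zero-inflated low counts with
#' seasonally modulated detection).
#'
#' When `B` (or `r`) is `NULL`, defaults are drawn under `seed`: species
#' 1..5 form a directed interaction ring with two chord links (couplings
#' about `b_core`) and chaotic growth rates in \[3.6, 3.9\]; the remaining
#' species are non-interacting stable populations (growth rates in
#' \[2.2, 2.8\]) perturbed by process noise.
#'
#' @param S number of species (>= 2).
#' @param B `S x S` directed coupling matrix (entry \[i, j\] = effect of
#'   species i on species j), or `NULL` for the planted default.
#' @param r length-`S` growth-rate vector, or `NULL` for the default.
#' @param b_core coupling scale of the planted interacting core.
#' @param seasonal_amplitude relative amplitude of the shared sinusoidal
#'   forcing on growth rates.
#' @param seasonal_period forcing period in samples (26 = annual cycle at
#'   biweekly sampling).
#' @param noise_sd standard deviation of the lognormal observation noise.
#' @param process_sd process-noise standard deviation applied to the
#'   non-chaotic species.
#' @param rare_species_mask indices simulated as zero-inflated sporadic
#'   species (default: every species outside the interacting core).
#' @param rare_detection mean per-sample detection probability of rare
#'   species.
#' @param rare_detection_seasonality strength of the seasonal modulation of
#'   detection (0 = none).
#' @param rare_scale abundance scale factor of rare species.
#' @param n_steps series length (default 285, a 12-year biweekly census).
#' @param seed integer seed governing every random draw.
#' @param interaction_threshold couplings with `|B|` at or above this value
#'   define the ground-truth interacting species set.
#' @return An object of class `community_params`.
#' @export
community_params <- function(S = 15L, B = NULL, r = NULL, b_core = 0.5,
                             seasonal_amplitude = 0.1, seasonal_period = 26,
                             noise_sd = 0.1, process_sd = 0.05,
                             rare_species_mask = NULL,
                             rare_detection = 0.0045,
                             rare_detection_seasonality = 4,
                             rare_scale = 0.15,
                             n_steps = 285L, seed = 42L,
                             interaction_threshold = 0.1) {
  S <- as.integer(S)
  if (S < 2) oif_error("need at least 2 species", "oifnet_bad_config")
  if (!is.null(B)) {
    B <- as.matrix(B)
    if (!all(dim(B) == c(S, S))) {
      oif_error("`B` must be S x S", "oifnet_bad_config")
    }
  }
  if (!is.null(rare_species_mask) &&
      !all(rare_species_mask %in% seq_len(S))) {
    oif_error("`rare_species_mask` must index species 1..S",
              "oifnet_bad_config")
  }
  structure(list(S = S, B = B, r = r, b_core = b_core,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_period = seasonal_period, noise_sd = noise_sd,
                 process_sd = process_sd,
                 rare_species_mask = rare_species_mask,
                 rare_detection = rare_detection,
                 rare_detection_seasonality = rare_detection_seasonality,
                 rare_scale = rare_scale, n_steps = as.integer(n_steps),
                 seed = as.integer(seed),
                 interaction_threshold = interaction_threshold),
            class = "community_params")
}

#' Simulate the synthetic multispecies community
#'
#' Runs the community generator (see [community_params()]) and returns the
#' observed abundances together with the ground truth needed for recovery
#' tests: the coupling matrix and the set of truly interacting species
#' (those with at least one `|B|` entry at or above the generator's
#' interaction threshold).
#'
#' @param params a [community_params()]; alternatively pass parameters
#'   through `...`.
#' @param ... forwarded to [community_params()] when `params` is missing.
#' @return An object of class `community_sim`: list with `ts` (a
#'   [time_series_set()], `n_steps x S`), `B`, `interacting` (integer
#'   indices), `rare_species`, and `params`.
#' @export
simulate_community <- function(params = NULL, ...) {
  if (is.null(params)) params <- community_params(...)
  stopifnot(inherits(params, "community_params"))
  S <- params$S; n <- params$n_steps
  set.seed(params$seed)
  core_default <- seq_len(min(5L, S - 1L))
  B <- params$B
  if (is.null(B)) {
    B <- matrix(0, S, S)
    nc <- length(core_default)
    for (k in core_default) {
      B[k, if (k == nc) 1L else k + 1L] <- params$b_core * stats::runif(1, 0.9, 1.1)
    }
    if (nc >= 5) {                 # two chord links thicken the core web
      B[1, 3] <- params$b_core * 0.8
      B[2, 5] <- params$b_core * 0.9
    }
  }
  chaotic <- which(apply(B != 0, 1, any) | apply(B != 0, 2, any))
  if (length(chaotic) == 0) chaotic <- core_default
  quiet <- setdiff(seq_len(S), chaotic)
  r <- params$r
  if (is.null(r)) {
    r <- numeric(S)
    r[chaotic] <- stats::runif(length(chaotic), 3.6, 3.9)
    r[quiet] <- stats::runif(length(quiet), 2.2, 2.8)
  }
  rare <- params$rare_species_mask
  if (is.null(rare)) rare <- quiet
  x <- matrix(NA_real_, n, S)
  x[1, ] <- stats::runif(S, 0.2, 0.6)
  for (t in seq_len(n - 1)) {
    rt <- r * (1 + params$seasonal_amplitude *
                 sin(2 * pi * t / params$seasonal_period))
    xn <- x[t, ] * (rt - rt * x[t, ] - as.vector(t(B) %*% x[t, ]))
    if (length(quiet) > 0 && params$process_sd > 0) {
      xn[quiet] <- xn[quiet] + stats::rnorm(length(quiet), 0, params$process_sd)
    }
    # clipped multiplicative update: states confined to (0, 1)
    x[t + 1, ] <- pmin(pmax(xn, 1e-3), 0.999)
    if (any(!is.finite(x[t + 1, ]))) {
      oif_error(sprintf("non-finite community state at step %d", t + 1),
                "oifnet_divergent_dynamics")
    }
  }
  obs <- x
  if (params$noise_sd > 0) {
    obs <- obs * exp(matrix(stats::rnorm(n * S, 0, params$noise_sd), n, S))
  }
  if (length(rare) > 0 && params$rare_detection < 1) {
    season <- (1 + sin(2 * pi * seq_len(n) / params$seasonal_period)) / 2
    p_t <- params$rare_detection *
      (1 + params$rare_detection_seasonality * season) /
      (1 + params$rare_detection_seasonality / 2)
    p_t <- pmin(pmax(p_t, 0), 1)
    for (j in rare) {
      obs[, j] <- obs[, j] * stats::rbinom(n, 1, p_t) * params$rare_scale
    }
  }
  interacting <- which(
    apply(abs(B) >= params$interaction_threshold, 1, any) |
      apply(abs(B) >= params$interaction_threshold, 2, any))
  ts <- time_series_set(obs, names = sprintf("sp%02d", seq_len(S)),
                        dt_label = "biweekly")
  structure(list(ts = ts, B = B, interacting = interacting,
                 rare_species = rare, params = params),
            class = "community_sim")
}

#' @export
print.community_sim <- function(x, ...) {
  cat(sprintf("community_sim: %d species x %d time points\n",
              ncol(x$ts$values), nrow(x$ts$values)))
  cat(sprintf("  interacting species: %s\n",
              paste(x$interacting, collapse = ", ")))
  cat(sprintf("  rare (zero-inflated) species: %s\n",
              paste(x$rare_species, collapse = ", ")))
  invisible(x)
}

#' Simulate a bivariate Gaussian first-order autoregression
#'
#' \eqn{Z_t = A Z_{t-1} + \epsilon_t}, \eqn{\epsilon_t \sim N(0, Q)}. The
#' empirical lag-0 covariance converges to the stationary solution of the
#' discrete Lyapunov equation \eqn{\Sigma = A \Sigma A' + Q} as the sample
#' size grows.
#'
#' @param params a [var_params()]; alternatively pass parameters through
#'   `...`.
#' @param ... forwarded to [var_params()] when `params` is missing.
#' @return A [time_series_set()] with columns `X` and `Y`.
#' @export
simulate_gaussian_var <- function(params = NULL, ...) {
  if (is.null(params)) params <- var_params(...)
  stopifnot(inherits(params, "var_params"))
  set.seed(params$seed)
  n <- params$n
  L <- chol(params$noise_cov)
  eps <- matrix(stats::rnorm(2 * n), n, 2) %*% L
  Z <- matrix(0, n, 2)
  Z[1, ] <- eps[1, ]
  for (t in 2:n) Z[t, ] <- as.vector(params$A %*% Z[t - 1, ]) + eps[t, ]
  out <- time_series_set(Z, names = c("X", "Y"))
  attr(out, "params") <- params
  out
}

#' Simulate a pair of series with a known coupling lag
#'
#' Generates a driver X (chaotic logistic map or i.i.d. Gaussian) and a
#' response \eqn{Y(t) = g(X(t - u_0)) + \epsilon}, with a fixed nonlinear
#' `g` by default. Used for delay-recovery tests of [optimal_delay()].
#'
#' @param u0 positive integer ground-truth lag.
#' @param n series length (must exceed `u0 + 10`).
#' @param noise_sd standard deviation of the additive response noise.
#' @param seed integer seed.
#' @param driver `"logistic"` (chaotic, r = 3.9) or `"gaussian"` (i.i.d.).
#' @param g response function; default the nonlinear square. (Avoid
#'   responses resembling the driver's own one-step map, which would shift
#'   the recoverable lag.)
#' @return A [time_series_set()] with columns `X` and `Y`; the true lag is
#'   attached as attribute `"true_lag"`.
#' @export
simulate_lagged_coupling <- function(u0, n = 1000L, noise_sd = 0,
                                     seed = 1L,
                                     driver = c("logistic", "gaussian"),
                                     g = function(x) x^2) {
  driver <- match.arg(driver)
  u0 <- as.integer(u0); n <- as.integer(n)
  if (u0 <= 0) oif_error("`u0` must be a positive lag", "oifnet_bad_config")
  if (n <= u0 + 10L) oif_error("need n > u0 + 10", "oifnet_bad_config")
  set.seed(as.integer(seed))
  if (driver == "logistic") {
    x <- numeric(n + u0)
    x[1] <- stats::runif(1, 0.1, 0.9)
    for (t in seq_len(n + u0 - 1)) x[t + 1] <- 3.9 * x[t] * (1 - x[t])
  } else {
    x <- stats::rnorm(n + u0)
  }
  y <- g(x[seq_len(n)])               # y(t) depends on x at t - u0
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
  out <- time_series_set(cbind(X = x[(u0 + 1):(u0 + n)], Y = y))
  attr(out, "true_lag") <- u0
  out
}

#' Scan pairwise predictability metrics over a grid of couplings
#'
#' For every pair of couplings \eqn{(\beta_{xy}, \beta_{yx})} on a grid,
#' simulates the coupled logistic model and evaluates a pairwise metric,
#' producing the phase-space map of inferred interaction versus true
#' embedded interaction. Divergent grid cells are recorded as `NA`.
#'
#' @param beta_xy_grid,beta_yx_grid numeric vectors of couplings in \[0, 1\].
#' @param metric one of `"corr"`, `"mi"`, `"te_x_to_y"`, `"te_y_to_x"`,
#'   `"rho_x_to_y"`, `"rho_y_to_x"`.
#' @param n_steps simulation length per cell (default 800).
#' @param config an [estimator_config()] for the information metrics.
#' @param E,tau embedding used by the cross-mapping metrics.
#' @param normalize if `TRUE`, min-max rescale the finite map values to
#'   \[0, 1\].
#' @return A matrix of metric values with `length(beta_xy_grid)` rows and
#'   `length(beta_yx_grid)` columns (dimnames carry the couplings), class
#'   `phase_space_map`.
#' @export
phase_space_scan <- function(beta_xy_grid, beta_yx_grid,
                             metric = c("corr", "mi", "te_x_to_y",
                                        "te_y_to_x", "rho_x_to_y",
                                        "rho_y_to_x"),
                             n_steps = 800L, config = estimator_config(),
                             E = 3L, tau = 1L, normalize = FALSE) {
  metric <- match.arg(metric)
  out <- matrix(NA_real_, length(beta_xy_grid), length(beta_yx_grid),
                dimnames = list(format(beta_xy_grid), format(beta_yx_grid)))
  for (i in seq_along(beta_xy_grid)) {
    for (j in seq_along(beta_yx_grid)) {
      ts <- tryCatch(
        simulate_coupled_logistic(beta_xy = beta_xy_grid[i],
                                  beta_yx = beta_yx_grid[j],
                                  n_steps = n_steps),
        oifnet_error = function(e) NULL)
      if (is.null(ts)) next    # divergent cell stays missing
      x <- ts$values[, "X"]; y <- ts$values[, "Y"]
      out[i, j] <- tryCatch(switch(
        metric,
        corr = pearson_corr(x, y),
        mi = mutual_information(x, y, u = 0L, config = config),
        te_x_to_y = transfer_entropy(x, y, config = config),
        te_y_to_x = transfer_entropy(y, x, config = config),
        rho_x_to_y = simplex_cross_map(embed_series(x, E = E, tau = tau),
                                       y, theiler = 1L)$rho,
        rho_y_to_x = simplex_cross_map(embed_series(y, E = E, tau = tau),
                                       x, theiler = 1L)$rho),
        oifnet_error = function(e) NA_real_)
    }
  }
  if (normalize) {
    fin <- is.finite(out)
    if (any(fin)) {
      lo <- min(out[fin]); hi <- max(out[fin])
      if (hi > lo) out[fin] <- (out[fin] - lo) / (hi - lo)
    }
  }
  structure(out, metric = metric, class = c("phase_space_map", "matrix"))
}
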