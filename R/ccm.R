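#' Time-delay (shadow manifold) embedding of a series
#'
#' Builds the lagged-coordinate reconstruction of a scalar series: point i
#' is \eqn{(x(t_i), x(t_i - \tau), \ldots, x(t_i - (E-1)\tau))}, for
#' \eqn{t_i = (E-1)\tau + 1, \ldots, n}.
#'
#' @param x numeric series of length at least `(E-1) * tau + 1`.
#' @param E embedding dimension (>= 1).
#' @param tau embedding lag in samples (>= 1).
#' @param source_name optional label of the embedded variable.
#' @return An object of class `shadow_manifold`: list with `points`
#'   (matrix, one row per embedded vector), `time_index` (original time
#'   stamps, strictly increasing), `E`, `tau`, `series` (the full original
#'   series) and `source_name`.
#' @export
embed_series <- function(x, E, tau = 1L, source_name = NULL) {
  E <- as.integer(E); tau <- as.integer(tau)
  if (E < 1 || tau < 1) oif_error("need E >= 1 and tau >= 1", "oifnet_bad_config")
  n <- length(x)
  first <- (E - 1L) * tau + 1L
  if (n < first) {
    oif_error(sprintf("series of length %d too short for E=%d, tau=%d",
                      n, E, tau), "oifnet_series_too_short")
  }
  idx <- first:n
  pts <- vapply(0:(E - 1L), function(j) x[idx - j * tau], numeric(length(idx)))
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = E)
  structure(list(points = pts, time_index = idx, E = E, tau = tau,
                 series = x, source_name = source_name),
            class = "shadow_manifold")
}

#' @export
print.shadow_manifold <- function(x, ...) {
  cat(sprintf("shadow_manifold: %d points in dimension E=%d (tau=%d)\n",
              nrow(x$points), x$E, x$tau))
  invisible(x)
}

#' Simplex-projection cross mapping
#'
#' Estimates a target series from the local geometry of a source shadow
#' manifold: for each embedded point, the `E + 1` nearest library neighbors
#' (Euclidean distance; neighbors within `theiler` samples of the prediction
#' time are excluded, so `theiler = 0` excludes exactly the point itself)
#' yield an exponentially distance-weighted average
#' \eqn{w_i \propto e^{-d_i / d_1}} of the target's contemporaneous values.
#' The cross-map skill \eqn{\rho} is the Pearson correlation between
#' predictions and observations; by the cross-mapping convention, a high
#' skill when predicting X from the manifold of Y indicates that X causally
#' forces Y.
#'
#' @param manifold a [embed_series()] shadow manifold of the predictor
#'   variable.
#' @param target numeric series aligned to the manifold's original time
#'   stamps (same length as the embedded series).
#' @param L library length: the first `L` embedded points form the neighbor
#'   pool (default: all points).
#' @param theiler temporal exclusion radius (>= 0).
#' @param direction optional label stored in the result.
#' @return An object of class `cross_map`: list with `rho`, `predicted`,
#'   `observed`, `time`, `L`, `E`, `tau`, `direction`.
#' @export
simplex_cross_map <- function(manifold, target, L = NULL, theiler = 0L,
                              direction = NULL) {
  stopifnot(inherits(manifold, "shadow_manifold"))
  pts <- manifold$points
  n_pts <- nrow(pts)
  if (length(target) != length(manifold$series)) {
    oif_error("target must be aligned to the manifold's original series",
              "oifnet_bad_input")
  }
  if (is.null(L)) L <- n_pts
  L <- as.integer(L)
  if (L < manifold$E + 2L) {
    oif_error(sprintf("library length %d too small (need >= E + 2 = %d)",
                      L, manifold$E + 2L), "oifnet_library_too_small")
  }
  if (L > n_pts) {
    oif_error("library length exceeds available embedded points",
              "oifnet_bad_config")
  }
  lib <- seq_len(L)
  times <- manifold$time_index
  k <- manifold$E + 1L               # bounding-simplex neighbor count
  # full distance matrix prediction points x library
  d2 <- outer(rowSums(pts^2), rowSums(pts[lib, , drop = FALSE]^2), "+") -
    2 * pts %*% t(pts[lib, , drop = FALSE])
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  pred <- rep(NA_real_, n_pts)
  tgt_lib <- target[times[lib]]
  for (i in seq_len(n_pts)) {
    dd <- dmat[i, ]
    dd[abs(times[lib] - times[i]) <= theiler] <- Inf
    ord <- order(dd)[seq_len(k)]
    if (!all(is.finite(dd[ord]))) next     # not enough admissible neighbors
    d1 <- dd[ord[1]]
    if (d1 == 0) {
      w <- as.numeric(dd[ord] == 0)        # uniform over exact matches
    } else {
      w <- exp(-dd[ord] / d1)
    }
    w <- w / sum(w)
    pred[i] <- sum(w * tgt_lib[ord])
  }
  ok <- is.finite(pred)
  obs <- target[times]
  if (sum(ok) < 3) {
    oif_error("too few prediction points", "oifnet_insufficient_data")
  }
  if (stats::sd(pred[ok]) == 0 || stats::sd(obs[ok]) == 0) {
    oif_error("degenerate (constant) predictions or observations",
              "oifnet_degenerate_cross_map")
  }
  rho <- stats::cor(pred[ok], obs[ok])
  structure(list(rho = rho, predicted = pred[ok], observed = obs[ok],
                 time = times[ok], L = L, E = manifold$E,
                 tau = manifold$tau, theiler = theiler,
                 direction = direction),
            class = "cross_map")
}

#' @export
print.cross_map <- function(x, ...) {
  cat(sprintf("cross_map%s: rho = %.4f (E=%d, tau=%d, L=%d)\n",
              if (is.null(x$direction)) "" else paste0(" [", x$direction, "]"),
              x$rho, x$E, x$tau, x$L))
  invisible(x)
}

#' Cross-map skill as a function of library length
#'
#' Computes the convergence profile of convergent cross mapping: for each
#' library length L (libraries are the first L embedded points, so the
#' profile is deterministic), the cross-map skill in both causal directions.
#' Direction `"x_to_y"` denotes the causal hypothesis X forces Y, assessed
#' by cross-mapping X from the manifold of Y; `"y_to_x"` the reverse.
#' Convergence (skill increasing to a stable plateau with L) is the CCM
#' causality criterion.
#'
#' @param x,y equal-length numeric series.
#' @param E embedding dimension; `tau` embedding lag; `theiler` exclusion
#'   radius.
#' @param L_grid increasing vector of library lengths (minimum 30, the
#'   minimum-data rule).
#' @return A data frame with columns `L`, `direction`, `rho`.
#' @export
convergence_profile <- function(x, y, E = 3L, tau = 1L, theiler = 0L,
                                L_grid = NULL) {
  if (length(x) != length(y)) {
    oif_error("series must have equal length", "oifnet_bad_input")
  }
  mx <- embed_series(x, E = E, tau = tau, source_name = "x")
  my <- embed_series(y, E = E, tau = tau, source_name = "y")
  n_pts <- nrow(mx$points)
  if (is.null(L_grid)) {
    L_grid <- unique(round(seq(30, n_pts, length.out = 8)))
  }
  if (min(L_grid) < 30) {
    oif_error("library lengths below 30 points are unreliable",
              "oifnet_library_too_small")
  }
  if (max(L_grid) > n_pts) {
    oif_error("largest library length exceeds available embedded points",
              "oifnet_bad_config")
  }
  rows <- lapply(L_grid, function(L) {
    rho_xy <- simplex_cross_map(my, x, L = L, theiler = theiler)$rho
    rho_yx <- simplex_cross_map(mx, y, L = L, theiler = theiler)$rho
    data.frame(L = c(L, L), direction = c("x_to_y", "y_to_x"),
               rho = c(rho_xy, rho_yx))
  })
  do.call(rbind, rows)
}

#' Select the embedding dimension by simplex self-prediction
#'
#' Sweeps candidate embedding dimensions and selects the one maximizing the
#' leave-one-out simplex-projection skill of one-step-ahead self-prediction
#' (smallest dimension on ties) — the standard univariate criterion when no
#' embedding dimension is known a priori.
#'
#' @param x numeric series.
#' @param E_range non-empty set of candidate dimensions.
#' @param tau embedding lag.
#' @param theiler temporal exclusion radius (default 0: exclude only the
#'   predictee itself).
#' @return An integer `E_star`; the skill profile is attached as attribute
#'   `"skill"`.
#' @export
select_embedding_dim <- function(x, E_range = 1:10, tau = 1L, theiler = 0L) {
  E_range <- sort(unique(as.integer(E_range)))
  if (length(E_range) < 1) oif_error("empty E_range", "oifnet_bad_config")
  skill <- vapply(E_range, function(E) {
    man <- embed_series(x, E = E, tau = tau)     # errors if too short
    n_pts <- nrow(man$points)
    if (n_pts < E + 3L) {
      oif_error("series too short for self-prediction sweep",
                "oifnet_series_too_short")
    }
    # one-step-ahead: predict x(t+1) from neighbors of the vector at t,
    # leave-one-out through the temporal exclusion
    n <- length(x)
    tryCatch(
      simplex_cross_map(embed_series(x[seq_len(n - 1L)], E = E, tau = tau),
                        x[2:n], theiler = theiler)$rho,
      oifnet_error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(skill))) {
    oif_error("self-prediction failed for every E", "oifnet_estimation_failed")
  }
  # near-ties (within 1e-6 of the maximum) go to the smallest dimension
  sk <- replace(skill, is.na(skill), -Inf)
  E_star <- E_range[which(sk >= max(sk) - 1e-6)[1]]
  attr(E_star, "skill") <- stats::setNames(skill, E_range)
  E_star
}
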