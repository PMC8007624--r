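test_that("correlation matrix of identical copies is all ones", {
  x <- logistic_series(n = 120)
  ts <- time_series_set(cbind(a = x, b = x, c = x))
  m <- infer_interaction_matrix(ts, method = "corr")
  off <- m$values[row(m$values) != col(m$values)]
  expect_equal(off, rep(1, 6), tolerance = 1e-12)
  expect_true(all(diag(m$values) == 0))
})

test_that("independent noise panel has near-zero transfer entropies", {
  set.seed(19)
  ts <- time_series_set(matrix(runif(3 * 1e4), ncol = 3))
  m <- infer_interaction_matrix(ts, method = "te",
                                config = kern_cfg(),
                                delay_policy = "fixed")
  off <- m$values[row(m$values) != col(m$values)]
  expect_true(all(off <= 0.05))
})

test_that("a planted strong coupling is the matrix maximum", {
  cm <- simulate_community(S = 8, n_steps = 285, seed = 21,
                           B = {
                             B <- matrix(0, 8, 8); B[2, 5] <- 0.6; B
                           },
                           rare_species_mask = integer(0))
  m <- infer_interaction_matrix(cm$ts, method = "te", config = kern_cfg(),
                                delay_policy = "fixed",
                                bias_correction = "shuffle",
                                shuffle_seed = 21)
  v <- m$values
  expect_equal(which(v == max(v)), which(row(v) == 2 & col(v) == 5))
})

test_that("zero-variance species score zero with a warning, not an error", {
  x <- logistic_series(n = 200)
  y <- logistic_series(r = 3.7, x0 = 0.3, n = 200)
  ts <- time_series_set(cbind(a = x, b = y, dead = rep(0, 200)))
  expect_warning(m <- infer_interaction_matrix(ts, method = "corr"),
                 "zero-variance")
  expect_true(all(m$values[3, ] == 0) && all(m$values[, 3] == 0))
  expect_false(m$values[1, 2] == 0)
})

test_that("min-max normalization floors negatives and fixes the range", {
  v <- matrix(c(0, 2, -0.3, 0, 4, 0.5, 1, 0, 0), 3, 3)
  m <- interaction_matrix(v, method = "corr")
  nm <- normalize_matrix(m)
  off <- nm$values[row(nm$values) != col(nm$values)]
  expect_equal(min(off), 0)
  expect_equal(max(off), 1)
  # already-normalized values {0, 0.5, 1} are left unchanged
  v2 <- matrix(0, 3, 3); v2[1, 2] <- 0.5; v2[1, 3] <- 1
  nm2 <- normalize_matrix(interaction_matrix(v2, method = "te"))
  expect_equal(nm2$values, v2, ignore_attr = TRUE)
  # {2, 4} -> {0, 1}
  v3 <- matrix(0, 2, 2); v3[1, 2] <- 2; v3[2, 1] <- 4
  nm3 <- normalize_matrix(interaction_matrix(v3, method = "te"))
  expect_equal(sort(nm3$values[row(v3) != col(v3)]), c(0, 1))
  expect_warning(normalize_matrix(interaction_matrix(matrix(0, 2, 2),
                                                     method = "te")),
                 "all-zero")
})

test_that("dynamical networks produce the documented window counts", {
  set.seed(23)
  ts <- time_series_set(matrix(rnorm(285 * 3), ncol = 3))
  nets <- suppressWarnings(
    dynamical_networks(ts, method = "corr", g = 30, step = 1))
  expect_equal(length(nets$matrices), 256)      # n - g + 1
  expect_equal(nets$windows$start, rep(1L, 256))
  one <- suppressWarnings(
    dynamical_networks(ts$values[1:30, ], method = "corr", g = 30))
  expect_equal(length(one$matrices), 1)
  sl <- suppressWarnings(
    dynamical_networks(ts, method = "corr", g = 30,
                       window_mode = "sliding", step = 15))
  expect_true(all(sl$windows$end - sl$windows$start + 1 == 30))
  expect_error(dynamical_networks(ts$values[1:20, ], method = "corr",
                                  g = 30),
               class = "oifnet_insufficient_data")
})

test_that("taxonomic alpha counts present species in a window", {
  v <- cbind(a = c(1, 2, 3), b = c(0, 0, 0), c = c(0, 1, 0))
  ts <- time_series_set(v)
  expect_equal(taxonomic_alpha(ts), 2)
  expect_equal(taxonomic_alpha(ts, c(1, 1)), 1)
  expect_equal(taxonomic_alpha(ts, c(2, 3)), 2)
  expect_error(taxonomic_alpha(ts, c(3, 2)), class = "oifnet_bad_input")
})

test_that("effective alpha applies the incidence rule on normalized
           matrices", {
  v <- matrix(0.1, 3, 3); v[1, 2] <- 0.9; diag(v) <- 0
  m <- normalize_matrix(interaction_matrix(v, method = "te"))
  # after min-max normalization the 0.1 links map to 0 and 0.9 to 1
  expect_equal(effective_alpha(m, 0.5), 2)     # species 1 and 2
  expect_equal(effective_alpha(m, 0), 2)
  raw <- interaction_matrix(v, method = "te")
  expect_error(effective_alpha(raw, 0.5), class = "oifnet_bad_input")
  expect_error(effective_alpha(m, 1.5), class = "oifnet_bad_config")
  # boundary counts: a saturated network keeps every species at any theta
  ones <- interaction_matrix(matrix(1, 4, 4) - diag(4), method = "te",
                             normalized = TRUE)
  expect_equal(effective_alpha(ones, 0.99), 4)
  expect_equal(effective_alpha(ones, 0), 4)
  # min-max of an all-equal matrix collapses it to zero with a warning
  expect_warning(z <- normalize_matrix(interaction_matrix(
    matrix(1, 4, 4) - diag(4), method = "te")), "all-zero")
  expect_equal(effective_alpha(z, 0.2), 0)
  none <- interaction_matrix(matrix(0, 4, 4), method = "te",
                             normalized = TRUE)
  expect_equal(effective_alpha(none, 0.2), 0)
})

test_that("effective alpha is exactly monotone non-increasing in theta", {
  cm <- simulate_community(seed = 29)
  cfg <- kern_cfg()
  nets <- suppressWarnings(
    dynamical_networks(cm$ts, method = "te", config = cfg, g = 30,
                       window_mode = "sliding", step = 24,
                       delay_policy = "fixed"))
  thetas <- seq(0, 1, by = 0.1)
  for (m in nets$matrices) {
    if (is.null(m)) next
    counts <- vapply(thetas, function(th) effective_alpha(m, th), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("alpha series are equivariant under species permutation", {
  cm <- simulate_community(S = 6, seed = 31, n_steps = 120,
                           rare_species_mask = 5:6)
  perm <- c(3, 1, 6, 2, 5, 4)
  ts_p <- time_series_set(cm$ts$values[, perm],
                          names = cm$ts$names[perm])
  cfg <- kern_cfg()
  nets <- suppressWarnings(
    dynamical_networks(cm$ts, method = "te", config = cfg, g = 40,
                       window_mode = "sliding", step = 40,
                       delay_policy = "fixed"))
  nets_p <- suppressWarnings(
    dynamical_networks(ts_p, method = "te", config = cfg, g = 40,
                       window_mode = "sliding", step = 40,
                       delay_policy = "fixed"))
  for (w in seq_along(nets$matrices)) {
    m <- nets$matrices[[w]]; mp <- nets_p$matrices[[w]]
    expect_equal(mp$values, m$values[perm, perm], ignore_attr = TRUE)
    expect_equal(effective_alpha(mp, 0.3), effective_alpha(m, 0.3))
  }
  a <- alpha_diversity_series(nets, cm$ts, theta = 0.3)
  ap <- alpha_diversity_series(nets_p, ts_p, theta = 0.3)
  expect_equal(a$alpha_tax, ap$alpha_tax)
})

test_that("TE is direction sensitive on a planted unidirectional edge", {
  hits <- 0
  for (s in 1:20) {
    cm <- simulate_community(S = 6, n_steps = 285, seed = s,
                             B = {
                               B <- matrix(0, 6, 6); B[1, 2] <- 0.6; B
                             },
                             rare_species_mask = integer(0))
    m <- infer_interaction_matrix(cm$ts, method = "te",
                                  config = kern_cfg(),
                                  delay_policy = "fixed",
                                  bias_correction = "shuffle",
                                  shuffle_seed = s)
    hits <- hits + (m$values[1, 2] > m$values[2, 1])
  }
  expect_gte(hits, 18)     # >= 90% of replicates
})

test_that("threshold search enforces its grid contract and tie rule", {
  set.seed(37)
  ts <- time_series_set(matrix(abs(rnorm(60 * 4)), ncol = 4))
  nets <- suppressWarnings(
    dynamical_networks(ts, method = "corr", g = 30,
                       window_mode = "sliding", step = 5))
  expect_error(optimize_threshold(nets, ts, theta_grid = seq(0.2, 1, 0.1)),
               class = "oifnet_bad_config")
  expect_error(optimize_threshold(nets, ts,
                                  theta_grid = c(0, 0.25, 0.5, 1)),
               class = "oifnet_bad_config")
  # all-ones matrices: every theta ties, smallest returned
  ones <- lapply(nets$matrices, function(m) {
    interaction_matrix(matrix(1, 4, 4) - diag(4), method = "corr",
                       normalized = TRUE)
  })
  nets_ones <- nets
  nets_ones$matrices <- ones
  res <- optimize_threshold(nets_ones, ts, criterion = "corr")
  expect_equal(res$theta_star, 0)
  res_mi <- optimize_threshold(nets_ones, ts, criterion = "mi")
  expect_equal(res_mi$theta_star, 0)
  expect_true(all(res_mi$score_curve == 0))
})

test_that("threshold search recovers the planted interacting count", {
  cm <- simulate_community(seed = 41)
  nets <- suppressWarnings(
    dynamical_networks(cm$ts, method = "te", config = kern_cfg(),
                       g = 30, window_mode = "sliding", step = 15,
                       delay_policy = "fixed",
                       bias_correction = "shuffle", shuffle_seed = 41))
  res <- optimize_threshold(nets, cm$ts, criterion = "corr")
  dev <- mean(abs(res$alpha$alpha_eff - length(cm$interacting)),
              na.rm = TRUE)
  expect_lte(dev, 2)
})

test_that("oif fit object exposes the network through its methods", {
  ts <- simulate_coupled_logistic(beta_yx = 0.8, n_steps = 400)
  fit <- oif(ts, method = "te", delay_policy = "fixed")
  expect_s3_class(fit, "oif")
  expect_equal(dim(coef(fit)), c(2, 2))
  expect_gte(coef(fit)["X", "Y"], coef(fit)["Y", "X"])
  expect_output(print(fit), "oif network")
  expect_output(print(summary(fit)), "strongest directed")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})
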