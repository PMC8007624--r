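test_that("standardize_series gives zero mean, unit sd, and is idempotent", {
  z <- standardize_series(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  expect_equal(standardize_series(z), z, tolerance = 1e-12)
  expect_error(standardize_series(c(5, 5, 5)),
               class = "oifnet_zero_variance")
  expect_error(standardize_series(1), class = "oifnet_bad_input")
})

test_that("histogram joint pdf counts cells correctly", {
  p1 <- joint_pdf(rep(0.1, 10), r = 0.25)
  expect_equal(p1$probabilities, 1)
  p2 <- joint_pdf(c(0.1, 0.1, 0.6, 0.6), r = 0.25)
  expect_equal(sort(p2$probabilities), c(0.5, 0.5))
  set.seed(1)
  u <- runif(1e5)
  p3 <- joint_pdf(u, r = 0.25)
  expect_equal(length(p3$probabilities), 4)
  expect_equal(unname(p3$probabilities), rep(0.25, 4), tolerance = 0.01)
  expect_equal(sum(p3$probabilities), 1, tolerance = 1e-10)
  expect_error(joint_pdf(numeric(0)), class = "oifnet_bad_input")
})

test_that("kernel joint pdf gives pointwise box masses", {
  x <- c(0, 0.1, 1)
  p <- joint_pdf(x, r = 0.2, kind = "kernel")
  expect_equal(p$probabilities, c(2 / 3, 2 / 3, 1 / 3))
  expect_true(all(p$probabilities > 0 & p$probabilities <= 1))
})

test_that("pearson correlation matches its definition and degenerate cases
           error", {
  x <- logistic_series(n = 100)
  expect_equal(pearson_corr(x, x), 1)
  expect_equal(pearson_corr(x, -x), -1)
  expect_equal(round(pearson_corr(c(1, 2, 3), c(1, 2, 4)), 4), 0.9820)
  expect_error(pearson_corr(x, rep(1, 100)),
               class = "oifnet_zero_variance")
  expect_error(pearson_corr(1:5, 1:4), class = "oifnet_bad_input")
})

test_that("mutual information is symmetric at u = 0, non-negative, and
           matches exact plug-in values", {
  set.seed(2)
  a <- rnorm(2000); b <- rnorm(2000)
  expect_equal(mutual_information(a, b), mutual_information(b, a),
               tolerance = 1e-12)
  expect_gte(mutual_information(a, b), -1e-12)
  # identical binary sequences share exactly one bit
  s <- rep(c(0, 1), 50)
  cfg <- symbol_cfg()
  expect_equal(mutual_information(s, s, u = 0, config = cfg), 1)
  # MI(X;X) equals the plug-in entropy of the binned series
  x <- logistic_series(n = 2000)
  sym <- floor(standardize_series(x) / 0.25)
  h <- -sum(table(sym) / length(sym) * log2(table(sym) / length(sym)))
  expect_equal(mutual_information(x, x), h, tolerance = 1e-12)
})

test_that("independent series carry almost no mutual information", {
  set.seed(3)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(mutual_information(a, b), 0.05)
})

test_that("estimator preconditions are enforced", {
  set.seed(4)
  a <- rnorm(100)
  expect_error(mutual_information(a, a, u = 80),
               class = "oifnet_insufficient_data")
  expect_error(mutual_information(a, rep(1, 100)),
               class = "oifnet_zero_variance")
  expect_error(transfer_entropy(a[1:20], a[1:20]),
               class = "oifnet_insufficient_data")
  expect_error(estimator_config(r = -1), class = "oifnet_bad_config")
  expect_error(estimator_config(k = 0), class = "oifnet_bad_config")
})

test_that("transfer entropy recovers a planted one-step copy exactly", {
  # target(t) = source(t-1), source i.i.d. uniform over b symbols:
  # TE(source -> target) = log2 b, TE(target -> source) = 0
  for (b in c(2, 4)) {
    set.seed(b)
    s <- sample.int(b, 4000, replace = TRUE)
    x <- c(1L, s[-4000])
    cfg <- symbol_cfg()
    expect_equal(transfer_entropy(s, x, cfg), log2(b), tolerance = 0.02)
    expect_lt(transfer_entropy(x, s, cfg), 0.02)
  }
})

test_that("independent i.i.d. series give near-zero transfer entropy", {
  set.seed(5)
  a <- runif(1e4); b <- runif(1e4)
  expect_lt(transfer_entropy(a, b, kern_cfg()), 0.05)
  expect_gte(transfer_entropy(a, b, kern_cfg()), -1e-12)
})

test_that("histogram transfer entropy agrees with the brute-force oracle", {
  set.seed(6)
  for (i in 1:12) {
    b <- sample(2:8, 1); k <- sample(1:2, 1); l <- sample(1:2, 1)
    u <- sample(1:3, 1)
    s <- sample.int(b, 400, replace = TRUE)
    x <- sample.int(b, 400, replace = TRUE)
    expect_equal(transfer_entropy(s, x, symbol_cfg(k, l, u)),
                 plugin_te_oracle(s, x, u = u, k = k, l = l),
                 tolerance = 1e-12)
  }
  # constant source contributes nothing
  expect_equal(plugin_te_oracle(rep(1L, 100), sample.int(3, 100, TRUE)), 0)
  expect_error(plugin_te_oracle(1:5, 1:4), class = "oifnet_bad_input")
})

test_that("bits and nats differ exactly by ln 2 in every estimator", {
  x <- logistic_series(n = 400)
  y <- logistic_series(r = 3.62, x0 = 0.3, n = 400)
  nats <- estimator_config(log_base = exp(1))
  expect_equal(transfer_entropy(x, y, estimator_config()) * log(2),
               transfer_entropy(x, y, nats), tolerance = 1e-12)
  expect_equal(mutual_information(x, y, config = estimator_config()) * log(2),
               mutual_information(x, y, config = nats), tolerance = 1e-12)
  expect_equal(convert_info_units(1, from = 2, to = exp(1)), log(2))
})

test_that("TE and MI respect their entropy upper bounds", {
  x <- logistic_series(n = 1000)
  y <- logistic_series(r = 3.67, x0 = 0.21, n = 1000)
  ent <- function(v) {
    p <- table(floor(standardize_series(v) / 0.25)) / length(v)
    -sum(p * log2(p))
  }
  expect_lte(mutual_information(x, y), min(ent(x), ent(y)) + 1e-12)
  expect_lte(transfer_entropy(x, y), ent(y) + 1e-12)
})

test_that("optimal delay recovers planted lags and breaks ties at the
           smallest candidate", {
  lt <- simulate_lagged_coupling(3, n = 1000, seed = 7)
  ds <- optimal_delay(lt$values[, "X"], lt$values[, "Y"], u_range = 1:10)
  expect_equal(ds$u_star, 3)
  expect_equal(ds$mi_profile[3], max(ds$mi_profile))
  lt1 <- simulate_lagged_coupling(1, n = 500, seed = 8, g = identity)
  expect_equal(optimal_delay(lt1$values[, "X"], lt1$values[, "Y"],
                             u_range = 1:5)$u_star, 1)
  expect_error(optimal_delay(rep(1, 100), rnorm(100)),
               class = "oifnet_estimation_failed")
  # distance profile is exp(-MI in nats), strictly decreasing in MI
  expect_equal(ds$distance_profile,
               exp(-ds$mi_profile * log(2)))
  expect_true(all(ds$distance_profile > 0 & ds$distance_profile <= 1))
})

test_that("information distance follows its closed form", {
  expect_equal(info_distance(0), 1)
  expect_equal(info_distance(log(2)), 0.5)
  expect_lt(info_distance(20), 1e-8)
  expect_error(info_distance(-0.1), class = "oifnet_bad_input")
})

test_that("analytic gaussian TE matches triangular structure and a
           regression brute force", {
  A <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  vp <- var_params(A = A, n = 5e5, seed = 9)
  expect_equal(analytic_gaussian_te(vp, "y_to_x"), 0)
  te_an <- analytic_gaussian_te(vp, "x_to_y")
  expect_gt(te_an, 0)
  # brute force: restricted vs full least squares on a long simulation
  ts <- simulate_gaussian_var(vp)
  x <- ts$values[, 1]; y <- ts$values[, 2]
  n <- length(y)
  full <- stats::lm(y[2:n] ~ y[1:(n - 1)] + x[1:(n - 1)])
  restr <- stats::lm(y[2:n] ~ y[1:(n - 1)])
  te_reg <- 0.5 * log2(mean(restr$residuals^2) / mean(full$residuals^2))
  expect_equal(te_reg, te_an, tolerance = 0.02)
})

test_that("shuffling the source destroys the information flow", {
  ts <- simulate_coupled_logistic(beta_yx = 0.8, n_steps = 10000)
  set.seed(11)
  shuf <- sample(ts$values[, "X"])
  expect_lt(transfer_entropy(shuf, ts$values[, "Y"], kern_cfg()), 0.05)
})

test_that("shuffle-corrected TE subtracts a reproducible baseline", {
  ts <- simulate_coupled_logistic(beta_yx = 0.6, n_steps = 400)
  x <- ts$values[, 1]; y <- ts$values[, 2]
  e1 <- transfer_entropy(x, y, kern_cfg(), bias_correction = "shuffle",
                         shuffle_seed = 1)
  e2 <- transfer_entropy(x, y, kern_cfg(), bias_correction = "shuffle",
                         shuffle_seed = 1)
  expect_identical(e1, e2)
  expect_lt(e1, transfer_entropy(x, y, kern_cfg()))
})
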