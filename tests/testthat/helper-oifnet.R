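# shared fixtures, built in code at test time

# single chaotic logistic map trajectory
logistic_series <- function(r = 3.8, x0 = 0.4, n = 500) {
  x <- numeric(n)
  x[1] <- x0
  # written in the same algebraic form as the coupled map so that uncoupled
  # trajectories agree bitwise (chaos amplifies rounding differences)
  for (t in seq_len(n - 1)) x[t + 1] <- x[t] * (r - r * x[t])
  x
}

# estimator config shortcuts
hist_cfg <- function(...) estimator_config(...)
kern_cfg <- function(...) estimator_config(estimator_kind = "kernel", ...)

# config for pre-symbolized integer sequences (identity binning)
symbol_cfg <- function(k = 1, l = 1, u = 1) {
  estimator_config(r = 1, k = k, l = l, u = u, standardize = FALSE,
                   min_samples = 10)
}
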