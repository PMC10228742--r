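# Shared test helpers: independent oracles and scaled-down configs.

# Brute-force per-sample modulation index, independent of the package's
# vectorised implementation (used for oracle-equivalence tests).
mi_oracle <- function(phase, amplitude, n_bins = 18L) {
  sums <- numeric(n_bins); cnt <- numeric(n_bins)
  width <- 360 / n_bins
  for (i in seq_along(phase)) {
    j <- floor((phase[i] + 180) / width) + 1L
    if (j > n_bins) j <- n_bins
    sums[j] <- sums[j] + amplitude[i]
    cnt[j] <- cnt[j] + 1
  }
  fbar <- numeric(n_bins)
  fbar[cnt > 0] <- sums[cnt > 0] / cnt[cnt > 0]
  P <- fbar / sum(fbar)
  H <- -sum(P[P > 0] * log(P[P > 0]))
  (log(n_bins) - H) / log(n_bins)
}

# Brute-force sliding-window count: walk the interval step by step.
count_windows_oracle <- function(L, window_s, step_s) {
  n <- 0L; st <- 0
  while (st + window_s <= L + 1e-9) { n <- n + 1L; st <- st + step_s }
  n
}

# Small single-combination hyperparameter grid: the full 27-point default
# grid is exercised in test-classify; elsewhere tests keep the runtime
# budget by fixing the conventional forest.
fast_rf <- function(k = 10L, seed = 1L)
  rf_config(n_estimators = 100L, min_samples_split = 2L, max_depth = Inf,
            k = k, seed = seed)

# Gaussian feature table with a given per-group window count; mirrors the
# separable synthetic features used in classifier contracts.
gaussian_table <- function(n_groups = 10L, n = 30L, mu_pre = 0.4, sd_pre = 0.05,
                           mu_int = 0.05, sd_int = 0.02, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_groups), function(sid) data.frame(
    window_start = seq_len(2 * n), label = rep(c("preictal", "interictal"), each = n),
    seizure_id = sid, channel = "ch1",
    mi_beta_gamma = c(rnorm(n, mu_pre, sd_pre), rnorm(n, mu_int, sd_int)))))
}
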