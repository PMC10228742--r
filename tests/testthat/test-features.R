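# Modulation index, amplitude distribution, comodulogram, spectral features.

fs <- 256

test_that("instantaneous phase behaves analytically", {
  t <- (0:(10 * fs - 1)) / fs
  ph <- instantaneous_phase(sin(2 * pi * 6 * t))
  mid <- (fs + 1):(9 * fs)
  # unwrapped slope ~ 6 cycles/s
  d <- diff(ph[mid]); d[d < -180] <- d[d < -180] + 360
  slope <- mean(d) * fs / 360
  expect_equal(slope, 6, tolerance = 0.06)

  phc <- instantaneous_phase(cos(2 * pi * 6 * t))
  off <- (phc - ph)[mid] %% 360
  expect_true(all(abs(off - 90) < 1))

  # long pure sinusoid: phase histogram uniform over the 18 bins
  ph2 <- instantaneous_phase(sin(2 * pi * 5 * (0:(200 * fs - 1)) / fs))
  cnt <- tabulate(pmin(floor((ph2 + 180) / 20) + 1, 18), 18)
  expect_true(all(abs(cnt / length(ph2) - 1 / 18) < 0.02))

  expect_error(instantaneous_phase(numeric(100)), "zero")
})

test_that("amplitude envelope recovers known modulators", {
  t <- (0:(10 * fs - 1)) / fs
  env <- amplitude_envelope(3.5 * sin(2 * pi * 60 * t))
  core <- env[(0.5 * fs):(9.5 * fs)]
  expect_equal(mean(core), 3.5, tolerance = 0.035)

  m <- 1 + 0.5 * sin(2 * pi * 6 * t)
  x <- m * sin(2 * pi * 60 * t)
  env2 <- amplitude_envelope(x)
  core2 <- fs:(9 * fs)
  expect_gt(cor(env2[core2], m[core2]), 0.95)

  expect_equal(amplitude_envelope(numeric(64)), numeric(64))
})

test_that("amplitude_distribution matches its contract and the brute-force oracle", {
  set.seed(11)
  ph <- runif(1000, -180, 180)
  expect_equal(amplitude_distribution(ph, rep(1, 1000)), rep(1 / 18, 18),
               tolerance = 1e-12)

  conc <- amplitude_distribution(
    phase = c(runif(500, -100, -81), runif(500, 100, 180)),
    amplitude = c(rep(2, 500), rep(0, 500)))
  expect_equal(conc[5], 1)
  expect_equal(sum(conc[-5]), 0)

  for (i in 1:20) {
    ph <- runif(1000, -180, 180); am <- rexp(1000)
    P <- amplitude_distribution(ph, am)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(modulation_index(P), mi_oracle(ph, am), tolerance = 1e-12)
  }
  expect_error(amplitude_distribution(1:3, 1:4), "length")
  expect_error(amplitude_distribution(runif(10, -180, 180), rep(0, 10)), "zero")
})

test_that("modulation index analytic extremes and invariances", {
  expect_identical(modulation_index(rep(1 / 18, 18)), 0)
  expect_identical(modulation_index(c(1, rep(0, 17))), 1)
  expect_equal(modulation_index(c(0.5, 0.5, rep(0, 16))), 1 - log(2) / log(18),
               tolerance = 1e-12)

  # base invariance: MI written with log10 equals the natural-log version
  P <- c(0.4, 0.3, 0.2, 0.1, rep(0, 14))
  H10 <- -sum(P[P > 0] * log10(P[P > 0]))
  expect_equal(modulation_index(P), (log10(18) - H10) / log10(18), tolerance = 1e-12)

  # amplitude-scale invariance and [0,1] bounds under fuzzing
  set.seed(5)
  for (i in 1:50) {
    ph <- runif(500, -180, 180); am <- rexp(500)
    expect_equal(modulation_index(amplitude_distribution(ph, am)),
                 modulation_index(amplitude_distribution(ph, 17.3 * am)),
                 tolerance = 1e-12)
    P <- amplitude_distribution(ph, am)
    mi <- modulation_index(P)
    expect_gte(mi, 0); expect_lte(mi, 1)
  }
})

test_that("comodulogram recovers the generating pair and orders chi", {
  x8 <- generate_pac_signal(pac_spec(f_phase = 6, f_amp = 60, chi = 0.8),
                            30, fs, noise_sd = 1, seed = 3)
  cm <- comodulogram(x8, fs)
  expect_equal(names(which.max(cm)), "theta_gamma")

  x0 <- generate_pac_signal(pac_spec(f_phase = 6, f_amp = 60, chi = 0),
                            30, fs, noise_sd = 1, seed = 3)
  cm0 <- comodulogram(x0, fs)
  expect_lt(cm0["theta_gamma"], cm["theta_gamma"])

  bad <- list(list(phase = band("gamma", 30, 80), amp = band("theta", 4, 8)))
  expect_error(comodulogram(x8, fs, bad), "above")
})

test_that("white-noise MI stays below its permutation null", {
  # scaled-down version of the 50-trial null calibration (acceptance runs
  # the full one); 20 seeded trials, 100 permutations
  hits <- 0L
  for (trial in 1:20) {
    x <- generate_pac_signal(pac_spec(f_phase = 6, f_amp = 60, chi = 0),
                             30, fs, noise_sd = 1, seed = 100 + trial)
    th <- bandpass(x, fs, band("theta", 4, 8))
    gm <- bandpass(x, fs, band("gamma", 30, 80))
    ph <- instantaneous_phase(th); env <- amplitude_envelope(gm)
    obs <- modulation_index(amplitude_distribution(ph, env))
    set.seed(trial)
    null <- mi_permutation_null(ph, env, n_perm = 100L)
    if (quantile(null, 0.95) > obs) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("spectral features: peak, median, and a dense-FFT oracle", {
  t <- (0:(30 * fs - 1)) / fs
  sf <- spectral_features(sin(2 * pi * 10 * t), fs, band("alpha", 8, 13))
  expect_equal(unname(sf["peak_freq"]), 10, tolerance = 0.51)

  two <- sin(2 * pi * 35 * t) + sin(2 * pi * 75 * t)
  sf2 <- spectral_features(two, fs, band("gamma", 30, 80))
  expect_gte(sf2[["median_freq"]], 35); expect_lte(sf2[["median_freq"]], 75)
  expect_equal(sf2[["median_freq"]], 55, tolerance = 21)  # between the tones

  set.seed(8)
  x <- bandpass(rnorm(30 * fs), fs, band("beta", 13, 30))
  sf3 <- spectral_features(x, fs, band("beta", 13, 30), filtered = TRUE)
  # oracle: single dense periodogram median
  X <- Mod(fft(x))^2
  f <- (seq_along(X) - 1) * fs / length(X)
  sel <- f >= 13 & f <= 30
  cum <- cumsum(X[sel])
  med_oracle <- f[sel][which(cum >= cum[length(cum)] / 2)[1]]
  expect_equal(sf3[["median_freq"]], med_oracle, tolerance = 1)

  expect_error(spectral_features(numeric(2 * fs) + 0, fs, band("beta", 13, 30),
                                 filtered = TRUE), "power")
})

test_that("feature table has the documented shape", {
  cfg <- synthetic_config(fs = 128, n_channels = 4L, duration = 400,
                          seizure_onsets = numeric(0), seed = 2, noise_sd = 1)
  rec <- generate_recording(cfg)
  wins <- data.frame(start_s = seq(10, 145, by = 15), label = "interictal",
                     seizure_id = 1L)[1:10, ]
  attr(wins, "window_s") <- 30
  bands4 <- canonical_bands(exclude_delta = TRUE, fs = 128)
  ft <- build_feature_table(rec, wins, feature_config(bands = bands4, feature_set = "pac"))
  expect_equal(nrow(ft), 40)  # 10 windows x 4 channels
  mi_cols <- grep("^mi_", names(ft), value = TRUE)
  expect_setequal(mi_cols, c("mi_theta_alpha", "mi_theta_beta", "mi_theta_gamma",
                             "mi_alpha_beta", "mi_alpha_gamma", "mi_beta_gamma"))

  ft_sp <- build_feature_table(rec, wins,
                               feature_config(bands = canonical_bands(fs = 128),
                                              feature_set = "spectral"))
  expect_equal(sum(grepl("^(peak|median)_", names(ft_sp))), 10)  # 2 per band x 5

  empty <- wins[0, , drop = FALSE]
  ft0 <- build_feature_table(rec, empty, feature_config(bands = bands4))
  expect_equal(nrow(ft0), 0)
})
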