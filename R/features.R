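# Phase-amplitude coupling (modulation index) and band spectral features.
#
# The coupling statistic is the Tort-style modulation index: bin the
# low-frequency instantaneous phase into N = 18 bins of 20 degrees, average
# the high-frequency amplitude envelope per bin, normalise to a probability
# vector P, and measure the Kullback-Leibler distance of P from the uniform
# distribution, scaled to [0, 1]:
#
#   H(P)  = -sum_j P(j) log P(j)
#   MI    = (log N - H(P)) / log N
#
# MI = 0 for phase-independent amplitude, 1 when all amplitude concentrates
# in a single phase bin. MI is invariant to the log base and to positive
# rescaling of the amplitude.

#' Instantaneous phase of a band-limited signal
#'
#' Analytic-signal angle in degrees, in (-180, 180].
#'
#' @param x Band-limited (already filtered) signal.
#' @return Phase series in degrees.
#' @export
instantaneous_phase <- function(x) {
  if (all(x == 0)) stop("phase undefined for an all-zero signal")
  ph <- Arg(analytic_signal(x)) * 180 / pi
  # Arg returns (-180, 180]; map the -180 edge up for a half-open convention
  ph[ph <= -180] <- 180
  ph
}

#' Amplitude envelope of a band-limited signal
#'
#' Analytic-signal modulus.
#'
#' @param x Band-limited signal.
#' @return Non-negative envelope series.
#' @export
amplitude_envelope <- function(x) {
  Mod(analytic_signal(x))
}

#' Phase-binned normalized mean-amplitude distribution
#'
#' Bin j (1..n_bins) covers `[-180 + 20*(j-1), -180 + 20*j)` degrees for the
#' default 18 bins; a phase of exactly +180 maps to the last bin. The mean
#' envelope per bin is normalised to sum to one.
#'
#' @param phase Phase series in degrees, (-180, 180].
#' @param amplitude Envelope series, same length, non-negative.
#' @param n_bins Number of phase bins (default 18).
#' @return Numeric vector `P` of length `n_bins` summing to 1. Bins that
#'   receive no samples get mean amplitude 0 (they then contribute nothing
#'   to the entropy via the 0 log 0 = 0 convention).
#' @export
amplitude_distribution <- function(phase, amplitude, n_bins = 18L) {
  if (length(phase) != length(amplitude)) stop("phase and amplitude lengths differ")
  if (n_bins < 2) stop("need at least 2 bins")
  if (all(amplitude == 0)) stop("all-zero amplitude: distribution undefined")
  width <- 360 / n_bins
  j <- pmin(floor((phase + 180) / width) + 1L, n_bins)
  mean_amp <- numeric(n_bins)
  sums <- vapply(split(amplitude, factor(j, levels = seq_len(n_bins))), sum, numeric(1))
  cnts <- tabulate(j, nbins = n_bins)
  nz <- cnts > 0
  mean_amp[nz] <- sums[nz] / cnts[nz]
  mean_amp / sum(mean_amp)
}

#' Modulation index from an amplitude distribution
#'
#' Shannon entropy of `P`, Kullback-Leibler distance from uniform
#' (`log N - H`), normalised by `log N`. Natural logarithms; the ratio is
#' base-invariant.
#'
#' @param P Normalized amplitude distribution (sums to 1, non-negative).
#' @return MI in `[0, 1]`.
#' @export
modulation_index <- function(P) {
  if (any(P < 0)) stop("P must be non-negative")
  if (abs(sum(P) - 1) > 1e-8) stop("P must sum to 1")
  nb <- length(P)
  pl <- P[P > 0]
  H <- -sum(pl * log(pl))
  (log(nb) - H) / log(nb)
}

#' Low/high band pairs for the comodulogram
#'
#' All ordered pairs (phase band, amplitude band) where the amplitude band
#' lies strictly above the phase band, i.e. the lower triangle of the
#' band-by-band grid.
#'
#' @param bands Named list of [band()] objects, ordered low to high.
#' @return List of `list(phase = band, amp = band)` pairs.
#' @export
band_pairs <- function(bands = canonical_bands()) {
  out <- list()
  nb <- length(bands)
  for (i in seq_len(nb)) for (k in seq_len(nb)) {
    if (bands[[k]]$lo >= bands[[i]]$hi && k > i) {
      out[[length(out) + 1L]] <- list(phase = bands[[i]], amp = bands[[k]])
    }
  }
  names(out) <- vapply(out, function(p) paste0(p$phase$name, "_", p$amp$name), character(1))
  out
}

#' Comodulogram of a single window
#'
#' MI per (phase band, amplitude band) pair, filtering the supplied window
#' itself. For production use on long records prefer [build_feature_table()],
#' which filters the continuous record once and slices windows out of the
#' phase/envelope series.
#'
#' @param x Signal window.
#' @param fs Sampling rate (Hz).
#' @param pairs Band pairs from [band_pairs()].
#' @param n_bins Phase bins (default 18).
#' @return Named numeric vector of MI values, one per pair.
#' @export
comodulogram <- function(x, fs, pairs = band_pairs(canonical_bands(fs = fs)), n_bins = 18L) {
  bands <- list()
  for (p in pairs) {
    if (p$amp$lo < p$phase$hi) stop("amplitude band must lie above the phase band")
    bands[[p$phase$name]] <- p$phase
    bands[[p$amp$name]] <- p$amp
  }
  filt <- lapply(bands, function(b) bandpass(x, fs, b))
  ph <- lapply(filt, instantaneous_phase)
  env <- lapply(filt, amplitude_envelope)
  out <- vapply(pairs, function(p) {
    modulation_index(amplitude_distribution(ph[[p$phase$name]], env[[p$amp$name]], n_bins))
  }, numeric(1))
  names(out) <- names(pairs)
  out
}

#' Permutation null distribution for MI
#'
#' Breaks the phase-amplitude relationship by circularly shifting the
#' envelope by random offsets (preserving both series' autocorrelation) and
#' recomputing MI.
#'
#' @param phase,amplitude As for [amplitude_distribution()].
#' @param n_perm Number of permutations (default 200).
#' @param min_shift_frac Minimum shift as a fraction of the series length.
#' @return Numeric vector of `n_perm` null MI values.
#' @export
mi_permutation_null <- function(phase, amplitude, n_perm = 200L, min_shift_frac = 0.1) {
  n <- length(amplitude)
  lo <- max(1L, floor(min_shift_frac * n))
  shifts <- sample.int(n - 2L * lo, n_perm, replace = TRUE) + lo
  vapply(shifts, function(s) {
    a <- c(amplitude[(s + 1L):n], amplitude[1:s])
    modulation_index(amplitude_distribution(phase, a))
  }, numeric(1))
}

#' Welch peak and median frequency of a band
#'
#' Welch PSD of the band-filtered window; the peak frequency is the PSD
#' argmax within the band, the median frequency the smallest frequency at
#' which cumulative band power reaches half the total band power.
#'
#' @param x Signal window (already band-filtered or raw; it is filtered to
#'   `band` unless `filtered = TRUE`).
#' @param fs Sampling rate.
#' @param band A [band()] object.
#' @param filtered Set `TRUE` when `x` is already band-limited to `band`.
#' @param seg_s,overlap Welch parameters (2-s Hann segments, 50% overlap).
#' @return Named vector `c(peak_freq, median_freq)` in Hz.
#' @export
spectral_features <- function(x, fs, band, filtered = FALSE, seg_s = 2, overlap = 0.5) {
  xb <- if (filtered) x else bandpass(x, fs, band)
  w <- welch_psd(xb, fs, seg_s, overlap)
  sel <- which(w$freq >= band$lo & w$freq <= band$hi)
  if (length(sel) == 0 || sum(w$psd[sel]) <= 0) stop("zero power in band")
  p <- w$psd[sel]; f <- w$freq[sel]
  peak <- f[which.max(p)]
  cum <- cumsum(p)
  med <- f[which(cum >= cum[length(cum)] / 2)[1]]
  c(peak_freq = peak, median_freq = med)
}

#' Feature-extraction configuration
#'
#' @param bands Named list of [band()] objects.
#' @param feature_set `"pac"` (MI per band pair), `"spectral"`
#'   (peak/median frequency per band) or `"both"`.
#' @param pairs Optional subset of band pairs (list of
#'   `c(phase_name, amp_name)` character pairs); default all lower-triangle
#'   pairs.
#' @param line_freq Mains frequency for the notch (50 or 60); `NA` disables.
#' @param n_bins MI phase bins.
#' @param edge_guard_s Seconds excluded at each record edge (filter/Hilbert
#'   edge effects); windows overlapping the guard are skipped.
#' @export
feature_config <- function(bands = canonical_bands(), feature_set = c("both", "pac", "spectral"),
                           pairs = NULL, line_freq = 50, n_bins = 18L, edge_guard_s = 1) {
  feature_set <- match.arg(feature_set)
  structure(list(bands = bands, feature_set = feature_set, pairs = pairs,
                 line_freq = line_freq, n_bins = n_bins, edge_guard_s = edge_guard_s),
            class = "feature_config")
}

.resolve_pairs <- function(config) {
  all_pairs <- band_pairs(config$bands)
  if (is.null(config$pairs)) return(all_pairs)
  keys <- vapply(config$pairs, function(p) paste0(p[1], "_", p[2]), character(1))
  missing <- setdiff(keys, names(all_pairs))
  if (length(missing)) stop("unknown band pair(s): ", paste(missing, collapse = ", "))
  all_pairs[keys]
}

#' Build the per-window, per-channel feature table
#'
#' Filters each channel of the continuous record once per band (notch
#' first, since the mains frequency sits inside the gamma band), computes
#' the full-record Hilbert phase and envelope, then slices the per-window
#' series — windows therefore carry no per-window filter transients.
#'
#' @param rec A [recording()].
#' @param windows Window table from [extract_windows()] /
#'   [balance_windows()].
#' @param config A [feature_config()].
#' @return `data.frame`, one row per (window, channel): `window_start`,
#'   `label`, `seizure_id`, `channel`, then `mi_<phase>_<amp>` and/or
#'   `peak_<band>` / `median_<band>` columns.
#' @export
build_feature_table <- function(rec, windows, config = feature_config()) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  n <- ncol(rec$signal)
  dur <- n / fs
  pairs <- if (config$feature_set != "spectral") .resolve_pairs(config) else list()
  want_spec <- config$feature_set != "pac"
  spec_bands <- if (want_spec) config$bands else list()
  # bands actually needed
  need <- new.env()
  for (p in pairs) { need[[p$phase$name]] <- p$phase; need[[p$amp$name]] <- p$amp }
  for (b in spec_bands) need[[b$name]] <- b
  band_list <- as.list(need)

  mi_cols <- names(pairs)
  spec_cols <- if (want_spec)
    as.vector(rbind(paste0("peak_", names(spec_bands)), paste0("median_", names(spec_bands))))
  else character(0)
  feat_cols <- c(if (length(mi_cols)) paste0("mi_", mi_cols), spec_cols)

  if (nrow(windows) == 0) {
    out <- data.frame(window_start = numeric(0), label = character(0),
                      seizure_id = integer(0), channel = character(0))
    for (cc in feat_cols) out[[cc]] <- numeric(0)
    return(out)
  }

  guard <- config$edge_guard_s
  win_s <- attr(windows, "window_s")
  if (is.null(win_s)) win_s <- 30
  keep <- windows$start_s >= guard & (windows$start_s + win_s) <= (dur - guard)
  if (any(!keep)) message(sprintf("skipping %d window(s) inside the %g-s edge guard", sum(!keep), guard))
  windows <- windows[keep, , drop = FALSE]

  rows <- list()
  for (ch in seq_len(nrow(rec$signal))) {
    x <- rec$signal[ch, ]
    if (!is.na(config$line_freq)) x <- notch_filter(x, fs, config$line_freq)
    filt <- lapply(band_list, function(b) bandpass(x, fs, b))
    ph <- if (length(pairs)) lapply(filt, instantaneous_phase) else NULL
    env <- if (length(pairs)) lapply(filt, amplitude_envelope) else NULL
    for (wi in seq_len(nrow(windows))) {
      s0 <- windows$start_s[wi]
      i0 <- round(s0 * fs) + 1L
      i1 <- round((s0 + win_s) * fs)
      if (i1 > n) { message(sprintf("window at %g s extends past record end; skipped", s0)); next }
      vals <- numeric(0)
      if (length(pairs)) {
        mi <- vapply(pairs, function(p)
          modulation_index(amplitude_distribution(ph[[p$phase$name]][i0:i1],
                                                  env[[p$amp$name]][i0:i1],
                                                  config$n_bins)), numeric(1))
        vals <- c(vals, setNames(mi, paste0("mi_", names(pairs))))
      }
      if (want_spec) {
        for (b in spec_bands) {
          sf <- spectral_features(filt[[b$name]][i0:i1], fs, b, filtered = TRUE)
          vals <- c(vals, setNames(sf, c(paste0("peak_", b$name), paste0("median_", b$name))))
        }
      }
      rows[[length(rows) + 1L]] <- c(list(window_start = s0, label = windows$label[wi],
                                          seizure_id = windows$seizure_id[wi],
                                          channel = rec$channel_names[ch]),
                                     as.list(vals))
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(window_start = numeric(0), label = character(0),
                      seizure_id = integer(0), channel = character(0))
    for (cc in feat_cols) out[[cc]] <- numeric(0)
    return(out)
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
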