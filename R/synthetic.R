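# Synthetic annotated EEG with controllable, state-dependent
# phase-amplitude coupling.
#
# Construction: a low-frequency carrier plus a high-frequency carrier whose
# amplitude is modulated by the low carrier's phase,
#
#   s(t) = A_lo sin(2 pi f_p t)
#        + A_hi [1 - chi + chi (1 + sin(2 pi f_p t)) / 2] sin(2 pi f_a t)
#        + noise(t)
#
# chi = 0 gives a constant envelope (MI ~ 0), chi = 1 full modulation. The
# coupling can be gated by a seeded on/off square wave (duty cycle
# `burst_duty`) to mimic the rhythmic bursting of preictal coupling.

#' Specify a phase-amplitude coupling regime
#'
#' @param f_phase Low-frequency carrier (Hz), supplies the phase.
#' @param f_amp High-frequency carrier (Hz), supplies the amplitude.
#' @param chi Coupling strength in `[0, 1]`.
#' @param burst_duty Fraction of time coupling is switched on, `(0, 1]`.
#' @param amp_ratio Ratio of high- to low-carrier amplitude.
#' @param burst_period_s Period of the on/off gating square wave (s).
#' @export
pac_spec <- function(f_phase = 6, f_amp = 60, chi = 0.5, burst_duty = 1,
                     amp_ratio = 0.5, burst_period_s = 10) {
  if (chi < 0 || chi > 1) stop("chi must lie in [0, 1]")
  if (f_amp <= f_phase) stop("f_amp must exceed f_phase")
  if (burst_duty <= 0 || burst_duty > 1) stop("burst_duty must lie in (0, 1]")
  structure(list(f_phase = f_phase, f_amp = f_amp, chi = chi,
                 burst_duty = burst_duty, amp_ratio = amp_ratio,
                 burst_period_s = burst_period_s),
            class = "pac_spec")
}

# seeded noise; pink = 1/f amplitude shaping in the frequency domain
.gen_noise <- function(n, sd, color = c("white", "pink")) {
  color <- match.arg(color)
  if (sd <= 0) return(numeric(n))
  w <- rnorm(n)
  if (color == "white") return(sd * w)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))               # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)                 # symmetric shaping
  X <- X / sqrt(f)
  p <- Re(stats::fft(X, inverse = TRUE)) / n
  sd * p / stats::sd(p)
}

# on/off gate with duty cycle and a seeded random phase offset
.burst_gate <- function(t, duty, period_s) {
  if (duty >= 1) return(rep(1, length(t)))
  off <- runif(1, 0, period_s)
  as.numeric(((t + off) %% period_s) < duty * period_s)
}

#' Generate a single-channel phase-amplitude coupled signal
#'
#' @param spec A [pac_spec()].
#' @param duration Length in seconds.
#' @param fs Sampling rate (Hz).
#' @param noise_sd Additive noise standard deviation (signal units).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param noise_color `"white"` or `"pink"` (1/f).
#' @param a_low Low-carrier amplitude (default 10, microvolt-like).
#' @return Numeric signal vector of length `duration * fs`.
#' @export
generate_pac_signal <- function(spec, duration, fs, noise_sd = 0, seed = 1L,
                                noise_color = "white", a_low = 10) {
  stopifnot(inherits(spec, "pac_spec"))
  if (duration <= 0) stop("duration must be positive")
  if (spec$f_amp >= fs / 2 || spec$f_phase >= fs / 2)
    stop("carrier frequency at or above Nyquist")
  n <- round(duration * fs)
  if (n < 2) stop("need at least 2 samples")
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  gate <- .burst_gate(t, spec$burst_duty, spec$burst_period_s)
  chi_t <- spec$chi * gate
  low <- sin(2 * pi * spec$f_phase * t)
  m <- 1 - chi_t + chi_t * (1 + low) / 2
  a_high <- spec$amp_ratio * a_low
  a_low * low + a_high * m * sin(2 * pi * spec$f_amp * t) +
    .gen_noise(n, noise_sd, noise_color)
}

#' Configuration for a synthetic annotated recording
#'
#' Coupling timeline: outside any seizure-related span the channel carries
#' `interictal_pac`; in the window `[onset - coupling_start_s,
#' onset - coupling_end_s)` before each seizure it carries `preictal_pac`
#' (burst-gated). Defaults place that window exactly over the 30-min
#' preictal state at a 5-min seizure prediction horizon. The ictal span
#' (`ictal_dur_s` from each onset) adds a large-amplitude 4 Hz discharge
#' plus a broadband burst; it only needs to be annotated, never classified.
#'
#' @param fs Sampling rate (Hz).
#' @param n_channels Number of channels.
#' @param duration Total length (s); must exceed the last seizure offset.
#' @param seizure_onsets Onset times (s), strictly increasing.
#' @param interictal_pac,preictal_pac [pac_spec()] objects.
#' @param noise_sd Background noise SD.
#' @param noise_color `"white"` or `"pink"`.
#' @param seed Integer seed.
#' @param ictal_dur_s Seizure duration (s).
#' @param coupling_start_s,coupling_end_s Preictal-coupling window edges,
#'   seconds before onset (defaults 2100 and 300 = SPH 5 min + 30 min).
#' @export
synthetic_config <- function(fs = 256, n_channels = 1L, duration = 7200,
                             seizure_onsets = numeric(0),
                             interictal_pac = pac_spec(f_phase = 20, f_amp = 60, chi = 0.05),
                             preictal_pac = pac_spec(f_phase = 20, f_amp = 60, chi = 0.8,
                                                     burst_duty = 0.5),
                             noise_sd = 2, noise_color = "pink", seed = 1L,
                             ictal_dur_s = 60,
                             coupling_start_s = 2100, coupling_end_s = 300) {
  if (length(seizure_onsets) && is.unsorted(seizure_onsets, strictly = TRUE))
    stop("seizure_onsets must be strictly increasing")
  if (length(seizure_onsets) && max(seizure_onsets) + ictal_dur_s > duration)
    stop("duration must exceed the last seizure offset")
  if (coupling_end_s >= coupling_start_s) stop("coupling window is empty")
  structure(list(fs = fs, n_channels = as.integer(n_channels), duration = duration,
                 seizure_onsets = seizure_onsets, interictal_pac = interictal_pac,
                 preictal_pac = preictal_pac, noise_sd = noise_sd,
                 noise_color = noise_color, seed = as.integer(seed),
                 ictal_dur_s = ictal_dur_s, coupling_start_s = coupling_start_s,
                 coupling_end_s = coupling_end_s),
            class = "synthetic_config")
}

#' Construct a recording object
#'
#' @param signal Channels-by-samples numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param channel_names Character vector, one per row of `signal`.
#' @param annotations `data.frame` with `onset_s`, `offset_s` (seconds from
#'   record start, half-open intervals), strictly increasing onsets.
#' @export
recording <- function(signal, fs, channel_names = NULL,
                      annotations = data.frame(onset_s = numeric(0), offset_s = numeric(0))) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(signal)))
  stopifnot(length(channel_names) == nrow(signal))
  dur <- ncol(signal) / fs
  if (nrow(annotations)) {
    if (any(annotations$offset_s <= annotations$onset_s)) stop("annotation offset must exceed onset")
    if (is.unsorted(annotations$onset_s, strictly = TRUE)) stop("annotation onsets must be strictly increasing")
    if (min(annotations$onset_s) < 0 || max(annotations$offset_s) > dur)
      stop("annotations outside [0, duration]")
  }
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 annotations = annotations),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %d channel(s), fs = %g Hz, %.1f s, %d seizure(s)>\n",
              nrow(x$signal), x$fs, ncol(x$signal) / x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Generate a synthetic annotated multichannel recording
#'
#' Carrier phase is continuous across state boundaries (carriers are
#' evaluated on absolute time); only the coupling strength and gating
#' switch between states. Channels receive independent noise and gate
#' phases but share the annotation timeline.
#'
#' @param config A [synthetic_config()].
#' @return A [recording()].
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  on <- config$seizure_onsets
  if (length(on) > 1) {
    prev_off <- on[-length(on)] + config$ictal_dur_s
    if (any(on[-1] - config$coupling_start_s < prev_off))
      stop("preictal coupling window overlaps the previous seizure; space onsets further apart or merge clusters upstream")
  }
  n <- round(config$duration * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  ip <- config$interictal_pac; pp <- config$preictal_pac
  pre_mask <- rep(FALSE, n)
  ict_mask <- rep(FALSE, n)
  for (o in on) {
    pre_mask <- pre_mask | (t >= o - config$coupling_start_s & t < o - config$coupling_end_s)
    ict_mask <- ict_mask | (t >= o & t < o + config$ictal_dur_s)
  }
  a_low <- 10
  sig <- matrix(0, nrow = config$n_channels, ncol = n)
  for (ch in seq_len(config$n_channels)) {
    set.seed(config$seed + 7919L * (ch - 1L))
    gate_pre <- .burst_gate(t, pp$burst_duty, pp$burst_period_s)
    gate_int <- .burst_gate(t, ip$burst_duty, ip$burst_period_s)
    chi_t <- ifelse(pre_mask, pp$chi * gate_pre, ip$chi * gate_int)
    f_p <- ifelse(pre_mask, pp$f_phase, ip$f_phase)
    f_a <- ifelse(pre_mask, pp$f_amp, ip$f_amp)
    ar <- ifelse(pre_mask, pp$amp_ratio, ip$amp_ratio)
    low <- sin(2 * pi * f_p * t)
    m <- 1 - chi_t + chi_t * (1 + low) / 2
    x <- a_low * low + ar * a_low * m * sin(2 * pi * f_a * t) +
      .gen_noise(n, config$noise_sd, config$noise_color)
    if (any(ict_mask)) {
      x[ict_mask] <- x[ict_mask] + 5 * a_low * sin(2 * pi * 4 * t[ict_mask]) +
        rnorm(sum(ict_mask), sd = 2 * a_low)
    }
    sig[ch, ] <- x
  }
  ann <- data.frame(onset_s = on, offset_s = on + config$ictal_dur_s)
  recording(sig, config$fs, paste0("ch", seq_len(config$n_channels)), ann)
}
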