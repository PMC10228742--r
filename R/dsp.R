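# Filter design and spectral estimation primitives.
#
# Nothing here is EEG-specific: Butterworth band-pass design via the
# analog prototype -> LP->BP transform -> bilinear transform route,
# realised as second-order sections (SOS) for numerical stability at the
# narrow relative bandwidths of the delta band, plus zero-phase
# (forward-backward) application, an FFT Hilbert transform and a Welch
# periodogram. Designs were cross-checked against scipy.signal during
# development.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' @param lo,hi Band edges in Hz (`0 < lo < hi < fs/2`).
#' @param fs Sampling rate in Hz.
#' @param order Analog prototype order (default 5); the digital band-pass
#'   has `2 * order` poles, i.e. `order` biquad sections.
#' @return Numeric matrix with one row per section and columns
#'   `b0 b1 b2 a0 a1 a2` (`a0 = 1`).
#' @keywords internal
butter_bandpass_sos <- function(lo, hi, fs, order = 5L) {
  if (!(lo > 0 && hi > lo)) stop("band edges must satisfy 0 < lo < hi")
  if (hi >= fs / 2) stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)", hi, fs / 2))
  fs2 <- 2 * fs
  # pre-warped analog edges
  w1 <- fs2 * tan(pi * lo / fs)
  w2 <- fs2 * tan(pi * hi / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  n <- as.integer(order)
  # Butterworth low-pass prototype poles on the unit circle, Re < 0
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # LP -> BP in s: each prototype pole maps to a pair
  a <- p_lp * bw / 2
  s <- sqrt(a^2 - w0^2 + 0i)
  p_bp <- c(a + s, a - s)                       # 2n analog poles
  k_bp <- bw^n                                  # n analog zeros at s = 0
  # bilinear transform
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  # standard zpk bilinear gain: k * prod(fs2 - z) / prod(fs2 - p), zeros at 0
  k_z <- k_bp * Re(fs2^n / prod(fs2 - p_bp))
  # digital zeros: n at z = +1 (from s = 0) and n at z = -1 (degree deficit)
  .zpk_bp_to_sos(p_z, k_z, n)
}

# Pair the 2n digital band-pass poles into n biquads, each taking one zero
# at z = +1 and one at z = -1 (numerator 1, 0, -1). Complex poles pair with
# their conjugates; real poles (possible for wide relative bandwidths) pair
# among themselves. Sections ordered by increasing pole radius; overall gain
# folded into the first section.
.zpk_bp_to_sos <- function(p, k, n) {
  tol <- 1e-10
  cplx <- p[Im(p) > tol]
  reals <- sort(Re(p[abs(Im(p)) <= tol]))
  if (2 * length(cplx) + length(reals) != 2 * n)
    stop("internal: pole pairing failed")
  secs <- list()
  for (pc in cplx)
    secs[[length(secs) + 1L]] <- c(-2 * Re(pc), Mod(pc)^2, Mod(pc))
  if (length(reals) %% 2L != 0L) stop("internal: unpaired real pole")
  while (length(reals) >= 2) {
    r1 <- reals[1]; r2 <- reals[2]; reals <- reals[-(1:2)]
    secs[[length(secs) + 1L]] <- c(-(r1 + r2), r1 * r2, max(abs(r1), abs(r2)))
  }
  ord <- order(vapply(secs, `[`, numeric(1), 3))
  secs <- secs[ord]
  sos <- matrix(0, nrow = n, ncol = 6)
  for (i in seq_len(n)) {
    sos[i, ] <- c(1, 0, -1, 1, secs[[i]][1], secs[[i]][2])
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

#' Design a narrow IIR notch (band-stop) biquad
#'
#' Standard constrained-pole biquad with quality factor `q` (notch width
#' approximately `f0 / q` Hz at -3 dB).
#' @keywords internal
notch_sos <- function(f0, fs, q = 30) {
  if (f0 >= fs / 2) stop(sprintf("notch frequency %g Hz is at or above Nyquist (%g Hz)", f0, fs / 2))
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  matrix(c(1 / a0, -2 * cos(w0) / a0, 1 / a0,
           1, -2 * cos(w0) / a0, (1 - alpha) / a0),
         nrow = 1, byrow = TRUE)
}

# Steady-state (step-response) initial conditions per section, scaled along
# the cascade by the running DC gain; removes start-up transients in filtfilt.
.sos_zi <- function(sos) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 2)
  scale <- 1
  for (s in seq_len(ns)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    g <- sum(b) / sum(a)
    zi[s, 1] <- scale * (g - b[1])
    zi[s, 2] <- scale * (b[3] - a[3] * g)
    scale <- scale * g
  }
  zi
}

#' Apply an SOS filter forward-backward (zero phase)
#'
#' Odd-reflection padding at both ends with steady-state initial
#' conditions, mirroring common scientific-computing practice.
#' @keywords internal
sosfiltfilt <- function(sos, x) {
  n <- length(x)
  ntaps <- 2L * nrow(sos) + 1L
  padlen <- min(n - 1L, 3L * ntaps)
  if (padlen < 1L) stop("signal too short to filter")
  ext <- c(2 * x[1] - x[(padlen + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- .sos_zi(sos)
  y <- .sosfilt_cpp(sos, ext, zi * ext[1])
  y <- rev(y)
  y <- .sosfilt_cpp(sos, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1L):(padlen + n)]
}

#' Analytic signal via the FFT Hilbert transform
#'
#' @param x Real signal.
#' @return Complex vector of the same length; `Arg()` gives instantaneous
#'   phase, `Mod()` the amplitude envelope.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered overlapping segments; one-sided
#' density scaling so that `sum(psd) * df` approximates signal variance.
#'
#' @param x Signal.
#' @param fs Sampling rate (Hz).
#' @param seg_s Segment length in seconds (default 2, i.e. 0.5 Hz resolution).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nper <- round(seg_s * fs)
  if (length(x) < nper) stop("signal shorter than one Welch segment")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  u <- sum(w^2)
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nper even)
  if (nper %% 2 == 0) psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]
  else psd[2:nfreq] <- 2 * psd[2:nfreq]
  list(freq = (seq_len(nfreq) - 1L) * fs / nper, psd = psd)
}
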