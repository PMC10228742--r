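# Pre-processing: power-line notch, band decomposition, artifact hook.

#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-80 Hz.
#'
#' @param exclude_delta Drop the delta band (appropriate for recordings
#'   that were high-pass filtered at acquisition).
#' @param fs Optional sampling rate; when given, each band's upper edge is
#'   capped at `0.45 * fs` and bands that would collapse entirely are
#'   dropped with a message.
#' @return Named list of `band` objects (fields `name`, `lo`, `hi`).
#' @export
canonical_bands <- function(exclude_delta = FALSE, fs = NULL) {
  defs <- list(
    delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
    beta = c(13, 30), gamma = c(30, 80)
  )
  if (exclude_delta) defs$delta <- NULL
  out <- list()
  for (nm in names(defs)) {
    lo <- defs[[nm]][1]; hi <- defs[[nm]][2]
    if (!is.null(fs)) {
      hi <- min(hi, 0.45 * fs)
      if (hi <= lo) {
        message(sprintf("band %s collapses at fs = %g Hz; dropped", nm, fs))
        next
      }
    }
    out[[nm]] <- band(nm, lo, hi)
  }
  out
}

#' Construct a frequency band
#' @param name Band name.
#' @param lo,hi Edges in Hz, `lo < hi`.
#' @export
band <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1, lo > 0, hi > lo)
  structure(list(name = name, lo = lo, hi = hi), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Remove power-line interference with a zero-phase notch
#'
#' @param x Signal vector.
#' @param fs Sampling rate (Hz).
#' @param line_freq Mains frequency, 50 or 60 Hz depending on region.
#' @param q Notch quality factor (width about `line_freq / q` Hz).
#' @return Filtered signal, same length.
#' @export
notch_filter <- function(x, fs, line_freq, q = 30) {
  sos <- notch_sos(line_freq, fs, q)
  sosfiltfilt(sos, x)
}

#' Zero-phase Butterworth band-pass
#'
#' Fifth-order (by default) Butterworth applied forward-backward, so the
#' output has no group delay and downstream Hilbert phase estimates are
#' unbiased.
#'
#' @param x Signal vector.
#' @param fs Sampling rate (Hz).
#' @param band A [band()] object.
#' @param order Butterworth order (default 5).
#' @return Filtered signal, same length.
#' @export
bandpass <- function(x, fs, band, order = 5L) {
  stopifnot(inherits(band, "band"))
  hi <- band$hi
  if (hi >= fs / 2) stop(sprintf("band %s upper edge %g Hz is at or above Nyquist (fs = %g)",
                                 band$name, hi, fs))
  sos <- butter_bandpass_sos(band$lo, hi, fs, order)
  sosfiltfilt(sos, x)
}

#' Decompose a signal into EEG bands
#'
#' @inheritParams bandpass
#' @param bands List of [band()] objects (default [canonical_bands()]).
#' @return Named list of band-filtered signals, all the original length.
#' @export
decompose_bands <- function(x, fs, bands = canonical_bands(fs = fs), order = 5L) {
  if (length(bands) == 0) stop("empty band list")
  out <- lapply(bands, function(b) bandpass(x, fs, b, order))
  names(out) <- vapply(bands, `[[`, character(1), "name")
  out
}

#' Artifact-removal hook
#'
#' Placeholder for ICA-style artifact rejection on clinical data. Component
#' selection there is a manual judgement, so the default is an explicit
#' pass-through; callers may supply `fun(signal_matrix, fs)` implementing
#' any rejection scheme.
#'
#' @param signal Channels-by-samples matrix.
#' @param fs Sampling rate.
#' @param fun Optional function applied to the matrix; must preserve shape.
#' @return The (possibly cleaned) matrix.
#' @export
artifact_hook <- function(signal, fs, fun = NULL) {
  if (is.null(fun)) return(signal)
  out <- fun(signal, fs)
  if (!identical(dim(out), dim(signal)))
    stop("artifact hook must preserve the signal's dimensions")
  out
}
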