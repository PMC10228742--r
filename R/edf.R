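# Minimal EDF (European Data Format) reader/writer plus seizure-annotation
# parsing. EDF stores 16-bit integers per channel in fixed-duration data
# records with an ASCII header; physical scaling is linear per channel.
# Only what the pipeline needs is implemented: integer sampling rates,
# 1-second data records, no EDF+ TAL annotation streams (annotations
# travel in a CSV sidecar or a summary text file).

.pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

# format a number into <= 8 ASCII chars without silent truncation
.num8 <- function(x) {
  vapply(x, function(v) {
    for (d in 6:1) {
      s <- formatC(v, digits = d, format = "g")
      if (nchar(s) <= 8) return(s)
    }
    stop("cannot format ", v, " into 8 characters")
  }, character(1))
}

#' Write a recording to an EDF file
#'
#' One-second data records; requires an integer sampling rate and a
#' whole-second record length. Physical min/max are set per channel from
#' the data range, so the quantization step is
#' `(max - min) / (2^16 - 1)` per channel.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param annotations_path Optional CSV sidecar path for the seizure
#'   annotations (columns `onset_s`, `offset_s`); defaults to
#'   `paste0(path, ".seizures.csv")` when the recording has annotations.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, annotations_path = NULL) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  ns <- nrow(rec$signal)
  nsamp <- ncol(rec$signal)
  if (nsamp %% fs != 0) stop("recording length must be a whole number of seconds")
  n_rec <- nsamp %/% fs
  pmin_ <- apply(rec$signal, 1, min)
  pmax_ <- apply(rec$signal, 1, max)
  flat <- pmax_ <= pmin_
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad("0", 8), .pad("X X X X", 80), .pad("Startdate X X X X", 80),
    .pad("01.01.00", 8), .pad("00.00.00", 8),
    .pad(256 * (1 + ns), 8), .pad("", 44), .pad(n_rec, 8), .pad(1, 8), .pad(ns, 4))
  fld <- function(vals, width) paste0(vapply(vals, .pad, character(1), width), collapse = "")
  hdr <- paste0(hdr,
    fld(rec$channel_names, 16), fld(rep("", ns), 80), fld(rep("uV", ns), 8),
    fld(.num8(pmin_), 8), fld(.num8(pmax_), 8),
    fld(rep(dmin, ns), 8), fld(rep(dmax, ns), 8), fld(rep("", ns), 80),
    fld(rep(fs, ns), 8), fld(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  # physical values exactly as they will be re-read from the ASCII header
  pmin_r <- as.numeric(.num8(pmin_))
  pmax_r <- as.numeric(.num8(pmax_))
  scale <- (dmax - dmin) / (pmax_r - pmin_r)
  dig <- matrix(0L, ns, nsamp)
  for (ch in seq_len(ns)) {
    d <- round((rec$signal[ch, ] - pmin_r[ch]) * scale[ch]) + dmin
    dig[ch, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) writeBin(dig[ch, idx], con, size = 2L, endian = "little")
  }
  if (nrow(rec$annotations) > 0 || !is.null(annotations_path)) {
    if (is.null(annotations_path)) annotations_path <- paste0(path, ".seizures.csv")
    write_annotations(rec$annotations, annotations_path)
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file.
#' @param channels Optional character vector of channel labels to select
#'   (order preserved); channels absent from the file raise an error
#'   naming them.
#' @param annotations_path Optional CSV sidecar with seizure annotations;
#'   read automatically when `paste0(path, ".seizures.csv")` exists.
#' @return A [recording()].
#' @export
read_edf <- function(path, channels = NULL, annotations_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) stop("not an EDF file (bad version field): ", path)
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(32), character(1))

  sel <- seq_len(ns)
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing))
      stop("channel(s) not in file: ", paste(missing, collapse = ", "))
    sel <- match(channels, labels)
  }
  fs_all <- spr / rec_dur
  if (length(unique(fs_all[sel])) != 1)
    stop("selected channels have differing sampling rates")
  fs <- fs_all[sel[1]]

  total <- sum(spr)
  raw <- readBin(con, "integer", n = total * n_rec, size = 2L, endian = "little")
  if (length(raw) < total * n_rec) stop("truncated EDF data section: ", path)
  offs <- c(0L, cumsum(spr))
  sig <- matrix(0, nrow = length(sel), ncol = spr[sel[1]] * n_rec)
  for (k in seq_along(sel)) {
    ch <- sel[k]
    g <- (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
    idx <- as.vector(outer(seq_len(spr[ch]) + offs[ch], (seq_len(n_rec) - 1L) * total, `+`))
    sig[k, ] <- (raw[idx] - dmin[ch]) * g + pmin_[ch]
  }
  ann <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  if (is.null(annotations_path)) {
    cand <- paste0(path, ".seizures.csv")
    if (file.exists(cand)) annotations_path <- cand
  }
  if (!is.null(annotations_path)) ann <- read_annotations(annotations_path, "csv")$events
  recording(sig, fs, labels[sel], ann)
}

#' Write seizure annotations to CSV
#'
#' @param annotations `data.frame` with `onset_s`, `offset_s`.
#' @param path Output CSV path.
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations[, c("onset_s", "offset_s")], path, row.names = FALSE)
  invisible(path)
}

#' Read seizure annotations
#'
#' Two dialects: `"csv"` (columns `onset_s`, `offset_s`) and
#' `"chbmit-summary"` (free-text summary blocks containing lines such as
#' `Seizure Start Time: 2996 seconds` / `Seizure End Time: 3036 seconds`,
#' also accepting the numbered `Seizure 1 Start Time:` variant). Events
#' are returned sorted by onset; all times are seconds from record start.
#'
#' @param path Annotation file.
#' @param dialect `"csv"` or `"chbmit-summary"`.
#' @return List with `events` (`data.frame(onset_s, offset_s)`) and
#'   `source` (the dialect).
#' @export
read_annotations <- function(path, dialect = c("csv", "chbmit-summary")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- read.csv(path)
    if (!all(c("onset_s", "offset_s") %in% names(df)))
      stop("annotation CSV needs onset_s and offset_s columns")
    ev <- df[, c("onset_s", "offset_s")]
  } else {
    ln <- readLines(path, warn = FALSE)
    st <- grep("Seizure( [0-9]+)? Start Time:", ln, value = TRUE)
    en <- grep("Seizure( [0-9]+)? End Time:", ln, value = TRUE)
    if (length(st) != length(en)) stop("unbalanced seizure start/end lines")
    num <- function(v) as.numeric(sub(".*Time:\\s*([0-9.]+)\\s*seconds.*", "\\1", v))
    ev <- data.frame(onset_s = num(st), offset_s = num(en))
  }
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) && any(ev$offset_s <= ev$onset_s))
    stop("annotation with offset <= onset")
  list(events = ev, source = dialect)
}

#' Read a multi-file manifest and concatenate to one timeline
#'
#' Subjects in clinical databases are split across many EDF files. The
#' manifest is a JSON array of entries `{"edf": path, "start_s": optional
#' absolute start}`; files are laid end to end (or at their stated
#' `start_s`) and any gap between consecutive files is returned as an
#' unusable interval so that windows never span a discontinuity.
#'
#' @param path Manifest JSON.
#' @param channels Optional channel selection passed to [read_edf()].
#' @return List with `recording` (gaps zero-filled) and `unusable`
#'   (`data.frame(start_s, end_s)` of gap intervals).
#' @export
read_manifest <- function(path, channels = NULL) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(entries) == 0) stop("empty manifest")
  base <- dirname(path)
  recs <- list(); starts <- numeric(0); cursor <- 0
  unusable <- data.frame(start_s = numeric(0), end_s = numeric(0))
  for (e in entries) {
    p <- e$edf
    if (!file.exists(p)) p <- file.path(base, e$edf)
    r <- read_edf(p, channels)
    st <- if (!is.null(e$start_s)) as.numeric(e$start_s) else cursor
    if (st < cursor) stop("manifest entries overlap in time")
    if (st > cursor)
      unusable <- rbind(unusable, data.frame(start_s = cursor, end_s = st))
    recs[[length(recs) + 1L]] <- r
    starts <- c(starts, st)
    cursor <- st + ncol(r$signal) / r$fs
  }
  fs <- unique(vapply(recs, `[[`, numeric(1), "fs"))
  if (length(fs) != 1) stop("manifest files have differing sampling rates")
  nch <- unique(vapply(recs, function(r) nrow(r$signal), integer(1)))
  if (length(nch) != 1) stop("manifest files have differing channel counts")
  n_total <- round(cursor * fs)
  sig <- matrix(0, nrow = nch, ncol = n_total)
  ann <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  for (i in seq_along(recs)) {
    i0 <- round(starts[i] * fs) + 1L
    sig[, i0:(i0 + ncol(recs[[i]]$signal) - 1L)] <- recs[[i]]$signal
    if (nrow(recs[[i]]$annotations))
      ann <- rbind(ann, recs[[i]]$annotations + starts[i])
  }
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  list(recording = recording(sig, fs, recs[[1]]$channel_names, ann),
       unusable = unusable)
}
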