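# State labelling and sliding-window extraction.
#
# Around each retained lead seizure with onset t0 (seconds, 0-based,
# half-open intervals throughout):
#
#   ictal     [t0, offset)
#   sph       [t0 - SPH, t0)                    seizure prediction horizon
#   preictal  [t0 - SPH - P, t0 - SPH)          P = preictal length (30 min)
#
# plus a postictal guard (labelled unusable) after each offset so that
# "interictal" windows are genuinely between-seizure baseline. Seizures
# whose preictal + SPH lead-in would run off the start of the record or
# into the previous seizure are dropped from classification (their ictal
# span stays labelled).

#' Segmentation configuration
#'
#' @param sph_min Seizure prediction horizon in minutes (default 5).
#' @param preictal_min Preictal length in minutes (default 30).
#' @param window_s Window length in seconds (default 30).
#' @param step_s Slide step in seconds (default 15).
#' @param cluster_gap_min Lead-seizure merge threshold: a seizure starting
#'   within this many minutes of the previous offset is merged into it.
#'   Default `preictal_min + sph_min` (a follow-on seizure inside the lead
#'   seizure's prediction zone cannot have a clean preictal of its own).
#' @param postictal_guard_min Minutes after each seizure offset excluded
#'   from the interictal baseline (default 30).
#' @export
segmentation_config <- function(sph_min = 5, preictal_min = 30, window_s = 30,
                                step_s = 15, cluster_gap_min = preictal_min + sph_min,
                                postictal_guard_min = 30) {
  stopifnot(window_s > 0, step_s > 0, step_s <= window_s,
            sph_min > 0, preictal_min > 0, cluster_gap_min >= 0,
            postictal_guard_min >= 0)
  structure(list(sph_min = sph_min, preictal_min = preictal_min,
                 window_s = window_s, step_s = step_s,
                 cluster_gap_min = cluster_gap_min,
                 postictal_guard_min = postictal_guard_min),
            class = "segmentation_config")
}

#' Merge clustered seizures into their lead seizure
#'
#' Any seizure whose onset falls within `cluster_gap_min` minutes of the
#' previous (possibly already-extended) event's offset is absorbed into
#' that event, keeping the lead onset and extending the offset. Idempotent.
#'
#' @param annotations `data.frame(onset_s, offset_s)`, sorted by onset.
#' @param cluster_gap_min Gap threshold in minutes.
#' @return Merged annotation `data.frame`.
#' @export
merge_lead_seizures <- function(annotations, cluster_gap_min = 35) {
  if (nrow(annotations) == 0) return(annotations)
  ann <- annotations[order(annotations$onset_s), , drop = FALSE]
  gap <- cluster_gap_min * 60
  out <- ann[1, , drop = FALSE]
  for (i in seq_len(nrow(ann))[-1]) {
    j <- nrow(out)
    if (ann$onset_s[i] - out$offset_s[j] < gap) {
      out$offset_s[j] <- max(out$offset_s[j], ann$offset_s[i])
    } else {
      out <- rbind(out, ann[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

# overlay [s, e) with `label`/`sid` on a sorted, disjoint interval table
.paint <- function(iv, s, e, label, sid = NA_integer_) {
  if (e <= s) return(iv)
  keep <- list()
  for (i in seq_len(nrow(iv))) {
    a <- iv$start_s[i]; b <- iv$end_s[i]
    if (b <= s || a >= e) { keep[[length(keep) + 1L]] <- iv[i, ]; next }
    if (a < s) keep[[length(keep) + 1L]] <-
        data.frame(start_s = a, end_s = s, label = iv$label[i], seizure_id = iv$seizure_id[i])
    if (b > e) keep[[length(keep) + 1L]] <-
        data.frame(start_s = e, end_s = b, label = iv$label[i], seizure_id = iv$seizure_id[i])
  }
  keep[[length(keep) + 1L]] <- data.frame(start_s = s, end_s = e, label = label, seizure_id = sid)
  out <- do.call(rbind, keep)
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label the recording timeline into interictal / preictal / SPH / ictal
#'
#' @param duration_s Recording duration in seconds.
#' @param annotations Merged seizure annotations (see
#'   [merge_lead_seizures()]).
#' @param config A [segmentation_config()].
#' @param unusable Optional `data.frame(start_s, end_s)` of intervals to
#'   exclude outright (e.g. inter-file gaps from a manifest).
#' @return `data.frame(start_s, end_s, label, seizure_id)` partitioning
#'   `[0, duration_s)`; `seizure_id` indexes retained seizures on their
#'   preictal/sph/ictal intervals. Attribute `"dropped"` lists seizures
#'   excluded for insufficient lead-in, with reasons.
#' @export
label_states <- function(duration_s, annotations, config = segmentation_config(),
                         unusable = NULL) {
  sph_s <- config$sph_min * 60
  pre_s <- config$preictal_min * 60
  guard_s <- config$postictal_guard_min * 60
  iv <- data.frame(start_s = 0, end_s = duration_s,
                   label = "interictal", seizure_id = NA_integer_)
  ann <- annotations
  dropped <- data.frame(onset_s = numeric(0), reason = character(0))
  # postictal guards first (lowest priority above baseline)
  for (i in seq_len(nrow(ann)))
    iv <- .paint(iv, ann$offset_s[i], min(ann$offset_s[i] + guard_s, duration_s), "unusable")
  if (!is.null(unusable))
    for (i in seq_len(nrow(unusable)))
      iv <- .paint(iv, max(unusable$start_s[i], 0), min(unusable$end_s[i], duration_s), "unusable")
  sid <- 0L
  for (i in seq_len(nrow(ann))) {
    t0 <- ann$onset_s[i]
    pre_start <- t0 - sph_s - pre_s
    prev_off <- if (i > 1) ann$offset_s[i - 1] else -Inf
    if (pre_start < 0) {
      dropped <- rbind(dropped, data.frame(onset_s = t0, reason = "lead-in runs off record start"))
    } else if (pre_start < prev_off) {
      dropped <- rbind(dropped, data.frame(onset_s = t0, reason = "lead-in overlaps previous seizure"))
    } else {
      sid <- sid + 1L
      iv <- .paint(iv, pre_start, t0 - sph_s, "preictal", sid)
      iv <- .paint(iv, t0 - sph_s, t0, "sph", sid)
    }
    iv <- .paint(iv, t0, min(ann$offset_s[i], duration_s), "ictal",
                 if (pre_start >= 0 && pre_start >= prev_off) sid else NA_integer_)
  }
  if (nrow(dropped))
    message(sprintf("dropped %d seizure(s) from classification: %s",
                    nrow(dropped),
                    paste(sprintf("onset %gs (%s)", dropped$onset_s, dropped$reason), collapse = "; ")))
  attr(iv, "dropped") <- dropped
  attr(iv, "config") <- config
  iv
}

#' Extract sliding windows from labelled intervals
#'
#' Within each interval of length `L >= window_s` there are
#' `floor((L - window_s) / step_s) + 1` windows; windows never cross
#' interval boundaries. Unusable intervals yield no windows.
#'
#' @param intervals Output of [label_states()].
#' @param config A [segmentation_config()].
#' @param labels Which interval labels to window (default interictal,
#'   preictal, sph, ictal; classification later uses only the first two).
#' @return `data.frame(start_s, label, seizure_id)` with attribute
#'   `"window_s"`.
#' @export
extract_windows <- function(intervals, config = segmentation_config(),
                            labels = c("interictal", "preictal", "sph", "ictal")) {
  w <- config$window_s; st <- config$step_s
  rows <- list()
  for (i in seq_len(nrow(intervals))) {
    if (!(intervals$label[i] %in% labels)) next
    L <- intervals$end_s[i] - intervals$start_s[i]
    if (L < w) next
    k <- floor((L - w) / st) + 1
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = intervals$start_s[i] + (seq_len(k) - 1) * st,
      label = intervals$label[i],
      seizure_id = intervals$seizure_id[i])
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(start_s = numeric(0), label = character(0), seizure_id = integer(0))
  rownames(out) <- NULL
  attr(out, "window_s") <- w
  out
}

#' Balance interictal windows against preictal windows per seizure
#'
#' The interictal baseline of a long record dwarfs the preictal windows;
#' training on the imbalance inflates apparent accuracy. For each retained
#' seizure with `n` preictal windows, `n` interictal windows are sampled
#' without replacement (seeded) from the unassigned pool and tagged with
#' that seizure's id, so grouped cross-validation keeps each seizure's
#' preictal windows and its paired interictal sample in one fold.
#'
#' @param windows Output of [extract_windows()].
#' @param seed Integer seed.
#' @return Window table restricted to preictal windows plus the paired
#'   interictal samples.
#' @export
balance_windows <- function(windows, seed = 1L) {
  w_attr <- attr(windows, "window_s")
  pre <- windows[windows$label == "preictal", , drop = FALSE]
  pool <- windows[windows$label == "interictal", , drop = FALSE]
  set.seed(seed)
  out <- list()
  for (sid in sort(unique(pre$seizure_id))) {
    n_k <- sum(pre$seizure_id == sid)
    take <- min(n_k, nrow(pool))
    if (take < n_k)
      warning(sprintf("seizure %d: only %d interictal window(s) available for %d preictal",
                      sid, take, n_k))
    if (take > 0) {
      pick <- sample.int(nrow(pool), take)
      got <- pool[pick, , drop = FALSE]
      got$seizure_id <- sid
      out[[length(out) + 1L]] <- got
      pool <- pool[-pick, , drop = FALSE]
    }
  }
  res <- rbind(pre, if (length(out)) do.call(rbind, out))
  res <- res[order(res$start_s), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "window_s") <- w_attr
  res
}
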