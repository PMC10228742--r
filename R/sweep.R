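# Seizure-prediction-horizon sweep and Kruskal-Wallis comparison.

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on `groups - 1`
#' degrees of freedom (delegated to `stats::kruskal.test`). When every
#' observation is identical the statistic is defined as 0 (p = 1) rather
#' than the 0/0 the tie correction would produce. Small groups (< 5) make
#' the chi-square approximation rough; they are flagged in the result.
#'
#' @param groups List of >= 2 numeric vectors (e.g. per-recording
#'   accuracies at each SPH setting).
#' @return List with `H`, `p_value`, `df`, `group_sizes`,
#'   `small_sample` flag.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0)) stop("empty group")
  if (sum(sizes) < 3) stop("need at least 3 observations in total")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1) {
    return(list(H = 0, p_value = 1, df = length(groups) - 1L,
                group_sizes = sizes, small_sample = any(sizes < 5)))
  }
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(vals, g)
  list(H = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter), group_sizes = sizes,
       small_sample = any(sizes < 5))
}

#' Sweep the seizure prediction horizon
#'
#' Re-runs segmentation, feature extraction and classification on the same
#' recordings at each SPH setting, then compares per-recording mean
#' accuracies across settings with a Kruskal-Wallis test. Only the interval
#' labels change between settings; the feature code path is identical
#' across SPH values.
#'
#' @param recordings List of [recording()] objects (a synthetic cohort or
#'   loaded EDF files).
#' @param seg_config Base [segmentation_config()]; its `sph_min` is
#'   overridden by each sweep value.
#' @param feat_config A [feature_config()]; the default restricts features
#'   to the beta-gamma MI, the band pair that separates states best.
#' @param rf A [rf_config()].
#' @param sph_values SPH settings in minutes (default 5, 10, 15).
#' @param seed Top-level seed.
#' @return A `sweep_result`: `reports[[sph]][[recording]]`,
#'   `accuracy` data.frame (sph, recording, accuracy), `kruskal`,
#'   `dropped` log of recordings excluded at some SPH.
#' @export
run_sweep <- function(recordings, seg_config = segmentation_config(),
                      feat_config = feature_config(feature_set = "pac",
                                                   pairs = list(c("beta", "gamma"))),
                      rf = rf_config(), sph_values = c(5, 10, 15), seed = 1L) {
  if (length(recordings) == 0) stop("empty recording set")
  if (is.null(names(recordings)))
    names(recordings) <- paste0("rec", seq_along(recordings))
  acc <- list(); reports <- list(); dropped <- list()
  for (sph in sph_values) {
    sph_key <- paste0("sph", sph)
    reports[[sph_key]] <- list()
    for (nm in names(recordings)) {
      rec <- recordings[[nm]]
      sc <- seg_config; sc$sph_min <- sph
      ann <- merge_lead_seizures(rec$annotations, sc$cluster_gap_min)
      iv <- label_states(ncol(rec$signal) / rec$fs, ann, sc)
      wins <- extract_windows(iv, sc, labels = c("interictal", "preictal"))
      if (!any(wins$label == "preictal") ||
          length(unique(wins$seizure_id[wins$label == "preictal"])) < 2) {
        msg <- sprintf("recording %s dropped at SPH %d min: %s", nm, sph,
                       if (!any(wins$label == "preictal")) "no preictal windows"
                       else "fewer than 2 retained seizures")
        message(msg)
        dropped[[length(dropped) + 1L]] <- data.frame(recording = nm, sph = sph, reason = msg)
        next
      }
      wins <- balance_windows(wins, .subseed(seed, sph, match(nm, names(recordings))))
      feats <- build_feature_table(rec, wins, feat_config)
      rfc <- rf; rfc$seed <- .subseed(seed, sph, match(nm, names(recordings)), 2L)
      rep <- suppressWarnings(train_eval(feats, rfc))
      reports[[sph_key]][[nm]] <- rep
      acc[[length(acc) + 1L]] <- data.frame(sph = sph, recording = nm,
                                            accuracy = unname(rep$overall["accuracy"]))
    }
  }
  acc <- if (length(acc)) do.call(rbind, acc) else
    data.frame(sph = numeric(0), recording = character(0), accuracy = numeric(0))
  kw <- NULL
  groups <- split(acc$accuracy, acc$sph)
  if (length(groups) >= 2 && all(vapply(groups, length, integer(1)) >= 1))
    kw <- kruskal_wallis(groups)
  structure(list(reports = reports, accuracy = acc, kruskal = kw,
                 dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
                 sph_values = sph_values, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  if (nrow(x$accuracy)) {
    m <- tapply(x$accuracy$accuracy, x$accuracy$sph, mean)
    for (s in names(m)) cat(sprintf("  SPH %s min: mean accuracy %.4f (n=%d)\n",
                                    s, m[[s]], sum(x$accuracy$sph == as.numeric(s))))
  }
  if (!is.null(x$kruskal))
    cat(sprintf("  Kruskal-Wallis: H = %.4f, p = %.4f\n", x$kruskal$H, x$kruskal$p_value))
  invisible(x)
}
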