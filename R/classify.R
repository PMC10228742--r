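# Interictal-vs-preictal classification: max-min normalization, grouped
# k-fold cross-validation, random-forest grid search, confusion metrics.
# Preictal is the positive class throughout.

#' Fit max-min normalization parameters
#'
#' @param table Feature `data.frame` (training rows only).
#' @param cols Feature column names (default: all numeric columns except
#'   `window_start`).
#' @param range Target mapping range, default `c(-1, 1)`.
#' @return Object of class `minmax_params`.
#' @export
minmax_fit <- function(table, cols = NULL, range = c(-1, 1)) {
  if (is.null(cols)) cols <- .feature_cols(table)
  mins <- vapply(cols, function(cc) min(table[[cc]]), numeric(1))
  maxs <- vapply(cols, function(cc) max(table[[cc]]), numeric(1))
  structure(list(cols = cols, min = mins, max = maxs, range = range),
            class = "minmax_params")
}

#' Apply fitted max-min normalization
#'
#' Maps each feature's training minimum to `range[1]` and maximum to
#' `range[2]`; rows outside the training range (test data) map outside the
#' range, as the fitted affine map dictates. Constant training features map
#' to the range midpoint with a warning.
#'
#' @param table Feature `data.frame`.
#' @param params A `minmax_params` from [minmax_fit()].
#' @return `table` with normalized feature columns.
#' @export
minmax_apply <- function(table, params) {
  lo <- params$range[1]; hi <- params$range[2]
  for (cc in params$cols) {
    span <- params$max[[cc]] - params$min[[cc]]
    if (span <= 0) {
      warning("constant feature '", cc, "' mapped to the range midpoint")
      table[[cc]] <- rep((lo + hi) / 2, nrow(table))
    } else {
      table[[cc]] <- (table[[cc]] - params$min[[cc]]) / span * (hi - lo) + lo
    }
  }
  table
}

#' Fit-and-apply max-min normalization on one table
#' @inheritParams minmax_fit
#' @export
minmax_normalize <- function(table, cols = NULL, range = c(-1, 1)) {
  minmax_apply(table, minmax_fit(table, cols, range))
}

.feature_cols <- function(table) {
  cand <- setdiff(names(table), c("window_start", "label", "seizure_id", "channel"))
  cand[vapply(cand, function(cc) is.numeric(table[[cc]]), logical(1))]
}

#' Random-forest configuration and hyperparameter grid
#'
#' Grid-searched hyperparameters follow the usual random-forest trio:
#' number of trees, minimum samples to split, maximum depth (`Inf` =
#' unbounded). `mtry` is fixed at `floor(sqrt(p))`.
#'
#' @param n_estimators Candidate tree counts.
#' @param min_samples_split Candidate split minima.
#' @param max_depth Candidate depth caps (`Inf` allowed).
#' @param k Number of cross-validation folds (default 10).
#' @param inner_k Inner folds for grid search (default 3).
#' @param seed Top-level seed; fans out deterministically to folds,
#'   bootstraps and subsampling.
#' @export
rf_config <- function(n_estimators = c(50L, 100L, 200L),
                      min_samples_split = c(2L, 5L, 10L),
                      max_depth = c(5, 10, Inf),
                      k = 10L, inner_k = 3L, seed = 1L) {
  stopifnot(all(n_estimators >= 1), all(min_samples_split >= 2),
            all(max_depth >= 1), k >= 2, inner_k >= 2)
  structure(list(n_estimators = as.integer(n_estimators),
                 min_samples_split = as.integer(min_samples_split),
                 max_depth = max_depth, k = as.integer(k),
                 inner_k = as.integer(inner_k), seed = as.integer(seed)),
            class = "rf_config")
}

# deterministic small-integer sub-seed derivation (stays below 2^31)
.subseed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647L)
  for (v in c(...)) h <- (h * 31 + as.double(v) + 1) %% 2147483647
  as.integer(h)
}

#' Fit a bagged-tree (random forest) binary classifier
#'
#' @param x Numeric feature matrix.
#' @param y 0/1 integer labels (1 = positive class).
#' @param n_estimators Number of trees.
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param max_depth Depth cap (`Inf` for unbounded).
#' @param mtry Features sampled per split (default `floor(sqrt(p))`).
#' @param seed Integer seed.
#' @export
rf_fit <- function(x, y, n_estimators = 100L, min_samples_split = 2L,
                   max_depth = Inf, mtry = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(x) == length(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  md <- if (is.finite(max_depth)) as.integer(max_depth) else -1L
  trees <- .rf_fit_cpp(x, y, as.integer(n_estimators), as.integer(mtry),
                       as.integer(min_samples_split), md, as.integer(seed))
  structure(list(trees = trees, p = ncol(x)), class = "pac_rf")
}

#' Predict with a fitted random forest
#'
#' Majority vote over trees; ties go to the negative class.
#'
#' @param model A `pac_rf` from [rf_fit()].
#' @param x Feature matrix.
#' @param type `"class"` (0/1) or `"prob"` (fraction of trees voting 1).
#' @export
rf_predict <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  stopifnot(ncol(x) == model$p)
  votes <- .rf_predict_cpp(model$trees, x)
  if (type == "prob") votes else as.integer(votes > 0.5)
}

#' Assign seizure groups to cross-validation folds
#'
#' Grouped split: every row sharing a `seizure_id` (a seizure's preictal
#' windows plus its paired interictal sample) lands in one fold. Groups are
#' shuffled (seeded) and dealt to folds greedily by size so fold sizes stay
#' balanced to within one group. With fewer groups than `k`, `k` is
#' reduced to the group count (leave-one-seizure-out) with a warning.
#'
#' @param table Feature table with a `seizure_id` column.
#' @param k Requested fold count.
#' @param seed Integer seed.
#' @return Integer fold id per row; attribute `"k"` is the effective k.
#' @export
make_folds <- function(table, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  groups <- sort(unique(table$seizure_id))
  if (length(groups) < 2) stop("grouped cross-validation needs at least 2 seizure groups")
  if (length(groups) < k) {
    warning(sprintf("only %d seizure group(s); reducing k from %d (leave-one-seizure-out)",
                    length(groups), k))
    k <- length(groups)
  }
  set.seed(seed)
  sizes <- vapply(groups, function(g) sum(table$seizure_id == g), numeric(1))
  ord <- sample(seq_along(groups))                  # seeded shuffle breaks ties
  ord <- ord[order(-sizes[ord])]                    # largest first
  fold_of <- integer(length(groups))
  load <- numeric(k)
  for (g in ord) {
    f <- which.min(load)
    fold_of[g] <- f
    load[f] <- load[f] + sizes[g]
  }
  res <- fold_of[match(table$seizure_id, groups)]
  attr(res, "k") <- k
  res
}

#' Confusion-count metrics
#'
#' Accuracy, precision, recall and F1 from TP/TN/FP/FN with preictal as
#' the positive class. Zero-denominator precision or recall returns 0 with
#' a warning; F1 is 0 when precision + recall is 0.
#'
#' @param counts Named list or vector with `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts[["TP"]]; TN <- counts[["TN"]]; FP <- counts[["FP"]]; FN <- counts[["FN"]]
  total <- TP + TN + FP + FN
  if (total <= 0) stop("empty confusion table")
  acc <- (TP + TN) / total
  prec <- if (TP + FP > 0) TP / (TP + FP) else { warning("precision undefined (TP+FP=0); returning 0"); 0 }
  rec <- if (TP + FN > 0) TP / (TP + FN) else { warning("recall undefined (TP+FN=0); returning 0"); 0 }
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

.confusion <- function(truth, pred) {
  c(TP = sum(truth == 1 & pred == 1), TN = sum(truth == 0 & pred == 0),
    FP = sum(truth == 0 & pred == 1), FN = sum(truth == 1 & pred == 0))
}

# inner grouped CV over the hyperparameter grid; returns the best triple
.grid_search <- function(x, y, sid, config, seed) {
  grid <- expand.grid(n_estimators = config$n_estimators,
                      min_samples_split = config$min_samples_split,
                      max_depth = config$max_depth)
  if (nrow(grid) == 1) return(grid[1, ])
  tab <- data.frame(seizure_id = sid)
  k_in <- min(config$inner_k, length(unique(sid)))
  if (k_in < 2) return(grid[1, ])
  folds <- suppressWarnings(make_folds(tab, k_in, .subseed(seed, 17L)))
  k_in <- attr(folds, "k")
  best <- 1L; best_acc <- -1
  for (g in seq_len(nrow(grid))) {
    accs <- numeric(0)
    for (f in seq_len(k_in)) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[tr])) < 2 || !any(te)) next
      m <- rf_fit(x[tr, , drop = FALSE], y[tr],
                  grid$n_estimators[g], grid$min_samples_split[g], grid$max_depth[g],
                  seed = .subseed(seed, g, f))
      accs <- c(accs, mean(rf_predict(m, x[te, , drop = FALSE]) == y[te]))
    }
    a <- if (length(accs)) mean(accs) else -1
    if (a > best_acc + 1e-12) { best_acc <- a; best <- g }
  }
  grid[best, ]
}

#' Train and evaluate the interictal-vs-preictal classifier
#'
#' Per channel: seizure-grouped k-fold cross-validation. In each fold the
#' max-min normalization and the hyperparameter grid search see training
#' rows only; the selected forest is refit on the full training fold and
#' scored on the held-out seizures. Metrics are computed per (channel,
#' fold), then averaged over folds within channel and over channels.
#'
#' @param table Feature table from [build_feature_table()] with labels
#'   `interictal` / `preictal`.
#' @param config An [rf_config()].
#' @param pooled Pool channels into a single classifier instead of one per
#'   channel (default `FALSE`, matching single-channel analysis).
#' @return An `eval_report`: `per_fold` data.frame (channel, fold, counts,
#'   metrics, chosen hyperparameters), `per_channel` and `overall`
#'   aggregate metrics, and the seed.
#' @export
train_eval <- function(table, config = rf_config(), pooled = FALSE) {
  table <- table[table$label %in% c("interictal", "preictal"), , drop = FALSE]
  if (nrow(table) == 0) stop("no interictal/preictal rows to classify")
  cols <- .feature_cols(table)
  if (length(cols) == 0) stop("no feature columns found")
  channels <- if (pooled) "pooled" else sort(unique(table$channel))
  per_fold <- list()
  for (ch in channels) {
    sub <- if (pooled) table else table[table$channel == ch, , drop = FALSE]
    y <- as.integer(sub$label == "preictal")
    folds <- make_folds(sub, config$k, .subseed(config$seed, 1L))
    k_eff <- attr(folds, "k")
    for (f in seq_len(k_eff)) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[tr])) < 2) {
        warning(sprintf("channel %s fold %d: single-class training set; skipped", ch, f))
        next
      }
      norm <- minmax_fit(sub[tr, , drop = FALSE], cols)
      xtr <- as.matrix(minmax_apply(sub[tr, , drop = FALSE], norm)[, cols, drop = FALSE])
      xte <- as.matrix(minmax_apply(sub[te, , drop = FALSE], norm)[, cols, drop = FALSE])
      ch_i <- match(ch, channels)
      best <- .grid_search(xtr, y[tr], sub$seizure_id[tr], config,
                           .subseed(config$seed, ch_i, f))
      m <- rf_fit(xtr, y[tr], best$n_estimators, best$min_samples_split,
                  best$max_depth, seed = .subseed(config$seed, ch_i, f, 3L))
      pred <- rf_predict(m, xte)
      cnt <- .confusion(y[te], pred)
      met <- compute_metrics(cnt)
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        channel = ch, fold = f, t(cnt), t(met),
        n_estimators = best$n_estimators,
        min_samples_split = best$min_samples_split,
        max_depth = best$max_depth)
    }
  }
  if (length(per_fold) == 0) stop("all folds skipped")
  pf <- do.call(rbind, per_fold)
  metric_names <- c("accuracy", "precision", "recall", "f1")
  per_channel <- do.call(rbind, lapply(split(pf, pf$channel), function(d)
    data.frame(channel = d$channel[1], t(colMeans(d[, metric_names])))))
  rownames(per_channel) <- NULL
  overall <- colMeans(per_channel[, metric_names, drop = FALSE])
  structure(list(per_fold = pf, per_channel = per_channel, overall = overall,
                 seed = config$seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n  overall:",
      paste(sprintf("%s=%.4f", names(x$overall), x$overall), collapse = "  "),
      sprintf("\n  %d fold-evaluations over %d channel(s), seed %d\n",
              nrow(x$per_fold), nrow(x$per_channel), x$seed))
  invisible(x)
}
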