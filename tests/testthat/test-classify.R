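# Normalization, grouped folds, random forest, metrics.

test_that("max-min normalization follows the mapping formula", {
  tab <- data.frame(label = "interictal", seizure_id = 1L, channel = "c",
                    window_start = 1:3, f = c(0, 5, 10))
  got <- minmax_normalize(tab, cols = "f")
  expect_equal(got$f, c(-1, 0, 1))

  params <- minmax_fit(data.frame(f = c(0, 10)), cols = "f")
  out <- minmax_apply(data.frame(f = 20), params)
  expect_equal(out$f, 3)  # (20-0)/10 * 2 - 1

  cst <- data.frame(f = c(2, 2, 2))
  expect_warning(gotc <- minmax_normalize(cst, cols = "f"), "constant")
  expect_equal(gotc$f, c(0, 0, 0))
})

test_that("normalization and grid search never see test rows", {
  tab <- gaussian_table(n_groups = 4, n = 10, seed = 3)
  tr <- tab$seizure_id != 4
  p1 <- minmax_fit(tab[tr, ])
  # perturb test rows wildly; fitted params must not change
  tab2 <- tab
  tab2$mi_beta_gamma[!tr] <- tab2$mi_beta_gamma[!tr] * 1000
  p2 <- minmax_fit(tab2[tr, ])
  expect_identical(p1, p2)
})

test_that("grouped folds keep seizures intact and balance sizes", {
  tab <- gaussian_table(n_groups = 20, n = 5, seed = 2)
  f <- make_folds(tab, k = 10, seed = 1)
  expect_equal(attr(f, "k"), 10)
  split_tab <- split(tab$seizure_id, f)
  # no group split across folds
  for (g in unique(tab$seizure_id))
    expect_equal(length(unique(f[tab$seizure_id == g])), 1)
  # 2 groups per fold (equal group sizes)
  expect_true(all(vapply(split_tab, function(s) length(unique(s)), numeric(1)) == 2))

  expect_warning(f3 <- make_folds(gaussian_table(n_groups = 3, n = 5), k = 10), "reducing")
  expect_equal(attr(f3, "k"), 3)
  expect_error(make_folds(tab, k = 1), "at least 2")
  expect_identical(make_folds(tab, 10, seed = 5), make_folds(tab, 10, seed = 5))
})

test_that("metric formulas and identities hold", {
  m <- compute_metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unname(m), c(1, 1, 1, 1))

  m2 <- compute_metrics(c(TP = 40, TN = 30, FP = 20, FN = 10))
  expect_equal(unname(m2["accuracy"]), 0.70)
  expect_equal(unname(m2["precision"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(m2["recall"]), 0.80)
  expect_equal(unname(m2["f1"]), 0.72727272727, tolerance = 1e-9)
  # F1 = 2TP / (2TP + FP + FN)
  expect_equal(unname(m2["f1"]), 2 * 40 / (2 * 40 + 20 + 10), tolerance = 1e-12)
  # accuracy invariant under class swap
  m2s <- compute_metrics(c(TP = 30, TN = 40, FP = 10, FN = 20))
  expect_equal(m2s[["accuracy"]], m2[["accuracy"]])

  expect_warning(m0 <- compute_metrics(c(TP = 0, TN = 10, FP = 0, FN = 5)), "precision")
  expect_equal(unname(m0["precision"]), 0)
})

test_that("the forest separates separable features and is seed-deterministic", {
  tab <- gaussian_table(n_groups = 10, n = 20, seed = 1)
  rep1 <- train_eval(tab, fast_rf(seed = 5))
  expect_gte(rep1$overall[["accuracy"]], 0.95)
  rep2 <- train_eval(tab, fast_rf(seed = 5))
  expect_identical(rep1$per_fold, rep2$per_fold)

  set.seed(99)
  shuf <- tab; shuf$label <- sample(shuf$label)
  rep3 <- suppressWarnings(train_eval(shuf, fast_rf(seed = 5)))
  expect_gte(rep3$overall[["accuracy"]], 0.35)
  expect_lte(rep3$overall[["accuracy"]], 0.65)
})

test_that("the hyperparameter grid search selects within the declared grid", {
  tab <- gaussian_table(n_groups = 6, n = 8, seed = 4)
  cfg <- rf_config(n_estimators = c(20L, 50L), min_samples_split = c(2L, 10L),
                   max_depth = c(3, Inf), k = 3L, seed = 2L)
  rep <- suppressWarnings(train_eval(tab, cfg))
  expect_true(all(rep$per_fold$n_estimators %in% c(20, 50)))
  expect_true(all(rep$per_fold$min_samples_split %in% c(2, 10)))
  expect_true(all(rep$per_fold$max_depth %in% c(3, Inf)))
  expect_gte(rep$overall[["accuracy"]], 0.9)
})

test_that("rf_fit/rf_predict expose a sane standalone interface", {
  set.seed(6)
  x <- matrix(c(rnorm(50, 0), rnorm(50, 3)), ncol = 1)
  y <- rep(c(0L, 1L), each = 50)
  m <- rf_fit(x, y, n_estimators = 50, seed = 3)
  expect_equal(mean(rf_predict(m, x) == y), 1, tolerance = 0.02)
  pr <- rf_predict(m, x, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))
  m2 <- rf_fit(x, y, n_estimators = 50, seed = 3)
  expect_identical(rf_predict(m2, x, "prob"), pr)
})
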