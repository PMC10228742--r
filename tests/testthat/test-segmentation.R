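# Lead-seizure merging, state labelling, window extraction.

test_that("lead-seizure merging follows the cluster rule and is idempotent", {
  ev <- data.frame(onset_s = c(100, 200), offset_s = c(160, 260))
  m <- merge_lead_seizures(ev, 60)  # threshold 3600 s
  expect_equal(nrow(m), 1)
  expect_equal(unlist(m[1, ], use.names = FALSE), c(100, 260))

  far <- data.frame(onset_s = c(1000, 1000 + 7200), offset_s = c(1060, 1060 + 7200))
  expect_equal(merge_lead_seizures(far, 35), far)

  # chain of 3 events 10 min apart collapses into one under a 35-min gap
  chain <- data.frame(onset_s = c(0, 600, 1200), offset_s = c(60, 660, 1260))
  mc <- merge_lead_seizures(chain, 35)
  expect_equal(nrow(mc), 1)
  expect_equal(c(mc$onset_s, mc$offset_s), c(0, 1260))

  expect_equal(merge_lead_seizures(mc, 35), mc)  # idempotent
  expect_equal(nrow(merge_lead_seizures(ev[0, ], 35)), 0)
})

test_that("state labelling arithmetic matches the SPH/SOP scheme", {
  ann <- data.frame(onset_s = 3600, offset_s = 3660)
  iv <- label_states(7200, ann, segmentation_config(sph_min = 5))
  pre <- iv[iv$label == "preictal", ]
  sph <- iv[iv$label == "sph", ]
  expect_equal(c(pre$start_s, pre$end_s), c(1500, 3300))
  expect_equal(c(sph$start_s, sph$end_s), c(3300, 3600))

  iv15 <- label_states(7200, ann, segmentation_config(sph_min = 15))
  pre15 <- iv15[iv15$label == "preictal", ]
  expect_equal(c(pre15$start_s, pre15$end_s), c(900, 2700))

  # insufficient lead-in: onset at 1000 s needs 2100 s
  expect_message(
    iv_drop <- label_states(7200, data.frame(onset_s = 1000, offset_s = 1060),
                            segmentation_config(sph_min = 5)),
    "dropped")
  expect_false(any(iv_drop$label == "preictal"))
  expect_true(any(iv_drop$label == "ictal"))  # the seizure itself stays labelled
  expect_equal(nrow(attr(iv_drop, "dropped")), 1)
})

test_that("labelled intervals partition the record", {
  set.seed(21)
  for (trial in 1:25) {
    dur <- runif(1, 5000, 40000)
    n_seiz <- sample(0:4, 1)
    onsets <- sort(runif(n_seiz, 100, dur - 200))
    ann <- data.frame(onset_s = onsets, offset_s = onsets + runif(n_seiz, 20, 90))
    ann <- merge_lead_seizures(ann, 35)
    iv <- suppressMessages(label_states(dur, ann, segmentation_config()))
    expect_equal(iv$start_s[1], 0)
    expect_equal(iv$end_s[nrow(iv)], dur)
    if (nrow(iv) > 1) {
      expect_true(all(iv$start_s[-1] == iv$end_s[-nrow(iv)]))  # disjoint, gap-free
      expect_true(all(iv$end_s > iv$start_s))
    }
  }
})

test_that("preictal geometry is SPH-consistent", {
  ann <- data.frame(onset_s = 20000, offset_s = 20060)
  for (sph in c(5, 10, 15)) {
    iv <- label_states(30000, ann, segmentation_config(sph_min = sph))
    pre <- iv[iv$label == "preictal", ]
    expect_equal(pre$end_s, 20000 - sph * 60)
    expect_equal(pre$end_s - pre$start_s, 1800)  # always preictal_min
  }
})

test_that("window extraction counts match the formula and an enumeration oracle", {
  sc <- segmentation_config()
  mk <- function(L) data.frame(start_s = 0, end_s = L, label = "preictal", seizure_id = 1L)
  expect_equal(nrow(extract_windows(mk(1800), sc)), 119)
  expect_equal(nrow(extract_windows(mk(30), sc)), 1)
  expect_equal(nrow(extract_windows(mk(29), sc)), 0)

  set.seed(4)
  for (i in 1:1000) {
    L <- runif(1, 0, 400)
    w <- extract_windows(mk(L), sc)
    expect_equal(nrow(w), count_windows_oracle(L, 30, 15))
  }

  # windows lie wholly inside their interval
  w <- extract_windows(mk(100), sc)
  expect_true(all(w$start_s >= 0 & w$start_s + 30 <= 100))
})

test_that("interictal balancing pairs windows with seizures", {
  wins <- rbind(
    data.frame(start_s = seq(0, 3000, 15), label = "interictal", seizure_id = NA_integer_),
    data.frame(start_s = seq(4000, 4300, 15), label = "preictal", seizure_id = 1L),
    data.frame(start_s = seq(9000, 9300, 15), label = "preictal", seizure_id = 2L))
  attr(wins, "window_s") <- 30
  bal <- balance_windows(wins, seed = 7)
  for (sid in 1:2) {
    n_pre <- sum(bal$label == "preictal" & bal$seizure_id == sid)
    n_int <- sum(bal$label == "interictal" & bal$seizure_id == sid)
    expect_equal(n_int, n_pre)
  }
  # determinism
  expect_equal(balance_windows(wins, seed = 7), bal)
  # shortage: fewer interictal windows than preictal
  short <- wins[c(1:3, which(wins$label == "preictal" & wins$seizure_id == 1L)), ]
  attr(short, "window_s") <- 30
  expect_warning(balance_windows(short, seed = 1), "available")
})
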