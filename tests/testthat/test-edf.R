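# EDF read/write, annotation dialects, multi-file manifests.

test_that("EDF round trip preserves structure to quantization accuracy", {
  cfg <- synthetic_config(fs = 256, duration = 60, n_channels = 3L, seed = 13,
                          seizure_onsets = numeric(0))
  rec <- generate_recording(cfg)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, 256)
  expect_identical(back$channel_names, rec$channel_names)
  step <- (apply(rec$signal, 1, max) - apply(rec$signal, 1, min)) / (2^16 - 1)
  for (ch in 1:3)
    expect_lte(max(abs(back$signal[ch, ] - rec$signal[ch, ])), step[ch] * 1.01)
  # sample bookkeeping: fs * duration
  expect_equal(ncol(back$signal), 256 * 60)
})

test_that("annotations survive the sidecar round trip exactly", {
  cfg <- synthetic_config(fs = 128, duration = 7200, seizure_onsets = 3600, seed = 2)
  rec <- generate_recording(cfg)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$annotations$onset_s, rec$annotations$onset_s)
  expect_equal(back$annotations$offset_s, rec$annotations$offset_s)
})

test_that("channel selection errors name the missing channels", {
  rec <- recording(matrix(rnorm(512), nrow = 2), 256, c("A", "B"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_error(read_edf(path, channels = c("A", "C")), "C")
  sel <- read_edf(path, channels = "B")
  expect_identical(sel$channel_names, "B")
  expect_error(read_edf(tempfile(), ), "no such file")
})

test_that("CSV annotation dialect parses and sorts", {
  p <- tempfile(fileext = ".csv")
  writeLines("onset_s,offset_s\n100,160", p)
  ann <- read_annotations(p, "csv")
  expect_equal(ann$events$onset_s, 100)
  expect_equal(ann$events$offset_s, 160)

  writeLines("onset_s,offset_s\n500,560\n100,160", p)
  expect_equal(read_annotations(p, "csv")$events$onset_s, c(100, 500))

  writeLines("onset_s,offset_s\n100,90", p)
  expect_error(read_annotations(p, "csv"), "offset")
})

test_that("summary-text dialect parses the documented grammar", {
  p <- tempfile(fileext = ".txt")
  writeLines(c(
    "File Name: chb01_03.edf",
    "File Start Time: 13:43:04",
    "Number of Seizures in File: 2",
    "Seizure 1 Start Time: 2996 seconds",
    "Seizure 1 End Time: 3036 seconds",
    "Seizure 2 Start Time: 4100 seconds",
    "Seizure 2 End Time: 4180 seconds"), p)
  ann <- read_annotations(p, "chbmit-summary")
  expect_equal(ann$events$onset_s, c(2996, 4100))
  expect_equal(ann$events$offset_s, c(3036, 4180))
  # unnumbered variant
  writeLines(c("Seizure Start Time: 2996 seconds",
               "Seizure End Time: 3036 seconds"), p)
  expect_equal(read_annotations(p, "chbmit-summary")$events$onset_s, 2996)
})

test_that("manifests concatenate files and expose gaps as unusable time", {
  d <- tempfile(); dir.create(d)
  r1 <- recording(matrix(rnorm(256 * 10), nrow = 1), 256, "A",
                  data.frame(onset_s = 4, offset_s = 6))
  r2 <- recording(matrix(rnorm(256 * 10), nrow = 1), 256, "A")
  write_edf(r1, file.path(d, "a.edf"))
  write_edf(r2, file.path(d, "b.edf"))
  mf <- file.path(d, "manifest.json")
  jsonlite::write_json(list(list(edf = "a.edf"),
                            list(edf = "b.edf", start_s = 15)),
                       mf, auto_unbox = TRUE)
  got <- read_manifest(mf)
  expect_equal(ncol(got$recording$signal) / 256, 25)
  expect_equal(got$unusable, data.frame(start_s = 10, end_s = 15))
  expect_equal(got$recording$annotations$onset_s, 4)
  # gap must never be windowed
  iv <- label_states(25, got$recording$annotations,
                     segmentation_config(postictal_guard_min = 0),
                     unusable = got$unusable)
  lab <- iv$label[iv$start_s <= 12 & iv$end_s >= 12]
  expect_equal(lab, "unusable")
})
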