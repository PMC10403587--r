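# EDF+ writing and reading

test_that("EDF roundtrip is lossless up to 16-bit quantization", {
  set.seed(1)
  ann <- data.frame(onset_s = c(10.5, 60, 100), duration_s = c(0, 90, 0),
                    label = c("montage_change", "hyperventilation", "eye_close"),
                    stringsAsFactors = FALSE)
  rec <- new_recording(matrix(rnorm(19 * 120 * 200, sd = 30), 19), 200,
                       channels_1020(), ann, eeg_id = "E42", patient_id = "P7")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  # quantization bound: one step of the padded physical range
  step <- apply(rec$signal, 1, function(v) diff(range(v)) * 1.1 / 65535)
  expect_true(all(abs(back$signal - rec$signal) <= step + 1e-12))
  expect_equal(back$annotations$onset_s, ann$onset_s)
  expect_equal(back$annotations$duration_s, ann$duration_s)
  expect_equal(back$annotations$label, ann$label)
  expect_equal(back$channel_labels, channels_1020())
  expect_equal(back$sampling_rate, 200)
  expect_equal(back$patient_id, "P7")
})

test_that("EDF header advertises the declared geometry", {
  set.seed(2)
  rec <- new_recording(matrix(rnorm(19 * 300 * 200), 19), 200, channels_1020())
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  hdr <- readBin(f, "raw", 256)
  expect_equal(as.integer(trimws(rawToChar(hdr[253:256]))), 19)  # no annotations
  expect_equal(as.integer(trimws(rawToChar(hdr[237:244]))), 300)  # 1-s records
  back <- read_edf(f)
  expect_equal(nrow(back$annotations), 0)
})

test_that("truncated and malformed files raise informative errors", {
  set.seed(3)
  rec <- new_recording(matrix(rnorm(2 * 20 * 200), 2), 200, c("Cz", "Pz"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  sz <- file.info(f)$size
  raw <- readBin(f, "raw", sz)
  f2 <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw[1:(sz - 2000)], f2)
  expect_error(read_edf(f2), "truncated.*20.*records", ignore.case = TRUE)
  f3 <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw[1:100], f3)
  expect_error(read_edf(f3), "header")
})

test_that("out-of-range samples are clipped with a warning", {
  x <- sin(2 * pi * 5 * (0:399) / 200) * 50
  x[100] <- 400  # exceeds the declared range
  rec <- new_recording(matrix(x, 1), 200, "Cz")
  f <- withr::local_tempfile(fileext = ".edf")
  expect_warning(write_edf(rec, f, physical_range = c(-100, 100)), "clipped 1")
  back <- read_edf(f)
  expect_equal(back$signal[1, 100], 100, tolerance = 0.01)
  expect_equal(back$signal[1, 50], x[50], tolerance = 0.01)
})

test_that("an independent EDF reader agrees with the writer", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(4)
  rec <- new_recording(matrix(rnorm(3 * 30 * 200, sd = 25), 3), 200,
                       c("Fp1", "Cz", "O2"),
                       data.frame(onset_s = 5, duration_s = 2, label = "eye_open"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  script <- paste(
    "import sys, json, mne, numpy as np",
    "raw = mne.io.read_raw_edf(sys.argv[1], preload=True, verbose='ERROR')",
    "sig = raw.get_data() * 1e6",
    "print(json.dumps({'ch': raw.ch_names, 'max0': float(np.max(np.abs(sig[0]))),",
    "  'n': int(sig.shape[1]), 'ann': list(raw.annotations.description)}))",
    sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- suppressWarnings(system2("python", c(sf, f), stdout = TRUE, stderr = FALSE))
  info <- jsonlite::fromJSON(out[length(out)])
  expect_equal(info$n, 30 * 200)
  expect_true(all(c("Fp1", "Cz", "O2") %in% sub("^EEG ", "", info$ch)))
  expect_equal(info$max0, max(abs(rec$signal[1, ])), tolerance = 1e-3)
  expect_true("eye_open" %in% info$ann)
})
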