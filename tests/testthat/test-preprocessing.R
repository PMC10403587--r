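# Filtering, referencing, epoching, artifact rejection and repair

fs <- 200

test_that("high-pass and notch filters have the required frequency response", {
  t <- (0:(60 * fs - 1)) / fs
  mid <- 2000:10000  # avoid edges
  atten_db <- function(x, y) -20 * log10(sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2)))
  rec <- function(x) new_recording(matrix(x, 1), fs, "Cz")

  s60 <- sin(2 * pi * 60 * t)
  expect_gt(atten_db(s60, filter_recording(rec(s60))$signal[1, ]), 30)
  s02 <- sin(2 * pi * 0.2 * t)
  expect_gt(atten_db(s02, filter_recording(rec(s02))$signal[1, ]), 20)
  s10 <- sin(2 * pi * 10 * t)
  expect_lt(abs(atten_db(s10, filter_recording(rec(s10))$signal[1, ])), 1)
  z <- filter_recording(rec(numeric(60 * fs)))
  expect_true(all(z$signal == 0))
  expect_error(filter_recording(rec(s10), hp_cutoff_hz = 150), "Nyquist")
})

test_that("average reference zeroes channel sums and is idempotent", {
  set.seed(1)
  rec <- new_recording(matrix(rnorm(4 * 100), 4), fs, c("Fp1", "Fp2", "O1", "O2"))
  ar <- to_average_reference(rec)
  expect_lt(max(abs(colSums(ar$signal))), 1e-9)
  expect_equal(to_average_reference(ar)$signal, ar$signal)
  two <- new_recording(rbind(a = rnorm(50), b = rnorm(50)), fs, c("C3", "C4"))
  ar2 <- to_average_reference(two)
  expect_equal(ar2$signal[1, ], (two$signal[1, ] - two$signal[2, ]) / 2)
})

test_that("epoch extraction follows the annotation schedule", {
  dur <- 300
  sig <- matrix(rnorm(2 * dur * fs), 2)
  mk <- function(ann) new_recording(sig, fs, c("Cz", "Pz"), ann)

  one <- extract_epochs(mk(data.frame(onset_s = 30, duration_s = 0,
                                      label = "montage_change")))
  expect_length(one, 1)
  expect_equal(one[[1]]$onset_s, 30)
  expect_equal(ncol(one[[1]]$data), 10 * fs)

  hv <- extract_epochs(mk(data.frame(onset_s = 60, duration_s = 90,
                                     label = "hyperventilation")))
  expect_equal(sum(vapply(hv, `[[`, "", "condition") == "hyperventilation"), 6)
  expect_equal(sum(vapply(hv, `[[`, "", "condition") == "post_hyperventilation"), 8)
  expect_equal(vapply(hv, `[[`, 0, "onset_s")[1:6], 60 + c(0, 15, 30, 45, 60, 75))

  late <- suppressWarnings(
    extract_epochs(mk(data.frame(onset_s = dur - 5, duration_s = 0,
                                 label = "eye_close"))))
  expect_length(late, 0)
  expect_warning(extract_epochs(mk(empty_annotations())), "no epochs")
})

test_that("threshold CV flags injected high-amplitude channel-epochs", {
  set.seed(2)
  base <- matrix(sin(2 * pi * 10 * (0:1999) / fs), 19, 2000, byrow = TRUE) * 20
  epochs <- lapply(1:22, function(i) make_epoch(base + rnorm(19 * 2000), epoch_index = i))
  for (i in 21:22) epochs[[i]]$data[5, ] <- epochs[[i]]$data[5, ] * 10
  thr <- fit_rejection_thresholds(epochs, k_folds = 5)
  ptp5 <- vapply(epochs, function(ep) diff(range(ep$data[5, ])), numeric(1))
  rejected <- which(ptp5 > thr$thresholds[5])
  expect_setequal(rejected, 21:22)
  # monotone: raising the threshold never grows the rejected set
  expect_true(all(ptp5 > thr$thresholds[5] * 2) || sum(ptp5 > thr$thresholds[5] * 2) <= length(rejected))

  # grid of size one -> that threshold
  thr1 <- fit_rejection_thresholds(epochs, k_folds = 5, candidate_grid = 123)
  expect_true(all(thr1$thresholds == 123))

  # identical epochs -> smallest candidate above their peak-to-peak
  same <- lapply(1:6, function(i) make_epoch(base, epoch_index = i))
  g <- c(10, 50, 90, 130)
  thr2 <- fit_rejection_thresholds(same, k_folds = 5, candidate_grid = g)
  ptp <- diff(range(base[1, ]))
  expect_true(all(thr2$thresholds == min(g[g >= ptp])))
})

test_that("repair interpolates flagged channels and drops hopeless epochs", {
  set.seed(3)
  pos <- electrode_positions()
  field <- 40 * (pos[, "y"] + 0.6 * pos[, "z"])  # smooth low-order topography
  epochs <- lapply(1:6, function(i) {
    make_epoch(matrix(field, 19, 2000) + rnorm(19 * 2000, sd = 0.5), epoch_index = i)
  })
  thr <- structure(list(thresholds = stats::setNames(rep(1e6, 19), channels_1020())),
                   class = "threshold_map")
  expect_equal(repair_epochs(epochs, thr)[[1]]$data, epochs[[1]]$data)  # nothing to do

  bad_ep <- epochs[[1]]
  bad_ep$data[9, ] <- bad_ep$data[9, ] * 5e4  # C3 blown up (huge peak-to-peak)
  thr2 <- thr; thr2$thresholds["C3"] <- 100
  rep1 <- repair_epochs(list(bad_ep), thr2)[[1]]
  expect_identical(rep1$interpolated_channels, "C3")
  err <- sqrt(mean((rep1$data[9, ] - field[9])^2))
  expect_lt(err, 0.10 * sqrt(mean(field^2)))
  # unmasked channels untouched
  expect_equal(rep1$data[-9, ], bad_ep$data[-9, ])

  many_bad <- epochs[[2]]
  many_bad$data[1:7, ] <- many_bad$data[1:7, ] * 5e4
  thr3 <- thr; thr3$thresholds[1:7] <- 100
  expect_message(out <- repair_epochs(list(many_bad), thr3), "dropping")
  expect_length(out, 0)  # 7/19 > 0.3
})
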