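# Marker estimators: wavelets, spectra, complexity measures

test_that("wavelet decomposition conserves energy and localizes tones", {
  set.seed(1)
  x <- rnorm(1920)  # divisible by 2^6: periodized transform is orthogonal
  d <- wavelet_decompose(x)
  e <- sum(vapply(d$details, function(v) sum(v^2), numeric(1))) + sum(d$approx^2)
  expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-8)

  s <- sin(2 * pi * 10 * (0:1999) / 200)  # 10 Hz at 200 Hz -> level 4 (12.5-6.25)
  energies <- vapply(wavelet_decompose(s)$details, function(v) sum(v^2), numeric(1))
  expect_identical(which.max(energies), 4L)

  z <- wavelet_decompose(numeric(256))
  expect_true(all(vapply(z$details, function(v) all(v == 0), logical(1))))
  expect_error(wavelet_decompose(numeric(32), wavelet_spec(n_levels = 6)), "too short")
})

test_that("band power concentrates tone energy and satisfies Parseval", {
  tone <- sin(2 * pi * 9 * (0:1999) / 200)
  pw <- 10^band_power(tone, 200)
  expect_gt(pw[["alpha_low"]] / sum(pw), 0.90)

  expect_equal(unname(band_power(numeric(2000), 200)), rep(-12, 10))
  expect_error(band_power(tone, 150), "Nyquist")

  # white-noise total band power ~ variance fraction in 1-100 Hz
  rel_err <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(2000, sd = 2)
    tot <- sum(10^band_power(x, 200))
    sp <- multitaper_psd(x, 200)
    df <- sp$freq[2] - sp$freq[1]
    expected <- sum(sp$psd[sp$freq >= 1 & sp$freq < 100]) * df
    abs(tot - expected) / expected
  }, numeric(1))
  expect_lt(mean(rel_err), 0.10)
})

test_that("peak alpha frequency finds tones and defaults sensibly on noise", {
  expect_equal(peak_alpha_frequency(sin(2 * pi * 9.5 * (0:1999) / 200), 200),
               9.5, tolerance = 0.1)
  # exact tie -> lower peak
  sp_freq <- peak_alpha_frequency(numeric(2000), 200)
  expect_gte(sp_freq, 8); expect_lte(sp_freq, 13)
  pafs <- vapply(1:50, function(s) {
    set.seed(s); peak_alpha_frequency(rnorm(2000), 200)
  }, numeric(1))
  expect_true(all(pafs >= 8 & pafs <= 13))
  expect_gt(stats::sd(pafs), 0.5)  # spread across the band, not stuck at an edge
})

test_that("hurst exponent recovers white noise and random-walk regimes", {
  h_wn <- vapply(1:30, function(s) { set.seed(s); hurst_exponent(rnorm(2000)) },
                 numeric(1))
  expect_lt(abs(mean(h_wn) - 0.5), 0.1)
  h_rw <- vapply(1:30, function(s) { set.seed(s); hurst_exponent(cumsum(rnorm(2000))) },
                 numeric(1))
  expect_gt(mean(h_rw), 0.85)
  expect_error(hurst_exponent(rnorm(19)), "too short")
  expect_true(is.na(hurst_exponent(rep(1, 100))))
})

test_that("line length matches hand computation and is homogeneous", {
  expect_equal(line_length(rep(3, 50)), 0)
  expect_equal(line_length(c(0, 1, 0, 1)), 3)
  set.seed(2)
  x <- rnorm(100)
  expect_equal(line_length(-2.5 * x), 2.5 * line_length(x))
})

test_that("correlation dimension separates noise from a limit cycle", {
  cd_noise <- vapply(1:20, function(s) { set.seed(s); correlation_dimension(rnorm(1000)) },
                     numeric(1))
  expect_gt(mean(cd_noise), 2.2)
  expect_lt(mean(cd_noise), 3.2)
  cd_sine <- correlation_dimension(sin(2 * pi * 3 * (0:999) / 100))
  expect_gt(cd_sine, 0.7); expect_lt(cd_sine, 1.4)
  expect_true(is.na(correlation_dimension(rep(1, 500))))
})

test_that("marker tensor has the documented layout and degenerate rules", {
  set.seed(3)
  ep <- make_epoch(matrix(rnorm(19 * 2000), 19))
  tens <- extract_marker_tensor(list(ep), 200)
  expect_equal(nrow(tens), 19 * (10 + 1 + 6 * 8))
  expect_identical(tens, extract_marker_tensor(list(ep), 200))  # deterministic

  flat <- ep
  flat$data[3, ] <- 0
  tf <- extract_marker_tensor(list(flat), 200)
  ch3 <- tf[tf$channel == flat$channel_labels[3], ]
  expect_true(all(is.na(ch3$value[ch3$marker == "HE"])))
  expect_true(all(is.na(ch3$value[ch3$marker == "CD"])))
  expect_true(all(ch3$value[ch3$marker == "LL"] == 0))
})

test_that("entropy-parameter selection favors discriminative settings", {
  # two recording families that differ only in a tau-visible timescale
  set.seed(4)
  mk_rec_eps <- function(freq, n_ep) {
    lapply(seq_len(n_ep), function(i) {
      make_epoch(matrix(sin(2 * pi * freq * (0:499) / 200) + rnorm(500, sd = 0.3),
                        1), labels = "Cz", epoch_index = i)
    })
  }
  grid <- list(entropy_params(tau = 1), entropy_params(tau = 5))
  recs <- c(lapply(c(5, 5.2), function(f) mk_rec_eps(f, 3)),
            lapply(c(30, 31), function(f) mk_rec_eps(f, 3)))
  sel <- select_entropy_params(recs, grid, fs = 200)
  expect_s3_class(sel, "entropy_params")
  expect_true(sel$tau %in% c(1L, 5L))
  # grid of one -> that point
  expect_identical(select_entropy_params(recs, grid[2], fs = 200)$tau, 5L)
  # score invariant to recording relabeling
  s1 <- attr(select_entropy_params(recs, grid, fs = 200), "scores")
  s2 <- attr(select_entropy_params(rev(recs), grid, fs = 200), "scores")
  expect_equal(s1, s2)
})

test_that("iterative imputation restores structured missing values", {
  set.seed(5)
  z <- rnorm(80)
  x <- cbind(a = z, b = z * 2 + 1, c = rnorm(80))
  expect_equal(impute_missing(x)$data, x)  # nothing missing -> unchanged
  xm <- x
  xm[7, "b"] <- NA
  imp <- impute_missing(xm)
  expect_lt(abs(imp$data[7, "b"] - x[7, "b"]), 1e-2)
  expect_equal(imp$data, impute_missing(xm)$data)  # deterministic
  # train/apply split uses training statistics
  xnew <- cbind(a = z[1:10], b = NA_real_, c = rnorm(10))
  filled <- impute_apply(imp, xnew)
  expect_lt(max(abs(filled[, "b"] - (z[1:10] * 2 + 1))), 0.05)
  expect_error(impute_missing(matrix(NA_real_, 2, 2)), "all-missing rows")
})
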