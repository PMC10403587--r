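# Synthetic cohort generator

test_that("simulation is deterministic and respects the configured prevalence", {
  cfg <- sim_config(n_patients = 8, duration_s = 60, seed = 42,
                    annotation_schedule = list(montage_interval_s = 20,
                                               hv_start_s = NULL, hv_duration_s = NULL,
                                               photic_start_s = NULL, photic_freqs = NULL,
                                               photic_dur_s = NULL, eye_interval_s = NULL))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$recordings[[1]]$signal, b$recordings[[1]]$signal)

  # binomial oracle for the observed prevalence across seeds
  prevs <- vapply(1:50, function(s) {
    cfg2 <- sim_config(n_patients = 200, prevalence_recurrence = 0.3, seed = s)
    mean(simulate_cohort(cfg2, recordings = FALSE)$cohort$outcome_recurrence_1y)
  }, numeric(1))
  se <- sqrt(0.3 * 0.7 / (200 * 50))
  expect_lt(abs(mean(prevs) - 0.3), 3 * se)

  empty <- simulate_cohort(sim_config(n_patients = 0))
  expect_equal(nrow(empty$cohort), 0)
  expect_length(empty$recordings, 0)
})

test_that("cohort table satisfies its survival invariants", {
  co <- simulate_cohort(sim_config(n_patients = 300, seed = 7),
                        recordings = FALSE)$cohort
  expect_true(all(co$time_to_event_weeks[co$event_observed] <=
                    co$followup_weeks[co$event_observed] + 1e-9))
  expect_identical(co$outcome_recurrence_1y,
                   co$event_observed & co$time_to_event_weeks <= 52)
  expect_false(any(duplicated(co$patient_id)))
  expect_error(sim_config(prevalence_recurrence = 1.5), "prevalence")
  expect_error(sim_config(survival = list(baseline_hazard_week = -1,
                                          log_hr_risk = 0, followup_min_weeks = 1,
                                          followup_max_weeks = 2)),
               "baseline_hazard")
})

test_that("recordings have the declared geometry and annotations", {
  cfg <- sim_config(n_patients = 1, seed = 3)
  sim <- simulate_cohort(cfg)
  rec <- sim$recordings[[1]]
  expect_equal(dim(rec$signal), c(19, 300 * 200))
  expect_equal(rec$channel_labels, channels_1020())
  labs <- rec$annotations$label
  expect_true(any(startsWith(labs, "montage_change")))
  expect_true(any(startsWith(labs, "hyperventilation")))
  expect_equal(sum(startsWith(labs, "photic")), 10)
  expect_true(any(startsWith(labs, "eye")))
  # schedule exceeding the duration errors
  bad <- sim_config(n_patients = 1, duration_s = 100, seed = 3)
  expect_error(simulate_recording(sim$cohort[1, ], bad), "exceeds")
})

test_that("injected PAF shift is recovered by the markers", {
  shift <- -2
  diffs <- local({
    cfg0 <- sparse_sim_config(30, seed = 21,
                              effect_sizes = c(bp_alpha = 0, paf_hz = shift, entropy = 0),
                              n_channels = 4, prevalence = 0.5)
    sim <- simulate_cohort(cfg0)
    paf <- vapply(seq_len(nrow(sim$cohort)), function(i) {
      rec <- sim$recordings[[i]]
      ep <- rec$signal[4, 1:2000]  # an occipital channel, first 10 s
      peak_alpha_frequency(ep, 200)
    }, numeric(1))
    split(paf, sim$cohort$outcome_recurrence_1y)
  })
  d <- mean(diffs[["TRUE"]]) - mean(diffs[["FALSE"]])
  se <- sqrt(var(diffs[["TRUE"]]) / length(diffs[["TRUE"]]) +
               var(diffs[["FALSE"]]) / length(diffs[["FALSE"]]))
  expect_lt(abs(d - shift), 2 * se + 0.3)
  expect_lt(d, -1)  # sign and rough magnitude
})

test_that("flat-effect runs show less band-power spread than injected-effect runs", {
  get_alpha_sd <- function(es, seed) {
    cfg <- sparse_sim_config(24, seed = seed, effect_sizes = es,
                             prevalence = 0.5)
    sim <- simulate_cohort(cfg)
    a <- vapply(sim$recordings, function(r) {
      ch <- match("O1", r$channel_labels)
      unname(band_power(r$signal[ch, 1:2000], 200)["alpha_high"])
    }, numeric(1))
    sd(a)
  }
  flat <- get_alpha_sd(c(bp_alpha = 0, paf_hz = 0, entropy = 0), 31)
  eff <- get_alpha_sd(c(bp_alpha = 5, paf_hz = 0, entropy = 0), 31)
  expect_gt(eff / flat, 1.5)
})

test_that("unconditional outcome generator matches the exponential law", {
  lam <- 0.01
  o <- simulate_outcomes(rep(0, 5000),
                         list(baseline_hazard_week = lam, log_hr_risk = 0,
                              followup_min_weeks = 200, followup_max_weeks = 400),
                         seed = 5)
  km <- kaplan_meier(o$time_to_event_weeks, o$event_observed)
  i <- max(which(km$curves$time <= 52))
  expect_gt(exp(-52 * lam), km$curves$ci_low[i])
  expect_lt(exp(-52 * lam), km$curves$ci_high[i])
  # degenerate: zero follow-up -> everything censored at 0
  o0 <- simulate_outcomes(rep(0, 10),
                          list(baseline_hazard_week = lam, log_hr_risk = 0,
                               followup_min_weeks = 0, followup_max_weeks = 0),
                          seed = 6)
  expect_true(all(!o0$event_observed))
  expect_true(all(o0$time_to_event_weeks == 0))
  expect_error(simulate_outcomes(0, list(baseline_hazard_week = 0,
                                         log_hr_risk = 0, followup_min_weeks = 0,
                                         followup_max_weeks = 1)),
               "positive")
})

test_that("fractional Gaussian noise carries the requested Hurst exponent", {
  for (H in c(0.3, 0.7)) {
    est <- vapply(1:30, function(s) hurst_exponent(simulate_fgn(2000, H, seed = s)),
                  numeric(1))
    expect_lt(abs(mean(est) - H), 0.15)
  }
})
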