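# Synthetic cohort generator: annotated EEG recordings + clinical table
# with known ground-truth effect structure.

#' Simulation configuration
#'
#' Defines a synthetic cohort: annotated multichannel recordings whose
#' spectral/complexity structure differs between outcome classes through a
#' latent risk, plus a clinical covariate table with censored time-to-seizure
#' outcomes.
#'
#' Effect sizes (`effect_sizes`): `bp_alpha` and `entropy` are standardized
#' shifts (units of the within-class SD of log10 alpha power and of the
#' broadband-mix logit, respectively) between outcome classes; `paf_hz` is the
#' peak-alpha-frequency shift of cases in Hz.
#'
#' @param n_patients Number of patients (one recording each).
#' @param prevalence_recurrence Probability of one-year seizure recurrence
#'   (default 0.24, the scale reported for routine-EEG cohorts).
#' @param duration_s Recording duration in seconds (default 300).
#' @param n_channels Number of channels (default 19; taken from the start of
#'   the 10-20 label list).
#' @param sampling_rate Sampling rate in Hz (default 200).
#' @param effect_sizes Named numeric vector with entries `bp_alpha`, `paf_hz`,
#'   `entropy`.
#' @param alpha_center_hz Population mean of the alpha-oscillator peak
#'   frequency (default 10.5 Hz).
#' @param ied_rate_positive,ied_rate_negative IED insertions per minute for
#'   recurrence-positive/-negative recordings.
#' @param artifact_rate High-amplitude artifact transients per minute.
#' @param annotation_schedule List: `montage_interval_s`, `hv_start_s`,
#'   `hv_duration_s`, `photic_start_s`, `photic_freqs`, `photic_dur_s`,
#'   `eye_interval_s`. Any entry may be `NULL` to disable that event family.
#' @param survival List: `baseline_hazard_week` (exponential hazard per week),
#'   `log_hr_risk` (log-hazard coefficient on the latent risk),
#'   `followup_min_weeks`, `followup_max_weeks` (uniform follow-up).
#' @param train_fraction Fraction of patients labelled `train` in
#'   `cohort_split` (the rest form the temporally shifted test split).
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 60L,
                       prevalence_recurrence = 0.24,
                       duration_s = 300,
                       n_channels = 19L,
                       sampling_rate = 200,
                       effect_sizes = c(bp_alpha = 0.5, paf_hz = -0.5, entropy = 0.3),
                       alpha_center_hz = 10.5,
                       ied_rate_positive = 0.4,
                       ied_rate_negative = 0.05,
                       artifact_rate = 1,
                       annotation_schedule = list(
                         montage_interval_s = 150,
                         hv_start_s = 60, hv_duration_s = 90,
                         photic_start_s = 160, photic_freqs = seq(4, 22, by = 2),
                         photic_dur_s = 10,
                         eye_interval_s = 60),
                       survival = list(baseline_hazard_week = 0.006,
                                       log_hr_risk = 0.8,
                                       followup_min_weeks = 26,
                                       followup_max_weeks = 156),
                       train_fraction = 0.7,
                       seed = 1L) {
  chk <- function(ok, field) if (!ok) stop(sprintf("invalid config field: %s", field))
  chk(is.numeric(n_patients) && n_patients >= 0, "n_patients")
  chk(prevalence_recurrence >= 0 && prevalence_recurrence <= 1, "prevalence_recurrence")
  chk(duration_s > 0, "duration_s")
  chk(n_channels >= 1 && n_channels <= 19, "n_channels")
  chk(sampling_rate > 0, "sampling_rate")
  chk(all(c("bp_alpha", "paf_hz", "entropy") %in% names(effect_sizes)), "effect_sizes")
  chk(ied_rate_positive >= 0 && ied_rate_negative >= 0, "ied_rate_positive/negative")
  chk(artifact_rate >= 0, "artifact_rate")
  chk(survival$baseline_hazard_week > 0, "survival$baseline_hazard_week")
  chk(survival$followup_min_weeks >= 0 &&
        survival$followup_max_weeks >= survival$followup_min_weeks, "survival$followup")
  chk(train_fraction >= 0 && train_fraction <= 1, "train_fraction")
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_recurrence = prevalence_recurrence,
                 duration_s = duration_s, n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate, effect_sizes = effect_sizes,
                 alpha_center_hz = alpha_center_hz,
                 ied_rate_positive = ied_rate_positive,
                 ied_rate_negative = ied_rate_negative,
                 artifact_rate = artifact_rate,
                 annotation_schedule = annotation_schedule,
                 survival = survival, train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Build the annotation table for one recording from the configured schedule;
# errors when a scheduled event would not leave room for a 10-s epoch.
.schedule_annotations <- function(config, epoch_len_s = 10) {
  s <- config$annotation_schedule
  dur <- config$duration_s
  ann <- empty_annotations()
  add <- function(onset, duration, label) {
    rbind(ann, data.frame(onset_s = onset, duration_s = duration, label = label,
                          stringsAsFactors = FALSE))
  }
  if (!is.null(s$montage_interval_s) && s$montage_interval_s + epoch_len_s <= dur) {
    t <- seq(s$montage_interval_s, dur, by = s$montage_interval_s)
    t <- t[t + epoch_len_s <= dur]
    for (tt in t) ann <- add(tt, 0, "montage_change")
  }
  if (!is.null(s$hv_start_s)) {
    if (s$hv_start_s + s$hv_duration_s + epoch_len_s > dur) {
      stop("annotation schedule exceeds the recording duration (hyperventilation)")
    }
    ann <- add(s$hv_start_s, s$hv_duration_s, "hyperventilation")
  }
  if (!is.null(s$photic_start_s)) {
    t <- s$photic_start_s + (seq_along(s$photic_freqs) - 1) * s$photic_dur_s
    if (any(t + epoch_len_s > dur)) {
      stop("annotation schedule exceeds the recording duration (photic)")
    }
    for (i in seq_along(t)) {
      ann <- add(t[i], s$photic_dur_s, sprintf("photic_%gHz", s$photic_freqs[i]))
    }
  }
  if (!is.null(s$eye_interval_s)) {
    t <- seq(s$eye_interval_s, dur - epoch_len_s, by = s$eye_interval_s)
    lab <- rep(c("eye_close", "eye_open"), length.out = length(t))
    for (i in seq_along(t)) ann <- add(t[i], 0, lab[i])
  }
  ann[order(ann$onset_s), , drop = FALSE]
}

# FFT-shaped Gaussian noise with a given one-sided amplitude-shaping function.
.shaped_noise <- function(n, fs, shape_fn) {
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]  # mirror to [0, fs/2]
  amp <- shape_fn(f)
  amp[1] <- 0
  z <- stats::fft(stats::rnorm(n))
  x <- Re(stats::fft(z * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate one annotated EEG recording
#'
#' Background model per channel: pink (1/f) noise, a narrowband alpha
#' oscillator (Gaussian spectral bump whose center frequency and log-power are
#' shifted by the configured effects times the patient's latent risk, weighted
#' toward posterior channels), and a broadband mixture of AR(1) and white
#' noise whose mixing fraction carries the entropy effect. IED-like
#' spike-and-slow-wave templates are inserted at a class-dependent rate with
#' focal spatial weighting; artifacts are high-amplitude boxcar transients.
#' Activation-procedure annotations follow the configured schedule (the
#' physiological responses to activation are not modelled).
#'
#' @param profile One row of the cohort table (needs `latent_risk`,
#'   `outcome_recurrence_1y`, `eeg_id`, `patient_id`).
#' @param config A [sim_config()].
#' @param seed Integer seed for this recording.
#' @return An [new_recording()] object, microvolts, as-recorded reference.
#' @export
simulate_recording <- function(profile, config, seed = config$seed) {
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration_s * fs))
  nch <- config$n_channels
  labels <- channels_1020()[seq_len(nch)]
  ann <- .schedule_annotations(config)
  risk <- profile$latent_risk
  es <- config$effect_sizes

  .with_seed(seed, {
    # recording-level draws
    paf_center <- config$alpha_center_hz + es[["paf_hz"]] * risk +
      stats::rnorm(1, 0, 0.2)
    paf_center <- min(max(paf_center, 8.2), 12.4)
    log10_alpha_amp <- log10(12) + 0.5 * 0.3 * (es[["bp_alpha"]] * risk + stats::rnorm(1))
    w_white <- stats::plogis(0.6 * (es[["entropy"]] * risk + stats::rnorm(1)))

    alpha_w <- ifelse(grepl("^(O|P)", labels), 1,
                      ifelse(grepl("^(C|T)", labels), 0.6, 0.4))
    sig <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      pink <- .shaped_noise(n, fs, function(f) ifelse(f > 0.5, 1 / sqrt(f), 0)) * 6
      alpha <- .shaped_noise(n, fs, function(f) exp(-(f - paf_center)^2 / (2 * 0.25^2))) *
        (10^log10_alpha_amp) * alpha_w[ch]
      ar <- as.numeric(stats::arima.sim(list(ar = 0.95), n,
                                        innov = stats::rnorm(n)))
      ar <- ar / stats::sd(ar)
      broad <- (sqrt(1 - w_white) * ar + sqrt(w_white) * stats::rnorm(n)) * 6
      sig[ch, ] <- pink + alpha + broad
    }
    bg_sd <- stats::sd(as.numeric(sig))

    # IED-like spike (70 ms triangle) + slow wave (300 ms half-sine)
    ied_rate <- if (isTRUE(profile$outcome_recurrence_1y)) config$ied_rate_positive
                else config$ied_rate_negative
    n_ied <- stats::rpois(1, ied_rate * config$duration_s / 60)
    if (n_ied > 0 && nch >= 2) {
      pos <- electrode_positions(labels)
      spike_n <- round(0.070 * fs); wave_n <- round(0.300 * fs)
      tmpl <- c(3 * bg_sd * (1 - abs(seq(-1, 1, length.out = spike_n))),
                2 * bg_sd * sin(seq(0, pi, length.out = wave_n)))
      for (k in seq_len(n_ied)) {
        t0 <- sample.int(n - length(tmpl), 1)
        center <- sample.int(nch, 1)
        d <- sqrt(rowSums(sweep(pos, 2, pos[center, ])^2))
        wgt <- numeric(nch)
        near <- order(d)[1:min(5, nch)]  # center + 4 nearest neighbors
        wgt[near] <- c(1, rep(0.5, length(near) - 1))
        idx <- t0:(t0 + length(tmpl) - 1L)
        sig[, idx] <- sig[, idx] + outer(wgt, tmpl)
      }
    }

    # boxcar artifacts, 10x SD, 0.5-2 s, on 1-3 random channels
    n_art <- stats::rpois(1, config$artifact_rate * config$duration_s / 60)
    if (n_art > 0) {
      for (k in seq_len(n_art)) {
        len <- round(stats::runif(1, 0.5, 2) * fs)
        t0 <- sample.int(n - len, 1)
        chs <- sample.int(nch, sample.int(min(3, nch), 1))
        sig[chs, t0:(t0 + len - 1L)] <- sig[chs, t0:(t0 + len - 1L)] + 10 * bg_sd
      }
    }

    new_recording(signal = sig, sampling_rate = fs, channel_labels = labels,
                  annotations = ann, eeg_id = profile$eeg_id,
                  patient_id = profile$patient_id, reference = "as-recorded")
  })
}

#' Simulate censored time-to-seizure outcomes
#'
#' Event times are exponential with hazard `lambda * exp(beta * risk)`;
#' censoring happens at an independently drawn uniform follow-up. The one-year
#' label is `event_observed & time_to_event_weeks <= 52`.
#'
#' @param latent_risk Numeric vector of per-patient risks.
#' @param survival_params List as in [sim_config()]'s `survival` entry.
#' @param seed Integer seed.
#' @return Data frame with `time_to_event_weeks`, `event_observed`,
#'   `followup_weeks`, `outcome_recurrence_1y`.
#' @export
simulate_outcomes <- function(latent_risk, survival_params, seed = 1L) {
  lam <- survival_params$baseline_hazard_week
  if (lam <= 0) stop("baseline hazard must be positive")
  beta <- survival_params$log_hr_risk
  .with_seed(seed, {
    n <- length(latent_risk)
    rate <- lam * exp(beta * latent_risk)
    t_event <- stats::rexp(n, rate)
    fup <- stats::runif(n, survival_params$followup_min_weeks,
                        survival_params$followup_max_weeks)
    event <- t_event <= fup
    tt <- pmin(t_event, fup)
    data.frame(time_to_event_weeks = tt, event_observed = event,
               followup_weeks = fup,
               outcome_recurrence_1y = event & tt <= 52)
  })
}

# Conditional survival draw given the one-year label: exponential with hazard
# lambda*exp(beta*risk), truncated so that the derived label matches y.
.outcomes_given_label <- function(y, risk, sp) {
  n <- length(y)
  rate <- sp$baseline_hazard_week * exp(sp$log_hr_risk * risk)
  fup <- stats::runif(n, sp$followup_min_weeks, sp$followup_max_weeks)
  horizon <- pmin(52, fup)
  u <- stats::runif(n)
  t_event <- numeric(n)
  # cases: T | T <= horizon ; controls: T | T > horizon (memoryless shift)
  t_event[y] <- -log(1 - u[y] * (1 - exp(-rate[y] * horizon[y]))) / rate[y]
  t_event[!y] <- horizon[!y] + stats::rexp(sum(!y), rate[!y])
  event <- t_event <= fup
  tt <- pmin(t_event, fup)
  data.frame(time_to_event_weeks = tt, event_observed = event,
             followup_weeks = fup, outcome_recurrence_1y = event & tt <= 52)
}

#' Simulate a full synthetic cohort
#'
#' Draws the one-year recurrence label at the configured prevalence, a latent
#' risk coupling the EEG effects to the survival model, clinical covariates
#' with class-dependent frequencies, censored event times consistent with the
#' label, and one annotated recording per patient.
#'
#' @param config A [sim_config()].
#' @param recordings If `FALSE`, skip signal generation and return only the
#'   cohort table (useful for survival-only analyses).
#' @return List with `cohort` (data.frame, one row per recording) and
#'   `recordings` (named list of [new_recording()] objects, or `NULL`).
#' @export
simulate_cohort <- function(config, recordings = TRUE) {
  n <- config$n_patients
  if (n == 0L) {
    return(list(cohort = .empty_cohort(), recordings = if (recordings) list() else NULL))
  }
  cohort <- .with_seed(config$seed, {
    y <- stats::runif(n) < config$prevalence_recurrence
    risk <- y + stats::rnorm(n, 0, 0.2)
    surv <- .outcomes_given_label(y, risk, config$survival)
    ied <- ifelse(stats::runif(n) < ifelse(y, 0.35, 0.13), "present",
                  ifelse(stats::runif(n) < 0.08, "uncertain", "absent"))
    ep_type <- ifelse(y, sample(c("focal", "generalized", "unknown"), n, TRUE,
                                prob = c(0.65, 0.30, 0.05)),
                      sample(c("focal", "generalized", "none", "unknown"), n, TRUE,
                             prob = c(0.30, 0.12, 0.55, 0.03)))
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      eeg_id = sprintf("E%04d", seq_len(n)),
      cohort_split = ifelse(seq_len(n) <= round(config$train_fraction * n), "train", "test"),
      age = pmin(pmax(round(stats::rnorm(n, 48, 18)), 18), 90),
      sex = sample(c("F", "M"), n, replace = TRUE),
      asm_count = ifelse(y, stats::rpois(n, 1.6), stats::rpois(n, 0.7)),
      ied_status = ied,
      focal_lesion = stats::runif(n) < ifelse(y, 0.40, 0.34),
      slowing = stats::runif(n) < ifelse(y, 0.28, 0.26),
      epilepsy_type = ep_type,
      outcome_recurrence_1y = y,
      time_to_event_weeks = surv$time_to_event_weeks,
      event_observed = surv$event_observed,
      followup_weeks = surv$followup_weeks,
      latent_risk = risk,
      stringsAsFactors = FALSE)
  })
  recs <- NULL
  if (recordings) {
    recs <- lapply(seq_len(n), function(i) {
      simulate_recording(cohort[i, ], config, seed = .child_seed(config$seed, i))
    })
    names(recs) <- cohort$eeg_id
  }
  list(cohort = cohort, recordings = recs)
}

.empty_cohort <- function() {
  data.frame(patient_id = character(0), eeg_id = character(0),
             cohort_split = character(0), age = numeric(0), sex = character(0),
             asm_count = integer(0), ied_status = character(0),
             focal_lesion = logical(0), slowing = logical(0),
             epilepsy_type = character(0), outcome_recurrence_1y = logical(0),
             time_to_event_weeks = numeric(0), event_observed = logical(0),
             followup_weeks = numeric(0), latent_risk = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate fractional Gaussian noise (Davies-Harte)
#'
#' Exact circulant-embedding simulation of fGn with Hurst exponent `H`; used
#' to validate the rescaled-range estimator.
#'
#' @param n Series length.
#' @param H Hurst exponent in (0, 1).
#' @param seed Integer seed.
#' @return Numeric series of length `n`.
#' @export
simulate_fgn <- function(n, H, seed = 1L) {
  stopifnot(H > 0, H < 1)
  m <- 2L * n
  k <- 0:(n)
  gamma_k <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  cvec <- c(gamma_k, rev(gamma_k[2:n]))
  lambda <- Re(stats::fft(cvec))
  lambda[lambda < 0] <- 0  # numerical guard
  .with_seed(seed, {
    z <- stats::rnorm(m) + 1i * stats::rnorm(m)
    x <- Re(stats::fft(sqrt(lambda / (2 * m)) * z, inverse = FALSE))
    x[seq_len(n)] * sqrt(2)
  })
}
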