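# Naive quadratic-time reference implementations used as independent oracles.
# Deliberately written in plain R, directly from the defining formulas, with
# no shared code with the package kernels.

oracle_embed <- function(x, m, tau) {
  M <- length(x) - (m - 1) * tau
  t(vapply(seq_len(M), function(i) x[i + (0:(m - 1)) * tau], numeric(m)))
}

oracle_sampen <- function(x, m, r, tau) {
  N <- length(x)
  M <- N - m * tau  # shared template range for orders m and m+1
  em <- oracle_embed(x, m, tau)[seq_len(M), , drop = FALSE]
  em1 <- oracle_embed(x, m + 1, tau)[seq_len(M), , drop = FALSE]
  A <- 0; B <- 0
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      if (max(abs(em[i, ] - em[j, ])) <= r) {
        B <- B + 1
        if (max(abs(em1[i, ] - em1[j, ])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_apen <- function(x, m, r, tau) {
  phi <- function(mm) {
    em <- oracle_embed(x, mm, tau)
    M <- nrow(em)
    cnt <- vapply(seq_len(M), function(i) {
      sum(vapply(seq_len(M), function(j) {
        max(abs(em[i, ] - em[j, ])) <= r
      }, logical(1)))
    }, numeric(1))
    mean(log(cnt / M))
  }
  phi(m) - phi(m + 1)
}

oracle_fuzzen <- function(x, m, r, n_exp, tau) {
  N <- length(x)
  M <- N - m * tau
  phi <- function(mm) {
    em <- oracle_embed(x, mm, tau)[seq_len(M), , drop = FALSE]
    em <- em - rowMeans(em)
    tot <- 0
    for (i in seq_len(M - 1)) {
      for (j in (i + 1):M) {
        d <- max(abs(em[i, ] - em[j, ]))
        tot <- tot + exp(-(d / r)^n_exp)
      }
    }
    2 * tot / (M * (M - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

oracle_permen <- function(x, k, tau) {
  M <- length(x) - (k - 1) * tau
  pats <- vapply(seq_len(M), function(i) {
    paste(order(x[i + (0:(k - 1)) * tau]), collapse = "")
  }, "")
  p <- table(pats) / M
  -sum(p * log(p)) / log(factorial(k))
}

# Pair-counting AUC with ties counted one half.
oracle_auc <- function(scores, labels) {
  cases <- scores[as.logical(labels)]
  controls <- scores[!as.logical(labels)]
  mean(outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b)))
}

# A bare epoch object around a data matrix (for marker-level tests).
make_epoch <- function(data, labels = channels_1020()[seq_len(nrow(data))],
                       eeg_id = "E1", epoch_index = 1L) {
  list(eeg_id = eeg_id, patient_id = paste0("pat_", eeg_id),
       epoch_index = epoch_index, onset_s = 0, condition = "montage_change",
       channel_labels = labels, data = data,
       bad_channel_mask = rep(FALSE, nrow(data)),
       interpolated_channels = character(0))
}

# Epoch-level synthetic feature matrix with a few informative columns.
make_sim_fm <- function(n_pat = 40, n_ep = 3, p = 60, d = 1.2, prev = 0.4,
                        n_inform = 5, seed = 1) {
  set.seed(seed)
  pat <- rep(sprintf("P%03d", seq_len(n_pat)), each = n_ep)
  eeg <- rep(sprintf("E%03d", seq_len(n_pat)), each = n_ep)
  y <- rep(stats::runif(n_pat) < prev, each = n_ep)
  x <- matrix(stats::rnorm(n_pat * n_ep * p), ncol = p)
  if (n_inform > 0) x[, seq_len(n_inform)] <- x[, seq_len(n_inform)] + y * d
  colnames(x) <- paste0("f", seq_len(p))
  structure(list(x = x, eeg_id = eeg, patient_id = pat, y = y,
                 marker = rep_len(c("BP", "LL", "SampEn"), p)),
            class = "feature_matrix")
}

# Cohort-shaped epoch-level feature matrix with the full marker layout
# (channel x marker x band-or-level columns) and a standardized class shift
# planted in exactly one marker family.
make_marker_layout_fm <- function(n_pat, n_ep, n_ch, inject_marker, d,
                                  prev = 0.4, seed = 1) {
  set.seed(seed)
  chs <- channels_1020()[seq_len(n_ch)]
  mk <- c(rep("BP", 10), "PAF", rep(c("HE", "LL", "CD", "ApEn", "SampEn",
                                      "FuzzEn", "PermEn", "SpecEn"), each = 6))
  sub <- c(band_scheme()$name, "alpha",
           rep(paste0("L", 1:6), times = 8))
  cols <- as.vector(outer(paste(mk, sub, sep = "."), chs,
                          function(a, b) paste(b, a, sep = ".")))
  marker <- rep(mk, times = n_ch)
  n_row <- n_pat * n_ep
  pat <- rep(sprintf("P%03d", seq_len(n_pat)), each = n_ep)
  y_pat <- stats::runif(n_pat) < prev
  y <- rep(y_pat, each = n_ep)
  x <- matrix(stats::rnorm(n_row * length(cols)), n_row, length(cols),
              dimnames = list(NULL, cols))
  inj <- which(marker == inject_marker)
  x[, inj] <- x[, inj] + d * y
  structure(list(x = x, eeg_id = pat, patient_id = pat, y = y, marker = marker),
            class = "feature_matrix")
}

# Sparse-schedule simulation config used by integration-style tests: three
# montage-change epochs per recording, no artifacts.
sparse_sim_config <- function(n_patients, seed,
                              effect_sizes = c(bp_alpha = 1.5, paf_hz = -0.3,
                                               entropy = 1.5),
                              n_channels = 19L, prevalence = 0.4,
                              alpha_center_hz = 10.5) {
  sim_config(n_patients = n_patients, prevalence_recurrence = prevalence,
             duration_s = 100, n_channels = n_channels,
             effect_sizes = effect_sizes, alpha_center_hz = alpha_center_hz,
             artifact_rate = 0,
             ied_rate_positive = 0, ied_rate_negative = 0,
             annotation_schedule = list(montage_interval_s = 30,
                                        hv_start_s = NULL, hv_duration_s = NULL,
                                        photic_start_s = NULL,
                                        photic_freqs = NULL, photic_dur_s = NULL,
                                        eye_interval_s = NULL),
             seed = seed)
}

# Preprocess + extract features for a simulated cohort (no artifact repair:
# these cohorts are generated artifact-free). `channels` restricts marker
# extraction to a channel subset.
extract_cohort_features <- function(sim, markers = marker_names(),
                                    channels = NULL) {
  epochs <- list()
  for (id in sim$cohort$eeg_id) {
    rec <- to_average_reference(filter_recording(sim$recordings[[id]]))
    eps <- extract_epochs(rec)
    if (!is.null(channels)) {
      eps <- lapply(eps, function(ep) {
        sel <- match(channels, ep$channel_labels)
        ep$data <- ep$data[sel, , drop = FALSE]
        ep$channel_labels <- ep$channel_labels[sel]
        ep$bad_channel_mask <- ep$bad_channel_mask[sel]
        ep
      })
    }
    epochs <- c(epochs, eps)
  }
  tensor <- extract_marker_tensor(epochs, sim$recordings[[1]]$sampling_rate,
                                  markers = markers)
  build_feature_matrix(tensor, sim$cohort)
}
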