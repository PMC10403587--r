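# Preprocessing: filtering, average reference, epoching, artifact repair

#' High-pass and notch filter a recording
#'
#' Zero-phase Hamming-window FIR filtering per channel: high-pass at
#' `hp_cutoff_hz` (transition bandwidth 0.75 Hz) followed by a band-stop notch
#' at `notch_hz` (2 Hz wide). Signal length is preserved.
#'
#' @param recording An [new_recording()] object.
#' @param hp_cutoff_hz High-pass cutoff in Hz (default 0.75).
#' @param notch_hz Notch center frequency in Hz (default 60); `NULL` disables
#'   the notch.
#' @return The filtered recording.
#' @export
filter_recording <- function(recording, hp_cutoff_hz = 0.75, notch_hz = 60) {
  fs <- recording$sampling_rate
  if (hp_cutoff_hz >= fs / 2) stop("high-pass cutoff must be below the Nyquist frequency")
  if (!is.null(notch_hz) && notch_hz >= fs / 2) stop("notch frequency must be below the Nyquist frequency")
  ord_hp <- ceiling(3.3 * fs / 0.75)
  if (ord_hp %% 2L == 1L) ord_hp <- ord_hp + 1L
  h_hp <- as.numeric(signal::fir1(ord_hp, hp_cutoff_hz / (fs / 2), type = "high"))
  h_notch <- NULL
  if (!is.null(notch_hz)) {
    ord_n <- ceiling(3.3 * fs / 2)
    if (ord_n %% 2L == 1L) ord_n <- ord_n + 1L
    h_notch <- as.numeric(signal::fir1(ord_n, c(notch_hz - 1, notch_hz + 1) / (fs / 2),
                                       type = "stop"))
  }
  for (ch in seq_len(nrow(recording$signal))) {
    x <- .fir_zerophase(recording$signal[ch, ], h_hp)
    if (!is.null(h_notch)) x <- .fir_zerophase(x, h_notch)
    recording$signal[ch, ] <- x
  }
  recording
}

#' Re-reference a recording to the common average
#'
#' Subtracts the across-channel mean at every sample, so channel sums are zero
#' everywhere. Idempotent.
#'
#' @param recording An [new_recording()] object with >= 2 channels.
#' @return The average-referenced recording (`reference = "average"`).
#' @export
to_average_reference <- function(recording) {
  if (nrow(recording$signal) < 2L) stop("average reference needs >= 2 channels")
  recording$signal <- sweep(recording$signal, 2, colMeans(recording$signal))
  recording$reference <- "average"
  recording
}

.new_epoch <- function(rec, onset_s, condition, epoch_index, epoch_len_s, fs) {
  i0 <- round(onset_s * fs) + 1L
  n <- as.integer(epoch_len_s * fs)
  list(eeg_id = rec$eeg_id, patient_id = rec$patient_id,
       epoch_index = epoch_index, onset_s = onset_s, condition = condition,
       channel_labels = rec$channel_labels,
       data = rec$signal[, i0:(i0 + n - 1L), drop = FALSE],
       bad_channel_mask = rep(FALSE, nrow(rec$signal)),
       interpolated_channels = character(0))
}

#' Extract 10-second epochs at annotation-driven time points
#'
#' One epoch starts at: every montage change; offsets 0, 15, 30, ... s within
#' the hyperventilation window; offsets 0, 15, ... s within the 120 s
#' following hyperventilation; every photic stimulation annotation; and every
#' eye opening/closure. Epochs that would run past the end of the recording
#' are skipped. Annotation labels are matched by prefix: `montage_change`,
#' `hyperventilation` (with its duration), `photic`, `eye_open`/`eye_close`.
#'
#' @param recording A filtered, average-referenced recording.
#' @param epoch_len_s Epoch length in seconds (default 10).
#' @return List of epochs (possibly empty, with a warning when the recording
#'   has no usable annotations).
#' @export
extract_epochs <- function(recording, epoch_len_s = 10) {
  ann <- recording$annotations
  fs <- recording$sampling_rate
  dur <- ncol(recording$signal) / fs
  onsets <- numeric(0); conds <- character(0)
  add <- function(t, cond) {
    onsets <<- c(onsets, t); conds <<- c(conds, cond)
  }
  if (nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      lab <- ann$label[i]; t0 <- ann$onset_s[i]
      if (startsWith(lab, "montage_change")) {
        add(t0, "montage_change")
      } else if (startsWith(lab, "hyperventilation")) {
        D <- ann$duration_s[i]
        off <- seq(0, D, by = 15)
        off <- off[off <= D - epoch_len_s]
        for (o in off) add(t0 + o, "hyperventilation")
        post <- seq(0, 120 - epoch_len_s, by = 15)
        for (o in post) add(t0 + D + o, "post_hyperventilation")
      } else if (startsWith(lab, "photic")) {
        add(t0, "photic")
      } else if (startsWith(lab, "eye")) {
        add(t0, "eye_event")
      }
    }
  }
  keep <- onsets + epoch_len_s <= dur + 1e-9
  onsets <- onsets[keep]; conds <- conds[keep]
  if (!length(onsets)) {
    warning(sprintf("recording %s: no epochs extracted (no usable annotations)", recording$eeg_id))
    return(list())
  }
  ord <- order(onsets)
  mapply(function(t, cond, idx) .new_epoch(recording, t, cond, idx, epoch_len_s, fs),
         onsets[ord], conds[ord], seq_along(ord), SIMPLIFY = FALSE)
}

.ptp <- function(x) max(x) - min(x)

#' Fit per-channel peak-to-peak rejection thresholds by cross-validation
#'
#' For each channel, candidate thresholds are scored by k-fold CV: on each
#' fold, the mean signal of the retained (peak-to-peak <= threshold) training
#' epochs is compared by RMSE to the pointwise median signal of the validation
#' epochs; the candidate minimizing the mean loss is chosen (smallest
#' candidate on ties). By default the candidate grid is 40 log-spaced values
#' between the 10th and 99.9th percentiles of that channel's observed
#' peak-to-peak values.
#'
#' @param epochs List of epochs.
#' @param k_folds Number of CV folds (default 5).
#' @param candidate_grid Optional shared numeric grid of thresholds (uV).
#' @param seed Seed for the fold shuffle.
#' @return List of class `threshold_map` with `thresholds` (named per channel)
#'   and `loss` (channels x candidates matrix).
#' @export
fit_rejection_thresholds <- function(epochs, k_folds = 5L, candidate_grid = NULL,
                                     seed = 1L) {
  n_ep <- length(epochs)
  if (n_ep < k_folds) stop("need at least k_folds epochs")
  labels <- epochs[[1]]$channel_labels
  nch <- length(labels)
  ptp <- vapply(epochs, function(ep) apply(ep$data, 1, .ptp), numeric(nch))
  ptp <- matrix(ptp, nrow = nch)  # channels x epochs
  fold <- .with_seed(seed, sample(rep_len(seq_len(k_folds), n_ep)))
  thresholds <- numeric(nch)
  grids <- vector("list", nch)
  losses <- vector("list", nch)
  nsamp <- ncol(epochs[[1]]$data)
  for (ch in seq_len(nch)) {
    grid <- candidate_grid
    if (is.null(grid)) {
      qs <- stats::quantile(ptp[ch, ], c(0.10, 0.999), names = FALSE)
      qs[qs <= 0] <- 1e-6
      grid <- exp(seq(log(qs[1]), log(max(qs[2], qs[1] * 1.001)), length.out = 40))
    }
    grid <- sort(grid)
    E <- vapply(epochs, function(ep) ep$data[ch, ], numeric(nsamp))
    fold_data <- lapply(seq_len(k_folds), function(f) {
      va <- which(fold == f)
      if (!length(va)) return(NULL)
      list(med = cpp_row_median(E[, va, drop = FALSE]), tr = which(fold != f))
    })
    loss <- vapply(grid, function(thr) {
      fold_loss <- vapply(fold_data, function(fd) {
        if (is.null(fd) || !length(fd$tr)) return(NA_real_)
        keep <- fd$tr[ptp[ch, fd$tr] <= thr]
        if (!length(keep)) return(NA_real_)
        mu <- rowMeans(E[, keep, drop = FALSE])
        sqrt(mean((mu - fd$med)^2))
      }, numeric(1))
      if (all(is.na(fold_loss))) Inf else mean(fold_loss, na.rm = TRUE)
    }, numeric(1))
    if (all(!is.finite(loss))) {
      warning(sprintf("channel %s: all epochs rejected at every candidate; using the largest threshold",
                      labels[ch]))
      thresholds[ch] <- max(grid)
    } else {
      thresholds[ch] <- grid[which.min(loss)]
    }
    grids[[ch]] <- grid
    losses[[ch]] <- loss
  }
  names(thresholds) <- labels
  structure(list(thresholds = thresholds, grids = grids, losses = losses),
            class = "threshold_map")
}

# Perrin-style spherical-spline interpolation matrices (order-4 Legendre
# expansion, 50 terms, regularization 1e-5 on the diagonal).
.gmatrix <- function(cosang, order = 4L, n_terms = 50L) {
  g <- matrix(0, nrow(cosang), ncol(cosang))
  p_prev <- matrix(1, nrow(cosang), ncol(cosang))   # P_0
  p_cur <- cosang                                   # P_1
  for (l in seq_len(n_terms)) {
    g <- g + (2 * l + 1) / (l^order * (l + 1)^order) * p_cur
    p_next <- ((2 * l + 1) * cosang * p_cur - l * p_prev) / (l + 1)
    p_prev <- p_cur; p_cur <- p_next
  }
  g / (4 * pi)
}

#' Spherical-spline interpolation of masked channels
#'
#' @param data Channels x samples matrix.
#' @param labels Channel labels (10-20 names).
#' @param bad Logical mask of channels to re-estimate.
#' @param lambda Diagonal regularization (default 1e-5).
#' @return `data` with the masked rows replaced by the spline estimate.
#' @export
interpolate_channels <- function(data, labels, bad, lambda = 1e-5) {
  if (!any(bad)) return(data)
  if (all(bad)) stop("cannot interpolate: all channels are bad")
  pos <- electrode_positions(labels)
  good <- !bad
  cos_gg <- tcrossprod(pos[good, , drop = FALSE])
  cos_bg <- pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE])
  cos_gg[cos_gg > 1] <- 1; cos_gg[cos_gg < -1] <- -1
  cos_bg[cos_bg > 1] <- 1; cos_bg[cos_bg < -1] <- -1
  G <- .gmatrix(cos_gg) + lambda * diag(sum(good))
  Gb <- .gmatrix(cos_bg)
  ng <- sum(good)
  A <- rbind(cbind(G, rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  w <- sol[seq_len(ng), , drop = FALSE]
  cc <- sol[ng + 1L, ]
  data[bad, ] <- Gb %*% w + matrix(cc, nrow = sum(bad), ncol = ncol(data), byrow = TRUE)
  data
}

#' Mask and repair artifactual channel-epochs
#'
#' Channel-epochs whose peak-to-peak amplitude exceeds the fitted threshold
#' are masked and re-estimated by spherical-spline interpolation from the good
#' channels. Epochs with more than `max_bad_fraction` of channels bad are
#' dropped (with a logged reason).
#'
#' @param epochs List of epochs.
#' @param thresholds A `threshold_map` from [fit_rejection_thresholds()].
#' @param max_bad_fraction Maximum tolerated fraction of bad channels
#'   (default 0.3).
#' @return List of repaired epochs (dropped epochs removed); each epoch's
#'   `bad_channel_mask` and `interpolated_channels` record what was done.
#' @export
repair_epochs <- function(epochs, thresholds, max_bad_fraction = 0.3) {
  thr <- thresholds$thresholds
  out <- list()
  for (ep in epochs) {
    if (!all(ep$channel_labels %in% names(thr))) {
      stop("thresholds were fitted on a different channel set")
    }
    t_ch <- thr[ep$channel_labels]
    bad <- apply(ep$data, 1, .ptp) > t_ch
    if (mean(bad) > max_bad_fraction) {
      message(sprintf("repair_epochs: dropping %s epoch %d (%d/%d channels bad)",
                      ep$eeg_id, ep$epoch_index, sum(bad), length(bad)))
      next
    }
    if (any(bad)) {
      ep$data <- interpolate_channels(ep$data, ep$channel_labels, bad)
      ep$bad_channel_mask <- bad
      ep$interpolated_channels <- ep$channel_labels[bad]
    }
    out[[length(out) + 1L]] <- ep
  }
  out
}
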