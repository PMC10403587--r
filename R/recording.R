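# Recording container

#' Construct an annotated multichannel EEG recording
#'
#' @param signal Channels x samples numeric matrix, in uV.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per row of `signal`.
#' @param annotations Data frame with columns `onset_s`, `duration_s`, `label`
#'   (may have zero rows).
#' @param eeg_id,patient_id Identifiers.
#' @param reference `"as-recorded"` or `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(signal, sampling_rate, channel_labels,
                          annotations = empty_annotations(),
                          eeg_id = "eeg", patient_id = "patient",
                          reference = c("as-recorded", "average")) {
  reference <- match.arg(reference)
  signal <- as.matrix(signal)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (length(channel_labels) != nrow(signal)) {
    stop("channel_labels must match the number of signal rows")
  }
  dur <- ncol(signal) / sampling_rate
  if (nrow(annotations) && (any(annotations$onset_s < 0) || any(annotations$onset_s > dur))) {
    stop("annotation onsets must lie within [0, duration]")
  }
  structure(list(eeg_id = eeg_id, patient_id = patient_id,
                 sampling_rate = sampling_rate,
                 channel_labels = as.character(channel_labels),
                 signal = signal, annotations = annotations,
                 reference = reference),
            class = "eeg_recording")
}

#' Empty annotation table
#' @return Zero-row data.frame with columns `onset_s`, `duration_s`, `label`.
#' @export
empty_annotations <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s> patient %s: %d ch x %.1f s @ %g Hz (%s ref), %d annotations\n",
              x$eeg_id, x$patient_id, nrow(x$signal),
              ncol(x$signal) / x$sampling_rate, x$sampling_rate,
              x$reference, nrow(x$annotations)))
  invisible(x)
}

#' Standard 10-20 channel labels (19 electrodes)
#' @return Character vector of the 19 labels in canonical order.
#' @export
channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
    "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

# Unit-sphere positions of the 19 standard 10-20 electrodes (x toward the
# right ear, y toward the nasion, z up).
.positions_1020 <- local({
  m <- rbind(
    Fp1 = c(-0.329991, 0.940726, -0.078359),
    Fp2 = c(0.330899, 0.940402, -0.078426),
    F7  = c(-0.847627, 0.512395, -0.137767),
    F3  = c(-0.595220, 0.629189, 0.499834),
    Fz  = c(0.003526, 0.660786, 0.750566),
    F4  = c(0.606623, 0.635512, 0.477633),
    F8  = c(0.846108, 0.514567, -0.139004),
    T7  = c(-0.976571, -0.185874, -0.108447),
    C3  = c(-0.706876, -0.125802, 0.696060),
    Cz  = c(0.003983, -0.091066, 0.995837),
    C4  = c(0.720988, -0.117092, 0.682983),
    T8  = c(0.978884, -0.172815, -0.109187),
    P7  = c(-0.701950, -0.711819, -0.024101),
    P3  = c(-0.480960, -0.714878, 0.507570),
    Pz  = c(0.002804, -0.700597, 0.713552),
    P4  = c(0.498504, -0.703519, 0.506513),
    P8  = c(0.706832, -0.706954, -0.024575),
    O1  = c(-0.252329, -0.964666, 0.075827),
    O2  = c(0.256398, -0.963610, 0.075607))
  colnames(m) <- c("x", "y", "z")
  m
})

#' Unit-sphere electrode positions for given 10-20 labels
#' @param labels Channel labels (subset of [channels_1020()]).
#' @return Matrix with one row per label and columns x, y, z.
#' @export
electrode_positions <- function(labels = channels_1020()) {
  unknown <- setdiff(labels, rownames(.positions_1020))
  if (length(unknown)) stop("unknown electrode label(s): ", paste(unknown, collapse = ", "))
  .positions_1020[labels, , drop = FALSE]
}
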