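# EDF/EDF+ reading and writing
#
# Minimal but standard-conformant EDF+C implementation: fixed 256-byte main
# header, 256 bytes per signal, 16-bit little-endian samples, annotations in
# an "EDF Annotations" signal holding time-stamped annotation lists (TALs).

.pad <- function(s, width) {
  s <- substr(s, 1L, width)
  sprintf(sprintf("%%-%ds", width), s)
}

.num_field <- function(x, width) {
  s <- formatC(x, width = 0, format = "g", digits = width - 1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = width), 1L, width)
  .pad(s, width)
}

#' Write a recording to an EDF+ file
#'
#' EDF+C, 1-second data records, physical dimension uV, per-channel physical
#' range set from the observed min/max padded by 5%. Annotations are
#' serialized into an "EDF Annotations" signal (omitted when the recording has
#' none). Samples outside the declared physical range are clipped with a
#' warning reporting the clipped-sample count.
#'
#' @param recording An [new_recording()] object.
#' @param path Output path.
#' @param physical_range Optional `c(min, max)` overriding the per-channel
#'   physical range (default: observed min/max padded 5%). Samples outside it
#'   are clipped.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_range = NULL) {
  rec <- recording
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(rec$signal)
  nsamp <- ncol(rec$signal)
  n_rec <- ceiling(nsamp / fs)
  has_annot <- nrow(rec$annotations) > 0L

  if (!is.null(physical_range)) {
    pmin_v <- rep(physical_range[1], nch)
    pmax_v <- rep(physical_range[2], nch)
  } else {
    # physical range padded 5%; guard degenerate flat channels
    pmin_v <- apply(rec$signal, 1, min)
    pmax_v <- apply(rec$signal, 1, max)
    span <- pmax(pmax_v - pmin_v, 1e-6)
    pmin_v <- pmin_v - 0.05 * span
    pmax_v <- pmax_v + 0.05 * span
  }
  dig_min <- -32768L; dig_max <- 32767L

  # annotation payload per record: timestamp TAL + TALs of annotations whose
  # onset falls inside that record
  ann_records <- NULL
  ann_samples <- 0L
  if (has_annot) {
    nul <- as.raw(0)
    ann_records <- lapply(seq_len(n_rec) - 1L, function(r) {
      tals <- sprintf("+%g\x14\x14", r)  # timekeeping TAL
      sel <- rec$annotations$onset_s >= r & rec$annotations$onset_s < r + 1
      if (any(sel)) {
        a <- rec$annotations[sel, , drop = FALSE]
        tals <- c(tals, sprintf("+%g\x15%g\x14%s\x14",
                                a$onset_s, a$duration_s, a$label))
      }
      do.call(c, lapply(tals, function(s) c(charToRaw(s), nul)))
    })
    max_bytes <- max(vapply(ann_records, length, 1L)) + 2L
    ann_samples <- as.integer(ceiling(max_bytes / 2))
  }

  n_sig <- nch + as.integer(has_annot)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * n_sig
  writeChar(paste0(
    .pad("0", 8),
    .pad(rec$patient_id, 80),
    .pad(paste("Startdate 01-JAN-2000", rec$eeg_id), 80),
    "01.01.00", "00.00.00",
    .num_field(hdr_bytes, 8),
    .pad("EDF+C", 44),
    .num_field(n_rec, 8),
    .num_field(1, 8),
    .num_field(n_sig, 4)), con, eos = NULL)

  lab <- c(.pad(rec$channel_labels, 16), if (has_annot) .pad("EDF Annotations", 16))
  writeChar(paste0(lab, collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(.pad("", 80), n_sig), collapse = ""), con, eos = NULL)  # transducer
  writeChar(paste0(c(rep(.pad("uV", 8), nch), if (has_annot) .pad("", 8)), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(c(vapply(pmin_v, .num_field, "", width = 8),
                     if (has_annot) .num_field(-1, 8)), collapse = ""), con, eos = NULL)
  writeChar(paste0(c(vapply(pmax_v, .num_field, "", width = 8),
                     if (has_annot) .num_field(1, 8)), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(.num_field(dig_min, 8), n_sig), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(.num_field(dig_max, 8), n_sig), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(.pad("HP:0Hz", 80), n_sig), collapse = ""), con, eos = NULL)  # prefilter
  writeChar(paste0(c(rep(.num_field(fs, 8), nch),
                     if (has_annot) .num_field(ann_samples, 8)), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(rep(.pad("", 32), n_sig), collapse = ""), con, eos = NULL)

  scale <- (pmax_v - pmin_v) / (dig_max - dig_min)
  n_clip <- 0L
  for (r in seq_len(n_rec) - 1L) {
    idx <- (r * fs + 1L):min((r + 1L) * fs, nsamp)
    for (ch in seq_len(nch)) {
      x <- rec$signal[ch, idx]
      if (length(idx) < fs) x <- c(x, rep(0, fs - length(idx)))
      clipped <- pmin(pmax(x, pmin_v[ch]), pmax_v[ch])
      n_clip <- n_clip + sum(clipped != x)
      dig <- as.integer(round((clipped - pmin_v[ch]) / scale[ch]) + dig_min)
      writeBin(dig, con, size = 2L, endian = "little")
    }
    if (has_annot) {
      payload <- ann_records[[r + 1L]]
      buf <- raw(ann_samples * 2L)
      buf[seq_along(payload)] <- payload
      writeBin(buf, con)
    }
  }
  if (n_clip > 0L) warning(sprintf("write_edf: clipped %d sample(s) to the physical range", n_clip))
  invisible(path)
}

.read_field <- function(raw_hdr, offset, width) {
  trimws(rawToChar(raw_hdr[(offset + 1L):(offset + width)]))
}

#' Read an EDF/EDF+ file
#'
#' Signals are returned in physical units using the header scaling;
#' annotations are parsed from the "EDF Annotations" signal when present
#' (timekeeping TALs are dropped).
#'
#' @param path Path to an EDF file.
#' @param eeg_id,patient_id Optional identifier overrides; by default the
#'   recording-id and patient-id header fields are used.
#' @return An [new_recording()] object.
#' @export
read_edf <- function(path, eeg_id = NULL, patient_id = NULL) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (shorter than the 256-byte header)")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  n_sig <- suppressWarnings(as.integer(.read_field(hdr, 252L, 4L)))
  if (is.na(n_sig) || n_sig < 1L) stop("malformed EDF header at byte offset 252 (signal count)")
  n_rec <- suppressWarnings(as.integer(.read_field(hdr, 236L, 8L)))
  rec_dur <- suppressWarnings(as.numeric(.read_field(hdr, 244L, 8L)))
  if (is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    stop("malformed EDF header at byte offset 236 (record count/duration)")
  }
  pat_field <- .read_field(hdr, 8L, 80L)
  rec_field <- .read_field(hdr, 88L, 80L)

  sig_hdr <- readBin(con, "raw", 256L * n_sig)
  fld <- function(width, block_offset) {
    vapply(seq_len(n_sig) - 1L, function(i) {
      .read_field(sig_hdr, block_offset * n_sig + i * width, width)
    }, "")
  }
  labels <- fld(16L, 0L)
  # per-signal field blocks: label 16, transducer 80, dim 8, pmin 8, pmax 8,
  # dmin 8, dmax 8, prefilter 80, n_samples 8, reserved 32
  off <- cumsum(c(0L, 16L, 80L, 8L, 8L, 8L, 8L, 8L, 80L, 8L)) * n_sig
  fld_at <- function(k, width) {
    vapply(seq_len(n_sig) - 1L, function(i) {
      .read_field(sig_hdr, off[k] + i * width, width)
    }, "")
  }
  pmin_v <- as.numeric(fld_at(4L, 8L))
  pmax_v <- as.numeric(fld_at(5L, 8L))
  dmin_v <- as.numeric(fld_at(6L, 8L))
  dmax_v <- as.numeric(fld_at(7L, 8L))
  nsamp_v <- as.integer(fld_at(9L, 8L))
  if (any(is.na(nsamp_v)) || any(nsamp_v < 1L)) stop("malformed per-signal sample counts")

  rec_bytes <- sum(nsamp_v) * 2L
  avail <- (sz - (256L + 256L * n_sig)) %/% rec_bytes
  if (avail < n_rec) {
    stop(sprintf("truncated EDF: header advertises %d data records but file holds %d",
                 n_rec, avail))
  }
  is_ann <- labels == "EDF Annotations"
  data <- vector("list", n_sig)
  for (i in seq_len(n_sig)) data[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_sig)) {
      if (is_ann[i]) {
        data[[i]][[r]] <- readBin(con, "raw", nsamp_v[i] * 2L)
      } else {
        data[[i]][[r]] <- readBin(con, "integer", nsamp_v[i], size = 2L,
                                  signed = TRUE, endian = "little")
      }
    }
  }

  sig_idx <- which(!is_ann)
  fs <- nsamp_v[sig_idx[1]] / rec_dur
  signal <- matrix(0, nrow = length(sig_idx), ncol = nsamp_v[sig_idx[1]] * n_rec)
  for (k in seq_along(sig_idx)) {
    i <- sig_idx[k]
    dig <- unlist(data[[i]], use.names = FALSE)
    signal[k, ] <- (dig - dmin_v[i]) * (pmax_v[i] - pmin_v[i]) / (dmax_v[i] - dmin_v[i]) + pmin_v[i]
  }

  annotations <- empty_annotations()
  if (any(is_ann)) {
    payload <- do.call(c, data[[which(is_ann)[1]]])
    nz <- payload != as.raw(0)
    tals <- vapply(split(payload[nz], cumsum(!nz)[nz]), rawToChar, "")
    rows <- list()
    for (tal in tals) {
      if (!nzchar(tal)) next
      parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      if (length(parts) < 2L || !nzchar(parts[2])) next  # timekeeping TAL
      od <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = as.numeric(od[1]),
        duration_s = if (length(od) > 1L) as.numeric(od[2]) else 0,
        label = parts[2], stringsAsFactors = FALSE)
    }
    if (length(rows)) annotations <- do.call(rbind, rows)
  }

  new_recording(signal = signal, sampling_rate = fs,
                channel_labels = labels[sig_idx],
                annotations = annotations,
                eeg_id = eeg_id %||% sub("^Startdate \\S+ ?", "", rec_field),
                patient_id = patient_id %||% pat_field)
}

`%||%` <- function(a, b) if (is.null(a) || !nzchar(a)) b else a
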