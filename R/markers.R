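# Time-domain complexity markers and the marker tensor

#' Hurst exponent by rescaled-range analysis
#'
#' For log-spaced window sizes from `min_window` up to `length(x)/2`, the R/S
#' statistic is averaged over non-overlapping windows and the Hurst exponent
#' is the least-squares slope of `log(R/S)` against `log(window size)`.
#'
#' @param x Numeric series.
#' @param min_window Smallest window size in samples (default 10).
#' @return Hurst exponent estimate, or `NA` for a constant series.
#' @export
hurst_exponent <- function(x, min_window = 10L) {
  n <- length(x)
  if (n < 2L * min_window) {
    stop(sprintf("series too short for R/S analysis: need >= %d samples, got %d",
                 2L * min_window, n))
  }
  if (stats::sd(x) == 0) return(NA_real_)
  sizes <- unique(round(exp(seq(log(min_window), log(n / 2), length.out = 10))))
  rs <- cpp_rs_stat(as.numeric(x), as.integer(sizes))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2L) return(NA_real_)
  lx <- log(sizes[ok]); ly <- log(rs[ok])
  stats::cov(lx, ly) / stats::var(lx)
}

#' Line length
#'
#' Sum of absolute successive differences, a waveform-complexity surrogate.
#'
#' @param x Numeric series (uV).
#' @return Line length in uV.
#' @export
line_length <- function(x) {
  if (length(x) < 2L) stop("line length needs at least 2 samples")
  sum(abs(diff(x)))
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Delay-embeds the series with `(m, tau)`, evaluates the correlation sum
#' C(rho) at `n_radii` log-spaced radii between the 5th and 50th percentile of
#' the pairwise embedded distances, and returns the least-squares slope of
#' `log C` against `log rho` over that scaling region.
#'
#' @param x Numeric series.
#' @param params An [entropy_params()] (uses `m` and `tau`).
#' @param n_radii Number of radii in the scaling region (default 20).
#' @param max_points Cap on the number of embedded templates entering the
#'   correlation sum (evenly strided subset; default 500). Keeps the pairwise
#'   cost bounded on long series.
#' @return Correlation-dimension estimate, or `NA` for degenerate input.
#' @export
correlation_dimension <- function(x, params = entropy_params(), n_radii = 20L,
                                  max_points = 500L) {
  n <- length(x)
  if (n < (params$m - 1L) * params$tau + 50L) return(NA_real_)
  if (stats::sd(x) == 0) return(NA_real_)
  cs <- cpp_corr_sums(x, params$m, params$tau, n_radii, 0.05, 0.50, max_points)
  if (length(cs$radii) < 2L) return(NA_real_)
  keep <- cs$counts > 0
  if (sum(keep) < 2L) return(NA_real_)
  logC <- log(cs$counts[keep] / cs$n_pairs)
  logR <- log(cs$radii[keep])
  stats::cov(logR, logC) / stats::var(logR)
}

#' Names of the ten computational markers
#' @return Character vector of marker names.
#' @export
marker_names <- function() {
  c("BP", "PAF", "HE", "LL", "CD", "ApEn", "SampEn", "FuzzEn", "PermEn", "SpecEn")
}

.level_markers <- c("HE", "LL", "CD", "ApEn", "SampEn", "FuzzEn", "PermEn", "SpecEn")

#' Extract the marker tensor from a list of epochs
#'
#' Computes, for every epoch and channel: log10 band power in the ten bands
#' and the peak alpha frequency on the raw series, plus the Hurst exponent,
#' line length, correlation dimension, and the approximate, sample, fuzzy,
#' permutation and spectral entropies on each of the six sym5 wavelet detail
#' levels. One value per (epoch, channel, marker, band-or-level); degenerate
#' series yield flagged missing values rather than errors.
#'
#' @param epochs List of epochs as returned by [extract_epochs()] /
#'   [repair_epochs()].
#' @param fs Sampling rate in Hz.
#' @param wspec A [wavelet_spec()].
#' @param scheme A [band_scheme()].
#' @param params An [entropy_params()].
#' @param markers Character vector restricting extraction to a subset of
#'   [marker_names()] (default: all ten).
#' @return Long-format data.frame with columns `eeg_id`, `epoch_index`,
#'   `channel`, `marker`, `sub_index`, `value`, `missing`.
#' @export
extract_marker_tensor <- function(epochs, fs, wspec = wavelet_spec(),
                                  scheme = band_scheme(),
                                  params = entropy_params(),
                                  markers = marker_names()) {
  markers <- match.arg(markers, marker_names(), several.ok = TRUE)
  lvl_markers <- intersect(.level_markers, markers)
  rows <- vector("list", length(epochs))
  for (e in seq_along(epochs)) {
    ep <- epochs[[e]]
    nch <- nrow(ep$data)
    per_ch <- vector("list", nch)
    for (ch in seq_len(nch)) {
      x <- ep$data[ch, ]
      nm <- character(0); sub <- character(0); val <- numeric(0)
      if ("BP" %in% markers) {
        bp <- band_power(x, fs, scheme)
        nm <- c(nm, rep("BP", length(bp))); sub <- c(sub, names(bp)); val <- c(val, unname(bp))
      }
      if ("PAF" %in% markers) {
        nm <- c(nm, "PAF"); sub <- c(sub, "alpha")
        val <- c(val, peak_alpha_frequency(x, fs))
      }
      if (length(lvl_markers)) {
        dec <- wavelet_decompose(x, wspec)
        for (l in seq_len(wspec$n_levels)) {
          d <- dec$details[[l]]
          fs_l <- fs / 2^l  # effective rate of the level series
          lv <- paste0("L", l)
          for (mk in lvl_markers) {
            v <- switch(mk,
              HE = if (length(d) >= 20L && stats::sd(d) > 0)
                     hurst_exponent(d) else NA_real_,
              LL = line_length(d),
              CD = correlation_dimension(d, params),
              ApEn = entropy(d, "approximate", params),
              SampEn = entropy(d, "sample", params),
              FuzzEn = entropy(d, "fuzzy", params),
              PermEn = entropy(d, "permutation", params),
              SpecEn = entropy(d, "spectral", params, fs = fs_l))
            nm <- c(nm, mk); sub <- c(sub, lv); val <- c(val, v)
          }
        }
      }
      per_ch[[ch]] <- data.frame(
        eeg_id = ep$eeg_id, epoch_index = ep$epoch_index,
        channel = ep$channel_labels[ch], marker = nm, sub_index = sub,
        value = val, missing = !is.finite(val), stringsAsFactors = FALSE)
    }
    rows[[e]] <- do.call(rbind, per_ch)
  }
  out <- do.call(rbind, rows)
  out$value[out$missing] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Select entropy parameters on calibration recordings
#'
#' For each candidate parameter set, computes the embedded and spectral
#' entropies per epoch and channel (on the raw channel series), and scores the
#' candidate by the ratio of the variance of per-recording means to the mean
#' within-recording variance, averaged over channels and entropy kinds. The
#' argmax is returned; larger scores mean entropies that separate recordings
#' while staying stable within a recording.
#'
#' @param epochs_by_recording List (one element per recording) of epoch lists.
#' @param grid List of [entropy_params()] candidates.
#' @param fs Sampling rate in Hz.
#' @param kinds Entropy kinds entering the score.
#' @return The selected [entropy_params()], with the score table attached as
#'   attribute `"scores"`.
#' @export
select_entropy_params <- function(epochs_by_recording, grid, fs,
                                  kinds = c("approximate", "sample", "fuzzy", "permutation")) {
  if (length(epochs_by_recording) < 2L) stop("need >= 2 recordings")
  if (any(vapply(epochs_by_recording, length, 1L) < 2L)) stop("need >= 2 epochs per recording")
  scores <- vapply(grid, function(par) {
    ratios <- c()
    nch <- nrow(epochs_by_recording[[1]][[1]]$data)
    for (kind in kinds) {
      for (ch in seq_len(nch)) {
        per_rec <- lapply(epochs_by_recording, function(eps) {
          vapply(eps, function(ep) entropy(ep$data[ch, ], kind, par, fs = fs), numeric(1))
        })
        mu <- vapply(per_rec, mean, numeric(1), na.rm = TRUE)
        wv <- vapply(per_rec, stats::var, numeric(1), na.rm = TRUE)
        if (all(is.finite(mu)) && mean(wv, na.rm = TRUE) > 0) {
          ratios <- c(ratios, stats::var(mu) / mean(wv, na.rm = TRUE))
        }
      }
    }
    if (!length(ratios)) NA_real_ else mean(ratios)
  }, numeric(1))
  if (all(!is.finite(scores))) stop("zero within-recording variance for every candidate")
  best <- grid[[which.max(scores)]]
  attr(best, "scores") <- scores
  best
}

#' Multivariate iterative imputation (chained ridge regressions)
#'
#' Missing cells are initialized at column means, then each incomplete column
#' is regressed (ridge, kernel form) on all other columns and its missing
#' cells replaced by the fit, iterating until the largest cell change is below
#' `tol` or `max_iter` sweeps. Fitting statistics come from `x` only; pass the
#' returned object to [impute_apply()] for held-out data.
#'
#' @param x Numeric matrix with `NA`s (no all-missing rows).
#' @param tol Convergence tolerance on the largest cell change (default 1e-3).
#' @param max_iter Maximum sweeps (default 10).
#' @param lambda Ridge penalty (default 1e-3).
#' @return List with the completed `data`, and the fitted `means`, `models`
#'   needed by [impute_apply()]. Class `eeg_imputer`.
#' @export
impute_missing <- function(x, tol = 1e-3, max_iter = 10L, lambda = 1e-3) {
  x <- as.matrix(x)
  if (any(rowSums(!is.na(x)) == 0L)) stop("all-missing rows are not imputable")
  miss <- is.na(x)
  mu <- colMeans(x, na.rm = TRUE)
  all_na_cols <- which(!is.finite(mu))
  if (length(all_na_cols)) {
    warning(sprintf("%d all-missing column(s) filled with 0 after standardization",
                    length(all_na_cols)))
    mu[all_na_cols] <- 0
  }
  xf <- x
  for (j in seq_len(ncol(x))) xf[miss[, j], j] <- mu[j]
  models <- list()
  target_cols <- setdiff(which(colSums(miss) > 0L), all_na_cols)
  if (length(target_cols)) {
    n <- nrow(xf)
    for (it in seq_len(max_iter)) {
      delta <- 0
      # Gram matrix of the current completed data; each column's predictor
      # kernel is a rank-one downdate of it (kernel-form ridge keeps the
      # per-column cost at O(n^2) instead of O(n^2 p)).
      R <- tcrossprod(xf)
      for (j in target_cols) {
        obs <- which(!miss[, j]); ms <- which(miss[, j])
        q <- length(obs)
        yo <- x[obs, j]; y0 <- mean(yo)
        G <- R[obs, obs, drop = FALSE] - tcrossprod(xf[obs, j])
        g1 <- rowSums(G) / q
        gbar <- sum(g1) / q
        Kc <- G - outer(g1, rep(1, q)) - outer(rep(1, q), g1) + gbar
        alpha <- solve(Kc + lambda * diag(q), yo - y0)
        H <- R[ms, obs, drop = FALSE] - outer(xf[ms, j], xf[obs, j])
        Hc <- H - outer(rowSums(H) / q, rep(1, q)) -
          outer(rep(1, length(ms)), g1) + gbar
        pred <- as.numeric(Hc %*% alpha) + y0
        delta <- max(delta, max(abs(pred - xf[ms, j]), 0))
        xf[ms, j] <- pred
        # explicit coefficients for held-out application (cheap mat-vecs)
        cm <- colMeans(xf[obs, -j, drop = FALSE])
        beta <- as.numeric(crossprod(xf[obs, -j, drop = FALSE], alpha)) -
          cm * sum(alpha)
        models[[as.character(j)]] <- list(j = j, beta = beta, cm = cm, y0 = y0)
      }
      if (delta < tol) break
    }
  }
  structure(list(data = xf, means = mu, models = models,
                 all_na_cols = all_na_cols),
            class = "eeg_imputer")
}

#' Apply a fitted imputer to held-out data
#'
#' Uses the training column means and the training ridge fits; no statistics
#' are learned from `newdata`.
#'
#' @param imputer Result of [impute_missing()].
#' @param newdata Numeric matrix with the same columns.
#' @return Completed matrix.
#' @export
impute_apply <- function(imputer, newdata) {
  x <- as.matrix(newdata)
  miss <- is.na(x)
  for (j in seq_len(ncol(x))) x[miss[, j], j] <- imputer$means[j]
  for (md in imputer$models) {
    j <- md$j
    rows <- which(miss[, j])
    if (length(rows)) {
      x[rows, j] <- as.numeric(sweep(x[rows, -j, drop = FALSE], 2, md$cm) %*% md$beta) + md$y0
    }
  }
  x
}
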