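# Multitaper spectral estimation, band power, peak alpha frequency

# Cache for DPSS tapers (keyed by n/nw/k): the tridiagonal eigenproblem at
# n = 2000 costs a few seconds, so solve it once per session.
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computed from the standard symmetric tridiagonal formulation; tapers are
#' returned with unit energy (`colSums(tapers^2) == 1`).
#'
#' @param n Series length.
#' @param nw Time-bandwidth product (default 4).
#' @param k Number of tapers (default 7, i.e. `2*nw - 1`).
#' @return `n x k` matrix of tapers, ordered by decreasing concentration.
#' @export
dpss_tapers <- function(n, nw = 4, k = 7L) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (k >= n) stop("need k < n")
  W <- nw / n
  i <- 0:(n - 1)
  diag_v <- (((n - 1) - 2 * i) / 2)^2 * cos(2 * pi * W)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_v
  A[cbind(1:(n - 1), 2:n)] <- off_v
  A[cbind(2:n, 1:(n - 1))] <- off_v
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  # normalize and fix polarity: symmetric tapers positive mean, antisymmetric
  # tapers positive initial slope
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (tap[2, j] - tap[1, j] < 0) {
      tap[, j] <- -tap[, j]
    }
  }
  .dpss_cache[[key]] <- tap
  tap
}

#' Multitaper power spectral density
#'
#' DPSS multitaper estimate (time-bandwidth 4, 7 tapers by default) of the
#' one-sided PSD. The mean is removed before tapering. Satisfies
#' `sum(psd) * df ~ var(x)`.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @return List with `freq` (Hz, from 0 to Nyquist) and `psd` (power per Hz).
#' @export
multitaper_psd <- function(x, fs, nw = 4, k = 7L) {
  n <- length(x)
  x <- x - mean(x)
  tap <- dpss_tapers(n, nw, k)
  nf <- n %/% 2L + 1L
  X <- stats::mvfft(tap * x)[seq_len(nf), , drop = FALSE]
  psd <- rowSums(Re(X)^2 + Im(X)^2) / (k * fs)
  # one-sided doubling (all bins except DC and, for even n, Nyquist)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2L == 0L) dbl[nf] <- 1
  list(freq = seq(0, fs / 2, length.out = nf), psd = psd * dbl)
}

# Composite Simpson integration on a uniform grid (trapezoid on the final
# interval when the number of intervals is odd).
.simpson <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  if (n == 2L) return(dx * (y[1] + y[2]) / 2)
  m <- if ((n - 1L) %% 2L == 0L) n else n - 1L
  i <- seq(2L, m - 1L)
  w <- ifelse(i %% 2L == 0L, 4, 2)
  s <- dx / 3 * (y[1] + sum(w * y[i]) + y[m])
  if (m < n) s <- s + dx * (y[m] + y[n]) / 2
  s
}

#' Frequency-band scheme
#'
#' The ten-band scheme used throughout: low/high delta (1-2, 2-4 Hz), low/high
#' theta (4-6, 6-8), low/high alpha (8-10, 10-13), low/high beta (13-20,
#' 20-40), low/high gamma (40-75, 75-100).
#'
#' @return A data.frame with columns `name`, `f_low`, `f_high`.
#' @export
band_scheme <- function() {
  data.frame(
    name = c("delta_low", "delta_high", "theta_low", "theta_high",
             "alpha_low", "alpha_high", "beta_low", "beta_high",
             "gamma_low", "gamma_high"),
    f_low = c(1, 2, 4, 6, 8, 10, 13, 20, 40, 75),
    f_high = c(2, 4, 6, 8, 10, 13, 20, 40, 75, 100),
    stringsAsFactors = FALSE
  )
}

#' Band power from the multitaper PSD
#'
#' Integrates the multitaper PSD over each band of `scheme` with Simpson's
#' rule and reports log10 power with a floor of 1e-12 uV^2 (degenerate inputs
#' therefore return -12 in every band). Alternatively (`method =
#' "filtered"`), each band is FIR band-pass filtered first and the variance of
#' the filtered signal is reported on the same log scale.
#'
#' @param x Numeric series (one epoch, one channel), in uV.
#' @param fs Sampling rate in Hz.
#' @param scheme A [band_scheme()] data.frame.
#' @param method `"multitaper"` (default) or `"filtered"`.
#' @return Named numeric vector of log10 band power, one entry per band.
#' @export
band_power <- function(x, fs, scheme = band_scheme(), method = c("multitaper", "filtered")) {
  method <- match.arg(method)
  if (any(scheme$f_high > fs / 2)) {
    stop("band above Nyquist frequency")
  }
  floor_pow <- 1e-12
  out <- numeric(nrow(scheme))
  names(out) <- scheme$name
  if (stats::sd(x) == 0) {
    out[] <- log10(floor_pow)
    return(out)
  }
  if (method == "multitaper") {
    sp <- multitaper_psd(x, fs)
    df <- sp$freq[2] - sp$freq[1]
    for (b in seq_len(nrow(scheme))) {
      sel <- sp$freq >= scheme$f_low[b] & sp$freq < scheme$f_high[b]
      out[b] <- log10(max(.simpson(sp$psd[sel], df), floor_pow))
    }
  } else {
    for (b in seq_len(nrow(scheme))) {
      xb <- fir_bandpass(x, fs, scheme$f_low[b], scheme$f_high[b])
      out[b] <- log10(max(stats::var(xb), floor_pow))
    }
  }
  out
}

#' Peak alpha frequency
#'
#' Band-pass filters to 8-13 Hz (Hamming-window FIR), then returns the
#' frequency of the multitaper-PSD maximum within the band. Exact ties go to
#' the lower frequency.
#'
#' @inheritParams band_power
#' @return Peak frequency in Hz (always inside \[8, 13\]).
#' @export
peak_alpha_frequency <- function(x, fs) {
  if (stats::sd(x) > 0) x <- fir_bandpass(x, fs, 8, 13)
  sp <- multitaper_psd(x, fs)
  sel <- which(sp$freq >= 8 & sp$freq <= 13)
  sp$freq[sel][which.max(sp$psd[sel])]
}

#' Spectral entropy
#'
#' Shannon entropy of the multitaper PSD normalized to a probability
#' distribution, divided by log of the number of frequency bins, giving a
#' value in \[0, 1\]. A constant series returns 0.
#'
#' @inheritParams band_power
#' @return Normalized spectral entropy in \[0, 1\].
#' @export
spectral_entropy <- function(x, fs) {
  if (stats::sd(x) == 0) return(0)
  sp <- multitaper_psd(x, fs)
  p <- sp$psd / sum(sp$psd)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(sp$psd))
}

# Zero-phase FIR filtering helpers ------------------------------------------

# Apply a symmetric (linear-phase) FIR filter with zero overall phase:
# reflect-pad, FFT convolution, compensate the (L-1)/2 group delay.
.fir_zerophase <- function(x, h) {
  L <- length(h)
  half <- (L - 1L) %/% 2L
  n <- length(x)
  pad_l <- x[pmin(pmax(seq(half + 1L, 2L), 1L), n)]
  pad_r <- x[pmin(pmax(seq(n - 1L, n - half), 1L), n)]
  xp <- c(pad_l, x, pad_r)
  m <- length(xp) + L - 1L
  nfft <- stats::nextn(m, 2)
  y <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - length(xp)))) *
                     stats::fft(c(h, numeric(nfft - L))), inverse = TRUE)) / nfft
  y[(2L * half + 1L):(2L * half + n)]
}

#' Zero-phase FIR band-pass filter (Hamming window design)
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param f_low,f_high Band edges in Hz.
#' @param trans_hz Transition bandwidth in Hz (sets the filter order).
#' @return Filtered series, same length as `x`.
#' @export
fir_bandpass <- function(x, fs, f_low, f_high, trans_hz = 2) {
  if (f_high >= fs / 2) f_high <- fs / 2 * 0.999
  ord <- ceiling(3.3 * fs / trans_hz)
  if (ord %% 2L == 1L) ord <- ord + 1L  # even order -> odd length, type I
  h <- signal::fir1(ord, c(f_low, f_high) / (fs / 2), type = "pass")
  .fir_zerophase(x, as.numeric(h))
}
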