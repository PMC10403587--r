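# Discrete wavelet decomposition (sym5, periodized)

# Symlet-5 decomposition filters (orthogonal, 10 taps).
.sym5_lo <- c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
              0.1993975339773936, 0.7234076904024206, 0.6339789634582119,
              0.01660210576452232, -0.17532808990845047, -0.021101834024758855,
              0.019538882735286728)
.sym5_hi <- c(-0.019538882735286728, -0.021101834024758855, 0.17532808990845047,
              0.01660210576452232, -0.6339789634582119, 0.7234076904024206,
              -0.1993975339773936, -0.039134249302383094, -0.029519490925774643,
              0.027333068345077982)

#' Wavelet decomposition specification
#'
#' Sym5 discrete wavelet transform with six decomposition levels. At a 200 Hz
#' sampling rate the detail levels nominally cover 100-50, 50-25, 25-12.5,
#' 12.5-6.25, 6.25-3.125 and 3.125-1.56 Hz.
#'
#' @param wavelet Wavelet name; only `"sym5"` is implemented.
#' @param n_levels Number of detail levels (default 6).
#' @return An object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(wavelet = "sym5", n_levels = 6L) {
  if (!identical(wavelet, "sym5")) stop("only the sym5 wavelet is implemented")
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("n_levels must be >= 1")
  structure(list(wavelet = wavelet, n_levels = n_levels,
                 dec_lo = .sym5_lo, dec_hi = .sym5_hi),
            class = "wavelet_spec")
}

# One periodized analysis step: circular convolution + dyadic downsampling.
# For even input lengths the step is orthogonal (energy preserving); odd
# lengths are padded by repeating the last sample, as in standard
# periodization implementations.
.dwt_step <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  L <- length(lo)
  # y[k] = sum_t h[t] * x[(2k - 1 + t - 1) mod n + 1], k = 1..n/2 with the
  # filter anchored so that perfect reconstruction holds.
  idx <- outer(seq(1L, n, by = 2L), 0:(L - 1L), `+`)  # (n/2) x L start indices
  idx <- (idx - 1L) %% n + 1L
  xm <- matrix(x[idx], nrow = n %/% 2L)
  list(a = as.numeric(xm %*% lo), d = as.numeric(xm %*% hi))
}

#' Discrete wavelet decomposition of a series
#'
#' Periodized pyramid decomposition returning the detail coefficients at each
#' level plus the final approximation. Level `l` nominally covers
#' `[fs/2^(l+1), fs/2^l]` Hz.
#'
#' @param x Numeric series.
#' @param spec A [wavelet_spec()].
#' @return List with `details` (list of length `n_levels`, coarser levels
#'   later) and `approx` (final approximation coefficients).
#' @export
wavelet_decompose <- function(x, spec = wavelet_spec()) {
  min_len <- 2L^spec$n_levels
  if (length(x) < min_len) {
    stop(sprintf("series too short for %d levels: need at least %d samples, got %d",
                 spec$n_levels, min_len, length(x)))
  }
  details <- vector("list", spec$n_levels)
  a <- as.numeric(x)
  for (l in seq_len(spec$n_levels)) {
    st <- .dwt_step(a, spec$dec_lo, spec$dec_hi)
    details[[l]] <- st$d
    a <- st$a
  }
  list(details = details, approx = a)
}
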