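# Entropy estimators (wrappers over the compiled kernels)

#' Entropy parameter set
#'
#' Embedding parameters shared by the embedded entropies and the correlation
#' dimension: embedding dimension `m`, tolerance `r` as a fraction of the
#' series SD, embedding delay `tau` (samples), fuzzy membership exponent `n`,
#' and permutation order `k`. Defaults are the calibrated values m = 3,
#' r = 0.25, tau = 5, n = 2, k = 3.
#'
#' @param m Embedding dimension (>= 1).
#' @param r Tolerance as a fraction of the series SD (> 0).
#' @param tau Embedding delay in samples (>= 1).
#' @param n Fuzzy membership exponent.
#' @param k Permutation order (>= 2).
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(m = 3L, r = 0.25, tau = 5L, n = 2, k = 3L) {
  m <- as.integer(m); tau <- as.integer(tau); k <- as.integer(k)
  if (m < 1L) stop("m must be >= 1")
  if (r <= 0) stop("r must be > 0")
  if (tau < 1L) stop("tau must be >= 1")
  if (k < 2L) stop("k must be >= 2")
  structure(list(m = m, r = r, tau = tau, n = n, k = k),
            class = "entropy_params")
}

#' Entropy of a series
#'
#' Five estimators under one interface:
#' * `approximate` - Pincus ApEn, `phi_m - phi_{m+1}`, self-matches included,
#'   Chebyshev distance, delay-`tau` embedding;
#' * `sample` - Richman-Moorman SampEn, `-log(A/B)`, no self-matches;
#' * `fuzzy` - sample-style with membership `exp(-(d/r_abs)^n)` on
#'   baseline-removed templates;
#' * `permutation` - Shannon entropy of ordinal patterns of order `k`, delay
#'   `tau`, normalized by `log(k!)` (in \[0, 1\]);
#' * `spectral` - normalized Shannon entropy of the multitaper PSD (in
#'   \[0, 1\]; requires `fs`).
#'
#' The tolerance is `r_abs = r * sd(x)`. A constant series returns 0 for every
#' kind; a series shorter than the embedding needs returns `NA` (missing).
#'
#' @param x Numeric series.
#' @param kind One of `"approximate"`, `"sample"`, `"fuzzy"`, `"permutation"`,
#'   `"spectral"`.
#' @param params An [entropy_params()] object.
#' @param fs Sampling rate in Hz (spectral entropy only).
#' @return Entropy value in nats (normalized to \[0, 1\] for permutation and
#'   spectral), or `NA` when undefined.
#' @export
entropy <- function(x, kind = c("approximate", "sample", "fuzzy", "permutation", "spectral"),
                    params = entropy_params(), fs = NULL) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  n <- length(x)
  if (kind == "spectral") {
    if (is.null(fs)) stop("spectral entropy requires fs")
    if (n < 8L) return(NA_real_)
    return(spectral_entropy(x, fs))
  }
  s <- stats::sd(x)
  if (is.na(s)) return(NA_real_)
  if (s == 0) {
    # degenerate rule: all templates match / single ordinal pattern
    return(0)
  }
  if (kind == "permutation") {
    if (n < (params$k - 1L) * params$tau + 1L) return(NA_real_)
    return(cpp_permen(x, params$k, params$tau))
  }
  if (n < params$m * params$tau + 2L) return(NA_real_)
  r_abs <- params$r * s
  switch(kind,
    approximate = cpp_apen(x, params$m, r_abs, params$tau),
    sample = cpp_sampen(x, params$m, r_abs, params$tau),
    fuzzy = cpp_fuzzen(x, params$m, r_abs, params$n, params$tau)
  )
}
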