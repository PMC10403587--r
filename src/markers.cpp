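#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Chebyshev distance between delay-embedded templates starting at i and j,
// over `m` components with spacing `tau`. Early-abandons above `r`.
static inline bool cheb_le(const double* x, int i, int j, int m, int tau, double r) {
  for (int c = 0; c < m; ++c) {
    double d = std::fabs(x[i + c * tau] - x[j + c * tau]);
    if (d > r) return false;
  }
  return true;
}

// Sample entropy (Richman-Moorman): no self-matches, Chebyshev distance,
// delay-tau embedding; template index range shared between orders m and m+1.
// [[Rcpp::export]]
double cpp_sampen(NumericVector x, int m, double r, int tau) {
  const int n = x.size();
  const int M = n - m * tau;  // templates valid for both m and m+1
  if (M < 2) return NA_REAL;
  const double* p = REAL(x);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      if (cheb_le(p, i, j, m, tau, r)) {
        B += 1.0;
        if (std::fabs(p[i + m * tau] - p[j + m * tau]) <= r) A += 1.0;
      }
    }
  }
  if (B == 0.0 || A == 0.0) return NA_REAL;
  return -std::log(A / B);
}

// Approximate entropy (Pincus): self-matches included, phi_m - phi_{m+1}.
static double apen_phi(const double* p, int n, int m, double r, int tau) {
  const int M = n - (m - 1) * tau;
  if (M < 1) return NA_REAL;
  std::vector<int> cnt(M, 1);  // self-match
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      if (cheb_le(p, i, j, m, tau, r)) { ++cnt[i]; ++cnt[j]; }
    }
  }
  double phi = 0.0;
  for (int i = 0; i < M; ++i) phi += std::log((double)cnt[i] / (double)M);
  return phi / (double)M;
}

// [[Rcpp::export]]
double cpp_apen(NumericVector x, int m, double r, int tau) {
  const int n = x.size();
  if (n - m * tau < 1) return NA_REAL;
  const double* p = REAL(x);
  return apen_phi(p, n, m, r, tau) - apen_phi(p, n, m + 1, r, tau);
}

// Fuzzy entropy (Chen et al.): baseline-removed templates, membership
// exp(-(d/r)^nexp), no self-matches; shared index range for orders m, m+1.
// Memberships below exp(-30) are treated as zero (early skip).
static double fuzz_phi(const double* p, int n, int m, double r, double nexp, int tau, int M) {
  // template means
  std::vector<double> mu(M);
  for (int i = 0; i < M; ++i) {
    double s = 0.0;
    for (int c = 0; c < m; ++c) s += p[i + c * tau];
    mu[i] = s / m;
  }
  const double dmax = r * std::pow(30.0, 1.0 / nexp);
  const bool sq = (nexp == 2.0);
  const double inv_r = 1.0 / r;
  double tot = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double d = 0.0;
      for (int c = 0; c < m; ++c) {
        double dd = std::fabs((p[i + c * tau] - mu[i]) - (p[j + c * tau] - mu[j]));
        if (dd > d) d = dd;
        if (d > dmax) break;
      }
      if (d <= dmax) {
        double u = d * inv_r;
        tot += std::exp(sq ? -u * u : -std::pow(u, nexp));
      }
    }
  }
  return 2.0 * tot / ((double)M * (M - 1));
}

// [[Rcpp::export]]
double cpp_fuzzen(NumericVector x, int m, double r, double nexp, int tau) {
  const int n = x.size();
  const int M = n - m * tau;
  if (M < 2) return NA_REAL;
  const double* p = REAL(x);
  double pm = fuzz_phi(p, n, m, r, nexp, tau, M);
  double pm1 = fuzz_phi(p, n, m + 1, r, nexp, tau, M);
  if (pm <= 0.0 || pm1 <= 0.0) return NA_REAL;
  return std::log(pm) - std::log(pm1);
}

// Permutation entropy of ordinal patterns of order k, delay tau, normalized
// by log(k!). Ties broken by position (first occurrence ranks lower).
// [[Rcpp::export]]
double cpp_permen(NumericVector x, int k, int tau) {
  const int n = x.size();
  const int M = n - (k - 1) * tau;
  if (M < 1) return NA_REAL;
  const double* p = REAL(x);
  int nfact = 1;
  for (int i = 2; i <= k; ++i) nfact *= i;
  std::vector<double> counts(nfact, 0.0);
  std::vector<int> idx(k);
  for (int i = 0; i < M; ++i) {
    for (int c = 0; c < k; ++c) idx[c] = c;
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      return p[i + a * tau] < p[i + b * tau];
    });
    // Lehmer code of the permutation
    int code = 0;
    for (int a = 0; a < k; ++a) {
      int smaller = 0;
      for (int b = a + 1; b < k; ++b) if (idx[b] < idx[a]) ++smaller;
      code = code * (k - a) + smaller;
    }
    counts[code] += 1.0;
  }
  double H = 0.0;
  for (int c = 0; c < nfact; ++c) {
    if (counts[c] > 0) {
      double q = counts[c] / M;
      H -= q * std::log(q);
    }
  }
  return H / std::log((double)nfact);
}

// Row-wise median of a numeric matrix.
// [[Rcpp::export]]
NumericVector cpp_row_median(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nr);
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = x(i, j);
    const int h = nc / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    if (nc % 2 == 1) {
      out[i] = buf[h];
    } else {
      double hi = buf[h];
      out[i] = (hi + *std::max_element(buf.begin(), buf.begin() + h)) / 2.0;
    }
  }
  return out;
}

// Mean rescaled-range statistic over non-overlapping windows of each size.
// Returns NA for a size when every window has zero SD.
// [[Rcpp::export]]
NumericVector cpp_rs_stat(NumericVector x, IntegerVector sizes) {
  const int n = x.size();
  const double* p = REAL(x);
  NumericVector out(sizes.size());
  for (int s = 0; s < sizes.size(); ++s) {
    const int w = sizes[s];
    const int k = n / w;
    double tot = 0.0; int nok = 0;
    for (int b = 0; b < k; ++b) {
      const double* seg = p + b * w;
      double mu = 0.0;
      for (int i = 0; i < w; ++i) mu += seg[i];
      mu /= w;
      double ss = 0.0, z = 0.0, zmin = 0.0, zmax = 0.0;
      for (int i = 0; i < w; ++i) {
        double dev = seg[i] - mu;
        ss += dev * dev;
        z += dev;
        if (z < zmin) zmin = z;
        if (z > zmax) zmax = z;
      }
      double sd = std::sqrt(ss / (w - 1));
      if (sd > 0) { tot += (zmax - zmin) / sd; ++nok; }
    }
    out[s] = nok > 0 ? tot / nok : NA_REAL;
  }
  return out;
}

// Correlation-dimension scaffolding: all pairwise Euclidean distances of the
// (m, tau) delay embedding, then counts of pairs below each of n_radii
// log-spaced radii between the qlo and qhi distance quantiles.
// Returns list(radii, counts, n_pairs).
// [[Rcpp::export]]
List cpp_corr_sums(NumericVector x, int m, int tau, int n_radii, double qlo,
                   double qhi, int max_points) {
  const int n = x.size();
  const int M = n - (m - 1) * tau;
  if (M < 2) return List::create(_["radii"] = NumericVector(0),
                                 _["counts"] = NumericVector(0),
                                 _["n_pairs"] = 0.0);
  const double* p = REAL(x);
  // evenly strided template subset when the series is long
  std::vector<int> idx;
  if (max_points > 1 && M > max_points) {
    idx.reserve(max_points);
    for (int q = 0; q < max_points; ++q) {
      idx.push_back((int)((double)q * (M - 1) / (max_points - 1)));
    }
  } else {
    idx.reserve(M);
    for (int i = 0; i < M; ++i) idx.push_back(i);
  }
  const int K = (int)idx.size();
  const R_xlen_t npair = (R_xlen_t)K * (K - 1) / 2;
  std::vector<double> d;
  d.reserve(npair);
  for (int a = 0; a < K - 1; ++a) {
    const int i = idx[a];
    for (int b = a + 1; b < K; ++b) {
      const int j = idx[b];
      double s = 0.0;
      for (int c = 0; c < m; ++c) {
        double dd = p[i + c * tau] - p[j + c * tau];
        s += dd * dd;
      }
      d.push_back(s);  // squared distance; sqrt deferred
    }
  }
  std::vector<double> tmp(d);
  auto quant = [&](double q) {
    size_t k = (size_t)std::floor(q * (tmp.size() - 1));
    std::nth_element(tmp.begin(), tmp.begin() + k, tmp.end());
    return std::sqrt(tmp[k]);
  };
  double rlo = quant(qlo), rhi = quant(qhi);
  if (rlo <= 0.0 || rhi <= rlo) return List::create(_["radii"] = NumericVector(0),
                                                    _["counts"] = NumericVector(0),
                                                    _["n_pairs"] = (double)npair);
  NumericVector radii(n_radii);
  std::vector<double> r2(n_radii);
  for (int r = 0; r < n_radii; ++r) {
    double rr = rlo * std::pow(rhi / rlo, (double)r / (n_radii - 1));
    radii[r] = rr;
    r2[r] = rr * rr;
  }
  // hist bin b: first radius with r2 >= d, so counts[r] = # pairs with d <= radii[r]
  std::vector<double> hist(n_radii + 1, 0.0);
  for (size_t q = 0; q < d.size(); ++q) {
    hist[std::lower_bound(r2.begin(), r2.end(), d[q]) - r2.begin()] += 1.0;
  }
  NumericVector counts(n_radii);
  double acc = 0.0;
  for (int r = 0; r < n_radii; ++r) {
    acc += hist[r];
    counts[r] = acc;
  }
  return List::create(_["radii"] = radii, _["counts"] = counts,
                      _["n_pairs"] = (double)npair);
}
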