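#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median via partial selection; mutates its argument.
static double med_inplace(std::vector<double>& v) {
  const std::size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  const double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  const double lo = *std::max_element(v.begin(), v.begin() + n / 2);
  return 0.5 * (lo + hi);
}

// Raw MAD: median of absolute deviations from the median (no constant).
static double mad_raw(std::vector<double> v) {
  const double m = med_inplace(v);
  for (double& x : v) x = std::fabs(x - m);
  return med_inplace(v);
}

static double vi_of(const std::vector<double>& l,
                    const std::vector<double>& r) {
  const double ml = mad_raw(l), mr = mad_raw(r);
  const double den = ml + mr;
  if (den <= 0.0) return NA_REAL;
  return (mr - ml) / den;
}

// [[Rcpp::export]]
double vi_stat_cpp(NumericVector left, NumericVector right) {
  std::vector<double> l(left.begin(), left.end());
  std::vector<double> r(right.begin(), right.end());
  return vi_of(l, r);
}

// Hemisphere-swap permutation null: each pair is independently swapped
// with probability 0.5 (within-participant pairing preserved). Uses R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector perm_vi_cpp(NumericVector left, NumericVector right,
                          int n_perm) {
  const int n = left.size();
  NumericVector out(n_perm);
  std::vector<double> l(n), r(n);
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < n; ++i) {
      if (unif_rand() < 0.5) {
        l[i] = right[i];
        r[i] = left[i];
      } else {
        l[i] = left[i];
        r[i] = right[i];
      }
    }
    out[p] = vi_of(l, r);
  }
  return out;
}

// Exhaustive enumeration of all 2^n swap patterns (n <= 16).
// [[Rcpp::export]]
NumericVector exact_vi_cpp(NumericVector left, NumericVector right) {
  const int n = left.size();
  if (n > 16) stop("exact enumeration is limited to 16 pairs");
  const std::size_t total = std::size_t(1) << n;
  NumericVector out(total);
  std::vector<double> l(n), r(n);
  for (std::size_t mask = 0; mask < total; ++mask) {
    for (int i = 0; i < n; ++i) {
      const bool sw = (mask >> i) & 1u;
      l[i] = sw ? right[i] : left[i];
      r[i] = sw ? left[i] : right[i];
    }
    out[mask] = vi_of(l, r);
  }
  return out;
}
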