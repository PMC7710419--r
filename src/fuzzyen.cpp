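#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fuzzy entropy core: mean pairwise similarity of baseline-removed
// templates at embedding dimensions m and m+1, over the N - m templates
// starting at i = 0..N-m-1. Similarity of a template pair is
// exp(-(d / r)^n) with d the Chebyshev distance between the mean-removed
// templates. Self-matches (i == j) are excluded. Returns c(phi_m, phi_m1).
// [[Rcpp::export]]
NumericVector fuzzyen_phi(NumericVector x, int m, double r, double n_fuzz) {
  const int N = x.size();
  const int nt = N - m;  // templates of length m and m+1 both indexed 0..nt-1
  if (nt < 2) stop("signal too short for embedding dimension m");

  // template means for lengths m and m+1
  std::vector<double> mu_m(nt), mu_m1(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    mu_m[i] = s / m;
    double s1 = s + x[i + m];
    mu_m1[i] = s1 / (m + 1);
  }

  const bool quad = n_fuzz == 2.0;  // avoid pow() in the common exponent
  long double acc_m = 0.0L, acc_m1 = 0.0L;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs((x[i + k] - mu_m[i]) - (x[j + k] - mu_m[j]));
        if (d > dm) dm = d;
      }
      double u = dm / r;
      acc_m += std::exp(quad ? -(u * u) : -std::pow(u, n_fuzz));
      double dm1 = 0.0;
      for (int k = 0; k <= m; ++k) {
        double d = std::fabs((x[i + k] - mu_m1[i]) - (x[j + k] - mu_m1[j]));
        if (d > dm1) dm1 = d;
      }
      double u1 = dm1 / r;
      acc_m1 += std::exp(quad ? -(u1 * u1) : -std::pow(u1, n_fuzz));
    }
  }
  const double npairs = 0.5 * nt * (nt - 1);
  return NumericVector::create((double)(acc_m / npairs),
                               (double)(acc_m1 / npairs));
}
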