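#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Type-7 quantile (R's default) of an unsorted window copy.
static double quantile7(std::vector<double>& w, double p) {
  const int n = w.size();
  if (n == 1) return w[0];
  const double h = (n - 1) * p;
  const int lo = (int)std::floor(h);
  const double g = h - lo;
  std::nth_element(w.begin(), w.begin() + lo, w.end());
  const double xlo = w[lo];
  if (g <= 0.0) return xlo;
  const double xhi = *std::min_element(w.begin() + lo + 1, w.end());
  return xlo + g * (xhi - xlo);
}

// Centered rolling quantile with edge-truncated windows.
// x: signal; halfwidth: frames on each side; prob: quantile level in [0,1].
// [[Rcpp::export]]
NumericVector rolling_quantile_cpp(NumericVector x, int halfwidth, double prob) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> w;
  w.reserve(2 * halfwidth + 1);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - halfwidth);
    const int hi = std::min(n - 1, i + halfwidth);
    w.assign(x.begin() + lo, x.begin() + hi + 1);
    out[i] = quantile7(w, prob);
  }
  return out;
}

// Centered rolling mean with edge-truncated windows (cumsum-based).
// [[Rcpp::export]]
NumericVector rolling_mean_cpp(NumericVector x, int halfwidth) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - halfwidth);
    const int hi = std::min(n - 1, i + halfwidth);
    out[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
  }
  return out;
}
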