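#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Quantile (type 7) of the finite values in buf. Returns NA if empty.
static double quantile7(std::vector<double>& buf, double prob) {
  const std::size_t m = buf.size();
  if (m == 0) return NA_REAL;
  if (m == 1) return buf[0];
  double h = (static_cast<double>(m) - 1.0) * prob;
  std::size_t lo = static_cast<std::size_t>(std::floor(h));
  std::size_t hi = static_cast<std::size_t>(std::ceil(h));
  std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
  double vlo = buf[lo];
  if (hi == lo) return vlo;
  double vhi = *std::min_element(buf.begin() + lo + 1, buf.end());
  return vlo + (h - lo) * (vhi - vlo);
}

// Strided rolling quantile: for each 1-based center index, the type-7
// quantile of the finite samples in the window [center - half, center + half]
// clipped to the trace. Non-finite samples are ignored.
// [[Rcpp::export]]
NumericVector roll_quantile_strided(NumericVector x, int width, double prob,
                                    IntegerVector centers) {
  const int n = x.size();
  const int half = width / 2;
  NumericVector out(centers.size());
  std::vector<double> buf;
  buf.reserve(width + 1);
  for (int j = 0; j < centers.size(); ++j) {
    int c = centers[j] - 1;
    int lo = std::max(0, c - half);
    int hi = std::min(n - 1, c + half);
    buf.clear();
    for (int i = lo; i <= hi; ++i) {
      double v = x[i];
      if (R_finite(v)) buf.push_back(v);
    }
    out[j] = quantile7(buf, prob);
  }
  return out;
}
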