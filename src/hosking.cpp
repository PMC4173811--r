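// Hosking's exact simulation of a stationary Gaussian series with given
// autocovariance sequence, by the Durbin-Levinson recursion. O(n^2):
// intended for moderate lengths; long fractional-noise series use the
// circulant embedding sampler on the R side instead.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// gamma: autocovariances gamma(0..n-1); z: n iid standard normals.
// [[Rcpp::export]]
NumericVector hosking_sim(NumericVector gamma_, NumericVector z) {
  const int n = z.size();
  if (gamma_.size() < n) stop("need autocovariances up to lag n-1");
  NumericVector x(n);
  std::vector<double> phi(n, 0.0), phi_prev(n, 0.0);
  double v = gamma_[0];
  x[0] = std::sqrt(v) * z[0];
  for (int t = 1; t < n; ++t) {
    double num = gamma_[t];
    for (int j = 1; j < t; ++j) num -= phi_prev[j] * gamma_[t - j];
    double pk = num / v;
    phi[t] = pk;
    for (int j = 1; j < t; ++j) phi[j] = phi_prev[j] - pk * phi_prev[t - j];
    v *= (1.0 - pk * pk);
    if (v < 0) v = 0;           // numerical floor at long lags
    double m = 0.0;
    for (int j = 1; j <= t; ++j) m += phi[j] * x[t - j];
    x[t] = m + std::sqrt(v) * z[t];
    for (int j = 1; j <= t; ++j) phi_prev[j] = phi[j];
  }
  return x;
}
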