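// Delayed, weighted-network Kuramoto integrator:
//   dphi_i = (omega_i + (K/N) sum_j C_ij sin(phi_j(t - D_ij) - phi_i)) dt
//            + noise
// Per-edge delayed phase lookups come from a ring buffer over the phase
// history; history before t = 0 is backfilled by natural-frequency
// rotation from the random initial phases. Uses R's RNG.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix network_sim_cpp(NumericMatrix C, IntegerMatrix delay_steps,
                              NumericVector omega, NumericVector phi0,
                              double coupling, double noise_sd, double dt,
                              int n_steps) {
  const int N = C.nrow();
  if (C.ncol() != N || delay_steps.nrow() != N || delay_steps.ncol() != N)
    stop("C and delay matrices must be square and matched");
  if (omega.size() != N || phi0.size() != N)
    stop("omega/phi0 length mismatch");

  // edge list over nonzero weights (directed: input j -> oscillator i)
  std::vector<int> ei, ej, ed;
  std::vector<double> ew;
  int maxd = 0;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (i != j && C(i, j) != 0.0) {
        int d = delay_steps(i, j);
        if (d < 0) stop("negative delay step count");
        ei.push_back(i); ej.push_back(j); ed.push_back(d);
        ew.push_back(C(i, j));
        if (d > maxd) maxd = d;
      }
  const int H = maxd + 1;                 // ring-buffer depth
  if (H >= n_steps && maxd > 0 && H > n_steps)
    stop("delay exceeds the simulated horizon");

  NumericMatrix phases(N, n_steps);
  std::vector<double> ring((size_t)H * N);
  // backfill: phi_j(-k) = phi0_j - omega_j * k * dt, stored so that
  // slot ((t - d) mod H) holds phi(t - d)
  for (int k = 0; k < H; ++k) {
    int slot = ((0 - k) % H + H) % H;
    for (int j = 0; j < N; ++j)
      ring[(size_t)slot * N + j] = phi0[j] - omega[j] * k * dt;
  }
  std::vector<double> phi(phi0.begin(), phi0.end()), drive(N);
  const double sig = noise_sd * std::sqrt(dt);
  // with row-normalised C (rows sum to 1) the weighted input is already
  // an average over sources, so the coupling scales the drive directly
  const double KN = coupling;

  for (int t = 0; t < n_steps; ++t) {
    for (int j = 0; j < N; ++j) phases(j, t) = phi[j];
    std::fill(drive.begin(), drive.end(), 0.0);
    if (coupling != 0.0) {
      const size_t nE = ei.size();
      for (size_t e = 0; e < nE; ++e) {
        int slot = ((t - ed[e]) % H + H) % H;
        double pj = ring[(size_t)slot * N + ej[e]];
        drive[ei[e]] += ew[e] * std::sin(pj - phi[ei[e]]);
      }
    }
    int cur = ((t + 1) % H + H) % H;      // slot that phi(t+1) will occupy
    for (int i = 0; i < N; ++i) {
      phi[i] += dt * (omega[i] + KN * drive[i]);
      if (sig > 0) phi[i] += norm_rand() * sig;
      ring[(size_t)cur * N + i] = phi[i];
    }
  }
  return phases;
}
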