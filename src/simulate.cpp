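#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of a network of coupled phase oscillators.
//
// phi_i' = omega_i + sum_t coeff_t * trig(k_t * phi_target + l_t * phi_source)
//          + sqrt(D_i) * xi_i(t)
//
// Noise is drawn from R's RNG (norm_rand) so trajectories are reproducible
// under set.seed(). The full trajectory is subsampled every `keep` steps.
//
// term columns: target (0-based), source (0-based), k, l, is_sin (1 sin /
// 0 cos), coeff.
// [[Rcpp::export(name = ".sim_phase_network")]]
NumericMatrix sim_phase_network(NumericVector phi0, NumericVector omega,
                                NumericVector D, NumericMatrix terms,
                                double dt, int nsteps, int keep) {
  const int n = phi0.size();
  const int nterms = terms.nrow();
  const int nout = nsteps / keep + 1;
  NumericMatrix out(nout, n);
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> sqD(n);
  for (int i = 0; i < n; ++i) sqD[i] = std::sqrt(dt * D[i]);

  for (int i = 0; i < n; ++i) out(0, i) = phi[i];
  int row = 1;

  RNGScope scope;
  std::vector<double> drift(n);
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < n; ++i) drift[i] = omega[i];
    for (int t = 0; t < nterms; ++t) {
      const int tgt = (int) terms(t, 0);
      const int src = (int) terms(t, 1);
      const double arg = terms(t, 2) * phi[tgt] + terms(t, 3) * phi[src];
      const double val = terms(t, 4) > 0.5 ? std::sin(arg) : std::cos(arg);
      drift[tgt] += terms(t, 5) * val;
    }
    for (int i = 0; i < n; ++i) {
      phi[i] += dt * drift[i];
      if (sqD[i] > 0.0) phi[i] += sqD[i] * norm_rand();
    }
    if (s % keep == 0 && row < nout) {
      for (int i = 0; i < n; ++i) out(row, i) = phi[i];
      ++row;
    }
  }
  return out;
}
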