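#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs sweeps for a {0,1} Ising model:
// P(x_i = 1 | x_-i) = logistic(tau_i + sum_j w_ij x_j).
// Uses R's RNG so draws are reproducible under set.seed().
// [[Rcpp::export(name = ".gibbs_chain")]]
IntegerMatrix gibbs_chain(NumericVector tau, NumericMatrix w, int n,
                          int burn_in, int thin) {
  const int p = tau.size();
  IntegerMatrix out(n, p);
  std::vector<int> x(p);
  RNGScope scope;
  for (int i = 0; i < p; ++i)
    x[i] = (unif_rand() < 1.0 / (1.0 + std::exp(-tau[i]))) ? 1 : 0;
  const int total = burn_in + n * thin;
  int kept = 0;
  for (int s = 0; s < total; ++s) {
    for (int i = 0; i < p; ++i) {
      double eta = tau[i];
      for (int j = 0; j < p; ++j) if (x[j]) eta += w(i, j);
      x[i] = (unif_rand() < 1.0 / (1.0 + std::exp(-eta))) ? 1 : 0;
    }
    if (s >= burn_in && (s - burn_in) % thin == thin - 1) {
      for (int i = 0; i < p; ++i) out(kept, i) = x[i];
      ++kept;
      if (kept == n) break;
    }
  }
  return out;
}
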