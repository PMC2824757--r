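#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Euler-Maruyama integration of a noisy leaky integrate-and-fire neuron
//   tau_m dV/dt = -V + bias + drive(t),  plus sigma * dW
// On V >= threshold a spike is recorded and V <- reset in the same step.
// [[Rcpp::export(name = ".integrate_lif_cpp")]]
List integrate_lif_cpp(double threshold, double reset, double tau_m,
                       double bias, double sigma,
                       NumericVector drive, double dt, double v0,
                       double seed) {
  const int n = drive.size();
  NumericVector v(n + 1);
  std::vector<double> spikes;
  uint64_t root = static_cast<uint64_t>(seed);
  Rng rng(splitmix64_next(root));
  const double sq = sigma * std::sqrt(dt);
  double V = v0;
  v[0] = V;
  for (int i = 0; i < n; ++i) {
    if (ISNAN(drive[i])) stop("NaN in LIF drive at step %d", i + 1);
    V += dt / tau_m * (-V + bias + drive[i]) + sq * rng.norm();
    if (V >= threshold) {
      spikes.push_back((i + 1) * dt);
      V = reset;
    }
    v[i + 1] = V;
  }
  return List::create(_["v"] = v, _["spikes"] = wrap(spikes));
}
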