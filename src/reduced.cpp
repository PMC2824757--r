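#include <Rcpp.h>
#include "rng.h"
#include "prc.h"
using namespace Rcpp;

// Event-driven reduced model: two phase oscillators kicked at Poisson event
// times (Gillespie selection among shared / independent-1 / independent-2
// streams), with the shared rate lambda relaxing slowly toward
// lam_min + G(phase difference).
//
// g_mode 0: direct   G = amplitude * exp(kappa * (cos phi - 1))
// g_mode 1: order    G = amplitude * R^p, R the modulus of a trailing
//                    exponentially-weighted average of e^{i phi} (time
//                    constant tau_r)
// kick_eval 0: PRC evaluated at the pre-drift phase (map as printed)
//           1: PRC evaluated at the drifted phase
// [[Rcpp::export(name = ".run_reduced_cpp")]]
List run_reduced_cpp(double theta1, double theta2, double lam0,
                     double omega,
                     int prc_family, double prc_amplitude, NumericVector prc_table,
                     double kick_gain,
                     double lam_min, double lam_max,
                     double lam1, double lam2, double tau_lam,
                     int g_mode, double amplitude, double kappa,
                     double p_exp, double tau_r,
                     int kick_eval,
                     int n_events, int record_every,
                     double seed) {
  Prc prc{prc_family, prc_amplitude,
          std::vector<double>(prc_table.begin(), prc_table.end())};
  uint64_t root = static_cast<uint64_t>(seed);
  Rng rng(splitmix64_next(root));

  double lam = lam0, t = 0.0;
  if (lam < lam_min) lam = lam_min;
  if (lam > lam_max) lam = lam_max;
  // trailing exponentially-weighted average of e^{i phi}; the weight total
  // w_tot ramps from 0 so an empty window contributes G = 0
  double ew_c = 0.0, ew_s = 0.0, ew_w = 0.0;

  const int n_rec = n_events / record_every;
  NumericVector rec_t(n_rec), rec_phi(n_rec), rec_lam(n_rec), rec_g(n_rec);
  int irec = 0;

  for (int n = 0; n < n_events; ++n) {
    const double total = lam + lam1 + lam2;
    const double dt = rng.expo(total);
    t += dt;

    // Gillespie selection among the three streams
    const double u = rng.unif() * total;
    int k1 = 0, k2 = 0;
    if (u < lam) { k1 = 1; k2 = 1; }
    else if (u < lam + lam1) { k1 = 1; }
    else { k2 = 1; }

    const double d1 = theta1 + omega * dt, d2 = theta2 + omega * dt;
    if (kick_eval == 0) {   // PRC at the pre-drift phase
      theta1 = wrap_2pi(d1 + k1 * kick_gain * prc.eval(wrap_2pi(theta1)));
      theta2 = wrap_2pi(d2 + k2 * kick_gain * prc.eval(wrap_2pi(theta2)));
    } else {                // PRC at the drifted phase
      theta1 = wrap_2pi(d1 + k1 * kick_gain * prc.eval(wrap_2pi(d1)));
      theta2 = wrap_2pi(d2 + k2 * kick_gain * prc.eval(wrap_2pi(d2)));
    }

    const double phi = wrap_pm_pi(theta2 - theta1);

    // feedback functional
    double g_val;
    if (g_mode == 0) {
      g_val = amplitude * std::exp(kappa * (std::cos(phi) - 1.0));
    } else {
      const double w = std::exp(-dt / tau_r);
      ew_c = w * ew_c + (1.0 - w) * std::cos(phi);
      ew_s = w * ew_s + (1.0 - w) * std::sin(phi);
      ew_w = w * ew_w + (1.0 - w);
      const double R = ew_w > 0 ?
          std::sqrt(ew_c * ew_c + ew_s * ew_s) / ew_w : 0.0;
      g_val = amplitude * std::pow(std::min(R, 1.0), p_exp);
    }

    // exact exponential relaxation of lambda toward lam_min + G over dt
    const double target = lam_min + g_val;
    lam = target + (lam - target) * std::exp(-dt / tau_lam);
    if (lam > lam_max) lam = lam_max;
    if (lam < lam_min) lam = lam_min;

    if ((n + 1) % record_every == 0 && irec < n_rec) {
      rec_t[irec] = t; rec_phi[irec] = phi; rec_lam[irec] = lam;
      rec_g[irec] = g_val;
      irec++;
    }
  }

  return List::create(
      _["t"] = rec_t, _["phi"] = rec_phi, _["lambda"] = rec_lam,
      _["g"] = rec_g,
      _["final"] = NumericVector::create(
          _["theta1"] = theta1, _["theta2"] = theta2,
          _["phi"] = wrap_pm_pi(theta2 - theta1), _["lambda"] = lam, _["t"] = t));
}
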