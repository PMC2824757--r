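#include <Rcpp.h>
#include "rng.h"
#include "prc.h"
using namespace Rcpp;

// Closed-loop spiking network: N mitral phase oscillators drive M noisy LIF
// granule cells through exponentially decaying synapses; each granule spike
// raises the rate lambda_k of that granule pool's shared Poisson process,
// whose events kick all reciprocally connected mitral cells through the PRC.
// Independent Poisson streams kick each mitral cell alone.
//
// Event type codes: 0 shared kick, 1 independent kick, 2 granule spike,
// 3 mitral spike.
// [[Rcpp::export(name = ".run_spiking_cpp")]]
List run_spiking_cpp(int n_mitral, int n_granule,
                     List granule_inputs,   // 0-based mitral indices per granule
                     List mitral_feedback,  // 0-based granule indices per mitral
                     double omega,
                     int prc_family, double prc_amplitude, NumericVector prc_table,
                     double kick_gain,      // PRC kick magnitude a
                     double g,              // mitral -> granule coupling
                     double tau_s,
                     double threshold, double reset, double tau_m,
                     double bias, double sigma,
                     NumericVector lam_indep,
                     double lam_min, double lam_max, double tau_lam, double jump_a,
                     double t_total, double dt,
                     int sample_every,      // steps between trace samples
                     bool record_events,
                     double seed,
                     NumericVector theta0) {
  Prc prc{prc_family, prc_amplitude,
          std::vector<double>(prc_table.begin(), prc_table.end())};

  // independent named streams derived from the root seed
  uint64_t root = static_cast<uint64_t>(seed);
  std::vector<Rng> lif_rng, shared_rng, indep_rng;
  for (int k = 0; k < n_granule; ++k) lif_rng.emplace_back(splitmix64_next(root));
  for (int k = 0; k < n_granule; ++k) shared_rng.emplace_back(splitmix64_next(root));
  for (int i = 0; i < n_mitral; ++i) indep_rng.emplace_back(splitmix64_next(root));

  std::vector<std::vector<int> > gin(n_granule), mfb(n_mitral);
  for (int k = 0; k < n_granule; ++k) {
    IntegerVector v = granule_inputs[k];
    gin[k] = std::vector<int>(v.begin(), v.end());
  }
  for (int i = 0; i < n_mitral; ++i) {
    IntegerVector v = mitral_feedback[i];
    mfb[i] = std::vector<int>(v.begin(), v.end());
  }

  const int n_steps = static_cast<int>(std::round(t_total / dt));
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> V(n_granule, 0.0), lam(n_granule, lam_min);
  // per-granule, per-input synaptic drives s_{k,j}
  std::vector<std::vector<double> > syn(n_granule);
  for (int k = 0; k < n_granule; ++k) syn[k].assign(gin[k].size(), 0.0);

  const double dec_s = std::exp(-dt / tau_s);
  const double dec_lam = std::exp(-dt / tau_lam);
  const double sq = sigma * std::sqrt(dt);

  const int n_samp = n_steps / sample_every + 1;
  NumericVector samp_t(n_samp);
  NumericMatrix samp_theta(n_samp, n_mitral), samp_v(n_samp, n_granule),
      samp_lam(n_samp, n_granule);
  IntegerMatrix kick_counts(n_mitral, 2);  // cols: shared, independent
  IntegerVector mitral_spikes(n_mitral), granule_spikes(n_granule);

  std::vector<double> ev_t;
  std::vector<int> ev_type, ev_id, ev_target;
  auto log_ev = [&](double t, int type, int id, int target) {
    if (record_events) {
      ev_t.push_back(t); ev_type.push_back(type);
      ev_id.push_back(id); ev_target.push_back(target);
    }
  };

  std::vector<int> spiked(n_mitral);
  int isamp = 0;
  samp_t[0] = 0.0;
  for (int i = 0; i < n_mitral; ++i) samp_theta(0, i) = theta[i];
  for (int k = 0; k < n_granule; ++k) { samp_v(0, k) = V[k]; samp_lam(0, k) = lam[k]; }
  isamp = 1;

  for (int step = 0; step < n_steps; ++step) {
    const double t = (step + 1) * dt;

    // phase drift (unwrapped within the step)
    for (int i = 0; i < n_mitral; ++i) theta[i] += omega * dt;

    // Poisson kicks by thinning; a kick is applied before the crossing test,
    // so a kick that pushes theta past 2*pi fires the cell this step
    for (int k = 0; k < n_granule; ++k) {
      if (shared_rng[k].bern(lam[k] * dt)) {
        for (int i : gin[k]) {
          theta[i] += kick_gain * prc.eval(wrap_2pi(theta[i]));
          kick_counts(i, 0)++;
          log_ev(t, 0, k, i);
        }
      }
    }
    for (int i = 0; i < n_mitral; ++i) {
      if (indep_rng[i].bern(lam_indep[i] * dt)) {
        theta[i] += kick_gain * prc.eval(wrap_2pi(theta[i]));
        kick_counts(i, 1)++;
        log_ev(t, 1, i, i);
      }
    }

    // mitral spikes: upward crossings of 2*pi
    for (int i = 0; i < n_mitral; ++i) {
      int ns = 0;
      if (theta[i] >= 2.0 * M_PI) ns = static_cast<int>(std::floor(theta[i] / (2.0 * M_PI)));
      spiked[i] = ns;
      if (ns > 0) { mitral_spikes[i] += ns; log_ev(t, 3, i, i); }
      theta[i] = wrap_2pi(theta[i]);
    }

    // synapses decay, then jump by g per presynaptic mitral spike
    for (int k = 0; k < n_granule; ++k) {
      double drive = 0.0;
      for (size_t j = 0; j < gin[k].size(); ++j) {
        syn[k][j] = syn[k][j] * dec_s + g * spiked[gin[k][j]];
        drive += syn[k][j];
      }
      // LIF granule cell, Euler-Maruyama
      V[k] += dt / tau_m * (-V[k] + bias + drive) + sq * lif_rng[k].norm();
      int gsp = 0;
      if (V[k] >= threshold) { gsp = 1; V[k] = reset; granule_spikes[k]++; log_ev(t, 2, k, k); }
      // shared rate: exact exponential relaxation toward lam_min, jump, clip
      lam[k] = lam_min + (lam[k] - lam_min) * dec_lam + jump_a * gsp;
      if (lam[k] > lam_max) lam[k] = lam_max;
      if (lam[k] < lam_min) lam[k] = lam_min;
    }

    if ((step + 1) % sample_every == 0 && isamp < n_samp) {
      samp_t[isamp] = t;
      for (int i = 0; i < n_mitral; ++i) samp_theta(isamp, i) = theta[i];
      for (int k = 0; k < n_granule; ++k) {
        samp_v(isamp, k) = V[k];
        samp_lam(isamp, k) = lam[k];
      }
      isamp++;
    }
  }

  List events = List::create(
      _["t"] = wrap(ev_t), _["type"] = wrap(ev_type),
      _["id"] = wrap(ev_id), _["target"] = wrap(ev_target));
  return List::create(
      _["time"] = samp_t, _["theta"] = samp_theta, _["v"] = samp_v,
      _["lambda"] = samp_lam, _["kick_counts"] = kick_counts,
      _["mitral_spikes"] = mitral_spikes, _["granule_spikes"] = granule_spikes,
      _["events"] = events);
}

// Open-loop coincidence-detector probe: two mitral oscillators clamped at a
// fixed phase difference phi (no Poisson kicks), driving one noisy LIF.
// Returns the LIF spike count over the window.
// [[Rcpp::export(name = ".granule_rate_cpp")]]
int granule_rate_cpp(double phi, double omega,
                     double g, double tau_s,
                     double threshold, double reset, double tau_m,
                     double bias, double sigma,
                     double window, double dt, double seed) {
  uint64_t root = static_cast<uint64_t>(seed);
  Rng rng(splitmix64_next(root));
  const int n_steps = static_cast<int>(std::round(window / dt));
  const double dec_s = std::exp(-dt / tau_s);
  const double sq = sigma * std::sqrt(dt);
  // clamped phases: theta1 = omega t, theta2 = omega t + phi (mod 2*pi)
  double th1 = 0.0, th2 = wrap_2pi(phi);
  double s1 = 0.0, s2 = 0.0, V = 0.0;
  int count = 0;
  for (int step = 0; step < n_steps; ++step) {
    th1 += omega * dt; th2 += omega * dt;
    int sp1 = 0, sp2 = 0;
    if (th1 >= 2.0 * M_PI) { sp1 = 1; th1 -= 2.0 * M_PI; }
    if (th2 >= 2.0 * M_PI) { sp2 = 1; th2 -= 2.0 * M_PI; }
    s1 = s1 * dec_s + g * sp1;
    s2 = s2 * dec_s + g * sp2;
    V += dt / tau_m * (-V + bias + s1 + s2) + sq * rng.norm();
    if (V >= threshold) { V = reset; count++; }
  }
  return count;
}
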