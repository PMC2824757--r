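#include <Rcpp.h>
#include <deque>
#include "rng.h"
using namespace Rcpp;

// Morris-Lecar right-hand side; parameter vector layout:
// (C, gL, EL, gCa, ECa, gK, EK, v1, v2, v3, v4, phi_w, Iapp)
struct MLP {
  double C, gL, EL, gCa, ECa, gK, EK, v1, v2, v3, v4, phi_w, Iapp;
  explicit MLP(const NumericVector &p)
      : C(p[0]), gL(p[1]), EL(p[2]), gCa(p[3]), ECa(p[4]), gK(p[5]), EK(p[6]),
        v1(p[7]), v2(p[8]), v3(p[9]), v4(p[10]), phi_w(p[11]), Iapp(p[12]) {}
  inline void deriv(double V, double w, double i_syn,
                    double &dV, double &dw) const {
    const double minf = 0.5 * (1.0 + std::tanh((V - v1) / v2));
    const double winf = 0.5 * (1.0 + std::tanh((V - v3) / v4));
    const double lamw = phi_w * std::cosh((V - v3) / (2.0 * v4));
    dV = (Iapp + i_syn - gL * (V - EL) - gCa * minf * (V - ECa) -
          gK * w * (V - EK)) / C;
    dw = lamw * (winf - w);
  }
};

static inline void rk4_step(const MLP &p, double &V, double &w,
                            double i_syn, double dt) {
  double k1v, k1w, k2v, k2w, k3v, k3w, k4v, k4w;
  p.deriv(V, w, i_syn, k1v, k1w);
  p.deriv(V + 0.5 * dt * k1v, w + 0.5 * dt * k1w, i_syn, k2v, k2w);
  p.deriv(V + 0.5 * dt * k2v, w + 0.5 * dt * k2w, i_syn, k3v, k3w);
  p.deriv(V + dt * k3v, w + dt * k3w, i_syn, k4v, k4w);
  V += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
  w += dt / 6.0 * (k1w + 2.0 * k2w + 2.0 * k3w + k4w);
  if (w < 0.0) w = 0.0;
  if (w > 1.0) w = 1.0;
}

// Single ML cell with one optional square current pulse; used to measure the
// unperturbed period and to calibrate kick pulses against a target phase
// shift. Time in ms. Returns spike times (upward crossing of v_spike).
// [[Rcpp::export(name = ".ml_single_cpp")]]
NumericVector ml_single_cpp(NumericVector mlp, double v0, double w0,
                            double t_total, double dt,
                            double pulse_t, double pulse_amp, double pulse_dur,
                            double v_spike, double refrac) {
  MLP p(mlp);
  double V = v0, w = w0, last_spike = -1e9;
  std::vector<double> spikes;
  const int n = static_cast<int>(std::round(t_total / dt));
  double Vprev = V;
  for (int i = 0; i < n; ++i) {
    const double t = i * dt;
    double i_syn = 0.0;
    if (pulse_dur > 0 && t >= pulse_t && t < pulse_t + pulse_dur) i_syn = pulse_amp;
    Vprev = V;
    rk4_step(p, V, w, i_syn, dt);
    if (Vprev < v_spike && V >= v_spike && (t + dt - last_spike) > refrac) {
      // linear sub-step interpolation of the crossing time
      const double tc = t + dt * (v_spike - Vprev) / (V - Vprev);
      spikes.push_back(tc);
      last_spike = tc;
    }
  }
  return wrap(spikes);
}

// Closed-loop 2 Morris-Lecar mitral cells + 1 noisy LIF granule cell.
// Inhibitory kicks arrive as brief square current pulses (amplitude
// kick_amp < 0 effective, duration kick_dur ms). Time unit: ms; rates per ms.
// [[Rcpp::export(name = ".run_ml_cpp")]]
List run_ml_cpp(NumericVector mlp,
                NumericVector v0, NumericVector w0,
                double kick_amp, double kick_dur,
                double g, double tau_s,
                double threshold, double reset, double tau_m,
                double bias, double sigma,
                double lam1, double lam2,
                double lam_min, double lam_max, double tau_lam, double jump_a,
                double t_total, double dt,
                int sample_every,
                double v_spike, double refrac,
                double seed) {
  MLP p(mlp);
  uint64_t root = static_cast<uint64_t>(seed);
  Rng lif_rng(splitmix64_next(root));
  Rng shared_rng(splitmix64_next(root));
  Rng ind1_rng(splitmix64_next(root));
  Rng ind2_rng(splitmix64_next(root));

  double V[2] = {v0[0], v0[1]}, w[2] = {w0[0], w0[1]};
  double s[2] = {0.0, 0.0}, Vg = 0.0, lam = lam_min;
  double last_spike[2] = {-1e9, -1e9};
  std::deque<double> pulse_end[2];  // active square-pulse expiry times

  const int n_steps = static_cast<int>(std::round(t_total / dt));
  const double dec_s = std::exp(-dt / tau_s);
  const double dec_lam = std::exp(-dt / tau_lam);
  const double sq = sigma * std::sqrt(dt);

  const int n_samp = n_steps / sample_every + 1;
  NumericVector st(n_samp), sv1(n_samp), sv2(n_samp), slam(n_samp), svg(n_samp);
  st[0] = 0; sv1[0] = V[0]; sv2[0] = V[1]; slam[0] = lam; svg[0] = Vg;
  int isamp = 1;
  std::vector<double> gspikes;
  std::vector<double> mspikes1, mspikes2;

  for (int step = 0; step < n_steps; ++step) {
    const double t = (step + 1) * dt;

    // Poisson kicks by thinning: shared pulses hit both cells
    if (shared_rng.bern(lam * dt)) {
      pulse_end[0].push_back(t + kick_dur);
      pulse_end[1].push_back(t + kick_dur);
    }
    if (ind1_rng.bern(lam1 * dt)) pulse_end[0].push_back(t + kick_dur);
    if (ind2_rng.bern(lam2 * dt)) pulse_end[1].push_back(t + kick_dur);

    int spiked[2] = {0, 0};
    for (int i = 0; i < 2; ++i) {
      while (!pulse_end[i].empty() && pulse_end[i].front() <= t)
        pulse_end[i].pop_front();
      const double i_syn = kick_amp * static_cast<double>(pulse_end[i].size());
      const double Vprev = V[i];
      rk4_step(p, V[i], w[i], i_syn, dt);
      if (Vprev < v_spike && V[i] >= v_spike && (t - last_spike[i]) > refrac) {
        spiked[i] = 1;
        const double tc = t - dt + dt * (v_spike - Vprev) / (V[i] - Vprev);
        last_spike[i] = t;
        if (i == 0) mspikes1.push_back(tc); else mspikes2.push_back(tc);
      }
    }

    s[0] = s[0] * dec_s + g * spiked[0];
    s[1] = s[1] * dec_s + g * spiked[1];
    Vg += dt / tau_m * (-Vg + bias + s[0] + s[1]) + sq * lif_rng.norm();
    int gsp = 0;
    if (Vg >= threshold) { gsp = 1; Vg = reset; gspikes.push_back(t); }
    lam = lam_min + (lam - lam_min) * dec_lam + jump_a * gsp;
    if (lam > lam_max) lam = lam_max;
    if (lam < lam_min) lam = lam_min;

    if ((step + 1) % sample_every == 0 && isamp < n_samp) {
      st[isamp] = t; sv1[isamp] = V[0]; sv2[isamp] = V[1];
      slam[isamp] = lam; svg[isamp] = Vg;
      isamp++;
    }
  }

  return List::create(
      _["time"] = st, _["v1"] = sv1, _["v2"] = sv2, _["lambda"] = slam,
      _["v_granule"] = svg, _["granule_spikes"] = wrap(gspikes),
      _["mitral_spikes_1"] = wrap(mspikes1), _["mitral_spikes_2"] = wrap(mspikes2));
}
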