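#pragma once
#include <cstdint>
#include <cmath>
#include <random>
#include <vector>

#ifndef M_PI
#define M_PI 3.14159265358979323846
#endif

// splitmix64: derives independent stream seeds from one root seed so that
// individual noise sources (LIF noise, each Poisson stream) can be toggled
// without perturbing the draws of the others.
inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Deterministic generator built on std::mt19937_64 (a standardized stream)
// with hand-written inverse-transform / Box-Muller draws, so identical seeds
// give bit-identical trajectories on any conforming compiler.
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform in (0,1), never 0 or 1
  double unif() {
    return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  bool bern(double p) { return unif() < p; }
};

inline double wrap_2pi(double th) {
  th -= 2.0 * M_PI * std::floor(th / (2.0 * M_PI));
  if (th >= 2.0 * M_PI) th = 0.0;  // guard against rounding at the boundary
  return th;
}

// wrap a difference to (-pi, pi]; the boundary tie maps to +pi
inline double wrap_pm_pi(double d) {
  d -= 2.0 * M_PI * std::ceil((d - M_PI) / (2.0 * M_PI));
  if (d > M_PI) d = M_PI;
  if (d <= -M_PI) d = M_PI;
  return d;
}
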