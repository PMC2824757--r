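#pragma once
#include <vector>
#include <cmath>
#include "rng.h"

// Phase resetting curve Delta(theta), 2*pi-periodic.
// family 1: amplitude * (1 - cos theta)   (type I, non-negative)
// family 2: amplitude * sin theta         (type II, sinusoidal)
// family 3: tabulated on a uniform [0, 2*pi) grid, periodic linear interpolation
struct Prc {
  int family;
  double amplitude;
  std::vector<double> table;

  double eval(double theta) const {
    if (family == 1) return amplitude * (1.0 - std::cos(theta));
    if (family == 2) return amplitude * std::sin(theta);
    const int n = static_cast<int>(table.size());
    double x = wrap_2pi(theta) * n / (2.0 * M_PI);
    int i0 = static_cast<int>(std::floor(x));
    if (i0 >= n) i0 = 0;
    int i1 = (i0 + 1) % n;
    double f = x - std::floor(x);
    return amplitude * ((1.0 - f) * table[i0] + f * table[i1]);
  }
};
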