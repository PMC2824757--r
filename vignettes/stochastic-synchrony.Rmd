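---
title: "Feedback-amplified stochastic synchronization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-amplified stochastic synchronization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochsync)
```

## The scientific problem

Mitral cells, the principal neurons of the olfactory bulb, fire in the
gamma band and synchronize during odor responses, yet the inhibition they
receive from granule cells is weak, long-lasting, asynchronous and
aperiodic — nothing like the strong phasic inhibition that synchronizes
excitatory cells in PING-type circuits. An alternative mechanism is
*stochastic synchronization*: uncoupled limit-cycle oscillators driven by
partially shared noisy input synchronize, and the degree of synchrony is
set by the fraction `q` of input they share. In the bulb the shared input
comes from granule cells that are reciprocally (dendrodendritically)
connected to several mitral cells, so the shared fraction is not imposed
from outside: synchronous mitral firing recruits the common granule cells,
whose firing raises the shared input rate, which synchronizes the mitral
cells further. This package implements that positive feedback loop in
three tiers and the analysis machinery that explains its steady states:

1. **Spiking network** (`run_spiking`): mitral cells as phase oscillators
   with a phase resetting curve (PRC), a noisy leaky integrate-and-fire
   (LIF) granule cell, exponentially decaying synapses, and Poisson kick
   streams whose shared rate `lambda` is driven by granule spikes.
2. **Conductance-based network** (`run_ml_network`): the phase oscillators
   replaced by Morris-Lecar cells; inhibitory kicks arrive as brief square
   current pulses; synchrony is read out as a moving-window voltage
   correlation.
3. **Reduced event-driven map** (`run_reduced`): the analytically
   tractable two-oscillator model — Gillespie selection among shared and
   independent Poisson streams, a phase map at event times, and a slow
   relaxation of `lambda` toward `lam_min + G`, with a pluggable feedback
   functional `G`.

The theory layer (`stationary_density`, `averaged_dynamics`,
`find_fixed_points`) computes the stationary density `rho(phi; q)` of the
phase difference from the discretized Frobenius-Perron operator of the
event map, averages the feedback functional against it, and analyzes the
resulting slow scalar flow for `lambda`, including the bistability
classification.

## Model equations and conventions

Phases live on `[0, 2*pi)`; phase differences on `(-pi, pi]`, with the
boundary tie mapping to `+pi`. Between events a phase advances as
`theta <- theta + omega * dt`; an input arriving at phase `theta` shifts it
by `g * Delta(theta)` through the PRC. The shipped default PRC is
sinusoidal (`Delta = sin`), the near-universal shape measured for mitral
cells; `type1` (`1 - cos`) and tabulated PRCs (periodic linear
interpolation of a uniform-grid CSV) are also available. The default
natural frequency is gamma-band, 40 Hz, which makes a 0.75 rad phase
offset about 3 ms of spike-time offset (`phase_to_time(0.75, 40)`).

The granule cell is a noisy LIF unit, `tau_m dV/dt = -V + bias + s1 + s2`
plus a white-noise term whose Euler-Maruyama increment is
`sigma * sqrt(dt)`; threshold 1, reset 0. Each mitral spike (an upward
crossing of `2*pi`, tested after kicks are applied so that a kick can fire
the cell) increments its synapse by the coupling `g`; synapses decay
exponentially with `tau_s`. Each granule spike adds `jump_a` to the shared
rate `lambda`, which otherwise relaxes exponentially toward `lam_min` with
the slow time constant `tau_lam` and is clipped to `[lam_min, lam_max]`.

In the reduced map, events arrive at the merged rate
`lambda + lambda1 + lambda2`; the event is shared with probability
`lambda / total` (both oscillators kicked) or independent (one kicked),
exactly as in the Gillespie algorithm. The PRC is evaluated at the
pre-drift phase by default (`kick_eval = "pre_drift"`, the map as usually
written); the post-drift convention is available and differs at
`O(g * omega * dt)`.

## The feedback functional G

Two forms connect synchrony back to the shared rate:

* **direct**: `G(phi) = A * exp(kappa * (cos(phi) - 1))`, a smooth even
  bump peaked at zero phase difference with concentration `kappa = 5` —
  an idealization of the measured coincidence-detector rate of the
  granule cell. Averaged over the stationary density this always yields
  exactly one stable fixed point of the slow dynamics.
* **order_parameter**: `G = A * R^p` with `p = 2`, where `R` is the
  modulus of a trailing exponentially weighted average (time constant
  `tau_r`) of `exp(1i * phi)`. The quadratic small-`R` dependence makes
  the averaged drive superlinear in `q` at small `q`, which is what
  permits bistability between an asynchronous low-rate state and a
  synchronous high-rate state.

## Stationary density and averaging

For slowly varying `lambda`, the phase difference relaxes to a stationary
density determined by the common-input fraction
`q = lambda / (lambda + lambda1 + lambda2)`. The package computes
`rho(phi; q)` as the leading eigenvector of the discretized transfer
operator of the event map: with probability `q` the difference moves by
`g * (Delta(u + phi) - Delta(u))` with the base phase `u` marginalized
over a uniform grid, with probability `(1 - q) / 2` it shifts rigidly by
`-g * Delta(u)` or `+g * Delta(u)`. Kicked mass is scattered by periodic
linear binning, which conserves mass exactly, so the kernel is
column-stochastic by construction; power iteration is run to a sup-norm
residual of `1e-12`. At `q = 0` the density is uniform to machine
precision; as `q -> 1` it approaches a delta function at zero.

Two independent routes cross-validate this solver: a direct Monte-Carlo
sampler of the same stochastic phase-difference map
(`mc_stationary_density`), and the full two-oscillator reduced simulation
with the feedback frozen (`frozen_q_samples`). The second route does not
make the uniform-base-phase marginalization, so agreement also checks
that assumption; it holds well whenever the free drift between successive
events is large compared to one cycle (`omega / total rate >> 2*pi`), and
this condition guided the shipped rate scales below.

Averaging replaces the fast phase dynamics by `rho(phi; q)`:
`d lambda/dt = (lam_min - lambda + <G>(q)) / tau_lam` with
`<G>(q) = integral G(phi) rho(phi; q) dphi` (direct) or `A * m(q)^p`
(order mode), where `m(q) = integral cos(phi) rho(phi; q) dphi` is the
synchrony order parameter. `averaged_dynamics` tabulates `m(q)` and the
unit-amplitude `<G>(q)` on a `q` grid capped at 0.999 (the inverse map
`lambda(q) = q (lambda1 + lambda2) / (1 - q)` has a vertical asymptote at
`q = 1`); `find_fixed_points` locates the roots of the averaged
right-hand side by a dense sign-change scan refined by bisection to
`1e-10`, with stability from the central-difference slope. Because the
right-hand side is non-negative at `q = 0` and diverges to minus infinity
at the asymptote, at least one stable fixed point always exists; the root
count is odd and stability alternates.

One caveat found numerically: with the shipped bump (`kappa = 5`) the
direct-mode `<G>(q)` is concave only at small `q` and turns convex over
much of `(0.1, 1)` as the density sharpens. The classical argument for a
unique stable state pictures `<G>` as linear-then-saturating; the
conclusion nevertheless survives here — verified directly across a
`10^-1` to `10^3` amplitude sweep — because the `lambda(q)` asymptote
always dominates the growth of `<G>`.

## Shipped study conditions and why

All defaults are package choices, made once:

* **Phase network** (`spiking_config`): 40 Hz oscillators, sinusoidal PRC,
  kick magnitude 0.4; coupling `g` varied over `[0, 2]`; `tau_s = 3` ms;
  LIF with `tau_m = 1.5` ms and `sigma = 4`, placing the granule cell in
  the coincidence-detector regime (a single EPSP peaks well below
  threshold, a coincident pair near it); independent rate 20 events/s per
  cell; `lam_min = 0.5`, `lam_max = 100`, `jump_a = 4`, `tau_lam = 0.5` s;
  Euler-Maruyama step 0.1 ms with Poisson thinning on the same grid.
  With `g = 0` both shared and unshared rates are low and the
  phase-difference histogram is nearly flat; at `g = 2` the granule cell
  fires reliably on coincidences and `lambda` saturates high.
* **Coincidence-detector probe** (`granule_rate_vs_phase`): spike counts
  over a 10 s window with the loop open (phases clamped at a fixed lag).
  Shipped settings `(g, tau_s)` = (1, 2 ms), (1.25, 5 ms), (1.75, 10 ms)
  span the sharp-to-flat range: the weakest, shortest synapse is nearly
  silent beyond ~0.75 rad of lag, the strongest always fires.
* **Reduced map** (`reduced_config`): kick gain 0.8 and independent rates
  1.25 events/s per stream, so that the drift between events is tens of
  radians (keeping the operator's decorrelation assumption accurate) and
  phase mixing takes only tens of events; `lam_min = 0.05`,
  `lam_max = 10`; `tau_lam = 2400` s with the direct functional
  (`A = 1.5` default, swept 0.5-2.5), so `lambda` averages over many
  phase-mixing times and the trial medians sit within a few percent of
  the averaged-theory fixed point. For the bistable study the
  order-parameter functional uses `A = 22` and
  `tau_lam = tau_r = 38400` s (the window is deliberately as long as the
  relaxation itself; the default elsewhere keeps `tau_r = tau_lam / 2`). The long window matters: the modulus
  of a windowed mean vector is biased upward by sampling variance
  (roughly `2 / (rate * tau_r * sigma_step^2)` with `sigma_step^2` the
  per-event phase-difference increment variance), and with short windows
  that bias erases the shallow low-rate basin entirely. The shipped
  values keep the bias to a few percent of the low fixed point while
  trials of `3.2e6` events still equilibrate (about four `tau_lam`). The absolute
  time units are arbitrary for this abstract tier — only the
  dimensionless ratios (rate x window, `tau_lam / tau_r`, drift per
  event) matter, and a time-rescaling invariance test asserts exactly
  that.
* **Morris-Lecar network** (`ml_config`): the canonical Hopf-regime
  parameter set with `Iapp = 100` uA/cm^2 (period about 91 ms), RK4 at
  0.02 ms with spike times interpolated below the step; kicks as -15
  uA/cm^2, 1 ms square pulses (the calibration routine
  `ml_calibrate_kick` maps pulse amplitude to an equivalent PRC shift,
  delivered at the delay-sensitive 0.8 cycle phase); granule LIF with
  `sigma = 2.5` so that stray noise spikes seed transient rises of
  `lambda`; `lam_min = 1`, `lam_max = 25`, `jump_a = 3`, `tau_lam = 3` s,
  independent rate 1 events/s. Weak kicks synchronize this pair much
  better than strong ones (kick-induced excursions off the limit cycle
  act as extra noise), which is why the pulse is small. In long runs the
  network dwells alternately in a synchronized high-rate state and a
  desynchronized low-rate state, with the moving-window voltage
  correlation high exactly during the high-rate epochs and a bimodal
  long-run `lambda` histogram.

## Numerical choices, degenerate inputs, tie-breaks

* Synapse and shared-rate updates use the exact exponential formulas, not
  Euler steps; they agree with fine Euler integration to `1e-6`.
* A kick landing on a cycle boundary is applied before the crossing test,
  so a kick across `2*pi` fires the cell in the same step.
* The phase-difference boundary tie at `+/-pi` maps to `+pi`.
* Zero-variance windows in `sliding_correlation` report correlation 0
  with a warning; empty order-parameter windows give `G = 0`.
* All randomness derives from one root seed through named splitmix64
  streams (one per LIF, one per Poisson stream), so reruns are
  bit-identical and single components can be toggled without perturbing
  the draws of the others; `derive_seed` is the documented per-trial
  splitting rule at the R level.
* The bimodality verdict is a transparent histogram-trough rule (trough
  below 60% of the smaller mode, modes at least 3 bins apart, spurious
  tail peaks below 5% of the maximum ignored) rather than a formal dip
  test, for determinism.

## What the generator does and does not emulate

The simulations generate every input internally; there is no external
data. They emulate the *mechanism* — correlation feedback through shared
inhibitory noise — under idealized conditions: identical oscillator
frequencies, a single effective granule unit (or all-pairs pools),
Poisson input statistics, and stationary parameters. They do not emulate
synaptic depression or facilitation, spike-frequency adaptation, odor
drive dynamics, conduction delays, or heterogeneous PRCs. Passing tests
therefore demonstrate the internal consistency of the models and theory
at the shipped operating points, not a quantitative fit to bulb
physiology.

## Known limitations

* The transfer-operator density assumes the base phase is uniform and
  independent across events; at high event rates relative to `omega` the
  full map deviates (the shipped conditions avoid this regime, and the
  frozen-feedback cross-check quantifies it).
* The windowed order parameter is a biased estimator at small effective
  sample sizes; the bistable study conditions were chosen so the bias is
  negligible, but users lowering `tau_r` or the rates should expect the
  asynchronous state to wash out.
* Morris-Lecar epoch switching is a rare-event phenomenon; transition
  counts over a few hundred seconds vary between seeds.
* The reduced map covers exactly two oscillators; larger networks are the
  spiking tier's job.

## Worked example

```{r, eval = FALSE}
library(stochsync)

# stationary density and synchrony at q = 0.6
rho <- stationary_density(0.6, prc_spec("type2"), gain = 0.1)
order_parameter_of_density(rho)

# averaged theory vs simulation for the direct functional
avg <- averaged_dynamics(reduced_config())
find_fixed_points(avg)
predict_vs_simulate(avg, amplitudes = c(0.5, 1.5, 2.5),
                    n_trials = 30, n_events = 30000, seed = 1)

# closed-loop spiking network at strong coupling
res <- run_spiking(topology_2m1g(), spiking_config(g = 2),
                   t_total = 60, seed = 1)
phase_difference_histogram(res$phi[res$time > 3], n_bins = 24)
```

The figure-analogue experiment runners (`run_experiment`,
`experiment_config("fig2")` ... `"fig6"`) package these calls with fixed
parameter trees, CSV/JSON outputs and a reproducibility manifest; the
`inst/cli/stochsync.R` script exposes them from the shell.
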