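#' Morris-Lecar mitral-cell parameters
#'
#' Standard two-variable Morris-Lecar conductance model
#' \deqn{C dV/dt = I - g_L (V - E_L) - g_{Ca} m_\infty(V) (V - E_{Ca})
#'       - g_K w (V - E_K)}
#' \deqn{dw/dt = \phi_w \cosh((V - v_3)/(2 v_4)) (w_\infty(V) - w)}
#' with `m_inf(V) = 0.5 (1 + tanh((V - v1)/v2))` and
#' `w_inf(V) = 0.5 (1 + tanh((V - v3)/v4))`. Units: mV, ms, uA/cm^2,
#' mS/cm^2. The defaults are the canonical Hopf-regime set, with the applied
#' current placed above the Hopf bifurcation so the cell fires periodically.
#'
#' @param C membrane capacitance, uF/cm^2.
#' @param gL,EL leak conductance and reversal.
#' @param gCa,ECa calcium conductance and reversal.
#' @param gK,EK potassium conductance and reversal.
#' @param v1,v2 half-activation and slope of `m_inf`, mV.
#' @param v3,v4 half-activation and slope of `w_inf`, mV.
#' @param phi_w rate scale of the recovery variable, 1/ms.
#' @param Iapp applied current, uA/cm^2.
#' @return an object of class `ml_params`.
#' @export
ml_params <- function(C = 20, gL = 2, EL = -60, gCa = 4, ECa = 120,
                      gK = 8, EK = -84, v1 = -1.2, v2 = 18, v3 = 2,
                      v4 = 30, phi_w = 0.04, Iapp = 100) {
  stopifnot(C > 0, gL >= 0, gCa >= 0, gK >= 0, v2 > 0, v4 > 0, phi_w > 0)
  structure(list(C = C, gL = gL, EL = EL, gCa = gCa, ECa = ECa, gK = gK,
                 EK = EK, v1 = v1, v2 = v2, v3 = v3, v4 = v4,
                 phi_w = phi_w, Iapp = Iapp), class = "ml_params")
}

ml_param_vector <- function(p) {
  c(p$C, p$gL, p$EL, p$gCa, p$ECa, p$gK, p$EK, p$v1, p$v2, p$v3, p$v4,
    p$phi_w, p$Iapp)
}

#' Morris-Lecar right-hand side
#'
#' Pure function returning the derivatives of the membrane potential and the
#' recovery gating variable for a given state and synaptic current.
#'
#' @param state list or numeric with `V` (mV) and `w` (gating, in `[0, 1]`).
#' @param params an [ml_params()].
#' @param i_syn additional input current, uA/cm^2.
#' @return named numeric `c(dV = ..., dw = ...)` in mV/ms and 1/ms.
#' @export
ml_derivatives <- function(state, params, i_syn = 0) {
  stopifnot(inherits(params, "ml_params"))
  V <- if (is.list(state)) state$V else state[[1]]
  w <- if (is.list(state)) state$w else state[[2]]
  if (!all(is.finite(c(V, w)))) stop("non-finite Morris-Lecar state")
  minf <- 0.5 * (1 + tanh((V - params$v1) / params$v2))
  winf <- 0.5 * (1 + tanh((V - params$v3) / params$v4))
  lamw <- params$phi_w * cosh((V - params$v3) / (2 * params$v4))
  dV <- (params$Iapp + i_syn - params$gL * (V - params$EL) -
         params$gCa * minf * (V - params$ECa) -
         params$gK * w * (V - params$EK)) / params$C
  dw <- lamw * (winf - w)
  c(dV = dV, dw = dw)
}

#' Spike times of a single unperturbed (or pulse-perturbed) ML cell
#'
#' Integrates one Morris-Lecar cell with RK4 and returns the times of upward
#' crossings of `v_spike` (with a refractory hysteresis). Optionally a single
#' square current pulse is injected; this is the primitive used both to
#' measure the free-running period and to calibrate inhibitory kick pulses.
#'
#' @param params an [ml_params()].
#' @param t_total,dt integration horizon and step, ms.
#' @param v0,w0 initial state.
#' @param pulse_t,pulse_amp,pulse_dur square pulse onset (ms), amplitude
#'   (uA/cm^2, negative = inhibitory) and duration (ms); `pulse_dur = 0`
#'   disables it.
#' @param v_spike,refrac spike detection threshold (mV) and refractory (ms).
#' @return numeric vector of spike times in ms.
#' @export
ml_spike_times <- function(params, t_total = 2000, dt = 0.02,
                           v0 = -20, w0 = 0.2,
                           pulse_t = 0, pulse_amp = 0, pulse_dur = 0,
                           v_spike = 0, refrac = 2) {
  stopifnot(inherits(params, "ml_params"), dt > 0, t_total > 0)
  .ml_single_cpp(ml_param_vector(params), v0, w0, t_total, dt,
                 pulse_t, pulse_amp, pulse_dur, v_spike, refrac)
}

#' Free-running Morris-Lecar period
#'
#' @param params an [ml_params()].
#' @param dt RK4 step, ms.
#' @return mean inter-spike interval (ms) after discarding a transient;
#'   errors if the cell does not fire periodically at the configured drive.
#' @export
ml_period <- function(params, dt = 0.02) {
  sp <- ml_spike_times(params, t_total = 3000, dt = dt)
  sp <- sp[sp > 1000]
  if (length(sp) < 5)
    stop("Morris-Lecar cell is not firing periodically at Iapp = ",
         params$Iapp, "; pick parameters above the onset of repetitive firing")
  mean(diff(sp))
}

#' Calibrate an inhibitory kick pulse against a target mid-cycle phase shift
#'
#' Because the Morris-Lecar cell has two state variables, kicks are realized
#' as brief square inhibitory current pulses rather than instantaneous phase
#' jumps. This routine finds the pulse amplitude whose delivery at mid-cycle
#' delays the next spike by `target_shift` radians of phase, matching the
#' effective PRC amplitude used in the phase models.
#'
#' @param params an [ml_params()].
#' @param target_shift desired phase delay in radians (> 0) at the most
#'   delay-sensitive delivery phase.
#' @param pulse_dur pulse duration, ms.
#' @param pulse_frac delivery time as a fraction of the cycle after a spike;
#'   the default 0.8 sits near the maximum of the inhibitory delay for the
#'   Hopf-regime cell.
#' @param amp_range search interval for the (positive) pulse magnitude.
#' @param dt RK4 step, ms.
#' @return the calibrated pulse amplitude (negative, uA/cm^2), with the
#'   achieved shift as attribute `"shift"`.
#' @export
ml_calibrate_kick <- function(params, target_shift = 0.4, pulse_dur = 1,
                              pulse_frac = 0.8, amp_range = c(0.1, 80),
                              dt = 0.02) {
  period <- ml_period(params, dt = dt)
  sp0 <- ml_spike_times(params, t_total = 2000, dt = dt)
  sp0 <- sp0[sp0 > 1000]
  t_ref <- sp0[1]
  shift_of <- function(amp) {
    sp <- ml_spike_times(params, t_total = t_ref + 3 * period, dt = dt,
                         pulse_t = t_ref + pulse_frac * period,
                         pulse_amp = -amp, pulse_dur = pulse_dur)
    nxt <- sp[sp > t_ref + pulse_frac * period][1]
    ((nxt - t_ref) - period) / period * 2 * pi
  }
  f <- function(amp) shift_of(amp) - target_shift
  lo <- f(amp_range[1]); hi <- f(amp_range[2])
  if (lo * hi > 0)
    stop("target shift ", target_shift, " rad not bracketed by amplitudes in [",
         amp_range[1], ", ", amp_range[2], "]")
  amp <- stats::uniroot(f, amp_range, tol = 1e-3)$root
  structure(-amp, shift = shift_of(amp))
}

#' Configuration of the Morris-Lecar feedback network
#'
#' Two Morris-Lecar mitral cells drive one noisy LIF granule cell exactly as
#' in the phase-model network; inhibitory kicks return as brief square
#' current pulses. Network-level times are in seconds (converted internally
#' to the ms units of the ML cells).
#'
#' @param ml an [ml_params()].
#' @param kick_amp pulse amplitude, uA/cm^2 (negative = inhibitory).
#' @param kick_dur pulse duration, ms.
#' @param g,tau_s mitral-to-granule coupling and synaptic decay (s).
#' @param lif a [lif_params()] (times in s).
#' @param lam_indep independent Poisson rate per mitral cell, events/s.
#' @param lam_min,lam_max,tau_lam,jump_a shared-rate parameters (s, events/s).
#' @param dt RK4 / Euler-Maruyama step, ms.
#' @param v_spike,refrac spike detection threshold (mV), refractory (ms).
#' @return a list of class `ml_config`.
#' @export
ml_config <- function(ml = ml_params(),
                      kick_amp = -15, kick_dur = 1,
                      g = 2.2, tau_s = 0.004,
                      lif = lif_params(tau_m = 0.01, sigma = 2.5),
                      lam_indep = 1,
                      lam_min = 1, lam_max = 25, tau_lam = 3, jump_a = 3,
                      dt = 0.02, v_spike = 0, refrac = 2) {
  stopifnot(inherits(ml, "ml_params"), kick_dur >= 0, g >= 0, tau_s > 0,
            all(lam_indep >= 0), lam_min <= lam_max, tau_lam > 0, dt > 0)
  structure(list(ml = ml, kick_amp = kick_amp, kick_dur = kick_dur, g = g,
                 tau_s = tau_s, lif = lif, lam_indep = lam_indep,
                 lam_min = lam_min, lam_max = lam_max, tau_lam = tau_lam,
                 jump_a = jump_a, dt = dt, v_spike = v_spike,
                 refrac = refrac), class = "ml_config")
}

#' Run the closed-loop Morris-Lecar feedback network
#'
#' 2-mitral / 1-granule closed loop with conductance-based mitral cells.
#' Checks at startup that the ML cell fires periodically at the configured
#' drive. Returns voltage and shared-rate traces (time in seconds).
#'
#' @param config an [ml_config()].
#' @param t_total simulated time, seconds.
#' @param seed integer root seed.
#' @param sample_every trace sampling interval in steps.
#' @param v0,w0 initial states of the two cells (length-2 vectors); slightly
#'   desynchronized by default.
#' @return an object of class `ml_result` with `time` (s), `v1`, `v2`,
#'   `v_granule`, `lambda` (events/s), spike time vectors (s) and `dt_s`.
#' @export
run_ml_network <- function(config = ml_config(), t_total = 60, seed = 1,
                           sample_every = 25L,
                           v0 = c(-20, 30), w0 = c(0.2, 0.25)) {
  stopifnot(inherits(config, "ml_config"), t_total > 0)
  ml_period(config$ml, dt = config$dt)  # startup check: must oscillate
  lam_indep <- rep_len(config$lam_indep, 2)
  out <- .run_ml_cpp(
    ml_param_vector(config$ml), v0, w0,
    config$kick_amp, config$kick_dur,
    config$g, config$tau_s * 1000,
    config$lif$threshold, config$lif$reset, config$lif$tau_m * 1000,
    config$lif$bias, config$lif$sigma / sqrt(1000),
    lam_indep[1] / 1000, lam_indep[2] / 1000,
    config$lam_min / 1000, config$lam_max / 1000,
    config$tau_lam * 1000, config$jump_a / 1000,
    t_total * 1000, config$dt, as.integer(sample_every),
    config$v_spike, config$refrac, as.numeric(seed))
  structure(list(
    time = out$time / 1000, v1 = out$v1, v2 = out$v2,
    v_granule = out$v_granule, lambda = out$lambda * 1000,
    granule_spikes = out$granule_spikes / 1000,
    mitral_spikes_1 = out$mitral_spikes_1 / 1000,
    mitral_spikes_2 = out$mitral_spikes_2 / 1000,
    dt_s = config$dt * sample_every / 1000,
    config = config, seed = seed, t_total = t_total), class = "ml_result")
}

#' Pearson correlation of two traces over a moving window
#'
#' Synchrony measure for the conductance-based network: the correlation
#' between the two mitral voltage traces computed in windows of `width`
#' seconds advanced by `stride`, reported at window centers. Windows in
#' which either trace has zero variance get correlation 0 (with a warning).
#'
#' @param v1,v2 equal-length numeric traces sampled at interval `dt`.
#' @param dt sampling interval of the traces, seconds.
#' @param width,stride window width and stride, seconds.
#' @return data frame with `time` (window centers, s) and `corr`.
#' @export
sliding_correlation <- function(v1, v2, dt, width = 0.5, stride = width / 2) {
  stopifnot(length(v1) == length(v2), width > 0, stride > 0, dt > 0)
  nw <- max(2L, as.integer(round(width / dt)))
  if (nw >= length(v1)) stop("window must be shorter than the traces")
  ns <- max(1L, as.integer(round(stride / dt)))
  starts <- seq(1L, length(v1) - nw + 1L, by = ns)
  degenerate <- FALSE
  cc <- vapply(starts, function(i) {
    a <- v1[i:(i + nw - 1L)]; b <- v2[i:(i + nw - 1L)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      degenerate <<- TRUE
      return(0)
    }
    stats::cor(a, b)
  }, numeric(1))
  if (degenerate)
    warning("zero-variance window(s): correlation reported as 0 there")
  data.frame(time = (starts - 1 + (nw - 1) / 2) * dt, corr = cc)
}
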