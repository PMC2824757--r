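#' Parameters of the noisy LIF granule cell
#'
#' The granule cell is a leaky integrate-and-fire unit
#' `tau_m dV/dt = -V + bias + drive(t)` plus white noise of intensity
#' `sigma`; when `V` crosses `threshold` (set to 1) a spike is recorded and
#' `V` is reset to `reset` (0).
#'
#' @param threshold firing threshold (dimensionless), default 1.
#' @param reset post-spike reset value, default 0; must be below threshold.
#' @param tau_m membrane time constant in seconds.
#' @param bias constant baseline drive (dimensionless), default 0.
#' @param sigma noise intensity; the Euler-Maruyama noise increment per step
#'   is `sigma * sqrt(dt)`.
#' @return an object of class `lif_params`.
#' @export
lif_params <- function(threshold = 1, reset = 0, tau_m = 0.0015,
                       bias = 0, sigma = 4) {
  stopifnot(threshold > reset, tau_m > 0, sigma >= 0)
  structure(list(threshold = threshold, reset = reset, tau_m = tau_m,
                 bias = bias, sigma = sigma), class = "lif_params")
}

#' Integrate a noisy LIF neuron driven by an input trace
#'
#' Euler-Maruyama integration on a fixed grid. With `sigma = 0` and constant
#' suprathreshold drive `I`, the inter-spike period is
#' `tau_m * log(I / (I - threshold))`.
#'
#' @param params a [lif_params()].
#' @param drive input drive: a scalar (held constant) or a vector giving the
#'   drive at each step.
#' @param t_total total time in seconds (used when `drive` is scalar).
#' @param dt step in seconds; a warning is issued if `dt > tau_m / 10`.
#' @param seed integer seed for the noise stream.
#' @param v0 initial voltage.
#' @return list with `v` (voltage trace, length steps + 1), `spikes` (spike
#'   times in seconds) and `dt`.
#' @export
integrate_lif <- function(params, drive, t_total = NULL, dt = 1e-4,
                          seed = 1, v0 = 0) {
  stopifnot(inherits(params, "lif_params"), dt > 0)
  if (dt > params$tau_m / 10)
    warning("dt = ", dt, " is coarse relative to tau_m = ", params$tau_m)
  if (length(drive) == 1) {
    if (is.null(t_total)) stop("scalar drive needs `t_total`")
    drive <- rep(drive, round(t_total / dt))
  }
  if (anyNA(drive)) stop("NaN/NA in LIF drive")
  out <- .integrate_lif_cpp(params$threshold, params$reset, params$tau_m,
                            params$bias, params$sigma,
                            as.numeric(drive), dt, v0, as.numeric(seed))
  out$dt <- dt
  out
}

#' Exact update of an exponentially decaying synaptic drive
#'
#' Over a step `dt` the drive decays as `s * exp(-dt / tau_s)`; each
#' presynaptic mitral spike then increments it by the coupling `g`
#' (the unit jump scaled by the mitral-to-granule coupling strength).
#'
#' @param s current drive value(s), non-negative.
#' @param dt elapsed time in seconds, non-negative.
#' @param tau_s synaptic decay time constant in seconds.
#' @param n_spikes number of presynaptic spikes in the step.
#' @param g coupling strength (jump per spike).
#' @return updated drive.
#' @export
decay_and_jump_synapse <- function(s, dt, tau_s, n_spikes = 0, g = 1) {
  stopifnot(dt >= 0, tau_s > 0, n_spikes >= 0, g >= 0)
  s * exp(-dt / tau_s) + g * n_spikes
}

#' State of the shared Poisson rate of a granule pool
#'
#' `lam` relaxes exponentially toward `lam_min` with time constant
#' `tau_lam`; each granule spike adds `jump_a`; the rate is clipped to
#' `[lam_min, lam_max]`.
#'
#' @param lam current rate, events/s.
#' @param lam_min,lam_max rate bounds, events/s.
#' @param tau_lam relaxation time constant in seconds (slow compared to the
#'   oscillation period).
#' @param jump_a rate increment per granule spike, events/s.
#' @return an object of class `shared_rate_state`.
#' @export
shared_rate_state <- function(lam = lam_min, lam_min = 2, lam_max = 40,
                              tau_lam = 0.5, jump_a = 4) {
  stopifnot(lam_min <= lam_max, tau_lam > 0, jump_a >= 0)
  structure(list(lam = min(max(lam, lam_min), lam_max), lam_min = lam_min,
                 lam_max = lam_max, tau_lam = tau_lam, jump_a = jump_a),
            class = "shared_rate_state")
}

#' Update the shared rate over a time step
#'
#' @param state a [shared_rate_state()].
#' @param dt elapsed time in seconds.
#' @param n_granule_spikes granule spikes occurring in the step.
#' @return the updated `shared_rate_state`.
#' @export
update_shared_rate <- function(state, dt, n_granule_spikes = 0) {
  stopifnot(inherits(state, "shared_rate_state"), dt >= 0)
  lam <- state$lam_min + (state$lam - state$lam_min) * exp(-dt / state$tau_lam)
  lam <- lam + state$jump_a * n_granule_spikes
  state$lam <- min(max(lam, state$lam_min), state$lam_max)
  state
}

#' Network topologies of mitral and granule cells
#'
#' Each granule cell pools at least two mitral inputs; by the reciprocity of
#' the dendrodendritic synapse, the shared Poisson process of a granule pool
#' kicks exactly the mitral cells that drive it.
#'
#' `topology_2m1g()` is the two-mitral / one-granule circuit;
#' `topology_3m3g()` is the three-mitral / three-granule ring in which
#' oscillators (1,2), (1,3) and (2,3) drive granule cells 1, 2 and 3;
#' `topology_nm()` builds the all-pairs network with one granule cell per
#' mitral pair.
#'
#' @param n_mitral number of mitral cells (`topology_nm`).
#' @return an object of class `ms_topology` with `n_mitral`, `n_granule`,
#'   `granule_inputs` (list of mitral index vectors) and `mitral_feedback`.
#' @export
topology_2m1g <- function() {
  make_topology(2, list(c(1, 2)))
}

#' @rdname topology_2m1g
#' @export
topology_3m3g <- function() {
  make_topology(3, list(c(1, 2), c(1, 3), c(2, 3)))
}

#' @rdname topology_2m1g
#' @export
topology_nm <- function(n_mitral) {
  stopifnot(n_mitral >= 2)
  make_topology(n_mitral, utils::combn(n_mitral, 2, simplify = FALSE))
}

make_topology <- function(n_mitral, granule_inputs) {
  granule_inputs <- lapply(granule_inputs, function(v) sort(unique(as.integer(v))))
  if (any(vapply(granule_inputs, length, 1L) < 2))
    stop("every granule cell needs at least 2 distinct mitral inputs")
  if (any(unlist(granule_inputs) < 1) || any(unlist(granule_inputs) > n_mitral))
    stop("mitral indices out of range")
  mitral_feedback <- lapply(seq_len(n_mitral), function(i)
    which(vapply(granule_inputs, function(v) i %in% v, TRUE)))
  structure(list(n_mitral = n_mitral, n_granule = length(granule_inputs),
                 granule_inputs = granule_inputs,
                 mitral_feedback = mitral_feedback),
            class = "ms_topology")
}

validate_topology <- function(topology) {
  if (!inherits(topology, "ms_topology")) stop("not an `ms_topology`")
  if (any(vapply(topology$granule_inputs, length, 1L) < 2))
    stop("invalid topology: granule cell with fewer than 2 mitral inputs")
  for (k in seq_len(topology$n_granule))
    for (i in topology$granule_inputs[[k]])
      if (!(k %in% topology$mitral_feedback[[i]]))
        stop("invalid topology: reciprocity broken for granule ", k,
             " and mitral ", i)
  invisible(topology)
}

#' Default configuration of the spiking feedback network
#'
#' Bundles all parameters of the closed loop: gamma-band mitral oscillators
#' (40 Hz), sinusoidal PRC with kick magnitude `kick_gain`, synaptic decay
#' `tau_s`, the noisy LIF granule cell, and the Poisson rates. Defaults put
#' the granule cell in the coincidence-detector regime (weak, fast synapses,
#' short membrane time constant): near-coincident mitral spikes are required
#' to fire it.
#'
#' @param omega mitral angular frequency, rad/s.
#' @param prc a [prc_spec()].
#' @param kick_gain magnitude of a PRC kick (dimensionless).
#' @param g mitral-to-granule coupling, varied between 0 and 2.
#' @param tau_s synaptic decay time constant, s.
#' @param lif a [lif_params()].
#' @param lam_indep independent Poisson rate per mitral cell, events/s.
#' @param lam_min,lam_max,tau_lam,jump_a shared-rate parameters, see
#'   [shared_rate_state()].
#' @param dt integration step, s.
#' @return a list of class `spiking_config`.
#' @export
spiking_config <- function(omega = 2 * pi * 40,
                           prc = prc_spec("type2", amplitude = 1),
                           kick_gain = 0.4,
                           g = 1,
                           tau_s = 0.003,
                           lif = lif_params(),
                           lam_indep = 20,
                           lam_min = 0.5, lam_max = 100,
                           tau_lam = 0.5, jump_a = 4,
                           dt = 1e-4) {
  stopifnot(omega > 0, kick_gain >= 0, g >= 0, tau_s > 0,
            all(lam_indep >= 0), lam_min <= lam_max, tau_lam > 0, dt > 0)
  structure(list(omega = omega, prc = prc, kick_gain = kick_gain, g = g,
                 tau_s = tau_s, lif = lif, lam_indep = lam_indep,
                 lam_min = lam_min, lam_max = lam_max, tau_lam = tau_lam,
                 jump_a = jump_a, dt = dt),
            class = "spiking_config")
}

prc_to_cpp <- function(prc) {
  fam <- match(prc$family, c("type1", "type2", "tabulated"))
  tab <- if (is.null(prc$table)) numeric(0) else as.numeric(prc$table)
  list(family = fam, amplitude = prc$amplitude, table = tab)
}

#' Draw merged shared and independent Poisson kick events
#'
#' Generates the events of the shared process (rate `lam`, kicking every
#' mitral cell of the pool) and of each independent process over a window,
#' merged and time-sorted.
#'
#' @param lam shared rate, events/s.
#' @param lam_indep vector of independent rates per mitral cell.
#' @param t_window window length in seconds.
#' @param seed integer seed.
#' @return data frame with columns `t`, `source` (`"shared"` or
#'   `"independent"`), `stream` (0 for shared, mitral index otherwise).
#' @export
draw_kick_events <- function(lam, lam_indep, t_window, seed = 1) {
  stopifnot(lam >= 0, all(lam_indep >= 0), t_window > 0)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  draw1 <- function(rate, label, stream) {
    n <- stats::rpois(1, rate * t_window)
    if (n == 0) return(NULL)
    data.frame(t = sort(stats::runif(n, 0, t_window)),
               source = label, stream = stream)
  }
  parts <- c(list(draw1(lam, "shared", 0L)),
             lapply(seq_along(lam_indep), function(i)
               draw1(lam_indep[i], "independent", i)))
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0)
    return(data.frame(t = numeric(0), source = character(0),
                      stream = integer(0)))
  ev <- do.call(rbind, parts)
  ev[order(ev$t), , drop = FALSE]
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run the closed-loop spiking feedback network
#'
#' Full simulation of the feedback loop: mitral phases drift; each 2*pi
#' crossing increments the synapses of the granule cells the mitral cell
#' drives; the noisy LIF granule cells integrate their synaptic drive; each
#' granule spike raises the shared Poisson rate of its pool; shared events
#' kick all reciprocally connected mitral cells through the PRC, independent
#' events kick single cells. All randomness derives from `seed` through
#' named streams, so reruns are bit-identical.
#'
#' @param topology an `ms_topology`, see [topology_2m1g()].
#' @param config a [spiking_config()].
#' @param t_total simulated time in seconds.
#' @param seed integer root seed.
#' @param sample_every trace sampling interval in steps.
#' @param record_events if `TRUE`, return the full timestamped event log.
#' @param theta0 optional initial phases (default: evenly spread).
#' @return an object of class `spiking_result`: `time`, `theta` (matrix),
#'   `v`, `lambda` (matrices), `phi` (phase difference of mitral 1 and 2 at
#'   sample times), spike/kick counts and (optionally) `events`.
#' @export
run_spiking <- function(topology, config = spiking_config(), t_total = 30,
                        seed = 1, sample_every = 10L, record_events = FALSE,
                        theta0 = NULL) {
  validate_topology(topology)
  stopifnot(inherits(config, "spiking_config"), t_total > 0)
  min_rate <- min(c(config$lam_min, config$lam_indep[config$lam_indep > 0]))
  if (is.finite(min_rate) && min_rate > 0 && t_total < 10 / min_rate)
    warning("t_total = ", t_total, " s is short relative to the slowest ",
            "Poisson rate; statistics will be noisy")
  lam_indep <- rep_len(config$lam_indep, topology$n_mitral)
  if (is.null(theta0))
    theta0 <- 2 * pi * (seq_len(topology$n_mitral) - 1) / topology$n_mitral
  pr <- prc_to_cpp(config$prc)
  out <- .run_spiking_cpp(
    topology$n_mitral, topology$n_granule,
    lapply(topology$granule_inputs, function(v) as.integer(v - 1L)),
    lapply(topology$mitral_feedback, function(v) as.integer(v - 1L)),
    config$omega, pr$family, pr$amplitude, pr$table,
    config$kick_gain, config$g, config$tau_s,
    config$lif$threshold, config$lif$reset, config$lif$tau_m,
    config$lif$bias, config$lif$sigma,
    lam_indep, config$lam_min, config$lam_max, config$tau_lam, config$jump_a,
    t_total, config$dt, as.integer(sample_every), record_events,
    as.numeric(seed), wrap_phase(theta0))
  res <- list(
    time = out$time, theta = out$theta, v = out$v, lambda = out$lambda,
    phi = wrap_phase_difference(out$theta[, 1], out$theta[, 2]),
    kick_counts = out$kick_counts,
    mitral_spikes = out$mitral_spikes, granule_spikes = out$granule_spikes,
    config = config, topology = topology, seed = seed, t_total = t_total)
  if (record_events) {
    ev <- out$events
    res$events <- data.frame(
      t = ev$t,
      source = c("shared", "independent", "granule", "mitral")[ev$type + 1L],
      id = ev$id + 1L, target = ev$target + 1L)
  }
  structure(res, class = "spiking_result")
}

#' Granule-cell spike count as a function of the mitral phase difference
#'
#' Open-loop coincidence-detection probe: the two mitral oscillators are
#' clamped at a fixed phase difference `phi` (feedback and Poisson kicks
#' disabled), and the LIF spike count over a window (default 10 s) is
#' returned. For weak, fast synapses this count collapses rapidly with
#' `|phi|`: the granule cell acts as a coincidence detector.
#'
#' @param phi phase difference in radians (vectorized).
#' @param config a [spiking_config()]; `g` and `tau_s` set the synapse.
#' @param window counting window in seconds.
#' @param seed integer seed (one independent stream per `phi`).
#' @return integer vector of spike counts `F(phi)`.
#' @export
granule_rate_vs_phase <- function(phi, config = spiking_config(),
                                  window = 10, seed = 1) {
  stopifnot(inherits(config, "spiking_config"), window > 0)
  vapply(seq_along(phi), function(i)
    .granule_rate_cpp(phi[i], config$omega, config$g, config$tau_s,
                      config$lif$threshold, config$lif$reset,
                      config$lif$tau_m, config$lif$bias, config$lif$sigma,
                      window, config$dt,
                      as.numeric(seed) * 1009 + i),
    integer(1))
}

#' @export
print.spiking_result <- function(x, ...) {
  cat("spiking feedback network run:", x$topology$n_mitral, "mitral /",
      x$topology$n_granule, "granule cells,", x$t_total, "s\n")
  cat("  granule spikes:", paste(x$granule_spikes, collapse = ", "),
      " mean lambda:", format(round(mean(x$lambda), 2)), "events/s\n")
  invisible(x)
}
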