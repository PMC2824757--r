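#' Draw an inter-event interval of the merged Poisson process
#'
#' @param total_rate sum of all stream rates, events/s; must be positive.
#' @param n number of draws.
#' @return exponential variates with mean `1 / total_rate`.
#' @export
sample_interval <- function(total_rate, n = 1) {
  if (!is.numeric(total_rate) || total_rate <= 0)
    stop("`total_rate` must be positive to draw an inter-event interval")
  stats::rexp(n, rate = total_rate)
}

#' Gillespie selection among the shared and independent streams
#'
#' An event belongs to the shared process with probability
#' `lam / (lam + lam1 + lam2)` and to independent stream i with probability
#' `lam_i / (lam + lam1 + lam2)`.
#'
#' @param lam shared rate; `lam1`, `lam2` independent rates (events/s).
#' @param n number of events to draw.
#' @return data frame with `kind` (`"shared"`, `"indep1"`, `"indep2"`) and
#'   kick indicators `k1`, `k2`.
#' @export
select_event <- function(lam, lam1, lam2, n = 1) {
  stopifnot(lam >= 0, lam1 >= 0, lam2 >= 0)
  total <- lam + lam1 + lam2
  if (total <= 0) stop("all rates are zero: no event can be selected")
  kind <- sample(c("shared", "indep1", "indep2"), n, replace = TRUE,
                 prob = c(lam, lam1, lam2) / total)
  data.frame(kind = kind,
             k1 = as.integer(kind != "indep2"),
             k2 = as.integer(kind != "indep1"))
}

#' One step of the event-driven phase map
#'
#' Advances both phases by the drift `omega * dt` and applies a PRC kick to
#' each kicked oscillator. With `kick_eval = "pre_drift"` (the default, the
#' map as printed) the PRC is evaluated at the phase before the drift; with
#' `"post_drift"` at the drifted phase. The difference is O(g * omega * dt).
#'
#' @param state list with `theta1`, `theta2` (radians), `t` (s).
#' @param dt inter-event interval, s.
#' @param ev one row of [select_event()] output (or a list with `k1`, `k2`).
#' @param prc a [prc_spec()].
#' @param gain kick magnitude.
#' @param omega angular frequency, rad/s.
#' @param kick_eval `"pre_drift"` or `"post_drift"`.
#' @return the updated state.
#' @export
map_step <- function(state, dt, ev, prc, gain, omega = 2 * pi * 40,
                     kick_eval = c("pre_drift", "post_drift")) {
  stopifnot(dt >= 0)
  kick_eval <- match.arg(kick_eval)
  d1 <- state$theta1 + omega * dt
  d2 <- state$theta2 + omega * dt
  at1 <- if (kick_eval == "pre_drift") state$theta1 else d1
  at2 <- if (kick_eval == "pre_drift") state$theta2 else d2
  state$theta1 <- wrap_phase(d1 + ev$k1 * gain * prc_eval(prc, at1))
  state$theta2 <- wrap_phase(d2 + ev$k2 * gain * prc_eval(prc, at2))
  state$t <- (state$t %||% 0) + dt
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feedback functional G mapping synchrony to added shared rate
#'
#' Two forms of the dependence of the granule-pool drive on mitral
#' synchrony:
#' \describe{
#'   \item{direct}{`G(phi) = amplitude * exp(kappa * (cos(phi) - 1))`, a
#'     smooth even bump peaked at zero phase difference - the instantaneous
#'     coincidence-detector rate. Always yields a single stable state.}
#'   \item{order_parameter}{`G = amplitude * R^p` where `R` is the circular
#'     order parameter of `exp(1i * phi)` over a trailing
#'     exponentially-weighted window (time constant `tau_r`). For `p = 2`
#'     the small-synchrony dependence is superlinear, which permits
#'     bistability.}
#' }
#'
#' @param mode `"direct"` or `"order_parameter"`.
#' @param amplitude maximal added rate, events/s.
#' @param kappa concentration of the direct-mode bump.
#' @param p exponent of the order-parameter mode.
#' @param tau_r averaging time constant of the order-parameter window, s.
#' @return an object of class `g_functional`.
#' @export
g_functional <- function(mode = c("direct", "order_parameter"),
                         amplitude = 10, kappa = 5, p = 2, tau_r = 1200) {
  mode <- match.arg(mode)
  stopifnot(amplitude >= 0, kappa > 0, p > 0, tau_r > 0)
  structure(list(mode = mode, amplitude = amplitude, kappa = kappa,
                 p = p, tau_r = tau_r), class = "g_functional")
}

#' Evaluate the feedback functional
#'
#' Direct mode takes the instantaneous phase difference; order-parameter
#' mode takes a window of recent phase differences (equal weights) and
#' returns `amplitude * R^p`. An empty window gives 0 with a warning.
#'
#' @param spec a [g_functional()].
#' @param phi phase difference (direct) or numeric window of phase
#'   differences (order-parameter mode).
#' @return added rate in events/s, in `[0, amplitude]`.
#' @export
evaluate_G <- function(spec, phi) {
  stopifnot(inherits(spec, "g_functional"))
  if (spec$mode == "direct")
    return(spec$amplitude * exp(spec$kappa * (cos(phi) - 1)))
  if (length(phi) == 0) {
    warning("empty phase window in order-parameter mode: G = 0")
    return(0)
  }
  spec$amplitude * circular_order_parameter(phi)^spec$p
}

#' Exact slow relaxation of the shared rate toward `lam_min + G`
#'
#' Over an inter-event interval `dt` the rate relaxes exponentially with
#' time constant `tau_lam` toward the target `lam_min + G_val`, then is
#' clipped to `[lam_min, lam_max]`. Matches the small-step Euler limit.
#'
#' @param lam current rate, events/s.
#' @param G_val feedback drive, events/s.
#' @param dt elapsed time, s.
#' @param tau_lam slow time constant, s.
#' @param lam_min,lam_max bounds, events/s.
#' @return updated rate.
#' @export
relax_lambda <- function(lam, G_val, dt, tau_lam, lam_min, lam_max = Inf) {
  stopifnot(dt >= 0, tau_lam > 0)
  target <- lam_min + G_val
  lam <- target + (lam - target) * exp(-dt / tau_lam)
  min(max(lam, lam_min), lam_max)
}

#' Default configuration of the reduced event-driven model
#'
#' @param omega angular frequency of both oscillators, rad/s.
#' @param prc a [prc_spec()].
#' @param kick_gain PRC kick magnitude.
#' @param lam_min,lam_max shared-rate bounds, events/s.
#' @param lam1,lam2 independent rates, events/s.
#' @param tau_lam slow time constant of the shared rate, s.
#' @param G a [g_functional()].
#' @param kick_eval PRC evaluation convention, see [map_step()].
#' @return a list of class `reduced_config`.
#' @export
reduced_config <- function(omega = 2 * pi * 40,
                           prc = prc_spec("type2", amplitude = 1),
                           kick_gain = 0.8,
                           lam_min = 0.05, lam_max = 10,
                           lam1 = 1.25, lam2 = 1.25,
                           tau_lam = 2400,
                           G = g_functional("direct", amplitude = 1.5,
                                            tau_r = 1200),
                           kick_eval = c("pre_drift", "post_drift")) {
  kick_eval <- match.arg(kick_eval)
  stopifnot(omega > 0, kick_gain >= 0, lam_min <= lam_max,
            lam1 >= 0, lam2 >= 0, tau_lam > 0,
            inherits(G, "g_functional"))
  structure(list(omega = omega, prc = prc, kick_gain = kick_gain,
                 lam_min = lam_min, lam_max = lam_max, lam1 = lam1,
                 lam2 = lam2, tau_lam = tau_lam, G = G,
                 kick_eval = kick_eval), class = "reduced_config")
}

#' Run the reduced event-driven model
#'
#' Iterates interval sampling, Gillespie event selection, the phase map,
#' evaluation of the feedback functional and exact slow relaxation of the
#' shared rate; records `(t, phi, lambda)` every `record_every` events.
#' Seed-deterministic.
#'
#' @param config a [reduced_config()].
#' @param n_events number of events to simulate.
#' @param seed integer root seed.
#' @param init list with optional `theta1`, `theta2`, `lam` initial values.
#' @param record_every recording stride in events.
#' @return an object of class `reduced_result`: data frame `trace`
#'   (`t`, `phi`, `lambda`) and named vector `final`.
#' @export
run_reduced <- function(config = reduced_config(), n_events = 20000,
                        seed = 1, init = list(), record_every = 1L) {
  stopifnot(inherits(config, "reduced_config"), n_events >= 1)
  theta1 <- wrap_phase(init$theta1 %||% 0)
  theta2 <- wrap_phase(init$theta2 %||% pi)
  lam0 <- init$lam %||% config$lam_min
  pr <- prc_to_cpp(config$prc)
  G <- config$G
  out <- .run_reduced_cpp(
    theta1, theta2, lam0, config$omega,
    pr$family, pr$amplitude, pr$table, config$kick_gain,
    config$lam_min, config$lam_max, config$lam1, config$lam2,
    config$tau_lam,
    if (G$mode == "direct") 0L else 1L, G$amplitude, G$kappa, G$p, G$tau_r,
    if (config$kick_eval == "pre_drift") 0L else 1L,
    as.integer(n_events), as.integer(record_every), as.numeric(seed))
  structure(list(
    trace = data.frame(t = out$t, phi = out$phi, lambda = out$lambda,
                       g = out$g),
    final = out$final, config = config, seed = seed,
    n_events = n_events), class = "reduced_result")
}

#' Phase-difference samples of a reduced run with the feedback frozen
#'
#' Convenience wrapper used to estimate the stationary phase-difference
#' density at a fixed common-input fraction `q`: the feedback amplitude is
#' set to zero and the rates are chosen so that
#' `q = lam / (lam + lam1 + lam2)` stays constant.
#'
#' @param q common-input fraction in `[0, 1)`.
#' @param prc a [prc_spec()].
#' @param kick_gain kick magnitude.
#' @param n_events number of map events.
#' @param seed integer seed.
#' @param omega angular frequency, rad/s.
#' @return numeric vector of phase differences in `(-pi, pi]`.
#' @export
frozen_q_samples <- function(q, prc = prc_spec("type2"), kick_gain = 0.1,
                             n_events = 1e6, seed = 1, omega = 2 * pi * 40) {
  stopifnot(q >= 0, q < 1)
  lam1 <- 1
  lam <- q * (lam1 + lam1) / (1 - q)
  cfg <- reduced_config(
    omega = omega, prc = prc, kick_gain = kick_gain,
    lam_min = lam, lam_max = lam, lam1 = lam1, lam2 = lam1,
    G = g_functional("direct", amplitude = 0))
  run_reduced(cfg, n_events = n_events, seed = seed,
              init = list(lam = lam))$trace$phi
}
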