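# The stationary phase-difference density is computed as the leading
# eigenvector of the discretized Frobenius-Perron operator of the event map:
# with probability q both oscillators are kicked (the difference moves by
# g * (Delta(u + phi) - Delta(u)), the base phase u marginalized over a
# uniform grid), with probability (1 - q) / 2 one of them is kicked (rigid
# shift -/+ g * Delta(u)). Kicked mass is scattered by periodic linear
# binning, which conserves mass exactly, so the kernel is column-stochastic
# by construction.

# periodic linear scatter: mass `weight` at positions `target` (one per
# (base-phase, source-bin) pair) accumulated into an n x n column-stochastic
# kernel by splitting each point over its two neighbouring bins
scatter_kernel <- function(target, cols, weight, n, h) {
  x <- (target + pi) / h + 0.5
  i0 <- floor(x)
  f <- x - i0
  i0 <- ((i0 - 1) %% n) + 1
  i1 <- (i0 %% n) + 1
  K <- Matrix::sparseMatrix(i = c(i0, i1), j = c(cols, cols),
                            x = c(weight * (1 - f), weight * f),
                            dims = c(n, n))
  as.matrix(K)
}

# builds the three elementary kick kernels (shared, kick on oscillator 1,
# kick on oscillator 2) on the midpoint grid; columns sum to 1
build_kernels <- function(prc, gain, n_grid) {
  stopifnot(n_grid >= 64)
  h <- 2 * pi / n_grid
  phi <- -pi + (seq_len(n_grid) - 0.5) * h
  u <- (seq_len(n_grid) - 0.5) * 2 * pi / n_grid
  du <- prc_eval(prc, u)
  wu <- 1 / n_grid
  U <- matrix(u, n_grid, n_grid)                    # base phase, rows
  P <- matrix(phi, n_grid, n_grid, byrow = TRUE)    # source bin, cols
  cols <- as.vector(col(P))
  # shared kick at base phase u: difference-dependent shift
  Ts <- as.vector(P + gain * (prc_eval(prc, U + P) - du))
  # kick on oscillator 2 / 1: rigid shift of the difference
  Tp <- as.vector(P + gain * du)
  Tm <- as.vector(P - gain * du)
  list(Ks = scatter_kernel(Ts, cols, wu, n_grid, h),
       Kp = scatter_kernel(Tp, cols, wu, n_grid, h),
       Km = scatter_kernel(Tm, cols, wu, n_grid, h),
       phi = phi, h = h, n = n_grid)
}

stationary_from_kernels <- function(kern, q, tol = 1e-12, max_iter = 50000,
                                    start = NULL) {
  K <- q * kern$Ks + (1 - q) / 2 * (kern$Kp + kern$Km)
  p <- if (is.null(start)) rep(1 / kern$n, kern$n) else start / sum(start)
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric(K %*% p)
    p_new <- p_new / sum(p_new)
    res <- max(abs(p_new - p))
    p <- p_new
    if (res < tol)
      return(structure(list(grid = kern$phi, rho = p / kern$h,
                            width = kern$h, q = q, iterations = it,
                            mass = p), class = "phase_density"))
  }
  stop("transfer-operator power iteration did not converge: residual ",
       format(res), " after ", max_iter, " iterations")
}

#' Stationary phase-difference density under partially shared kicks
#'
#' Solves for the stationary density `rho(phi; q)` of the phase difference
#' of two identical oscillators receiving PRC kicks that are shared with
#' probability `q` and independent otherwise, by power iteration on the
#' discretized transfer operator (converged to `tol` in sup norm). At
#' `q = 0` the density is uniform; as `q` grows it sharpens toward a delta
#' function at zero phase difference.
#'
#' @param q common-input fraction in `[0, 1)`.
#' @param prc a [prc_spec()].
#' @param gain kick magnitude `g`.
#' @param n_grid number of bins (at least 64).
#' @param tol power-iteration tolerance (sup norm of successive mass
#'   vectors).
#' @param max_iter iteration cap; exceeding it is an error.
#' @return a `phase_density` object (fields `grid`, `rho`, `width`, `q`).
#' @export
stationary_density <- function(q, prc = prc_spec("type2"), gain = 0.1,
                               n_grid = 256, tol = 1e-12, max_iter = 50000) {
  stopifnot(q >= 0, q < 1)
  kern <- build_kernels(prc, gain, n_grid)
  stationary_from_kernels(kern, q, tol = tol, max_iter = max_iter)
}

density_integral <- function(rho) sum(rho$rho) * rho$width

#' Synchrony order parameter of a phase-difference density
#'
#' `m = integral of cos(phi) * rho(phi) dphi` over the circle; for an even
#' density this equals the modulus of the mean resultant vector. The sine
#' component is computed as a check and warned about if it exceeds `1e-8`.
#'
#' @param rho a `phase_density` (must be normalized).
#' @return `m` in `[-1, 1]` (in practice `[0, 1]` for the densities of this
#'   model), with attribute `"sine_component"`.
#' @export
order_parameter_of_density <- function(rho) {
  stopifnot(inherits(rho, "phase_density"))
  tot <- density_integral(rho)
  if (abs(tot - 1) > 1e-6)
    stop("density is not normalized: integral = ", format(tot))
  m <- sum(cos(rho$grid) * rho$rho) * rho$width
  s <- sum(sin(rho$grid) * rho$rho) * rho$width
  # operator densities are even by symmetry; finite-sample histograms may not be
  from_operator <- !is.null(rho$q) && !is.na(rho$q)
  if (from_operator && abs(s) > 1e-8)
    warning("sine component ", format(s), " is not negligible")
  structure(m, sine_component = s)
}

#' Average a feedback functional against a phase-difference density
#'
#' Direct mode integrates `G(phi) rho(phi) dphi` by the midpoint rule
#' (spectrally accurate for smooth periodic integrands); order-parameter
#' mode returns `amplitude * m^p` with `m` the density's order parameter.
#'
#' @param G a [g_functional()].
#' @param rho a normalized `phase_density`.
#' @return the averaged drive, in `[0, amplitude]`.
#' @export
averaged_G <- function(G, rho) {
  stopifnot(inherits(G, "g_functional"), inherits(rho, "phase_density"))
  if (G$mode == "direct")
    return(sum(evaluate_G(G, rho$grid) * rho$rho) * rho$width)
  m <- max(0, as.numeric(order_parameter_of_density(rho)))
  G$amplitude * m^G$p
}

#' Convert between the shared rate and the common-input fraction
#'
#' `q = lam / (lam + lam1 + lam2)` and its inverse
#' `lam = q (lam1 + lam2) / (1 - q)`; the inverse has a vertical asymptote
#' at `q = 1`.
#'
#' @param lam shared rate; `lam1`, `lam2` independent rates (events/s).
#' @param q common-input fraction, must satisfy `q < 1` for the inverse.
#' @return the corresponding fraction / rate.
#' @export
q_from_lambda <- function(lam, lam1, lam2) {
  stopifnot(all(lam >= 0), lam1 >= 0, lam2 >= 0)
  lam / (lam + lam1 + lam2)
}

#' @rdname q_from_lambda
#' @export
lambda_from_q <- function(q, lam1, lam2) {
  if (any(q >= 1)) stop("q has a vertical asymptote at 1; need q < 1")
  stopifnot(all(q >= 0))
  q * (lam1 + lam2) / (1 - q)
}

#' Averaged slow dynamics of the shared rate
#'
#' Precomputes, on a grid of common-input fractions, the stationary density
#' `rho(phi; q)`, its order parameter `m(q)` and the unit-amplitude averaged
#' feedback, and exposes the averaged right-hand side
#' `d lam / dt = (lam_min - lam(q) + <G>(q)) / tau_lam`.
#'
#' @param config a [reduced_config()]; supplies the PRC, kick gain, rates,
#'   `tau_lam` and the feedback functional.
#' @param n_grid transfer-operator grid size.
#' @param q_n number of points of the `q` grid on `[0, q_max]`.
#' @param q_max upper cap of the grid (below the `q = 1` asymptote).
#' @return an object of class `averaged_dynamics` with spline interpolants
#'   `m_fun(q)` and `gbar_unit_fun(q)` plus the copied parameters.
#' @export
averaged_dynamics <- function(config = reduced_config(), n_grid = 256,
                              q_n = 101, q_max = 0.999) {
  stopifnot(inherits(config, "reduced_config"), q_n >= 11)
  kern <- build_kernels(config$prc, config$kick_gain, n_grid)
  qs <- seq(0, q_max, length.out = q_n)
  m_q <- numeric(q_n)
  gbar <- numeric(q_n)
  G1 <- config$G
  G1$amplitude <- 1
  start <- NULL
  for (i in seq_along(qs)) {
    rho <- stationary_from_kernels(kern, qs[i], start = start)
    start <- rho$mass
    m_q[i] <- as.numeric(order_parameter_of_density(rho))
    gbar[i] <- averaged_G(G1, rho)
  }
  structure(list(
    q = qs, m_q = m_q, gbar_unit = gbar,
    m_fun = stats::splinefun(qs, m_q, method = "natural"),
    gbar_unit_fun = stats::splinefun(qs, gbar, method = "natural"),
    lam_min = config$lam_min, lam1 = config$lam1, lam2 = config$lam2,
    tau_lam = config$tau_lam, G = config$G, config = config,
    n_grid = n_grid), class = "averaged_dynamics")
}

#' Averaged right-hand side of the slow rate dynamics
#'
#' @param q common-input fraction(s) in `[0, 1)`.
#' @param params an [averaged_dynamics()].
#' @param amplitude optional override of the feedback amplitude.
#' @return `d lam / dt` in events/s^2.
#' @export
averaged_rhs <- function(q, params, amplitude = params$G$amplitude) {
  stopifnot(inherits(params, "averaged_dynamics"), all(q >= 0), all(q < 1))
  gb <- pmax(0, params$gbar_unit_fun(q))
  (params$lam_min - lambda_from_q(q, params$lam1, params$lam2) +
     amplitude * gb) / params$tau_lam
}

#' Fixed points and stability of the averaged rate dynamics
#'
#' Locates all roots of the averaged right-hand side on `[0, q_max]` by
#' scanning a dense grid for sign changes and refining each bracket by
#' bisection to `1e-10` in `q`. Stability is the sign of the central
#' difference slope at the root. Since the right-hand side is non-negative
#' at `q = 0` and diverges to `-Inf` at the `q = 1` asymptote, at least one
#' stable fixed point always exists (violations indicate a solver bug and
#' raise an error).
#'
#' @param params an [averaged_dynamics()].
#' @param amplitude optional override of the feedback amplitude.
#' @param q_grid number of scan points (at least 200).
#' @return a data frame of class `fixed_point_set` with columns `q`, `lam`
#'   and `stability` (`"stable"` / `"unstable"`), ordered by `q`.
#' @export
find_fixed_points <- function(params, amplitude = params$G$amplitude,
                              q_grid = 400) {
  stopifnot(inherits(params, "averaged_dynamics"), q_grid >= 200)
  q_max <- max(params$q)
  qs <- seq(0, q_max, length.out = q_grid)
  f <- function(q) averaged_rhs(q, params, amplitude = amplitude)
  fs <- f(qs)
  roots <- numeric(0)
  if (fs[1] == 0) roots <- c(roots, qs[1])
  for (i in seq_len(q_grid - 1)) {
    if (fs[i] == 0 && i > 1) roots <- c(roots, qs[i])
    if (fs[i] * fs[i + 1] < 0) {
      r <- stats::uniroot(f, c(qs[i], qs[i + 1]), tol = 1e-10)$root
      roots <- c(roots, r)
    }
  }
  if (length(roots) == 0)
    stop("internal error: no fixed point found although one must exist")
  h <- 1e-5
  slope <- vapply(roots, function(r)
    (f(min(r + h, q_max)) - f(max(r - h, 0))) /
      (min(r + h, q_max) - max(r - h, 0)), numeric(1))
  out <- data.frame(q = roots,
                    lam = lambda_from_q(roots, params$lam1, params$lam2),
                    stability = ifelse(slope < 0, "stable", "unstable"))
  out <- out[order(out$q), , drop = FALSE]
  if (!any(out$stability == "stable"))
    stop("internal error: no stable fixed point although one must exist")
  class(out) <- c("fixed_point_set", class(out))
  out
}

#' Compare averaged-theory fixed points with reduced-model simulations
#'
#' For a sweep of feedback amplitudes, computes the stable fixed point(s) of
#' the averaged dynamics and runs `n_trials` reduced-model simulations from
#' random initial phase differences and rates, summarizing the terminal
#' shared rate of each trial by the mean of the last tenth of its
#' trajectory. In direct mode the trial median is compared with the single
#' stable rate; in order-parameter mode trials are split at the unstable
#' fixed point and both cluster centers are compared.
#'
#' @param params an [averaged_dynamics()].
#' @param amplitudes numeric vector of feedback amplitudes to sweep.
#' @param n_trials trials per amplitude.
#' @param n_events events per trial.
#' @param seed integer root seed.
#' @return a data frame with one row per amplitude: predicted stable rates
#'   (`lam_lo`, `lam_hi`, equal in direct mode), simulated cluster centers,
#'   relative errors and cluster occupancies.
#' @export
predict_vs_simulate <- function(params, amplitudes = params$G$amplitude,
                                n_trials = 50, n_events = 40000, seed = 1) {
  stopifnot(inherits(params, "averaged_dynamics"))
  cfg0 <- params$config
  rows <- lapply(seq_along(amplitudes), function(a_i) {
    A <- amplitudes[a_i]
    fp <- find_fixed_points(params, amplitude = A)
    stable <- fp[fp$stability == "stable", , drop = FALSE]
    unstable <- fp[fp$stability == "unstable", , drop = FALSE]
    lam_lo <- stable$lam[1]
    lam_hi <- stable$lam[nrow(stable)]
    cfg <- cfg0
    cfg$G$amplitude <- A
    term <- vapply(seq_len(n_trials), function(tr) {
      s <- derive_seed(seed, a_i * 1000 + tr)
      old <- save_rng_state(); on.exit(restore_rng_state(old))
      set.seed(s)
      init <- list(theta1 = stats::runif(1, 0, 2 * pi),
                   theta2 = stats::runif(1, 0, 2 * pi),
                   lam = stats::runif(1, cfg$lam_min,
                                      min(cfg$lam_max,
                                          cfg$lam_min + max(A, 1))))
      res <- run_reduced(cfg, n_events = n_events, seed = s, init = init,
                         record_every = 10L)
      tail_lam <- res$trace$lambda
      mean(tail_lam[seq(floor(0.9 * length(tail_lam)), length(tail_lam))])
    }, numeric(1))
    if (nrow(unstable) >= 1 && nrow(stable) >= 2) {
      thr <- unstable$lam[1]
      lo <- term[term < thr]; hi <- term[term >= thr]
      sim_lo <- if (length(lo)) median(lo) else NA_real_
      sim_hi <- if (length(hi)) median(hi) else NA_real_
      frac_hi <- length(hi) / length(term)
    } else {
      sim_lo <- sim_hi <- median(term)
      frac_hi <- NA_real_
    }
    data.frame(amplitude = A, n_stable = nrow(stable),
               lam_lo = lam_lo, lam_hi = lam_hi,
               sim_lo = sim_lo, sim_hi = sim_hi, frac_hi = frac_hi,
               rel_err_lo = abs(sim_lo - lam_lo) / max(lam_lo, 1e-12),
               rel_err_hi = abs(sim_hi - lam_hi) / max(lam_hi, 1e-12))
  })
  do.call(rbind, rows)
}

#' Monte-Carlo estimate of the stationary phase-difference density
#'
#' Samples the same stochastic phase-difference map whose transfer operator
#' [stationary_density()] diagonalizes: at each event the base phase is
#' drawn uniformly and the difference is shifted by the shared or
#' independent kick displacement. Many independent chains are advanced in
#' parallel and the first half of each is discarded as burn-in. This
#' estimator is an independent sampling route to the same density and is
#' used to cross-validate the operator solution.
#'
#' @param q common-input fraction in `[0, 1)`.
#' @param prc a [prc_spec()].
#' @param gain kick magnitude.
#' @param n_events number of retained map events across all chains.
#' @param n_chains number of parallel chains.
#' @param n_bins histogram bins of the returned density.
#' @param burn_in per-chain events discarded before retention starts.
#' @param seed integer seed.
#' @return a `phase_density` histogram estimate.
#' @export
mc_stationary_density <- function(q, prc = prc_spec("type2"), gain = 0.1,
                                  n_events = 1e6, n_chains = 800,
                                  n_bins = 64, burn_in = 1500, seed = 1) {
  stopifnot(q >= 0, q < 1, n_events >= n_chains)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  steps <- burn_in + ceiling(n_events / n_chains)
  phi <- stats::runif(n_chains, -pi, pi)
  keep_from <- burn_in + 1
  kept <- vector("list", steps - keep_from + 1)
  for (s in seq_len(steps)) {
    u <- stats::runif(n_chains, 0, 2 * pi)
    b <- stats::runif(n_chains)
    shared <- b < q
    osc1 <- !shared & b < q + (1 - q) / 2
    shift <- ifelse(shared,
                    gain * (prc_eval(prc, u + phi) - prc_eval(prc, u)),
                    ifelse(osc1, -gain * prc_eval(prc, u),
                           gain * prc_eval(prc, u)))
    phi <- wrap_phase_difference(0, phi + shift)
    if (s >= keep_from) kept[[s - keep_from + 1]] <- phi
  }
  phi_all <- unlist(kept)
  out <- phase_difference_histogram(c(phi_all, -phi_all), n_bins = n_bins)
  out$n <- length(phi_all)
  out$q <- q
  out
}
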