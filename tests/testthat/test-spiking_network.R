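test_that("noise-free LIF decays with the leak and spikes at the closed-form period", {
  p <- lif_params(tau_m = 0.005, sigma = 0)
  out <- integrate_lif(p, drive = 0, t_total = 0.05, dt = 1e-5, v0 = 0.5)
  expect_length(out$spikes, 0)
  expect_true(all(diff(out$v) <= 0))
  expect_lt(out$v[length(out$v)], 0.5 * exp(-0.04 / 0.005) + 1e-3)
  # constant suprathreshold drive I: period tau_m * log(I / (I - threshold))
  I <- 1.5
  out <- integrate_lif(p, drive = I, t_total = 0.5, dt = 2e-6)
  period_theory <- p$tau_m * log(I / (I - p$threshold))
  expect_equal(mean(diff(out$spikes)), period_theory, tolerance = 0.01)
  expect_error(integrate_lif(p, drive = c(1, NA, 1)), "NaN")
})

test_that("LIF firing rate is nondecreasing in the noise intensity", {
  rates <- sapply(c(2, 4, 8), function(sig) {
    mean(sapply(1:10, function(s) {
      p <- lif_params(tau_m = 0.005, sigma = sig)
      length(integrate_lif(p, drive = 0.8, t_total = 4, dt = 1e-4,
                           seed = 100 + s)$spikes) / 4
    }))
  })
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("synaptic drive follows exact exponential decay with jumps", {
  expect_equal(decay_and_jump_synapse(1, dt = 0.003, tau_s = 0.003),
               exp(-1), tolerance = 1e-12)
  expect_equal(decay_and_jump_synapse(0, dt = 0, tau_s = 0.003,
                                      n_spikes = 1, g = 2), 2)
  # exact update matches a fine Euler integration
  tau_s <- 0.004
  s_exact <- decay_and_jump_synapse(1.3, dt = tau_s, tau_s = tau_s)
  s_euler <- 1.3
  h <- tau_s / 1000
  for (i in 1:1000) s_euler <- s_euler - h / tau_s * s_euler
  expect_equal(s_exact, s_euler, tolerance = 1e-3)
  # and with a much finer step, to the stated accuracy
  s_euler <- 1.3
  h <- tau_s / 1e6
  for (i in 1:100) s_euler <- s_euler - h / tau_s * s_euler
  expect_equal(decay_and_jump_synapse(1.3, dt = 100 * h, tau_s = tau_s),
               s_euler, tolerance = 1e-6)
})

test_that("shared rate relaxes toward lam_min, jumps on granule spikes and clips", {
  st <- shared_rate_state(lam = 2, lam_min = 2, lam_max = 40,
                          tau_lam = 0.5, jump_a = 4)
  expect_equal(update_shared_rate(st, dt = 1)$lam, 2)    # fixed point
  st$lam <- 40
  expect_equal(update_shared_rate(st, dt = 0.5)$lam, 2 + 38 * exp(-1),
               tolerance = 1e-12)
  for (i in 1:100) st <- update_shared_rate(st, dt = 0.01,
                                            n_granule_spikes = 5)
  expect_equal(st$lam, 40)  # saturates at lam_max
})

test_that("kick event streams have Poisson counts and correct shared fraction", {
  ev <- draw_kick_events(0, c(0, 0), t_window = 5)
  expect_equal(nrow(ev), 0)
  ev <- draw_kick_events(100, c(0, 0), t_window = 10, seed = 4)
  expect_lt(abs(nrow(ev) - 1000), 4 * sqrt(1000))
  expect_true(all(diff(ev$t) >= 0))
  # shared fraction ~ lam / (lam + sum(lam_i))
  ev <- draw_kick_events(30, c(10, 20), t_window = 50, seed = 9)
  frac <- mean(ev$source == "shared")
  p <- 30 / 60
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / nrow(ev)))
})

test_that("invalid topologies are rejected", {
  expect_error(make_topology <- topology_nm(1), "n_mitral")
  expect_error(stochsync:::make_topology(2, list(1)), "at least 2")
  expect_error(stochsync:::make_topology(2, list(c(1, 3))), "out of range")
  # reciprocity broken by hand
  topo <- topology_2m1g()
  topo$mitral_feedback[[2]] <- integer(0)
  expect_error(run_spiking(topo, spiking_config(), t_total = 0.1),
               "reciprocity")
})

test_that("closed-loop run respects rate bounds and conserves event counts", {
  cfg <- spiking_config(g = 1.5)
  res <- suppressWarnings(run_spiking(topology_2m1g(), cfg, t_total = 5,
                                      seed = 42, record_events = TRUE))
  expect_true(all(res$lambda >= cfg$lam_min - 1e-12))
  expect_true(all(res$lambda <= cfg$lam_max + 1e-12))
  # kicks applied to mitral i = shared events routed to i + independent i
  ev <- res$events
  for (i in 1:2) {
    n_shared <- sum(ev$source == "shared" & ev$target == i)
    n_indep <- sum(ev$source == "independent" & ev$target == i)
    expect_equal(res$kick_counts[i, 1], n_shared)
    expect_equal(res$kick_counts[i, 2], n_indep)
  }
  # event timestamps nondecreasing
  expect_true(all(diff(ev$t) >= 0))
})

test_that("identical config and seed give bit-identical event logs", {
  cfg <- spiking_config(g = 1)
  r1 <- suppressWarnings(run_spiking(topology_2m1g(), cfg, t_total = 3,
                                     seed = 7, record_events = TRUE))
  r2 <- suppressWarnings(run_spiking(topology_2m1g(), cfg, t_total = 3,
                                     seed = 7, record_events = TRUE))
  expect_identical(r1$events, r2$events)
  expect_identical(r1$lambda, r2$lambda)
  r3 <- suppressWarnings(run_spiking(topology_2m1g(), cfg, t_total = 3,
                                     seed = 8, record_events = TRUE))
  expect_false(identical(r1$events, r3$events))
})

test_that("with zero coupling the granule rate matches the open-loop LIF", {
  # nonzero rate regime: subthreshold bias plus noise
  lif <- lif_params(tau_m = 0.0015, bias = 0.85, sigma = 4)
  cfg <- spiking_config(g = 0, lif = lif)
  closed <- sapply(1:5, function(s)
    suppressWarnings(run_spiking(topology_2m1g(), cfg, t_total = 10,
                                 seed = s))$granule_spikes / 10)
  open <- sapply(1:5, function(s)
    length(integrate_lif(lif, drive = 0, t_total = 10, dt = cfg$dt,
                         seed = 1000 + s)$spikes) / 10)
  se <- sqrt(stats::var(closed) / 5 + stats::var(open) / 5)
  expect_lt(abs(mean(closed) - mean(open)), 4 * se + 0.5)
})

test_that("3M-3G network peaks are lower than 2M-1G at matched coupling", {
  p2 <- c(); p3 <- c()
  for (s in 1:5) {
    r2 <- run_spiking(topology_2m1g(), spiking_config(g = 1.5),
                      t_total = 40, seed = s)
    r3 <- run_spiking(topology_3m3g(), spiking_config(g = 1.5),
                      t_total = 40, seed = s)
    h2 <- phase_difference_histogram(r2$phi[r2$time > 3], 24)
    phi3 <- wrap_phase_difference(r3$theta[r3$time > 3, 1],
                                  r3$theta[r3$time > 3, 2])
    h3 <- phase_difference_histogram(phi3, 24)
    p2 <- c(p2, h2$rho[which.min(abs(h2$grid))])
    p3 <- c(p3, h3$rho[which.min(abs(h3$grid))])
  }
  expect_gt(mean(p2), mean(p3))
})

test_that("open-loop granule count is symmetric in the sign of the lag", {
  cfg <- spiking_config(g = 1.25, tau_s = 0.005)
  fp <- mean(granule_rate_vs_phase(rep(0.8, 6), cfg, window = 5, seed = 3))
  fm <- mean(granule_rate_vs_phase(rep(-0.8, 6), cfg, window = 5, seed = 4))
  expect_lt(abs(fp - fm) / max(fp, fm), 0.2)
})
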