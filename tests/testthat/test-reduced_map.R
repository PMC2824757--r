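test_that("inter-event intervals are exponential with the merged rate", {
  set.seed(1)
  x <- sample_interval(2, n = 1e5)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 0.5), 4 * 0.5 / sqrt(1e5))
  y <- sample_interval(4, n = 1e5)
  expect_equal(mean(x) / mean(y), 2, tolerance = 0.05)
  expect_error(sample_interval(0), "positive")
})

test_that("Gillespie selection reproduces the stream probabilities", {
  set.seed(2)
  ev <- select_event(1, 0.5, 0.5, n = 1e5)
  p_shared <- mean(ev$kind == "shared")
  expect_lt(abs(p_shared - 0.5), 4 * sqrt(0.25 / 1e5))
  # indicator structure
  expect_true(all(ev$k1[ev$kind == "shared"] == 1 &
                  ev$k2[ev$kind == "shared"] == 1))
  expect_true(all(ev$k2[ev$kind == "indep1"] == 0))
  # frequencies within 4 sigma of the multinomial expectation
  ev <- select_event(2, 1, 3, n = 1e5)
  for (kk in list(c("shared", 2), c("indep1", 1), c("indep2", 3))) {
    p <- as.numeric(kk[2]) / 6
    expect_lt(abs(mean(ev$kind == kk[1]) - p), 4 * sqrt(p * (1 - p) / 1e5))
  }
  expect_true(all(select_event(0, 1, 1, n = 1000)$kind != "shared"))
  expect_error(select_event(0, 0, 0), "zero")
})

test_that("the event map honors drift, kick indicators and synchrony", {
  prc <- prc_spec("type2")
  st <- list(theta1 = 0.7, theta2 = 2.1, t = 0)
  # a full free period leaves phases unchanged
  st2 <- map_step(st, dt = 1 / 40, ev = list(k1 = 0, k2 = 0), prc, gain = 0.5)
  expect_equal(st2$theta1, st$theta1, tolerance = 1e-9)
  expect_equal(st2$theta2, st$theta2, tolerance = 1e-9)
  # shared kicks preserve exact synchrony
  st <- list(theta1 = 1.2, theta2 = 1.2, t = 0)
  st2 <- map_step(st, dt = 0.013, ev = list(k1 = 1, k2 = 1), prc, gain = 0.6)
  expect_equal(st2$theta1, st2$theta2)
  # an independent kick leaves the other oscillator drift-only
  st <- list(theta1 = 0.4, theta2 = 2.5, t = 0)
  st2 <- map_step(st, dt = 0.002, ev = list(k1 = 1, k2 = 0), prc, gain = 0.6)
  expect_equal(st2$theta2, wrap_phase(2.5 + 2 * pi * 40 * 0.002))
  # pre-drift vs post-drift kick evaluation differ by O(g * omega * dt)
  a <- map_step(st, 0.002, list(k1 = 1, k2 = 0), prc, 0.6,
                kick_eval = "pre_drift")
  b <- map_step(st, 0.002, list(k1 = 1, k2 = 0), prc, 0.6,
                kick_eval = "post_drift")
  expect_false(isTRUE(all.equal(a$theta1, b$theta1)))
})

test_that("feedback functionals evaluate their defining forms", {
  Gd <- g_functional("direct", amplitude = 5, kappa = 5)
  expect_equal(evaluate_G(Gd, 0), 5)
  expect_equal(evaluate_G(Gd, pi), 5 * exp(-10), tolerance = 1e-12)
  expect_true(all(diff(evaluate_G(Gd, seq(0, pi, length.out = 20))) < 0))
  Go <- g_functional("order_parameter", amplitude = 5, p = 2)
  expect_equal(evaluate_G(Go, rep(0, 50)), 5)
  expect_equal(evaluate_G(Go, 2 * pi * (0:9) / 10), 0, tolerance = 1e-12)
  expect_warning(g0 <- evaluate_G(Go, numeric(0)), "empty")
  expect_equal(g0, 0)
})

test_that("slow rate relaxation is exact and clipped", {
  expect_equal(relax_lambda(2, G_val = 0, dt = 10, tau_lam = 1, lam_min = 2), 2)
  expect_equal(relax_lambda(0.5, G_val = 3, dt = 1e9, tau_lam = 1,
                            lam_min = 0.5), 3.5)
  expect_equal(relax_lambda(9, G_val = 3, dt = 1e9, tau_lam = 1,
                            lam_min = 0.5, lam_max = 3), 3)
  # matches a small-step Euler integration
  lam_e <- 1.7
  h <- 1e-4
  for (i in 1:100) lam_e <- lam_e + h / 2 * (0.5 + 3 - lam_e)
  expect_equal(relax_lambda(1.7, 3, dt = 100 * h, tau_lam = 2, lam_min = 0.5),
               lam_e, tolerance = 1e-6)
})

test_that("shared-kick-only dynamics keep synchronized oscillators synchronized", {
  cfg <- reduced_config(lam1 = 0, lam2 = 0, lam_min = 2, lam_max = 2,
                        G = g_functional("direct", amplitude = 0))
  res <- run_reduced(cfg, n_events = 5000, seed = 3,
                     init = list(theta1 = 1.1, theta2 = 1.1, lam = 2))
  expect_true(all(abs(res$trace$phi) < 1e-9))
})

test_that("the shared rate stays within its invariant range", {
  cfg <- reduced_config(G = g_functional("direct", amplitude = 1.5))
  res <- run_reduced(cfg, n_events = 30000, seed = 5,
                     init = list(lam = 1.2))
  expect_true(all(res$trace$lambda >= cfg$lam_min - 1e-12))
  expect_true(all(res$trace$lambda <=
                    cfg$lam_min + cfg$G$amplitude + 1e-9))
  # seed determinism
  r2 <- run_reduced(cfg, n_events = 30000, seed = 5, init = list(lam = 1.2))
  expect_identical(res$trace, r2$trace)
})

test_that("frozen-feedback phase differences match the stationary density", {
  q <- 0.5
  phis <- frozen_q_samples(q, prc_spec("type2"), kick_gain = 0.6,
                           n_events = 1e6, seed = 11)
  h <- phase_difference_histogram(phis[-(1:2000)], n_bins = 64)
  rho <- stationary_density(q, prc_spec("type2"), gain = 0.6, n_grid = 256)
  expect_lt(l1_density(h, aggregate_density(rho, 64)), 0.05)
})

test_that("time rescaling leaves normalized trajectories invariant", {
  base <- reduced_config(G = g_functional("direct", amplitude = 6))
  c_fac <- 4
  fast <- reduced_config(
    lam_min = base$lam_min * c_fac, lam_max = base$lam_max * c_fac,
    lam1 = base$lam1 * c_fac, lam2 = base$lam2 * c_fac,
    tau_lam = base$tau_lam / c_fac,
    G = g_functional("direct", amplitude = base$G$amplitude * c_fac,
                     tau_r = base$G$tau_r / c_fac))
  r1 <- run_reduced(base, n_events = 60000, seed = 21, init = list(lam = 1))
  r2 <- run_reduced(fast, n_events = 60000, seed = 22,
                    init = list(lam = c_fac))
  tail1 <- r1$trace[-(1:20000), ]
  tail2 <- r2$trace[-(1:20000), ]
  expect_equal(stats::median(tail2$lambda) / c_fac,
               stats::median(tail1$lambda), tolerance = 0.1)
  expect_equal(abs(mean(cos(tail2$phi))), abs(mean(cos(tail1$phi))),
               tolerance = 0.1)
})
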