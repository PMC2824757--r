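# shared fixtures: averaged dynamics tables built once per run
avg_direct <- averaged_dynamics(
  reduced_config(G = g_functional("direct", amplitude = 1.5)),
  n_grid = 256, q_n = 41)
avg_order <- averaged_dynamics(
  reduced_config(G = g_functional("order_parameter", amplitude = 22,
                                  tau_r = 38400), tau_lam = 38400),
  n_grid = 256, q_n = 41)

test_that("the discretized transfer operator conserves probability mass", {
  for (gain in c(0.1, 0.6)) {
    kern <- stochsync:::build_kernels(prc_spec("type2"), gain, 128)
    for (K in list(kern$Ks, kern$Kp, kern$Km)) {
      expect_lt(max(abs(colSums(K) - 1)), 1e-12)
      expect_true(all(K >= 0))
    }
  }
})

test_that("independent kicks leave the phase difference uniform (q = 0)", {
  rho <- stationary_density(0, prc_spec("type2"), gain = 0.1, n_grid = 128)
  expect_lt(max(abs(rho$rho - 1 / (2 * pi))), 1e-8)
})

test_that("stationary density sharpens with the common-input fraction", {
  m3 <- order_parameter_of_density(
    stationary_density(0.3, prc_spec("type2"), gain = 0.1))
  m9 <- order_parameter_of_density(
    stationary_density(0.9, prc_spec("type2"), gain = 0.1))
  expect_gt(as.numeric(m9), as.numeric(m3))
  expect_lt(abs(attr(m3, "sine_component")), 1e-8)
})

test_that("operator density agrees with the Monte-Carlo phase-map estimate", {
  rho <- stationary_density(0.6, prc_spec("type2"), gain = 0.1, n_grid = 256)
  mc <- mc_stationary_density(0.6, prc_spec("type2"), gain = 0.1,
                              n_events = 5e5, n_chains = 400, n_bins = 32,
                              seed = 5)
  expect_lt(l1_density(mc, aggregate_density(rho, 32)), 0.08)
})

test_that("order parameter of elementary densities", {
  n <- 128
  h <- 2 * pi / n
  grid <- -pi + (seq_len(n) - 0.5) * h
  uni <- structure(list(grid = grid, rho = rep(1 / (2 * pi), n), width = h,
                        q = 0), class = "phase_density")
  expect_equal(as.numeric(order_parameter_of_density(uni)), 0,
               tolerance = 1e-12)
  # von-Mises-like concentration approaches 1
  for (kap in c(5, 50)) {
    rho <- exp(kap * (cos(grid) - 1))
    rho <- rho / (sum(rho) * h)
    conc <- structure(list(grid = grid, rho = rho, width = h, q = NA),
                      class = "phase_density")
    expect_gt(as.numeric(order_parameter_of_density(conc)),
              c(0.85, 0.98)[match(kap, c(5, 50))])
  }
  bad <- uni
  bad$rho <- bad$rho * 2
  expect_error(order_parameter_of_density(bad), "not normalized")
})

test_that("averaging a functional against a density", {
  rho0 <- stationary_density(0, prc_spec("type2"), gain = 0.1, n_grid = 256)
  # near-constant functional averages to its amplitude
  expect_equal(averaged_G(g_functional("direct", amplitude = 3,
                                       kappa = 1e-9), rho0),
               3, tolerance = 1e-8)
  # uniform-density average of the peaked bump: exp(-kappa) * I0(kappa)
  got <- averaged_G(g_functional("direct", amplitude = 1, kappa = 5), rho0)
  expect_equal(got, besselI(5, 0, expon.scaled = TRUE), tolerance = 1e-10)
  # order mode at q = 0: m = 0 so the drive vanishes
  expect_equal(averaged_G(g_functional("order_parameter", amplitude = 7),
                          rho0), 0, tolerance = 1e-12)
})

test_that("shared-rate and common-input fraction conversions invert", {
  expect_equal(q_from_lambda(2, 1, 1), 0.5)
  set.seed(8)
  for (i in 1:20) {
    l1 <- runif(1, 0.1, 5); l2 <- runif(1, 0.1, 5); lam <- runif(1, 0, 50)
    q <- q_from_lambda(lam, l1, l2)
    expect_equal(lambda_from_q(q, l1, l2), lam, tolerance = 1e-12)
  }
  expect_error(lambda_from_q(1, 1, 1), "asymptote")
})

test_that("averaged right-hand side is finite and brackets the fixed points", {
  qs <- seq(0, 0.99, length.out = 200)
  v <- averaged_rhs(qs, avg_direct)
  expect_true(all(is.finite(v)))
  fp <- find_fixed_points(avg_direct)
  # rhs changes sign exactly at the located roots (bisection oracle)
  for (r in fp$q) {
    expect_lt(averaged_rhs(min(r + 0.01, 0.99), avg_direct) *
                averaged_rhs(max(r - 0.01, 0), avg_direct), 0)
  }
  # with no feedback the unique fixed point is lam = lam_min
  fp0 <- find_fixed_points(avg_direct, amplitude = 0)
  expect_equal(nrow(fp0), 1)
  expect_equal(fp0$stability, "stable")
  expect_equal(fp0$lam, avg_direct$lam_min, tolerance = 1e-6)
})

test_that("direct peaked feedback always yields exactly one stable state", {
  for (A in c(0.3, 0.8, 1.5, 3, 6)) {
    fp <- find_fixed_points(avg_direct, amplitude = A)
    expect_equal(sum(fp$stability == "stable"), 1)
  }
})

test_that("order-parameter feedback yields the bistable fixed-point pattern", {
  fp <- find_fixed_points(avg_order, amplitude = 22)
  expect_equal(nrow(fp), 3)
  expect_equal(fp$stability, c("stable", "unstable", "stable"))
  expect_equal(nrow(fp) %% 2, 1)  # odd root count, alternating stability
  # averaged order-mode feedback grows like q^2 for small q
  qs <- avg_order$q[avg_order$q > 0.005 & avg_order$q < 0.06]
  slope <- coef(lm(log(avg_order$gbar_unit_fun(qs)) ~ log(qs)))[2]
  expect_equal(as.numeric(slope), 2, tolerance = 0.1)
})

test_that("direct averaged feedback is monotone and never produces bistability", {
  g <- avg_direct$gbar_unit
  expect_true(all(diff(g) > 0))  # nondecreasing drive
  expect_true(all(g >= 0 & g <= 1 + 1e-9))
  # the no-bistability conclusion holds across four decades of amplitude
  for (A in 10^seq(-1, 3, length.out = 9)) {
    fp <- find_fixed_points(avg_direct, amplitude = A)
    expect_equal(sum(fp$stability == "stable"), 1)
    expect_equal(nrow(fp), 1)
  }
})

test_that("zero-amplitude prediction and simulation coincide at lam_min", {
  pv <- predict_vs_simulate(avg_direct, amplitudes = 0, n_trials = 3,
                            n_events = 60000, seed = 2)
  expect_equal(pv$lam_lo, avg_direct$lam_min, tolerance = 1e-6)
  expect_lt(abs(pv$sim_lo - avg_direct$lam_min), 0.02)
})
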