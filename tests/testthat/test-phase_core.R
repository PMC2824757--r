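test_that("phase drift wraps correctly and preserves differences", {
  # one full 40 Hz cycle returns to the same phase
  st <- phase_state(0, omega = 2 * pi * 40)
  expect_equal(advance_phase(st, 0.025)$theta, 0)
  # quarter cycle at 1 Hz angular frequency 2*pi
  st <- phase_state(pi / 2, omega = 2 * pi)
  expect_equal(advance_phase(st, 0.25)$theta, pi)
  # equal-frequency advance leaves the phase difference exactly constant
  st <- phase_state(c(0.3, 1.7))
  for (dt in c(0.001, 0.0137, 0.2)) {
    st2 <- advance_phase(st, dt)
    expect_equal(wrap_phase_difference(st2$theta[1], st2$theta[2]),
                 wrap_phase_difference(st$theta[1], st$theta[2]),
                 tolerance = 1e-12)
  }
  expect_error(advance_phase(st, -0.1), "non-negative")
})

test_that("PRC kicks follow theta + g * Delta(theta) with wrapping", {
  prc <- prc_spec("type2", amplitude = 1)
  expect_equal(apply_kick(0, prc, 0.5), 0)            # sin(0) = 0
  expect_equal(apply_kick(pi / 2, prc, 0.1), pi / 2 + 0.1)
  # kick past 2*pi wraps back into [0, 2*pi)
  th <- apply_kick(2 * pi - 0.01, prc, 3)
  expect_true(th >= 0 && th < 2 * pi)
  # type1 family is nonnegative: amplitude * (1 - cos)
  prc1 <- prc_spec("type1", amplitude = 0.5)
  expect_equal(prc_eval(prc1, pi), 1)
  expect_true(all(prc_eval(prc1, seq(0, 2 * pi, length.out = 50)) >= 0))
  # tabulated PRC interpolates its own nodes and is periodic
  grid <- 2 * pi * (0:63) / 64
  tab <- prc_spec("tabulated", amplitude = 2, table = sin(grid))
  expect_equal(prc_eval(tab, grid), 2 * sin(grid), tolerance = 1e-12)
  expect_equal(prc_eval(tab, grid + 2 * pi), prc_eval(tab, grid),
               tolerance = 1e-12)
})

test_that("phase differences wrap to (-pi, pi] with the +pi tie convention", {
  expect_equal(wrap_phase_difference(0.1, 0.1), 0)
  expect_equal(wrap_phase_difference(0, pi), pi)   # boundary maps to +pi
  expect_equal(wrap_phase_difference(pi, 0), pi)   # -pi also maps to +pi
  expect_equal(wrap_phase_difference(6.0, 0.2), 0.2 - 6.0 + 2 * pi,
               tolerance = 1e-12)
  x <- seq(-20, 20, length.out = 999)
  w <- wrap_phase_difference(0, x)
  expect_true(all(w > -pi & w <= pi))
})

test_that("phase wrapping is closed under random advance/kick compositions", {
  set.seed(42)
  n <- 1e5
  prc <- prc_spec("type2", amplitude = 1)
  th <- runif(n, 0, 2 * pi)
  st <- phase_state(th)
  for (i in 1:5) {
    st <- advance_phase(st, runif(1, 0, 0.1))
    st$theta <- apply_kick(st$theta, prc, runif(1, 0, 2))
  }
  expect_true(all(st$theta >= 0 & st$theta < 2 * pi))
})

test_that("phase-difference histogram is a normalized density", {
  # all mass in one bin for identical samples
  h <- phase_difference_histogram(rep(0, 100), n_bins = 16)
  expect_equal(sum(h$rho) * h$width, 1, tolerance = 1e-12)
  expect_equal(sum(h$rho > 0), 1)
  # uniform grid of samples gives the uniform density
  h <- phase_difference_histogram(seq(-pi + 1e-9, pi, length.out = 64000),
                                  n_bins = 64)
  expect_true(max(abs(h$rho - 1 / (2 * pi))) < 1e-3)
  # estimator converges to uniform for many random samples
  set.seed(7)
  h <- phase_difference_histogram(runif(1e6, -pi, pi), n_bins = 64)
  expect_lt(sum(abs(h$rho - 1 / (2 * pi))) * h$width, 0.01)
  expect_error(phase_difference_histogram(numeric(0)), "at least one")
})

test_that("circular order parameter behaves like |mean resultant vector|", {
  expect_equal(circular_order_parameter(rep(1.3, 10)), 1)
  expect_equal(circular_order_parameter(2 * pi * (0:9) / 10), 0,
               tolerance = 1e-12)
  expect_equal(circular_order_parameter(c(0, pi)), 0, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    r <- circular_order_parameter(runif(50, -pi, pi))
    expect_true(r >= 0 && r <= 1)
  }
  # R = 1 only when all phases coincide
  expect_lt(circular_order_parameter(c(0, 0, 1e-3)), 1)
  expect_error(circular_order_parameter(numeric(0)), "at least one")
})

test_that("phase offsets convert to spike-time offsets in ms", {
  expect_equal(phase_to_time(2 * pi, 40), 25)
  expect_equal(phase_to_time(0.75, 40), 2.984155, tolerance = 1e-6)
  expect_equal(phase_to_time(0, 77), 0)
  expect_error(phase_to_time(1, 0), "positive")
})

test_that("tabulated PRCs round-trip through two-column CSV", {
  grid <- 2 * pi * (0:31) / 32
  prc <- prc_spec("tabulated", amplitude = 1, table = 0.3 * sin(grid))
  path <- withr::local_tempfile(fileext = ".csv")
  prc_table_write(prc, path)
  back <- prc_table_read(path)
  expect_equal(prc_eval(back, grid), prc_eval(prc, grid), tolerance = 1e-12)
})
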