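#' Wrap angles into the canonical phase interval [0, 2*pi)
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to `[0, 2*pi)`.
#' @export
wrap_phase <- function(theta) {
  th <- theta %% (2 * pi)
  th[th == 2 * pi] <- 0
  th
}

#' Construct the state of a set of mitral-cell phase oscillators
#'
#' Phases live on `[0, 2*pi)`; all oscillators share one natural angular
#' frequency `omega` (mitral cells firing in a narrow gamma-band range are
#' treated as identical limit-cycle oscillators).
#'
#' @param theta numeric vector of phases in radians; wrapped into `[0, 2*pi)`.
#' @param omega angular frequency in radians per second; must be positive.
#'   Default corresponds to 40 Hz gamma-band firing.
#' @return an object of class `phase_state` with fields `theta` and `omega`.
#' @examples
#' st <- phase_state(c(0, pi / 2))
#' advance_phase(st, 0.0125)  # half a 40 Hz cycle
#' @export
phase_state <- function(theta, omega = 2 * pi * 40) {
  stopifnot(is.numeric(theta), length(theta) >= 1)
  if (!is.numeric(omega) || length(omega) != 1 || omega <= 0)
    stop("`omega` must be a single positive angular frequency (rad/s)")
  structure(list(theta = wrap_phase(theta), omega = omega),
            class = "phase_state")
}

#' Specify a phase resetting curve (PRC)
#'
#' The PRC `Delta(theta)` gives the phase shift produced by an impulsive
#' input arriving at phase `theta`. Families:
#' \describe{
#'   \item{type1}{`amplitude * (1 - cos(theta))`, non-negative.}
#'   \item{type2}{`amplitude * sin(theta)`, sinusoidal. The default, since
#'     measured mitral-cell PRCs are near-sinusoidal.}
#'   \item{tabulated}{sampled values on a uniform `[0, 2*pi)` grid,
#'     interpolated periodically (linear).}
#' }
#'
#' @param family one of `"type2"`, `"type1"`, `"tabulated"`.
#' @param amplitude dimensionless scale of the curve.
#' @param table for `family = "tabulated"`, numeric vector of `Delta` values
#'   sampled at `theta = 2*pi*(0:(n-1))/n`.
#' @return an object of class `prc_spec`.
#' @export
prc_spec <- function(family = c("type2", "type1", "tabulated"),
                     amplitude = 1, table = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1)
  if (family == "tabulated") {
    if (is.null(table) || length(table) < 4 || anyNA(table))
      stop("a tabulated PRC needs >= 4 finite sampled values")
  } else {
    table <- NULL
  }
  structure(list(family = family, amplitude = amplitude, table = table),
            class = "prc_spec")
}

#' Evaluate a phase resetting curve
#'
#' @param prc a [prc_spec()].
#' @param theta numeric vector of phases (any real; wrapped).
#' @return `Delta(theta)`, vectorized.
#' @export
prc_eval <- function(prc, theta) {
  stopifnot(inherits(prc, "prc_spec"))
  th <- wrap_phase(theta)
  switch(prc$family,
    type1 = prc$amplitude * (1 - cos(th)),
    type2 = prc$amplitude * sin(th),
    tabulated = {
      n <- length(prc$table)
      x <- th * n / (2 * pi)
      i0 <- floor(x)
      f <- x - i0
      i0 <- (i0 %% n) + 1
      i1 <- (i0 %% n) + 1
      prc$amplitude * ((1 - f) * prc$table[i0] + f * prc$table[i1])
    })
}

#' Advance phase oscillators by free drift
#'
#' Each phase moves by `omega * dt` and is wrapped back into `[0, 2*pi)`.
#' With equal frequencies the phase difference is exactly preserved.
#'
#' @param state a [phase_state()].
#' @param dt time step in seconds, non-negative.
#' @return the advanced `phase_state`.
#' @export
advance_phase <- function(state, dt) {
  stopifnot(inherits(state, "phase_state"))
  if (!is.numeric(dt) || length(dt) != 1 || is.na(dt) || dt < 0)
    stop("`dt` must be a single non-negative time step (s); got ", format(dt))
  state$theta <- wrap_phase(state$theta + state$omega * dt)
  state
}

#' Apply a PRC kick to a phase
#'
#' Returns `(theta + g * Delta(theta)) mod 2*pi`: an impulsive input at phase
#' `theta` shifts the next spike time through the phase resetting curve,
#' scaled by the kick magnitude `g`.
#'
#' @param theta numeric vector of phases; values outside `[0, 2*pi)` are
#'   wrapped on input.
#' @param prc a [prc_spec()].
#' @param gain kick magnitude `g >= 0`.
#' @return kicked phases in `[0, 2*pi)`.
#' @export
apply_kick <- function(theta, prc, gain) {
  stopifnot(is.numeric(gain), length(gain) == 1, gain >= 0)
  th <- wrap_phase(theta)
  wrap_phase(th + gain * prc_eval(prc, th))
}

#' Wrap a phase difference to (-pi, pi]
#'
#' Computes `theta2 - theta1` wrapped to the symmetric interval; the boundary
#' tie at +/-pi maps to `+pi` (documented convention).
#'
#' @param theta1,theta2 numeric vectors of phases in radians.
#' @return phase differences in `(-pi, pi]`.
#' @export
wrap_phase_difference <- function(theta1, theta2) {
  d <- (theta2 - theta1) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

#' Histogram estimate of the phase-difference density
#'
#' Bins samples of the phase difference on `(-pi, pi]` into `n_bins` equal
#' bins and normalizes to a probability density (total mass 1).
#'
#' @param phi numeric vector of phase differences (wrapped on input).
#' @param n_bins number of bins, at least 2.
#' @param weights optional non-negative sample weights.
#' @return an object of class `phase_density` with fields `grid` (bin
#'   centers), `rho` (density values), `width` (bin width) and `n` (sample
#'   count).
#' @export
phase_difference_histogram <- function(phi, n_bins = 64, weights = NULL) {
  if (length(phi) < 1) stop("need at least one phase-difference sample")
  stopifnot(n_bins >= 2)
  phi <- wrap_phase_difference(0, phi)
  h <- 2 * pi / n_bins
  # bins are (-pi + (i-1)h, -pi + i h]; the tie at +pi lands in the last bin
  idx <- ceiling((phi + pi) / h)
  idx[idx < 1] <- 1
  idx[idx > n_bins] <- n_bins
  if (is.null(weights)) weights <- rep(1, length(phi))
  stopifnot(length(weights) == length(phi), all(weights >= 0))
  # empty bins must be kept: sum weights within every bin explicitly
  mass <- vapply(split(weights, factor(idx, levels = seq_len(n_bins))),
                 sum, numeric(1))
  mass <- unname(mass) / sum(mass)
  structure(list(grid = -pi + (seq_len(n_bins) - 0.5) * h,
                 rho = mass / h, width = h, n = length(phi), q = NA_real_),
            class = "phase_density")
}

#' Circular (Kuramoto) order parameter
#'
#' Modulus of the mean resultant vector `R = |mean(exp(1i * phi))|`;
#' 0 means uniform/asynchronous, 1 means all phases identical.
#'
#' @param phis numeric vector of angles in radians, non-empty.
#' @return `R` in `[0, 1]`.
#' @export
circular_order_parameter <- function(phis) {
  if (length(phis) < 1) stop("need at least one phase sample")
  sqrt(mean(cos(phis))^2 + mean(sin(phis))^2)
}

#' Convert a phase offset to a spike-time offset
#'
#' A phase offset of `phi` radians for an oscillator at `frequency` Hz
#' corresponds to `phi / (2*pi) * 1000 / frequency` milliseconds. For
#' oscillators running at 40 Hz, 0.75 rad is about 3 ms.
#'
#' @param phi phase offset in radians.
#' @param frequency oscillation frequency in Hz, positive.
#' @return time offset in milliseconds.
#' @examples
#' phase_to_time(0.75, 40)  # ~ 3 ms
#' @export
phase_to_time <- function(phi, frequency) {
  if (!is.numeric(frequency) || length(frequency) != 1 || frequency <= 0)
    stop("`frequency` must be a single positive value in Hz")
  phi / (2 * pi) * 1000 / frequency
}

#' Read / write a tabulated PRC as two-column CSV
#'
#' The file has columns `theta` (uniform grid on `[0, 2*pi)`) and `delta`.
#'
#' @param path CSV file path.
#' @param prc a tabulated [prc_spec()] (for writing).
#' @return for reading, a `prc_spec` of family `"tabulated"` with the table
#'   scaled by the file values and `amplitude = 1`.
#' @export
prc_table_read <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("theta", "delta") %in% names(d)))
  n <- nrow(d)
  expect_grid <- 2 * pi * (0:(n - 1)) / n
  if (max(abs(sort(d$theta) - expect_grid)) > 1e-8)
    stop("`theta` column must be a uniform grid on [0, 2*pi)")
  prc_spec("tabulated", amplitude = 1, table = d$delta[order(d$theta)])
}

#' @rdname prc_table_read
#' @export
prc_table_write <- function(prc, path) {
  stopifnot(inherits(prc, "prc_spec"), prc$family == "tabulated")
  n <- length(prc$table)
  utils::write.csv(
    data.frame(theta = 2 * pi * (0:(n - 1)) / n,
               delta = prc$amplitude * prc$table),
    path, row.names = FALSE)
  invisible(path)
}

#' @export
print.phase_density <- function(x, ...) {
  cat("phase-difference density on (-pi, pi]:", length(x$grid), "bins")
  if (!is.na(x$q)) cat(", q =", format(x$q))
  m <- sum(cos(x$grid) * x$rho) * x$width
  cat(", order parameter m =", format(round(m, 4)), "\n")
  invisible(x)
}
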