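# Small configurations shared by the unit tests: shorter runs than the
# shipped experiment defaults, identical structure.

test_spiking_config <- function(...) {
  spiking_config(...)
}

# reduced-model configuration with the shipped study parameters
test_reduced_config <- function(...) {
  reduced_config(...)
}

# L1 distance between two densities on matched grids
l1_density <- function(a, b) {
  stopifnot(length(a$rho) == length(b$rho))
  sum(abs(a$rho - b$rho)) * a$width
}

# aggregate a fine phase_density onto a coarser bin count
aggregate_density <- function(rho, n_bins) {
  f <- length(rho$grid) / n_bins
  stopifnot(f == round(f))
  h <- 2 * pi / n_bins
  structure(list(grid = -pi + (seq_len(n_bins) - 0.5) * h,
                 rho = colSums(matrix(rho$rho * rho$width, nrow = f)) / h,
                 width = h, q = rho$q), class = "phase_density")
}
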