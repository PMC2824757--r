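#' Derive a per-stream / per-trial seed from a root seed
#'
#' Documented splitting rule: `(root * 48271 + 10007 * stream) mod (2^31 - 1)`,
#' a Lehmer-style mix keeping derived seeds in the 31-bit integer range.
#'
#' @param root integer root seed.
#' @param stream integer stream or trial index.
#' @return a single integer seed.
#' @export
derive_seed <- function(root, stream) {
  m <- 2147483647
  as.integer((as.numeric(root) %% m * 48271 + 10007 * as.numeric(stream)) %% m)
}

# deterministic FNV-1a hash of a configuration (hex string); the output
# directory is not part of the scientific configuration
config_hash <- function(config) {
  cfg <- unclass_deep(config)
  cfg$out_dir <- NULL
  s <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Read / write an experiment configuration as YAML
#'
#' Configurations round-trip losslessly through YAML; every run echoes its
#' resolved configuration next to its outputs.
#'
#' @param path YAML file path.
#' @param config an experiment configuration list (see
#'   [experiment_config()]).
#' @return for reading, the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  experiment_config(cfg$experiment, overrides = cfg$parameters,
                    seed = cfg$seed %||% 1, out_dir = cfg$out_dir)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(list(experiment = config$experiment,
                        seed = config$seed, out_dir = config$out_dir,
                        parameters = unclass_deep(config$parameters)), path,
                   precision = 15)
  invisible(path)
}

#' Build a figure-analogue experiment configuration
#'
#' Five canned experiments reproduce the package's study conditions:
#' \describe{
#'   \item{fig2}{closed-loop 2-mitral/1-granule spiking network swept over
#'     the mitral-to-granule coupling `g`; phase-difference histograms and
#'     shared-rate distributions.}
#'   \item{fig3}{Morris-Lecar 2M-1G long run; shared-rate trace and moving
#'     window voltage correlation.}
#'   \item{fig4}{open-loop granule spike count versus clamped phase
#'     difference for three (g, tau_s) settings.}
#'   \item{fig5}{reduced model with the direct (peaked) feedback functional
#'     from many random initial states, plus the averaged-theory fixed
#'     point.}
#'   \item{fig6}{reduced model with the order-parameter functional in the
#'     bistable regime.}
#' }
#'
#' @param experiment one of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`,
#'   `"fig6"`.
#' @param overrides named list merged over the experiment's default
#'   parameters.
#' @param seed integer root seed.
#' @param out_dir output directory (created by [run_experiment()]).
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("fig2", "fig3", "fig4", "fig5",
                                             "fig6"),
                              overrides = NULL, seed = 1,
                              out_dir = tempfile("stochsync-")) {
  experiment <- match.arg(experiment)
  pars <- switch(experiment,
    fig2 = list(g_sweep = c(0, 1, 2), t_total = 40, n_bins = 32,
                n_seeds = 3),
    fig3 = list(t_total = 400, corr_width = 0.25, corr_stride = 0.125),
    fig4 = list(settings = list(list(g = 1, tau_s = 0.002),
                                list(g = 1.25, tau_s = 0.005),
                                list(g = 1.75, tau_s = 0.010)),
                phi = seq(0, pi, length.out = 9), window = 10,
                n_seeds = 5),
    fig5 = list(amplitude = 1.5, tau_lam = 2400, tau_r = 1200,
                n_trials = 100, n_events = 30000, n_grid = 256),
    fig6 = list(amplitude = 22, tau_lam = 38400, tau_r = 38400,
                n_trials = 150, n_events = 3200000, n_grid = 512))
  if (!is.null(overrides)) pars[names(overrides)] <- overrides
  structure(list(experiment = experiment, parameters = pars,
                 seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

write_csv_units <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_units <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run a figure-analogue experiment
#'
#' Dispatches to the module runner for the configured experiment, writes all
#' outputs (CSV with unit-annotated headers, JSON summaries) into
#' `config$out_dir`, and writes + returns a run manifest. Identical
#' configuration and seed give identical outputs.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress messages.
#' @return the manifest (list with config hash, seed, package version,
#'   wall time and output file list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$out_dir))
    stop("cannot create output directory ", config$out_dir)
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(...)
  runner <- switch(config$experiment,
                   fig2 = run_fig2, fig3 = run_fig3, fig4 = run_fig4,
                   fig5 = run_fig5, fig6 = run_fig6)
  runner(config$parameters, config$seed, config$out_dir, say)
  write_config(config, file.path(config$out_dir, "config.yaml"))
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    experiment = config$experiment,
    config_hash = config_hash(config),
    seed = config$seed,
    version = as.character(utils::packageVersion("stochsync")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = files)
  jsonlite::write_json(manifest[setdiff(names(manifest), "wall_time_s")],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

run_fig2 <- function(p, seed, out, say) {
  hist_rows <- list(); lam_rows <- list()
  for (g in p$g_sweep) {
    say("fig2: g = ", g)
    phis <- c(); lams <- c()
    for (s in seq_len(p$n_seeds)) {
      cfg <- spiking_config(g = g)
      res <- run_spiking(topology_2m1g(), cfg, t_total = p$t_total,
                         seed = derive_seed(seed, s + 100 * which(p$g_sweep == g)))
      keep <- res$time > 2  # discard initial transient
      phis <- c(phis, res$phi[keep])
      lams <- c(lams, res$lambda[keep, 1])
    }
    hh <- phase_difference_histogram(phis, n_bins = p$n_bins)
    hist_rows[[length(hist_rows) + 1]] <-
      data.frame(g = g, bin_center = hh$grid, density = hh$rho)
    lam_rows[[length(lam_rows) + 1]] <-
      data.frame(g = g, lambda = lams)
  }
  write_csv_units(do.call(rbind, hist_rows), file.path(out, "histogram.csv"),
                  "g dimensionless, bin_center rad, density 1/rad")
  write_csv_units(do.call(rbind, lam_rows), file.path(out, "lambda.csv"),
                  "g dimensionless, lambda events/s")
}

run_fig3 <- function(p, seed, out, say) {
  say("fig3: Morris-Lecar network, ", p$t_total, " s")
  cfg <- ml_config()
  res <- run_ml_network(cfg, t_total = p$t_total, seed = derive_seed(seed, 1))
  write_csv_units(data.frame(time = res$time, v1 = res$v1, v2 = res$v2,
                             v_granule = res$v_granule),
                  file.path(out, "voltages.csv"),
                  "time s, voltages mV (granule dimensionless)")
  write_csv_units(data.frame(time = res$time, lambda = res$lambda),
                  file.path(out, "lambda.csv"), "time s, lambda events/s")
  cc <- sliding_correlation(res$v1, res$v2, res$dt_s,
                            width = p$corr_width, stride = p$corr_stride)
  write_csv_units(cc, file.path(out, "correlation.csv"),
                  "time s, corr dimensionless")
}

run_fig4 <- function(p, seed, out, say) {
  rows <- list()
  for (i in seq_along(p$settings)) {
    st <- p$settings[[i]]
    say("fig4: g = ", st$g, ", tau_s = ", st$tau_s)
    counts <- sapply(seq_len(p$n_seeds), function(s)
      granule_rate_vs_phase(p$phi,
                            spiking_config(g = st$g, tau_s = st$tau_s),
                            window = p$window,
                            seed = derive_seed(seed, 100 * i + s)))
    rows[[i]] <- data.frame(g = st$g, tau_s = st$tau_s, phi = p$phi,
                            count = rowMeans(counts))
  }
  write_csv_units(do.call(rbind, rows), file.path(out, "spike_count.csv"),
                  "g dimensionless, tau_s s, phi rad, count spikes/window")
}

run_fig5 <- function(p, seed, out, say, mode = "direct") {
  cfg <- reduced_config(
    tau_lam = p$tau_lam,
    G = g_functional(mode, amplitude = p$amplitude, tau_r = p$tau_r))
  say(mode, "-G reduced model: theory")
  avg <- averaged_dynamics(cfg, n_grid = p$n_grid %||% 256)
  fp <- find_fixed_points(avg)
  write_csv_units(as.data.frame(fp), file.path(out, "fixed_points.csv"),
                  "q dimensionless, lam events/s")
  say(mode, "-G reduced model: ", p$n_trials, " trials")
  term <- numeric(p$n_trials)
  tr_rows <- list()
  for (tr in seq_len(p$n_trials)) {
    s <- derive_seed(seed, tr)
    old <- save_rng_state()
    set.seed(s)
    init <- list(theta1 = stats::runif(1, 0, 2 * pi),
                 theta2 = stats::runif(1, 0, 2 * pi),
                 lam = stats::runif(1, cfg$lam_min,
                                    min(cfg$lam_max, cfg$lam_min + p$amplitude)))
    restore_rng_state(old)
    res <- run_reduced(cfg, n_events = p$n_events, seed = s, init = init,
                       record_every = 50L)
    lam_tr <- res$trace$lambda
    term[tr] <- mean(lam_tr[seq(floor(0.9 * length(lam_tr)), length(lam_tr))])
    if (tr <= 20)
      tr_rows[[tr]] <- data.frame(trial = tr, t = res$trace$t,
                                  lambda = lam_tr)
  }
  write_csv_units(do.call(rbind, tr_rows), file.path(out, "trajectories.csv"),
                  "t s, lambda events/s")
  write_csv_units(data.frame(trial = seq_along(term), terminal_lambda = term),
                  file.path(out, "terminal_lambda.csv"),
                  "terminal_lambda events/s")
}

run_fig6 <- function(p, seed, out, say) {
  run_fig5(p, seed, out, say, mode = "order_parameter")
}

#' Summarize the outputs of an experiment run
#'
#' Deterministic summary of a [run_experiment()] directory: histogram peak /
#' mean ratios, order parameters, terminal-rate cluster statistics and a
#' bimodality verdict. The bimodality rule is a transparent histogram-trough
#' test: the distribution is called bimodal when two modes separated by at
#' least `min_sep` bins have a trough below `trough_frac` of the smaller
#' mode.
#'
#' @param run_dir directory written by [run_experiment()].
#' @param trough_frac,min_sep,n_bins bimodality rule parameters.
#' @return a list (also written as `summary.json` in `run_dir`).
#' @export
summarize <- function(run_dir, trough_frac = 0.6, min_sep = 3, n_bins = 30) {
  if (!dir.exists(run_dir)) stop("no such run directory: ", run_dir)
  have <- list.files(run_dir)
  out <- list(run_dir = run_dir)
  if ("manifest.json" %in% have)
    out$experiment <- jsonlite::read_json(
      file.path(run_dir, "manifest.json"))$experiment
  if ("histogram.csv" %in% have) {
    hh <- read_csv_units(file.path(run_dir, "histogram.csv"))
    out$histogram <- lapply(split(hh, hh$g), function(d) {
      m <- sum(cos(d$bin_center) * d$density) * diff(d$bin_center[1:2])
      list(g = d$g[1], peak = max(d$density),
           peak_over_mean = max(d$density) / mean(d$density),
           flatness = max(d$density) / min(d$density),
           order_parameter = m)
    })
  }
  if ("terminal_lambda.csv" %in% have) {
    tl <- read_csv_units(file.path(run_dir, "terminal_lambda.csv"))
    out$terminal_lambda <- c(
      list(median = stats::median(tl$terminal_lambda)),
      bimodality_verdict(tl$terminal_lambda, trough_frac, min_sep, n_bins))
  }
  if ("lambda.csv" %in% have) {
    ll <- read_csv_units(file.path(run_dir, "lambda.csv"))
    if ("g" %in% names(ll))
      out$lambda_mean_by_g <- lapply(split(ll, ll$g), function(d)
        list(g = d$g[1], mean = mean(d$lambda)))
    else
      out$lambda <- c(list(mean = mean(ll$lambda)),
                      bimodality_verdict(ll$lambda, trough_frac, min_sep,
                                         n_bins))
  }
  if ("spike_count.csv" %in% have) {
    sc <- read_csv_units(file.path(run_dir, "spike_count.csv"))
    out$spike_count <- lapply(split(sc, interaction(sc$g, sc$tau_s,
                                                    drop = TRUE)),
                              function(d) list(g = d$g[1], tau_s = d$tau_s[1],
                                               f0 = d$count[which.min(abs(d$phi))],
                                               fpi = d$count[which.max(abs(d$phi))]))
  }
  missing <- setdiff(c("manifest.json", "config.yaml"), have)
  if (length(missing))
    stop("run directory is missing: ", paste(missing, collapse = ", "))
  jsonlite::write_json(out, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out
}

#' Histogram-trough bimodality verdict
#'
#' @param x numeric sample.
#' @param trough_frac trough must fall below this fraction of the smaller
#'   mode.
#' @param min_sep minimal separation of the two modes in bins.
#' @param n_bins histogram bins.
#' @param min_frac a mode must hold at least this fraction of the tallest
#'   bin (guards against spurious tail wiggles).
#' @return list with `bimodal` (logical) and the mode locations.
#' @export
bimodality_verdict <- function(x, trough_frac = 0.6, min_sep = 3,
                               n_bins = 30, min_frac = 0.05) {
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  cnt <- h$counts
  n <- length(cnt)
  best <- list(bimodal = FALSE, mode1 = h$mids[which.max(cnt)],
               mode2 = NA_real_)
  is_peak <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) cnt[i - 1] else -1
    r <- if (i < n) cnt[i + 1] else -1
    cnt[i] > 0 && cnt[i] >= l && cnt[i] >= r
  }, TRUE)
  peaks <- which(is_peak & cnt >= min_frac * max(cnt))
  if (length(peaks) < 2) return(best)
  for (a in peaks) for (b in peaks[peaks - a >= min_sep]) {
    trough <- min(cnt[a:b])
    smaller <- min(cnt[a], cnt[b])
    if (smaller > 0 && trough < trough_frac * smaller)
      return(list(bimodal = TRUE, mode1 = h$mids[a], mode2 = h$mids[b]))
  }
  best
}
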