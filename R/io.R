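#' Run a configured experiment and write a result bundle to disk
#'
#' Experiment kinds mirror the analyses the model supports:
#' \describe{
#'   \item{`koff_sweep`}{Uncoupled hybrid ensembles over a list of
#'     repressor/DNA dissociation rates; writes per-koff desynchronisation
#'     summaries.}
#'   \item{`variability`}{Deterministic-regulation ensembles with
#'     inter-cellular parameter variability; one desync summary per varied
#'     parameter.}
#'   \item{`notch`}{Delta-Notch coupled lattice runs (random initial
#'     conditions) with a synchrony summary, optionally over several koff
#'     values and a delay-scaling factor.}
#'   \item{`delay_quant`}{Notch-coupled run, in-silico dot counts and
#'     inter-allele delay estimates.}
#'   \item{`bootstrap`}{Bootstrap inference on a delay sample read from
#'     `config$sample_file`.}
#' }
#'
#' Outputs per experiment: trajectory tables (long format: time, cell,
#' species, value) when `config$write_trajectories` is true, gene-event
#' logs when recorded, metric tables as tab-separated text with unit-bearing
#' headers, and a JSON summary with all parameters and seeds.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list.  Required fields: `kind`, `seed`; others depend on the kind.
#' @param out_dir Output directory (created if absent; overrides
#'   `config$out_dir`).
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("kind", "seed"))
    if (is.null(config[[f]])) stop("config field missing: ", f)
  out_dir <- out_dir %||% config$out_dir %||% stop("config field missing: out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- c("koff_sweep", "variability", "notch", "delay_quant",
             "bootstrap")
  if (!config$kind %in% kinds)
    stop("unknown experiment kind '", config$kind, "'; one of: ",
         paste(kinds, collapse = ", "))
  res <- switch(config$kind,
    koff_sweep = exp_koff_sweep(config, out_dir),
    variability = exp_variability(config, out_dir),
    notch = exp_notch(config, out_dir),
    delay_quant = exp_delay_quant(config, out_dir),
    bootstrap = exp_bootstrap(config, out_dir))
  summary <- list(kind = config$kind, seed = config$seed,
                  config = config, results = res,
                  package_version =
                    as.character(utils::packageVersion("herclock")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_metric_table <- function(df, path, unit_note) {
  con <- file(path, "w")
  writeLines(paste0("# ", unit_note), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
}

write_trajectory_table <- function(traj, path) {
  long <- do.call(rbind, lapply(names(traj$species), function(nm) {
    X <- traj$species[[nm]]
    data.frame(time_min = rep(traj$time, ncol(X)),
               cell = rep(seq_len(ncol(X)), each = nrow(X)),
               species = nm, value = as.vector(X))
  }))
  write_metric_table(long, path,
                     "time_min in minutes; value in molecules per cell")
}

exp_koff_sweep <- function(config, out_dir) {
  koffs <- config$koff %||% c(1, 1 / 2, 1 / 3, 1 / 4, 1 / 6)
  n_cells <- config$n_cells %||% 100
  t_end <- config$t_end %||% 700
  base <- make_default_params("hybrid")
  rows <- list()
  for (ko in koffs) {
    p <- base
    p$koff <- ko
    tr <- simulate_ensemble(p, n_cells = n_cells, mode = "uncoupled",
                            t_end = t_end, seed = config$seed)
    ds <- desync_summary(tr)
    rows[[length(rows) + 1]] <- data.frame(
      koff_per_min = ko, period_min = ds$period,
      desynchronised = ds$desynchronised,
      desync_time_min = ds$time, desync_oscillation = ds$oscillation)
    if (isTRUE(config$write_trajectories))
      write_trajectory_table(tr, file.path(out_dir, sprintf(
        "trajectory_koff_%.4f.tsv", ko)))
  }
  df <- do.call(rbind, rows)
  write_metric_table(df, file.path(out_dir, "desync_summary.tsv"),
                     "koff_per_min in 1/min; times in minutes")
  df
}

exp_variability <- function(config, out_dir) {
  base <- make_default_params("deterministic")
  specs <- default_variability_specs()
  use <- config$parameters %||% names(specs)
  n_cells <- config$n_cells %||% 100
  t_end <- config$t_end %||% 950
  rows <- list()
  for (nm in use) {
    cp <- draw_cell_params(base, specs[[nm]], n_cells, seed = config$seed)
    tr <- simulate_ensemble(cp, mode = "uncoupled", t_end = t_end,
                            seed = config$seed)
    ds <- desync_summary(tr)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = nm, period_min = ds$period,
      desynchronised = ds$desynchronised,
      desync_time_min = ds$time, desync_oscillation = ds$oscillation)
  }
  df <- do.call(rbind, rows)
  write_metric_table(df, file.path(out_dir, "variability_summary.tsv"),
                     "times in minutes")
  df
}

#' Built-in inter-cellular variability experiment specifications
#'
#' The Gaussian (and one generalised Pareto) distributions of the
#' variability experiments: transcription rate N(33, 9^2), translation rate
#' N(9.2, 1.5^2), degradation rate N(0.23, 0.025^2), transcription delay
#' N(7, 0.5^2) or GPD(location 5.84, scale 1.10, shape 0.05), translation
#' delays N(1.1, 0.3^2) and N(0.7, 0.2^2), Hes6 count N(100, 25^2).
#'
#' @return Named list of [variability_spec()] lists.
#' @export
default_variability_specs <- function() {
  list(
    transcription_rate = list(variability_spec(
      c("alpha_h1", "alpha_h7"), "gaussian", mean = 33, sd = 9)),
    translation_rate = list(variability_spec(
      c("beta_h1", "beta_h7"), "gaussian", mean = 9.2, sd = 1.5)),
    degradation_rate = list(variability_spec(
      c("lambda_mh", "lambda_ph"), "gaussian", mean = 0.23, sd = 0.025)),
    transcription_delay = list(variability_spec(
      "tau_mh", "gaussian", mean = 7, sd = 0.5)),
    transcription_delay_gpd = list(variability_spec(
      "tau_mh", "gpd", location = 5.84, scale = 1.10, shape = 0.05)),
    translation_delay = list(
      variability_spec("tau_ph1", "gaussian", mean = 1.1, sd = 0.3),
      variability_spec("tau_ph7", "gaussian", mean = 0.7, sd = 0.2)),
    hes6_count = list(variability_spec(
      "p_h6", "gaussian", mean = 100, sd = 25))
  )
}

exp_notch <- function(config, out_dir) {
  koffs <- config$koff %||% (1 / 3)
  delay_scale <- config$delay_scale %||% 1
  rows_cfg <- config$rows %||% 8
  cols_cfg <- config$cols %||% 8
  t_end <- config$t_end %||% 700
  lat <- build_hex_lattice(rows_cfg, cols_cfg)
  rows <- list()
  for (ko in koffs) {
    p <- make_default_params("hybrid")
    p$koff <- ko
    for (nm in c("tau_mh", "tau_ph1", "tau_ph7", "tau_md", "tau_pd",
                 "tau_pN"))
      p[[nm]] <- p[[nm]] * delay_scale
    tr <- simulate_ensemble(p, mode = "notch", lattice = lat,
                            t_end = t_end, init = "random",
                            seed = config$seed)
    ds <- desync_summary(tr)
    sy <- synchrony_index(tr)
    rows[[length(rows) + 1]] <- data.frame(
      koff_per_min = ko, delay_scale = delay_scale,
      period_min = ds$period, desynchronised = ds$desynchronised,
      desync_time_min = ds$time, synchrony_index = sy)
    if (isTRUE(config$snapshots))
      write_lattice_snapshots(tr, lat, file.path(out_dir, sprintf(
        "lattice_koff_%.4f.tsv", ko)))
  }
  df <- do.call(rbind, rows)
  write_metric_table(df, file.path(out_dir, "notch_summary.tsv"),
                     "koff_per_min in 1/min; times in minutes")
  df
}

#' Amplitude-based synchrony index of an ensemble
#'
#' Ratio of the oscillation amplitude of the ensemble mean to the median
#' single-cell amplitude, over the second half of the trajectory (after
#' transients).  Near 1 for synchronous ensembles; near 0 for a
#' salt-and-pepper phase mosaic, where averaging cancels the oscillation.
#'
#' @param traj A `clock_trajectory`.
#' @param observable Recorded species.
#' @param from Start time (min); default half the trajectory.
#' @return Numeric synchrony index.
#' @export
synchrony_index <- function(traj, observable = "p_h1", from = NULL) {
  X <- trajectory_observable(traj, observable)
  from <- from %||% (max(traj$time) / 2)
  sel <- traj$time >= from
  X <- X[sel, , drop = FALSE]
  mu <- rowMeans(X)
  amp_mean <- (stats::quantile(mu, 0.95) - stats::quantile(mu, 0.05))
  amp_cells <- apply(X, 2, function(x)
    stats::quantile(x, 0.95) - stats::quantile(x, 0.05))
  as.numeric(amp_mean / stats::median(amp_cells))
}

write_lattice_snapshots <- function(traj, lat, path, every = 5) {
  sel <- which(traj$time %% every == 0)
  X <- traj$species$p_h1
  df <- data.frame(time_min = rep(traj$time[sel], each = lat$n_cells),
                   cell = rep(seq_len(lat$n_cells), length(sel)),
                   row = rep(rep(seq_len(lat$rows), each = lat$cols),
                             length(sel)),
                   col = rep(rep(seq_len(lat$cols), lat$rows), length(sel)),
                   p_h1 = as.vector(t(X[sel, , drop = FALSE])))
  write_metric_table(df, path, "p_h1 in molecules per cell; time in minutes")
}

exp_delay_quant <- function(config, out_dir) {
  p <- make_default_params("hybrid")
  p$koff <- config$koff %||% (1 / 3)
  lat <- build_hex_lattice(config$rows %||% 8, config$cols %||% 8)
  t_end <- config$t_end %||% 500
  n_windows <- config$n_windows %||% 4
  tr <- simulate_ensemble(p, mode = "notch", lattice = lat, t_end = t_end,
                          init = "random", seed = config$seed,
                          record_dt = 0.5)
  T0 <- config$T0 %||% 30
  ests <- simulated_delay_estimates(tr, T0 = T0, n_windows = n_windows)
  df <- data.frame(window = seq_along(ests),
                   delay_min = vapply(ests, identity, numeric(1)))
  write_metric_table(df, file.path(out_dir, "delay_estimates.tsv"),
                     "delay_min in minutes")
  list(delays_min = df$delay_min, mean_delay_min = mean(df$delay_min))
}

#' Inter-allele delay estimates from successive windows of a simulation
#'
#' Applies [dotcounts_from_simulation()] and [estimate_embryo_delay()] to
#' `n_windows` non-overlapping late windows of a Notch-coupled trajectory,
#' returning one delay estimate (minutes) per window; windows whose profile
#' lacks a usable rising edge are dropped.
#'
#' @param traj Hybrid trajectory with gene records.
#' @param T0 Clock period for the time-to-space map (min).
#' @param n_windows Number of windows.
#' @param window_periods Window length in periods (default 2).
#' @param skip Initial transient to skip (min, default 120).
#' @return Numeric vector of delay estimates (possibly shorter than
#'   `n_windows`).
#' @export
simulated_delay_estimates <- function(traj, T0 = 30, n_windows = 4,
                                      window_periods = 2, skip = 120) {
  wlen <- window_periods * T0
  t_max <- max(traj$time)
  starts <- seq(skip, t_max - wlen, by = wlen)
  starts <- utils::tail(starts, n_windows)
  out <- numeric(0)
  for (s in starts) {
    est <- tryCatch({
      dc <- dotcounts_from_simulation(traj, T0 = T0,
                                      window = c(s, s + wlen))
      estimate_embryo_delay(dc$profile)$delay_min
    }, error = function(e) NA_real_)
    if (is.finite(est)) out <- c(out, est)
  }
  out
}

exp_bootstrap <- function(config, out_dir) {
  path <- config$sample_file %||%
    system.file("extdata", "synthetic_delay_sample.csv",
                package = "herclock")
  ds <- read_delay_sample(path, T0 = config$T0 %||% 30)
  bt <- bootstrap_delay(ds, B = config$B %||% 10000, seed = config$seed)
  df <- data.frame(statistic = c("mean_frac_T0", "sd_frac_T0",
                                 "ci_lo_frac_T0", "ci_hi_frac_T0",
                                 "mean_min"),
                   value = c(bt$mean, bt$sd, bt$ci[1], bt$ci[2],
                             bt$mean_min))
  write_metric_table(df, file.path(out_dir, "bootstrap_summary.tsv"),
                     "frac_T0 = proportion of somite period; min = minutes")
  bt[c("mean", "sd", "ci", "mean_min", "sample_mean_min", "B", "n")]
}
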