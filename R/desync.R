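#' Local peak detection with a minimum spacing constraint
#'
#' Utility shared by the period/amplitude/phase diagnostics: light running-
#' mean smoothing followed by strict local-maximum detection, then greedy
#' thinning so that retained peaks are at least `min_spacing` apart (larger
#' peaks win).
#'
#' @param t Sample times.
#' @param x Signal.
#' @param min_spacing Minimum spacing between retained peaks (same units as
#'   `t`).
#' @param smooth_window Width of the running-mean smoother in samples
#'   (odd; 1 disables smoothing).
#' @param min_prominence Discard peaks whose height above the lower of the
#'   two flanking troughs is below this value.
#' @return data.frame with columns `time`, `value` (one row per peak).
#' @export
find_peaks <- function(t, x, min_spacing = 0, smooth_window = 5,
                       min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(data.frame(time = numeric(0), value = numeric(0)))
  if (smooth_window > 1) {
    k <- min(smooth_window, n - (1 - n %% 2))
    if (k %% 2 == 0) k <- k - 1
    if (k >= 3)
      x <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  }
  ok <- which(!is.na(x))
  xi <- x[ok]
  ti <- t[ok]
  m <- length(xi)
  cand <- which(xi[2:(m - 1)] > xi[1:(m - 2)] &
                  xi[2:(m - 1)] >= xi[3:m]) + 1L
  if (!length(cand)) return(data.frame(time = numeric(0), value = numeric(0)))
  ord <- cand[order(xi[cand], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in ord) {
    if (!length(chosen) || all(abs(ti[i] - ti[chosen]) >= min_spacing))
      chosen <- c(chosen, i)
  }
  chosen <- sort(chosen)
  if (min_prominence > 0 && length(chosen) > 1) {
    keep <- rep(TRUE, length(chosen))
    for (j in seq_along(chosen)) {
      lo_l <- if (j == 1) min(xi[1:chosen[1]]) else
        min(xi[chosen[j - 1]:chosen[j]])
      lo_r <- if (j == length(chosen)) min(xi[chosen[j]:m]) else
        min(xi[chosen[j]:chosen[j + 1]])
      if (xi[chosen[j]] - max(lo_l, lo_r) < min_prominence) keep[j] <- FALSE
    }
    chosen <- chosen[keep]
  }
  data.frame(time = ti[chosen], value = xi[chosen])
}

#' Sliding two-sample Kolmogorov-Smirnov p-value series of an ensemble
#'
#' At each recorded time `t`, compares the across-cell sample distribution
#' of the observable at `t` with the distribution `offset` minutes later by
#' a two-sided two-sample KS test (asymptotic p-value; the observable is
#' continuous but early synchronous ensembles are heavily tied, which the
#' asymptotic form tolerates).  The offset defaults to 16 minutes,
#' approximately half an oscillation period, so the comparison is peak
#' against trough: while the ensemble is synchronous those distributions
#' differ sharply and p stays small over part of every cycle; once the cells
#' have drifted into a salt-and-pepper phase mosaic the distribution becomes
#' stationary and p is large throughout.
#'
#' @param traj A `clock_trajectory` (needs at least 2 cells).
#' @param observable Recorded species, default Her1 protein.
#' @param offset Comparison lag in minutes (default 16).
#' @return data.frame with columns `time` and `p`.
#' @export
ks_pvalue_series <- function(traj, observable = "p_h1", offset = 16) {
  X <- trajectory_observable(traj, observable)
  if (ncol(X) < 2) stop("need at least 2 cells")
  times <- traj$time
  k <- round(offset / traj$record_dt)
  if (k < 1 || k >= length(times)) stop("offset outside trajectory range")
  idx <- seq_len(length(times) - k)
  p <- vapply(idx, function(i) {
    suppressWarnings(stats::ks.test(X[i, ], X[i + k, ],
                                    exact = FALSE)$p.value)
  }, numeric(1))
  data.frame(time = times[idx], p = p)
}

#' Declare the desynchronisation time of an ensemble
#'
#' The ensemble counts as desynchronised from the first grid time `t*` such
#' that the KS p-value stays above `threshold` for every sample in
#' `[t*, t* + period]`, i.e. the first instance in which the p-value for no
#' part of the oscillatory cycle drops below the threshold.  The oscillation
#' index is the 1-based count of ensemble-mean peaks up to `t*`.
#'
#' @param pseries data.frame from [ks_pvalue_series()].
#' @param period Oscillation period in minutes used for the full-cycle
#'   window (measure it with [ensemble_period()]).
#' @param threshold p-value threshold, default 0.1.
#' @param mean_peaks Optional vector of ensemble-mean peak times used for
#'   the oscillation index (otherwise the index is `NA`).
#' @return List with `desynchronised` (logical), `time` (min, `NA` when the
#'   ensemble stays synchronous) and `oscillation` (index).
#' @export
desync_time <- function(pseries, period, threshold = 0.1,
                        mean_peaks = NULL) {
  dt <- stats::median(diff(pseries$time))
  w <- round(period / dt)
  n <- nrow(pseries)
  if (w >= n) stop("p-value series shorter than one period")
  above <- pseries$p > threshold
  # run length of consecutive 'above' starting at each index
  run <- integer(n)
  run[n] <- above[n]
  for (i in (n - 1):1) run[i] <- if (above[i]) run[i + 1] + 1L else 0L
  hit <- which(run >= w + 1L)
  if (!length(hit))
    return(list(desynchronised = FALSE, time = NA_real_,
                oscillation = NA_integer_))
  tstar <- pseries$time[hit[1]]
  osc <- NA_integer_
  if (!is.null(mean_peaks) && length(mean_peaks)) {
    # detected peaks, extended by period counting where the decayed
    # ensemble mean no longer shows a detectable peak
    osc <- max(sum(mean_peaks <= tstar),
               1L + round((tstar - mean_peaks[1]) / period))
  }
  list(desynchronised = TRUE, time = tstar, oscillation = osc)
}

#' Measure the ensemble-mean oscillation period
#'
#' Median spacing of the first few ensemble-mean peaks (default 5 cycles),
#' used instead of a hard-coded period when scanning for desynchronisation.
#'
#' @param traj A `clock_trajectory`.
#' @param observable Recorded species.
#' @param n_cycles How many early cycles to use.
#' @return List with `period` (min) and `peaks` (all mean peak times).
#' @export
ensemble_period <- function(traj, observable = "p_h1", n_cycles = 5) {
  X <- trajectory_observable(traj, observable)
  mu <- rowMeans(X)
  sw <- max(3, round(2 / traj$record_dt))
  pk <- find_peaks(traj$time, mu, min_spacing = 12, smooth_window = sw,
                   min_prominence = 0.02 * (max(mu) - min(mu)))
  if (nrow(pk) < 2) stop("ensemble mean shows fewer than 2 oscillations")
  per <- stats::median(diff(utils::head(pk$time, n_cycles + 1)))
  list(period = per, peaks = pk$time)
}

#' Full desynchronisation summary of a trajectory
#'
#' Convenience pipeline: measures the ensemble-mean period, computes the
#' sliding KS p-value series, and declares the desynchronisation time and
#' oscillation index.
#'
#' @inheritParams ks_pvalue_series
#' @param threshold p-value threshold (default 0.1).
#' @return List with `period`, `pseries`, `desynchronised`, `time`,
#'   `oscillation`.
#' @export
desync_summary <- function(traj, observable = "p_h1", offset = 16,
                           threshold = 0.1) {
  ep <- ensemble_period(traj, observable)
  ps <- ks_pvalue_series(traj, observable, offset)
  res <- desync_time(ps, period = ep$period, threshold = threshold,
                     mean_peaks = ep$peaks)
  c(list(period = ep$period, pseries = ps), res)
}

#' Per-cell oscillation amplitudes and periods
#'
#' Detects peaks and troughs of every cell's trace after light smoothing;
#' the amplitude of a peak is its height above the preceding trough, the
#' period is the spacing of successive peaks.  Non-oscillatory traces yield
#' empty series rather than an error.
#'
#' @param traj A `clock_trajectory`.
#' @param observable Recorded species.
#' @param min_spacing Minimum peak spacing (min), default 12 (well below the
#'   ~30 min clock period, well above sample noise).
#' @return List (one element per cell) of data.frames with columns
#'   `peak_time`, `amplitude`, `period` (`period` is `NA` for the last
#'   peak).
#' @export
amplitude_period_per_cell <- function(traj, observable = "p_h1",
                                      min_spacing = 12) {
  X <- trajectory_observable(traj, observable)
  sw <- max(3, round(2 / traj$record_dt))
  lapply(seq_len(ncol(X)), function(i) {
    x <- X[, i]
    rng <- max(x) - min(x)
    if (rng <= 0)
      return(data.frame(peak_time = numeric(0), amplitude = numeric(0),
                        period = numeric(0)))
    pk <- find_peaks(traj$time, x, min_spacing = min_spacing,
                     smooth_window = sw, min_prominence = 0.05 * rng)
    tr <- find_peaks(traj$time, -x, min_spacing = min_spacing,
                     smooth_window = sw, min_prominence = 0.05 * rng)
    tr$value <- -tr$value
    if (nrow(pk) == 0)
      return(data.frame(peak_time = numeric(0), amplitude = numeric(0),
                        period = numeric(0)))
    amp <- vapply(seq_len(nrow(pk)), function(j) {
      prev <- tr$value[tr$time < pk$time[j]]
      if (length(prev)) pk$value[j] - prev[length(prev)] else NA_real_
    }, numeric(1))
    data.frame(peak_time = pk$time, amplitude = amp,
               period = c(diff(pk$time), NA_real_))
  })
}

#' Phase spread of an ensemble across oscillation cycles
#'
#' The phase of cell `i` at oscillation `k` is its `k`-th peak time; the
#' spread is the standard deviation of those times across cells.  For
#' uncoupled stochastic ensembles the spread grows with `k` as period
#' fluctuations accumulate.
#'
#' @inheritParams amplitude_period_per_cell
#' @return data.frame with columns `oscillation`, `spread` (min) and
#'   `n_cells` (cells contributing at least `k` peaks).
#' @export
phase_spread <- function(traj, observable = "p_h1", min_spacing = 12) {
  ap <- amplitude_period_per_cell(traj, observable, min_spacing)
  if (length(ap) < 2) stop("need at least 2 cells")
  npk <- vapply(ap, nrow, integer(1))
  kmax <- max(npk)
  rows <- lapply(seq_len(kmax), function(k) {
    tk <- unlist(lapply(ap, function(d)
      if (nrow(d) >= k) d$peak_time[k] else NULL))
    if (length(tk) < 2) return(NULL)
    data.frame(oscillation = k, spread = stats::sd(tk),
               n_cells = length(tk))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("fewer than 2 cells have any detected peaks")
  out
}
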