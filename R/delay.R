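#' Construct a dot-count profile
#'
#' Per-interval counts of nuclei showing exactly one and exactly two active
#' her1 transcription sites ("dots"), over `K` anteroposterior intervals
#' (interval 1 = posterior), plus the embryo geometry: somite length `S0`
#' and PSM length `L` on the normalised axis where 0 is the tail end of the
#' notochord and 1 the anterior end of the PSM, and the somite period `T0`
#' in minutes.
#'
#' @param one_dot,two_dot Integer count vectors of equal length `K`.
#' @param total Total nuclei per interval (>= one_dot + two_dot).
#' @param S0 Somite length, normalised axis units (default 0.12).
#' @param L PSM length, normalised units (default 1).
#' @param T0 Somite period, minutes (default 30).
#' @return Object of class `dot_count_profile`.
#' @export
dot_count_profile <- function(one_dot, two_dot, total, S0 = 0.12, L = 1,
                              T0 = 30) {
  K <- length(one_dot)
  if (length(two_dot) != K || length(total) != K)
    stop("count vectors must have equal length")
  if (any(one_dot < 0) || any(two_dot < 0))
    stop("counts must be non-negative")
  if (any(one_dot + two_dot > total))
    stop("one_dot + two_dot cannot exceed total nuclei")
  structure(list(one_dot = as.numeric(one_dot),
                 two_dot = as.numeric(two_dot),
                 total = as.numeric(total), K = K,
                 S0 = S0, L = L, T0 = T0),
            class = "dot_count_profile")
}

#' @export
print.dot_count_profile <- function(x, ...) {
  cat("dot_count_profile:", x$K, "intervals,",
      sum(x$total), "nucleus observations; S0 =", x$S0, ", L =", x$L,
      ", T0 =", x$T0, "min\n")
  invisible(x)
}

#' Smooth a dot-count profile into continuous frequency curves
#'
#' Converts the per-interval one-dot and two-dot counts to frequencies and
#' smooths them with a Gaussian kernel on the interval index
#' (Nadaraya-Watson weights, so constant profiles are preserved exactly),
#' evaluated on a fine grid of the normalised anteroposterior coordinate
#' `x` in `[0, 1]` (interval 1 maps to the posterior end).
#'
#' @param profile A [dot_count_profile()].
#' @param bandwidth Kernel standard deviation in interval units (default 2).
#' @param n_grid Evaluation grid size (default 1001).
#' @return Object of class `smoothed_profile`: list with `x`, `f1`, `f2`
#'   and the originating geometry scalars.
#' @export
smooth_profile <- function(profile, bandwidth = 2, n_grid = 1001) {
  stopifnot(inherits(profile, "dot_count_profile"))
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (profile$K < 10) stop("need at least 10 intervals")
  if (all(profile$one_dot == 0) && all(profile$two_dot == 0))
    stop("all-zero profile")
  tot <- pmax(profile$total, 1)
  f1 <- profile$one_dot / tot
  f2 <- profile$two_dot / tot
  xi <- (seq_len(profile$K) - 0.5) / profile$K
  h <- bandwidth / profile$K
  x <- seq(0, 1, length.out = n_grid)
  W <- outer(x, xi, function(a, b) stats::dnorm(a - b, sd = h))
  sw <- rowSums(W)
  structure(list(x = x, f1 = as.numeric(W %*% f1 / sw),
                 f2 = as.numeric(W %*% f2 / sw),
                 f_any = as.numeric(W %*% (f1 + f2) / sw),
                 bandwidth = bandwidth, S0 = profile$S0, L = profile$L,
                 T0 = profile$T0),
            class = "smoothed_profile")
}

# extend each copy's dot state w samples past deactivation: a dot at time t
# is visible if that copy was active at any sample in (t - w, t]
apply_dot_persistence <- function(M, w) {
  b1 <- M %% 2L
  b2 <- M %/% 2L
  runmax <- function(B) {
    out <- B
    for (k in seq_len(w)) {
      nr <- nrow(B)
      out[(k + 1):nr, ] <- pmax(out[(k + 1):nr, , drop = FALSE],
                                B[1:(nr - k), , drop = FALSE])
    }
    out
  }
  runmax(b1) + 2L * runmax(b2)
}

# centred finite-difference derivative on a uniform grid
grid_deriv <- function(x, y) {
  n <- length(y)
  d <- numeric(n)
  h <- x[2] - x[1]
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * h)
  d[1] <- (y[2] - y[1]) / h
  d[n] <- (y[n] - y[n - 1]) / h
  d
}

#' Locate the rising-edge inflection point of a frequency wave
#'
#' Reading the spatial wave from anterior to posterior (decreasing `x`), the
#' increase in the frequency of active genes reflects repressor dissociation
#' from the gene; its inflection point is invariant to the overall scale of
#' the wave and is therefore used as the wave landmark.  On the `x` axis
#' this rising edge is the anterior flank of a crest, where the curve is
#' steepest with negative slope.  The inflection is located as the zero
#' crossing of the numerical second derivative nearest the steepest grid
#' point, with linear sub-grid interpolation.
#'
#' @param sp A [smooth_profile()] result, or a list with fields `x` and the
#'   requested `curve`.
#' @param curve `"f1"` or `"f2"`.
#' @param window Optional `c(lo, hi)` restricting the search in `x`.  When
#'   omitted, the anterior flank of the most prominent interior crest of the
#'   curve is used; for curves monotone across the window the whole window
#'   is scanned for the steepest point.
#' @return The inflection coordinate `x` (attribute `"slope"` carries the
#'   slope there).
#' @export
find_rising_inflection <- function(sp, curve = "f1", window = NULL) {
  x <- sp$x
  f <- sp[[curve]]
  if (is.null(f)) stop("unknown curve: ", curve)
  if (is.null(window)) {
    fl <- rising_flank(x, f)
  } else {
    sel <- x >= window[1] & x <= window[2]
    if (sum(sel) < 5) stop("search window too narrow")
    fl <- list(x = x[sel], f = f[sel], sign = -1)
  }
  xs <- fl$x
  fs <- fl$f
  d1 <- grid_deriv(xs, fs)
  d2 <- grid_deriv(xs, d1)
  # steepest point: prefer the anterior-flank direction (f increasing as x
  # decreases, i.e. negative slope); fall back to the steepest ascending
  # point when the windowed segment is monotone increasing
  i0 <- if (min(d1) < 0) which.min(d1) else which.max(d1)
  if (abs(d1[i0]) < .Machine$double.eps)
    stop("no rising edge found in window")
  # nearest sign change of the second derivative
  sgn <- sign(d2)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(cross)) stop("no inflection (second derivative sign change)")
  j <- cross[which.min(abs(cross - i0))]
  frac <- d2[j] / (d2[j] - d2[j + 1])
  xout <- xs[j] + frac * (xs[j + 1] - xs[j])
  attr(xout, "slope") <- d1[i0]
  xout
}

# anterior flank of the most prominent interior crest: from the crest to the
# first minimum anterior of it (increasing x); slope negative in x
rising_flank <- function(x, f) {
  n <- length(f)
  pk <- find_peaks(x, f, min_spacing = 0, smooth_window = 1)
  if (!nrow(pk)) stop("curve has no interior crest")
  ic <- vapply(pk$time, function(tt) which.min(abs(x - tt)), integer(1))
  # prefer the most prominent crest whose anterior flank is inside
  ord <- order(pk$value, decreasing = TRUE)
  for (k in ord) {
    i <- ic[k]
    j <- i
    # walk anteriorly (increasing x) down to the next trough or boundary
    while (j < n && f[j + 1] <= f[j]) j <- j + 1
    if (j - i >= 3) return(list(x = x[i:j], f = f[i:j], sign = -1))
  }
  stop("curve has no usable anterior rising flank")
}

#' Local spatial wavelength of the expression wave
#'
#' `S(x)`: the distance between the pair of successive crests, or successive
#' troughs, of the smoothed one-dot wave whose midpoint lies nearest `x_mid`.
#'
#' @param sp A [smooth_profile()] result.
#' @param x_mid Query position on the normalised axis.
#' @param curve Which curve to measure (default `"f1"`).
#' @return Wavelength in normalised axis units.
#' @export
local_wavelength <- function(sp, x_mid, curve = "f1") {
  x <- sp$x
  f <- sp[[curve]]
  pk <- find_peaks(x, f, min_spacing = 0.05, smooth_window = 1,
                   min_prominence = 0.02 * (max(f) - min(f)))
  tr <- find_peaks(x, -f, min_spacing = 0.05, smooth_window = 1,
                   min_prominence = 0.02 * (max(f) - min(f)))
  pairs <- list()
  for (v in list(pk$time, tr$time)) {
    if (length(v) >= 2) {
      d <- diff(v)
      mid <- v[-length(v)] + d / 2
      pairs[[length(pairs) + 1]] <- data.frame(mid = mid, S = d)
    }
  }
  if (!length(pairs)) stop("fewer than 2 extrema: cannot measure wavelength")
  pp <- do.call(rbind, pairs)
  pp$S[which.min(abs(pp$mid - x_mid))]
}

#' Convert a spatial offset to the temporal inter-allele delay
#'
#' In the PSM the clock slows anteriorly, so clock-phase differences appear
#' as spatial offsets.  A spatial delay `dx` centred at `x` converts to a
#' temporal delay via `dt = T0 * dx / (S(x) - v(x) * S0)` with the cell
#' advection speed approximated linearly, `v(x) = x / L`.  At the tail end
#' of the notochord (`x = 0`) this reduces to `dt = T0 * dx / S(x)`: one
#' full local wavelength corresponds to one full clock period.
#'
#' @param dx Spatial offset, normalised axis units.
#' @param x Position of the offset midpoint.
#' @param S_x Local wavelength `S(x)`.
#' @param S0 Somite length (normalised units).
#' @param T0 Somite period, minutes.
#' @param L PSM length (normalised units).
#' @return Temporal delay in minutes.
#' @export
#' @examples
#' spatial_to_temporal_delay(0.02, x = 0.1, S_x = 0.25, S0 = 0.12, T0 = 30)
spatial_to_temporal_delay <- function(dx, x, S_x, S0, T0 = 30, L = 1) {
  denom <- S_x - (x / L) * S0
  if (denom <= 0)
    stop("invalid embryo measurement: S(x) - v(x)*S0 must be positive")
  T0 * dx / denom
}

#' Estimate the inter-allele expression delay of one embryo
#'
#' Full pipeline on a dot-count profile: smooth both waves, locate the
#' rising-edge inflection of the one-dot and two-dot curves (the falling
#' edge reflects stochastic repressor re-association, Notch unbinding and
#' related events, and is never used), take the spatial offset `dx` between
#' the two inflections and their midpoint `x`, measure the local wavelength
#' `S(x)` from the one-dot wave, and convert to minutes with
#' [spatial_to_temporal_delay()].
#'
#' @param profile A [dot_count_profile()].
#' @param bandwidth Smoothing bandwidth in intervals (default 1.5; at
#'   heavier smoothing the offset between the narrowly spaced inflections
#'   is biased towards zero).
#' @return List with `delay_min`, `delay_frac` (proportion of `T0`), and the
#'   intermediate quantities `x1`, `x2`, `x_mid`, `S_x`, `dx`.
#' @export
estimate_embryo_delay <- function(profile, bandwidth = 1.5) {
  if (all(profile$two_dot == 0))
    stop("profile has no two-dot signal")
  sp <- smooth_profile(profile, bandwidth = bandwidth)
  # anchor on the two-dot wave: it is unimodal over each cycle (the one-dot
  # wave shows a bump on both the activation and the deactivation side)
  rngf2 <- max(sp$f2) - min(sp$f2)
  pk2 <- find_peaks(sp$x, sp$f2, min_spacing = 0.08, smooth_window = 1,
                    min_prominence = 0.1 * rngf2)
  if (!nrow(pk2)) stop("two-dot wave has no crest")
  S_guess <- if (nrow(pk2) >= 2) stats::median(diff(sort(pk2$time))) else 0.35
  # one estimate per usable crest (ordered by prominence), pooled by median
  pk2 <- pk2[order(pk2$value, decreasing = TRUE), ]
  per_crest <- list()
  for (xc in pk2$time) {
    win <- c(xc, min(1, xc + 0.8 * S_guess))
    est <- tryCatch({
      x2 <- find_rising_inflection(sp, "f2", window = win)
      # first-allele landmark: the at-least-one-dot wave shares its rising
      # edge with the one-dot signal (the two-dot wave is still flat there)
      # but has the same edge shape as the two-dot wave, so the inflection
      # offset is not biased by the narrow exactly-one band
      x1 <- find_rising_inflection(sp, "f_any", window = win)
      dx <- abs(as.numeric(x1) - as.numeric(x2))
      x_mid <- (as.numeric(x1) + as.numeric(x2)) / 2
      S_x <- local_wavelength(sp, x_mid, curve = "f2")
      list(x1 = as.numeric(x1), x2 = as.numeric(x2), dx = dx,
           x_mid = x_mid, S_x = S_x,
           delay_min = spatial_to_temporal_delay(dx, x_mid, S_x, profile$S0,
                                                 profile$T0, profile$L))
    }, error = function(e) NULL)
    if (!is.null(est)) {
      per_crest[[1]] <- est
      break
    }
  }
  if (!length(per_crest)) stop("no usable rising edge for both waves")
  first <- per_crest[[1]]
  list(delay_min = first$delay_min,
       delay_frac = first$delay_min / profile$T0,
       x1 = first$x1, x2 = first$x2, x_mid = first$x_mid, S_x = first$S_x,
       dx = first$dx)
}

#' Construct a per-embryo delay sample
#'
#' @param values Per-embryo inter-allele delays expressed as a proportion of
#'   the somite period `T0`.
#' @param T0 Somite period for minute conversion (default 30).
#' @return Object of class `delay_sample`.
#' @export
delay_sample <- function(values, T0 = 30) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    stop("values must be a non-empty finite numeric vector")
  structure(list(values = values, n = length(values), T0 = T0),
            class = "delay_sample")
}

#' Read a per-embryo delay sample from a CSV file
#'
#' Expects a column `delay_frac` (proportion of T0).
#' @param path File path.
#' @param T0 Somite period (min).
#' @return A [delay_sample()].
#' @export
read_delay_sample <- function(path, T0 = 30) {
  df <- utils::read.csv(path)
  if (!"delay_frac" %in% names(df)) stop("no 'delay_frac' column")
  delay_sample(df$delay_frac, T0 = T0)
}

#' Non-parametric bootstrap inference on a delay sample
#'
#' Resamples the per-embryo delays with replacement (`n` out of `n`) `B`
#' times; the population mean and SD estimates are the means of the
#' resample means and resample SDs, and the interval is the 5th/95th
#' percentile of the resample means (nominally 90% coverage; reported as
#' the percentile pair, matching the original analysis' percentile choice).
#'
#' @param sample A [delay_sample()] (or numeric vector of proportions of
#'   T0).
#' @param B Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param T0 Somite period for the minutes conversion (used when `sample`
#'   is a bare vector).
#' @return List with `mean`, `sd`, `ci` (5th/95th percentiles of resample
#'   means), all as proportions of `T0`; `mean_min` and `sample_mean_min`
#'   in minutes; `B`, `n`.
#' @export
bootstrap_delay <- function(sample, B = 10000, seed = 1, T0 = 30) {
  if (!inherits(sample, "delay_sample")) sample <- delay_sample(sample, T0)
  v <- sample$values
  n <- length(v)
  if (B < 1) stop("B must be >= 1")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  M <- matrix(v[idx], nrow = n)
  bmeans <- colMeans(M)
  bsds <- apply(M, 2, stats::sd)
  if (n == 1) bsds[] <- 0
  ci <- unname(stats::quantile(bmeans, c(0.05, 0.95), type = 7))
  list(mean = mean(bmeans), sd = mean(bsds), ci = ci,
       mean_min = mean(bmeans) * sample$T0,
       sample_mean_min = mean(v) * sample$T0, B = B, n = n)
}

#' Derive dot-count signals and a profile from a simulated trajectory
#'
#' Computes, at each recorded time, the fraction of cells with exactly one
#' and exactly two active her1 gene copies (the in-silico analogue of the
#' one-dot and two-dot FISH signals), then maps a time window onto the
#' normalised anteroposterior axis with the frozen-wave correspondence: one
#' clock period `T0` spans one local wavelength `S_loc`, later times lying
#' more posterior (smaller `x`).  No cell advection enters this map, so the
#' returned profile carries `S0 = 0` and [estimate_embryo_delay()] inverts
#' the map exactly.
#'
#' @param traj A hybrid-variant `clock_trajectory` recorded with
#'   `record_genes = TRUE`.
#' @param T0 Clock period used for the mapping (min, default 30).
#' @param S_loc Imposed local wavelength on the normalised axis (default
#'   0.3).
#' @param K Number of intervals of the output profile (default 40).
#' @param window `c(t_lo, t_hi)` time window (min) to map; default the last
#'   `2 * T0` minutes.
#' @param dot_persistence Minutes a transcription-site dot remains visible
#'   after its gene copy shuts off (nascent transcripts keep elongating, so
#'   the FISH dot outlives the active state; default 7, the transcription
#'   delay).  Applied per gene copy; dot onset times are unaffected.
#' @return List with `signals` (data.frame `time`, `frac1`, `frac2`) and
#'   `profile` (a [dot_count_profile()]).
#' @export
dotcounts_from_simulation <- function(traj, T0 = 30, S_loc = 0.3, K = 40,
                                      window = NULL, dot_persistence = 7) {
  if (is.null(traj$genes_active))
    stop("trajectory lacks gene-state records (record_genes = TRUE)")
  M <- traj$genes_active$g_h1_mask
  if (is.null(M)) M <- traj$genes_active$g_h1  # counts-only fallback
  if (dot_persistence > 0) {
    w <- max(1L, round(dot_persistence / traj$record_dt))
    M <- apply_dot_persistence(M, w)
  }
  G <- (M %% 2L) + (M %/% 2L)
  frac1 <- rowMeans(G == 1)
  frac2 <- rowMeans(G == 2)
  signals <- data.frame(time = traj$time, frac1 = frac1, frac2 = frac2)
  if (is.null(window)) window <- c(max(traj$time) - 2 * T0, max(traj$time))
  sel <- which(traj$time >= window[1] & traj$time <= window[2])
  if (length(sel) < 2 * K)
    stop("time window too short for ", K, " intervals")
  tt <- traj$time[sel]
  # later time -> more posterior (smaller x)
  x <- (max(tt) - tt) * S_loc / T0
  n_cells <- ncol(G)
  br <- seq(0, max(x) + 1e-9, length.out = K + 1)
  bin <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  one <- tapply(rowSums(G[sel, , drop = FALSE] == 1), bin, sum)
  two <- tapply(rowSums(G[sel, , drop = FALSE] == 2), bin, sum)
  ntot <- tapply(rep(n_cells, length(sel)), bin, sum)
  keep <- !is.na(one)
  prof <- dot_count_profile(one[keep], two[keep], ntot[keep],
                            S0 = 0, L = 1, T0 = T0)
  # the binned axis is compressed to [0, span]; rescale interval->x mapping
  # by storing the true span via attribute used by smooth_profile's x in
  # [0,1]: rescale S_loc accordingly
  attr(prof, "x_span") <- max(x)
  list(signals = signals, profile = prof,
       S_loc_scaled = S_loc / max(x))
}
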