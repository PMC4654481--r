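#' Generate a synthetic embryo dot-count profile with known truth
#'
#' Emulates the frozen spatial wave of her1 transcription-site counts along
#' the anteroposterior axis.  The clock slows anteriorly, so the local
#' wavelength `S(x)` shrinks from `S_post` at the tail end of the notochord
#' to `S_ant` at the anterior end of the PSM; the phase field is
#' `phi(x) = 2*pi*integral_x^1 ds/S(s)` (posterior cells are phase-advanced).
#' Allele 1 is active with probability `g(phi(x))`, a smoothed square wave
#' with the given duty cycle; allele 2 follows the same wave with an extra
#' phase lag `2*pi*true_delay*(1 - v(x)*S0/S(x))`, which places its pattern
#' posterior to allele 1's by `true_delay * (S(x) - v(x)*S0)` - exactly the
#' kinematics inverted by [spatial_to_temporal_delay()].  Both alleles of a
#' nucleus share one activation-threshold jitter (they sit in the same
#' nuclear environment), so the two-dot wave is an exact lagged copy of the
#' at-least-one-dot wave; nuclei are sampled per interval at that joint law.
#'
#' @param true_delay Inter-allele delay as a proportion of `T0`, in
#'   `[0, 1)`.
#' @param T0 Somite period, minutes (default 30).
#' @param S0 Somite length, normalised units (default 0.12).
#' @param L PSM length, normalised units (default 1).
#' @param K Number of intervals (default 40).
#' @param nuclei_per_interval Nuclei sampled per interval (default 40).
#' @param S_post,S_ant Posterior and anterior local wavelength (defaults
#'   0.4 and 0.2).
#' @param duty Active fraction of the cycle (default 0.5).
#' @param steepness Logistic steepness of the smoothed square wave
#'   (default 8).
#' @param phase Global phase offset of the pattern, radians (default 0.6,
#'   placing a full rising edge inside the domain).
#' @param noise If `FALSE`, expected counts are used instead of sampling.
#' @param seed Integer seed.
#' @return A [dot_count_profile()] with attributes `true_delay_frac` and
#'   `true_delay_min`.
#' @export
generate_embryo_profile <- function(true_delay, T0 = 30, S0 = 0.12, L = 1,
                                    K = 40, nuclei_per_interval = 40,
                                    S_post = 0.4, S_ant = 0.2, duty = 0.5,
                                    steepness = 8, phase = 0.6,
                                    noise = TRUE, seed = 1) {
  if (true_delay < 0 || true_delay >= 1)
    stop("true_delay must be in [0, 1) as a proportion of T0")
  if (K < 10) stop("need at least 10 intervals")
  if (nuclei_per_interval < 1) stop("nuclei_per_interval must be >= 1")
  xi <- (seq_len(K) - 0.5) / K
  S <- function(x) S_post - (S_post - S_ant) * x
  # phi(x) = 2*pi * integral from x to 1 of 1/S  (posterior more advanced)
  a <- (S_post - S_ant)
  phi <- function(x) 2 * pi * (log(S(x)) - log(S(1))) / a + phase
  g <- function(ph) stats::plogis(steepness * (cos(ph) - cos(pi * duty)))
  a1 <- g(phi(xi))
  lag <- 2 * pi * true_delay * (1 - (xi / L) * S0 / S(xi))
  a2 <- g(phi(xi) - lag)
  # the two alleles of one nucleus share the nuclear repression state: both
  # activation indicators use a common per-nucleus threshold jitter, so the
  # second allele's wave is an exact phase-lagged copy of the first's
  # (comonotone coupling): P(>=1 dot) = max(a1, a2), P(2 dots) = min
  p_any <- pmax(a1, a2)
  p2 <- pmin(a1, a2)
  p1 <- p_any - p2
  n <- nuclei_per_interval
  if (noise) {
    set.seed(seed)
    one <- two <- numeric(K)
    for (i in seq_len(K)) {
      eta <- stats::rlogis(n, 0, 1 / steepness)
      on1 <- cos(phi(xi[i])) - cos(pi * duty) + eta > 0
      on2 <- cos(phi(xi[i]) - lag[i]) - cos(pi * duty) + eta > 0
      one[i] <- sum(xor(on1, on2))
      two[i] <- sum(on1 & on2)
    }
  } else {
    one <- p1 * n
    two <- p2 * n
  }
  prof <- dot_count_profile(one, two, rep(n, K), S0 = S0, L = L, T0 = T0)
  attr(prof, "true_delay_frac") <- true_delay
  attr(prof, "true_delay_min") <- true_delay * T0
  prof
}

#' Generate a cohort of per-embryo delay values
#'
#' Draws i.i.d. per-embryo inter-allele delays (proportions of `T0`) from a
#' point-mass or zero-truncated Gaussian specification; used for bootstrap
#' property and coverage tests.
#'
#' @param n_embryos Cohort size.
#' @param spec List: `kind = "point"` with `value`, or `kind = "gaussian"`
#'   with `mean`, `sd` (resampled until non-negative).
#' @param seed Integer seed.
#' @param T0 Somite period (min).
#' @return A [delay_sample()] with attribute `true_mean`.
#' @export
generate_delay_cohort <- function(n_embryos,
                                  spec = list(kind = "gaussian",
                                              mean = 0.11, sd = 0.06),
                                  seed = 1, T0 = 30) {
  if (n_embryos < 1) stop("n_embryos must be >= 1")
  set.seed(seed)
  vals <- switch(spec$kind,
    point = rep(spec$value, n_embryos),
    gaussian = {
      v <- numeric(n_embryos)
      for (i in seq_len(n_embryos)) {
        repeat {
          x <- stats::rnorm(1, spec$mean, spec$sd)
          if (x >= 0) break
        }
        v[i] <- x
      }
      v
    },
    stop("unknown cohort spec kind: ", spec$kind)
  )
  out <- delay_sample(vals, T0 = T0)
  attr(out, "true_mean") <- switch(spec$kind,
    point = spec$value,
    gaussian = truncnorm_mean(spec$mean, spec$sd))
  out
}

# mean of a Gaussian truncated at zero
truncnorm_mean <- function(mu, sd) {
  a <- -mu / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

#' Generate a sinusoid-plus-noise phase ensemble
#'
#' Calibration fixture for the desynchronisation detector: `n_cells` cells
#' with observable `A_i * (1 + sin(2*pi*t/period + phi_i(t)))`, where the
#' initial phases are common, Gaussian, or uniform on the cycle, and may
#' drift apart linearly in time (`phi_i(t) = phi_i + 2*pi*eta_i*t/period`
#' with `eta_i ~ N(0, drift^2)`).
#'
#' @param n_cells Number of cells (>= 2).
#' @param period Oscillation period, minutes (default 30).
#' @param phase List: `kind` in `"common"`, `"gaussian"` (with `sd`,
#'   radians), `"uniform"`.
#' @param amp_noise SD of the per-cell multiplicative amplitude factor
#'   around 1 (default 0.2; factors are resampled until positive).
#' @param drift Per-period phase-drift rate SD (cycles per cycle,
#'   default 0).
#' @param obs_noise SD of additive per-sample observation noise (default 0;
#'   fresh at every sample, so consecutive ensemble snapshots decorrelate
#'   the way measurement noise does).
#' @param phase_diffusion SD of the per-cell random-walk phase increment,
#'   radians per sqrt(minute) (default 0).  A desynchronised ensemble is
#'   not frozen: each cell's phase keeps diffusing, which is what makes the
#'   phase mosaic statistically stationary rather than periodic.
#' @param duration Simulated minutes.
#' @param record_dt Sampling interval, minutes.
#' @param seed Integer seed.
#' @return A `clock_trajectory`-compatible object (observable `p_h1`) with
#'   attribute `phase_kind`.
#' @export
generate_phase_ensemble <- function(n_cells, period = 30,
                                    phase = list(kind = "common"),
                                    amp_noise = 0.2, drift = 0,
                                    obs_noise = 0, phase_diffusion = 0,
                                    duration = 600,
                                    record_dt = 1, seed = 1) {
  if (n_cells < 2) stop("need at least 2 cells")
  set.seed(seed)
  tt <- seq(0, duration, by = record_dt)
  phi0 <- switch(phase$kind,
    common = rep(0, n_cells),
    gaussian = stats::rnorm(n_cells, 0, phase$sd),
    uniform = stats::runif(n_cells, 0, 2 * pi),
    stop("unknown phase spec kind: ", phase$kind)
  )
  A <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    repeat {
      a <- stats::rnorm(1, 1, amp_noise)
      if (a > 0.05) break
    }
    A[i] <- a
  }
  eta <- if (drift > 0) stats::rnorm(n_cells, 0, drift) else rep(0, n_cells)
  X <- sapply(seq_len(n_cells), function(i) {
    wob <- 0
    if (phase_diffusion > 0)
      wob <- cumsum(stats::rnorm(length(tt), 0,
                                 phase_diffusion * sqrt(record_dt)))
    A[i] * (1 + sin(2 * pi * tt / period + phi0[i] +
                      2 * pi * eta[i] * tt / period + wob))
  })
  if (obs_noise > 0) X <- X + stats::rnorm(length(X), 0, obs_noise)
  structure(list(time = tt, species = list(p_h1 = X), mode = "synthetic",
                 variant = "synthetic", seed = seed, dt = record_dt,
                 record_dt = record_dt, n_cells = n_cells, params = NULL),
            class = "clock_trajectory")
}
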