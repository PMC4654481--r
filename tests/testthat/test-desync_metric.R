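make_traj <- function(time, X) {
  structure(list(time = time, species = list(p_h1 = X), mode = "synthetic",
                 variant = "synthetic", record_dt = diff(time[1:2]),
                 n_cells = ncol(X)),
            class = "clock_trajectory")
}

test_that("KS p-values are uniform under the null and tiny for peak-vs-trough", {
  # same stationary distribution at both lags: p approximately U(0,1)
  set.seed(1)
  reps <- replicate(400, {
    X <- matrix(stats::rnorm(40 * 60), 40, 60)
    tr <- make_traj(0:39, X)
    ks_pvalue_series(tr, offset = 16)$p[1]
  })
  expect_lt(abs(mean(reps) - 0.5), 0.05)

  # synchronous cells at trough vs peak: disjoint samples, p ~ 0
  tt <- seq(0, 99, by = 1)
  X <- sapply(1:50, function(i) (0.8 + 0.01 * i) * (1 + sin(2 * pi * tt / 32)))
  tr <- make_traj(tt, X)
  ps <- ks_pvalue_series(tr, offset = 16)
  expect_lt(min(ps$p), 1e-6)
  expect_error(ks_pvalue_series(make_traj(0:39, matrix(1, 40, 1))), "cells")
})

test_that("desynchronisation is declared only when p clears a full cycle", {
  ps <- data.frame(time = 0:200, p = rep(1, 201))
  r <- desync_time(ps, period = 30)
  expect_true(r$desynchronised)
  expect_equal(r$time, 0)

  ps$p <- 0.05
  expect_false(desync_time(ps, period = 30)$desynchronised)

  # dips recurring once per cycle postpone the declaration
  ps$p <- ifelse(ps$time < 100, ifelse(ps$time %% 30 < 3, 0.01, 0.9), 0.9)
  r2 <- desync_time(ps, period = 30,
                    mean_peaks = seq(15, 200, by = 30))
  expect_true(r2$desynchronised)
  expect_gte(r2$time, 92)
  expect_error(desync_time(ps[1:10, ], period = 30), "shorter")
})

test_that("detector calibration: synchronous ensembles never fire, uniform phases fire fast", {
  # common phase + independent amplitude noise, 20 cycles
  sync <- generate_phase_ensemble(80, period = 30, amp_noise = 0.3,
                                  phase = list(kind = "common"),
                                  obs_noise = 0.05,
                                  duration = 600, seed = 2)
  ds <- desync_summary(sync)
  expect_false(ds$desynchronised)

  # uniformly random, still-diffusing phases (a salt-and-pepper mosaic is
  # statistically stationary, not frozen): declared within ~2 cycles
  fire <- sapply(1:3, function(s) {
    rand <- generate_phase_ensemble(80, period = 30, amp_noise = 0.3,
                                    phase = list(kind = "uniform"),
                                    phase_diffusion = 0.5,
                                    duration = 300, seed = s)
    r <- desync_time(ks_pvalue_series(rand, offset = 16), period = 30)
    expect_true(r$desynchronised)
    r$time
  })
  expect_lte(stats::median(fire), 60)

  # faster linear phase drift leads to earlier declaration
  t_fire <- sapply(c(0.03, 0.09), function(dr) {
    tr <- generate_phase_ensemble(80, period = 30, amp_noise = 0.2,
                                  phase = list(kind = "common"),
                                  drift = dr, duration = 800, seed = 4)
    desync_summary(tr)$time
  })
  expect_true(all(is.finite(t_fire)))
  expect_lt(t_fire[2], t_fire[1])
})

test_that("per-cell amplitude and period diagnostics recover a sinusoid", {
  tt <- seq(0, 300, by = 0.5)
  A <- c(3, 5)
  X <- sapply(A, function(a) a * sin(2 * pi * tt / 30))
  tr <- make_traj(tt, X)
  ap <- amplitude_period_per_cell(tr)
  for (i in 1:2) {
    expect_equal(stats::median(ap[[i]]$period, na.rm = TRUE), 30,
                 tolerance = 0.05)
    expect_equal(stats::median(ap[[i]]$amplitude, na.rm = TRUE), 2 * A[i],
                 tolerance = 0.06)
  }
  # constant trace: empty series, not an error
  flat <- make_traj(tt, cbind(rep(1, length(tt)), rep(2, length(tt))))
  expect_equal(nrow(amplitude_period_per_cell(flat)[[1]]), 0)
})

test_that("phase spread follows the linear drift law for fixed period offsets", {
  tt <- seq(0, 400, by = 0.5)
  dper <- c(-0.6, -0.2, 0.2, 0.6)  # per-cell period offsets around 30
  X <- sapply(dper, function(d) 1 + sin(2 * pi * tt / (30 + d)))
  tr <- make_traj(tt, X)
  ps <- phase_spread(tr)
  # k-th peak of period T+d sits near (k - 1/4) (T+d): spread grows ~ k sd(d)
  sel <- ps$oscillation %in% 3:10
  fit <- stats::lm(spread ~ oscillation, data = ps[sel, ])
  expect_equal(unname(stats::coef(fit)[2]), stats::sd(dper),
               tolerance = 0.12)

  ident <- make_traj(tt, sapply(1:4, function(i) sin(2 * pi * tt / 30)))
  expect_true(all(phase_spread(ident)$spread == 0))
  expect_error(phase_spread(make_traj(tt, X[, 1, drop = FALSE])), "cells")
})

test_that("phase spread grows faster for smaller koff (uncoupled ensembles)", {
  spread_at <- function(koff, k = 6) {
    p <- hybrid_params(koff = koff)
    tr <- simulate_ensemble(p, 25, t_end = 320, seed = 5)
    ps <- phase_spread(tr)
    ps$spread[ps$oscillation == k]
  }
  expect_gt(spread_at(1 / 6), spread_at(1))
})
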