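test_that("gaussian per-cell draws have the declared moments and truncation", {
  base <- det_params()
  sp <- variability_spec("alpha_h1", "gaussian", mean = 33, sd = 9)
  cp <- draw_cell_params(base, sp, 400, seed = 1)
  expect_lt(abs(mean(cp$alpha_h1) - 33), 3 * 9 / sqrt(400))
  expect_true(all(cp$alpha_h1 >= 1))  # oscillation-preserving bound

  # declared bounds are respected by resampling
  spb <- variability_spec("beta_h1", "gaussian", mean = 9.2, sd = 1.5)
  cpb <- draw_cell_params(base, spb, 500, seed = 2)
  expect_true(all(cpb$beta_h1 >= 4.6))

  # sd = 0 leaves every cell at the base value
  sp0 <- variability_spec("tau_mh", "gaussian", mean = 7, sd = 0)
  cp0 <- draw_cell_params(base, sp0, 10, seed = 3)
  expect_true(all(cp0$tau_mh == 7))

  expect_error(draw_cell_params(base, variability_spec(
    "no_such_param", "gaussian", mean = 1, sd = 1), 5), "unknown")
})

test_that("generalised Pareto transcription-delay spec reproduces mean 7, variance 1.5", {
  mo <- gpareto_moments(5.84, 1.10, 0.05)
  expect_equal(mo$mean, 7, tolerance = 1e-3)
  expect_equal(mo$variance, 1.5, tolerance = 0.01)

  # sample moments converge to the analytic ones
  u <- (seq_len(2e5) - 0.5) / 2e5
  q <- qgpareto(u, 5.84, 1.10, 0.05)
  expect_equal(mean(q), mo$mean, tolerance = 0.01)
  expect_equal(stats::var(q), mo$variance, tolerance = 0.05)

  base <- det_params()
  sp <- variability_spec("tau_mh", "gpd", location = 5.84, scale = 1.10,
                         shape = 0.05)
  cp <- draw_cell_params(base, sp, 500, seed = 4)
  expect_lt(abs(mean(cp$tau_mh) - 7), 3 * sqrt(1.5 / 500))
  expect_true(all(cp$tau_mh >= 5))
})

test_that("a spec naming several fields applies one shared draw per cell", {
  base <- det_params()
  sp <- variability_spec(c("alpha_h1", "alpha_h7"), "gaussian",
                         mean = 33, sd = 9)
  cp <- draw_cell_params(base, sp, 50, seed = 5)
  expect_identical(cp$alpha_h1, cp$alpha_h7)
  expect_gt(stats::sd(cp$alpha_h1), 0)
})

test_that("per-cell parameters stay fixed for the whole simulation", {
  base <- det_params()
  sp <- variability_spec("tau_mh", "gaussian", mean = 7, sd = 0.5)
  cp <- draw_cell_params(base, sp, 12, seed = 6)
  tr <- simulate_ensemble(cp, mode = "uncoupled", t_end = 400, seed = 6)
  ap <- amplitude_period_per_cell(tr)
  per <- vapply(ap, function(d) stats::median(d$period, na.rm = TRUE),
                numeric(1))
  # distinct delays give distinct, stable per-cell periods
  expect_gt(stats::sd(per), 0.2)
  wobble <- vapply(ap, function(d) stats::sd(d$period, na.rm = TRUE),
                   numeric(1))
  expect_lt(stats::median(wobble, na.rm = TRUE), 3)
})
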