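test_that("profile smoothing preserves constants and localised mass", {
  K <- 40
  prof <- dot_count_profile(rep(12, K), rep(6, K), rep(40, K))
  sp <- smooth_profile(prof, bandwidth = 2)
  expect_true(all(abs(sp$f1 - 0.3) < 1e-10))
  expect_true(all(abs(sp$f2 - 0.15) < 1e-10))

  # delta spike: smoothed mass (integral) preserved within 1%
  one <- rep(0, K); one[20] <- 40
  spike <- dot_count_profile(one, rep(0, K), rep(40, K))
  sps <- smooth_profile(spike, bandwidth = 2, n_grid = 4001)
  mass <- sum(sps$f1) * (sps$x[2] - sps$x[1])
  expect_equal(mass, 1 / K, tolerance = 0.01)

  expect_error(smooth_profile(dot_count_profile(rep(0, K), rep(0, K),
                                                rep(10, K))), "zero")
  expect_error(dot_count_profile(c(5, 5), c(6, 6), c(10, 10)), "exceed")
})

test_that("rising inflection of a logistic edge is exact and scale invariant", {
  x <- seq(0, 1, length.out = 2001)
  x0 <- 0.37
  for (A in c(1, 7.3)) {
    curve <- list(x = x, f1 = A / (1 + exp(-40 * (x - x0))))
    xi <- find_rising_inflection(curve, "f1", window = c(0.1, 0.9))
    expect_equal(as.numeric(xi), x0, tolerance = 2e-3)
  }
  # flat curve: no inflection
  expect_error(find_rising_inflection(list(x = x, f1 = rep(1, length(x))),
                                      "f1", window = c(0.1, 0.9)))
})

test_that("local wavelength tracks constant and chirped waves", {
  x <- seq(0, 1, length.out = 2001)
  sp <- list(x = x, f1 = sin(2 * pi * x / 0.25))
  expect_equal(local_wavelength(sp, 0.5), 0.25, tolerance = 0.01)

  # chirp: wavelength ~ W0 (1 + x); phase = integral of 1/W
  W0 <- 0.1
  phase <- 2 * pi * log1p(x) / W0
  spc <- list(x = x, f1 = sin(phase))
  for (xm in c(0.3, 0.6)) {
    expect_equal(local_wavelength(spc, xm), W0 * (1 + xm), tolerance = 0.1 *
                   W0 * (1 + xm))
  }
  expect_error(local_wavelength(list(x = x, f1 = x), 0.5), "extrema")
})

test_that("spatial-to-temporal conversion matches hand arithmetic and its limit", {
  # worked triple
  expect_equal(spatial_to_temporal_delay(0.02, x = 0.1, S_x = 0.25,
                                         S0 = 0.12, T0 = 30, L = 1),
               30 * 0.02 / (0.25 - 0.1 * 0.12))
  expect_equal(spatial_to_temporal_delay(0.02, 0.1, 0.25, 0.12, 30, 1),
               2.521, tolerance = 1e-3)
  # x -> 0 reduces to T0 dx / S(x)
  expect_equal(spatial_to_temporal_delay(0.05, 0, 0.3, 0.12, 30, 1),
               30 * 0.05 / 0.3)
  # zero offset, zero delay; one wavelength at the tail = one full period
  expect_equal(spatial_to_temporal_delay(0, 0.4, 0.3, 0.12, 30, 1), 0)
  expect_equal(spatial_to_temporal_delay(0.3, 0, 0.3, 0.12, 30, 1), 30)
  expect_error(spatial_to_temporal_delay(0.02, 1, 0.1, 0.2, 30, 1),
               "invalid")
})

test_that("noise-free profiles close the loop within 2%", {
  pr <- generate_embryo_profile(0.10, noise = FALSE)
  est <- estimate_embryo_delay(pr)
  expect_equal(est$delay_frac, 0.10, tolerance = 0.02)
  expect_equal(est$delay_min, 3, tolerance = 0.1)
  # the two-dot wave sits posterior to the one-dot wave
  expect_lt(est$x2, est$x1)
  prof0 <- dot_count_profile(rep(c(0, 10), 20), rep(0, 40), rep(40, 40))
  expect_error(estimate_embryo_delay(prof0), "two-dot")
})

test_that("bootstrap inference has the contracted degenerate and limit behaviour", {
  # identical values: mean v, sd 0, interval [v, v]
  bt <- bootstrap_delay(delay_sample(rep(0.2, 9)), B = 500, seed = 1)
  expect_equal(bt$mean, 0.2)
  expect_equal(bt$sd, 0)
  expect_equal(unname(bt$ci), c(0.2, 0.2))

  # single embryo: resample sd is zero by convention
  bt1 <- bootstrap_delay(delay_sample(0.1), B = 200, seed = 1)
  expect_equal(bt1$sd, 0)

  # bootstrap mean converges to the sample mean
  set.seed(2)
  v <- stats::rlnorm(13, log(0.1), 0.5)
  bt2 <- bootstrap_delay(delay_sample(v), B = 20000, seed = 3)
  se <- stats::sd(v) / sqrt(13) / sqrt(20000 / 13)
  expect_lt(abs(bt2$mean - mean(v)), 3 * stats::sd(v) / sqrt(13 * 20000) * 50)
  expect_lt(abs(bt2$mean - mean(v)), 0.005)
  # point-mass cohort: bootstrap mean is exactly the mass point
  pc <- generate_delay_cohort(7, list(kind = "point", value = 0.1), seed = 4)
  expect_equal(bootstrap_delay(pc, B = 100, seed = 5)$mean, 0.1)
  expect_error(bootstrap_delay(delay_sample(numeric(0))), "non-empty")
})

test_that("bootstrap percentile interval has near-nominal coverage", {
  # 5th-95th percentile interval: ~90% nominal coverage of the true mean
  hit <- 0
  n_cohort <- 250
  for (i in seq_len(n_cohort)) {
    co <- generate_delay_cohort(13, list(kind = "gaussian", mean = 0.11,
                                         sd = 0.06), seed = i)
    truth <- attr(co, "true_mean")
    bt <- bootstrap_delay(co, B = 400, seed = i + 1000)
    if (truth >= bt$ci[1] && truth <= bt$ci[2]) hit <- hit + 1
  }
  cover <- hit / n_cohort
  expect_gt(cover, 0.80)
  expect_lt(cover, 0.97)
})

test_that("in-silico dot counts behave at the limits", {
  # all genes permanently active: two-dot fraction 1, one-dot 0
  p <- hybrid_params(kon_rep = 0)
  tr <- simulate_ensemble(p, 4, t_end = 100, seed = 1, record_dt = 0.5)
  dc <- dotcounts_from_simulation(tr, T0 = 30)
  expect_true(all(dc$signals$frac2 == 1))
  expect_true(all(dc$signals$frac1 == 0))
  expect_true(all(dc$profile$two_dot == dc$profile$total))

  notr <- simulate_ensemble(p, 4, t_end = 100, seed = 1,
                            record_genes = FALSE)
  expect_error(dotcounts_from_simulation(notr, T0 = 30), "gene-state")
})

test_that("the synthetic fixture sample loads and bootstrap runs on it", {
  path <- system.file("extdata", "synthetic_delay_sample.csv",
                      package = "herclock")
  ds <- read_delay_sample(path)
  expect_equal(ds$n, 13)
  bt <- bootstrap_delay(ds, B = 2000, seed = 9)
  expect_true(bt$ci[1] < bt$mean && bt$mean < bt$ci[2])
  # values are delay fractions of T0 at a biologically sensible scale
  expect_true(all(ds$values > 0 & ds$values < 0.5))
})
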