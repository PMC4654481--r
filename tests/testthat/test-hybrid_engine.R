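test_that("integrator reproduces closed forms for decay and delayed onset", {
  # pure decay: all genes silenced, p(0) = 100, lambda = 0.23
  p <- hybrid_params(alpha_h1 = 0, alpha_h7 = 0)
  tr <- simulate_ensemble(p, 1, t_end = 10, record_dt = 1, seed = 1,
                          init_state = c(p_h1 = 100),
                          init_occupancy = rep("REP_H1", 4))
  p10 <- tail(tr$species$p_h1[, 1], 1)
  expect_lt(abs(p10 - 100 * exp(-0.23 * 10)) / (100 * exp(-2.3)), 1e-3)

  # step activation: genes on from t = 0 (kon = 0 keeps them free),
  # mRNA follows (alpha/lambda) (1 - exp(-lambda t)) exactly
  p2 <- hybrid_params(kon_rep = 0)
  tr2 <- simulate_ensemble(p2, 1, t_end = 12, record_dt = 1, seed = 1,
                           record = "all")
  m <- tr2$species$m_h1[, 1]
  expected <- (p2$alpha_h1 / p2$lambda_mh) *
    (1 - exp(-p2$lambda_mh * tr2$time))
  expect_lt(max(abs(m - expected) / max(expected)), 1e-3)

  # protein translation starts only after the translation delay
  pr <- tr2$species$p_h1[, 1]
  expect_equal(pr[tr2$time <= p2$tau_ph1], rep(0, sum(tr2$time <= 1.1)))
  expect_gt(pr[tr2$time == 3], 0)

  # zero-length integration leaves the state unchanged
  tr0 <- simulate_ensemble(p2, 1, t_end = 0.01, record_dt = 0.01, seed = 1,
                           init_state = c(p_h1 = 50))
  expect_equal(tr0$species$p_h1[1, 1], 50)
  expect_error(simulate_ensemble(p2, 1, t_end = -5, seed = 1))
  expect_error(simulate_ensemble(p2, 1, t_end = 10, dt = 2, seed = 1),
               "smallest")
})

test_that("trajectories are seed-deterministic and non-negative", {
  p <- hybrid_params()
  a <- simulate_ensemble(p, 5, t_end = 120, seed = 7)
  b <- simulate_ensemble(p, 5, t_end = 120, seed = 7)
  d <- simulate_ensemble(p, 5, t_end = 120, seed = 8)
  expect_identical(a$species$p_h1, b$species$p_h1)
  expect_false(identical(a$species$p_h1, d$species$p_h1))
  expect_true(all(a$species$p_h1 >= 0))
})

test_that("huge koff with kon = 0 reduces to the fully active deterministic solution", {
  p <- hybrid_params(kon_rep = 0, koff = 1e6)
  tr <- simulate_ensemble(p, 1, t_end = 80, seed = 1, record = "all")
  expect_true(all(tr$genes_active$g_h1 == 2L))  # both copies active
  # two-genes-on ODE fixed point for mRNA
  expect_lt(abs(tail(tr$species$m_h1[, 1], 1) -
                  p$alpha_h1 / p$lambda_mh) / (p$alpha_h1 / p$lambda_mh),
            0.01)
})

test_that("repressor dissociation times on the simulated path are exponential", {
  # kon = 0: each initially bound copy frees once at rate koff; the event
  # times across 100 cells x 4 copies must be Exp(koff)
  p <- hybrid_params(kon_rep = 0, koff = 1 / 3, alpha_h1 = 0, alpha_h7 = 0)
  tr <- simulate_ensemble(p, 100, t_end = 60, seed = 3,
                          init_occupancy = rep("REP_H1", 4),
                          return_events = TRUE)
  ev <- tr$events
  expect_true(all(ev$to == 0))
  ks <- suppressWarnings(stats::ks.test(ev$time, stats::pexp, rate = 1 / 3))
  expect_gt(ks$p.value, 0.01)
  expect_gt(nrow(ev), 350)  # nearly all 400 copies released within 60 min
})

test_that("event sampler inverts constant and linear cumulative hazards", {
  # constant hazard: exponential with the right mean, and agreement with
  # the textbook direct method
  tt <- sample_next_event(c(0, 100), c(2, 2), n = 10000, seed = 1)
  expect_lt(abs(mean(tt) - 0.5), 0.02)
  ks <- suppressWarnings(stats::ks.test(tt, stats::pexp, rate = 2))
  expect_gt(ks$p.value, 0.01)

  # linear hazard a(s) = c s: T = sqrt(2 (-log u) / c) in closed form
  cc <- 0.5
  grid <- seq(0, 40, by = 0.05)
  tt2 <- sample_next_event(grid, cc * grid, n = 10000, seed = 2)
  set.seed(4)
  ref <- sqrt(2 * (-log(stats::runif(10000))) / cc)
  ks2 <- suppressWarnings(stats::ks.test(tt2, ref))
  expect_gt(ks2$p.value, 0.01)

  # hazard that never accumulates to the threshold yields Inf
  expect_true(is.infinite(sample_next_event(c(0, 1), c(1e-9, 1e-9),
                                            n = 1, seed = 1)))
})

test_that("delayed-direct sampler matches a fine-grid Bernoulli oracle", {
  # oscillating hazard, compared at n = 1e4 draws
  times <- seq(0, 30, by = 0.1)
  hz <- 1 + 0.8 * sin(2 * pi * times / 7)
  draws <- sample_next_event(times, hz, n = 10000, seed = 5)
  oracle <- bernoulli_grid_event_times(times, hz, dt = 1e-3, n = 10000,
                                       seed = 6)
  ks <- suppressWarnings(stats::ks.test(draws, oracle))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("uncoupled cells with distinct streams are statistically independent", {
  p <- hybrid_params(koff = 1 / 3)
  tr <- simulate_ensemble(p, 20, t_end = 500, seed = 11)
  sel <- tr$time >= 250  # after phase randomisation has set in
  X <- tr$species$p_h1[sel, ]
  cors <- stats::cor(X)[upper.tri(diag(20))]
  expect_lt(abs(mean(cors)), 0.15)
})
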