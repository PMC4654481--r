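test_that("default parameter sets carry the fitted means and variant fields", {
  h <- make_default_params("hybrid")
  expect_equal(h$alpha_h1, 33)
  expect_equal(h$beta_h1, 9.2)
  expect_equal(h$lambda_mh, 0.23)
  expect_equal(h$lambda_ph, 0.23)
  expect_equal(h$tau_mh, 7)
  expect_equal(h$tau_ph1, 1.1)
  expect_equal(h$tau_ph7, 0.7)
  expect_equal(h$p_h6, 100)
  expect_equal(h$koff, 1 / 3)
  expect_true(h$kon_rep > 0 && h$kon_nicd > 0)

  d <- make_default_params("deterministic")
  expect_null(d$koff)
  expect_null(d$kon_rep)
  expect_null(d$kon_nicd)
  expect_true(d$P0_h1 > 0 && d$P0_h7 > 0)

  expect_error(make_default_params("nonsense"))

  rates <- unlist(h[c("alpha_h1", "beta_h1", "lambda_mh", "lambda_ph",
                      "koff", "kon_rep")])
  delays <- unlist(h[c("tau_mh", "tau_ph1", "tau_ph7", "tau_md", "tau_pd",
                       "tau_pN")])
  expect_true(all(rates >= 0) && all(delays >= 0))
})

test_that("smooth repression factor has the contracted shape", {
  p <- det_params()
  expect_equal(regulation_factor(0, 0, p), 1)
  expect_equal(regulation_factor(p$P0_h1, 0, p), 0.5)
  # symbolic check of the default form at an arbitrary point
  p1 <- 137; p7 <- 61
  expect_equal(regulation_factor(p1, p7, p),
               1 / (1 + (p1 / p$P0_h1)^2 +
                      (p7 * p$p_h6 / (p$P0_h7 * p$p_h6_ref))^2))
  # monotone non-increasing in both arguments
  g1 <- regulation_factor(seq(0, 5000, by = 100), 50, p)
  g7 <- regulation_factor(50, seq(0, 5000, by = 100), p)
  expect_true(all(diff(g1) <= 0) && all(diff(g7) <= 0))
  # saturating repression limit
  expect_lt(regulation_factor(1e9, 0, p), 1e-10)
  expect_error(regulation_factor(-1, 0, p))
})

test_that("reaction channels follow the competitive binding scheme", {
  p <- hybrid_params(kon_rep = 1e-5)
  # all four copies repressor-bound, no Notch: only 4 dissociations
  ch <- reaction_channels(rep("REP_H1", 4), 100, 100, 0, p)
  expect_equal(nrow(ch), 4)
  expect_true(all(ch$reaction == "unbind"))
  expect_true(all(ch$propensity == p$koff))

  # no proteins, all free: association propensities all zero
  ch0 <- reaction_channels(rep("FREE", 4), 0, 0, 0, p, notch = TRUE)
  expect_equal(sum(ch0$propensity), 0)

  # hand arithmetic: one free copy, p_h1 = 100, kon_rep = 1e-5
  ch1 <- reaction_channels(c("FREE", "REP_H1", "REP_H7", "REP_H1"),
                           100, 0, 0, p)
  her1 <- ch1$propensity[ch1$reaction == "bind_her1"]
  expect_equal(her1, 1e-5 * 100^2)  # = 0.1 per minute

  # channel counts: free copies get 2 channels (3 in notch mode)
  ch2 <- reaction_channels(c("FREE", "FREE", "REP_H7", "NICD"),
                           10, 10, 10, p, notch = TRUE)
  expect_equal(sum(ch2$reaction == "unbind"), 2)
  expect_equal(nrow(ch2), 2 * 3 + 2)
  expect_error(reaction_channels(rep("FREE", 3), 1, 1, 0, p))
})
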