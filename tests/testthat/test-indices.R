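test_that("per-triplet symmetry ratio: neutral cases, closed form, invariances", {
  # no data, and single-observed-triad neutrality, for a spread of tallies
  expect_equal(lr_sym_triplet(c(0, 0, 0), c(0, 0, 0), 1), 3 / 4)
  for (a in c(0.2, 1, 5)) for (C in c(0, 4, 9)) {
    expect_equal(lr_sym_triplet(c(C, 0, 0), c(9, 0, 0), a), 3 / 4)
  }
  # all three triads unanimous, a = 1: b_i = (1/2)^11 exactly
  b <- 0.5^11
  expect_equal(lr_sym_triplet(c(10, 10, 10), c(10, 10, 10), 1),
               1 - (1 - b)^3 - b^3, tolerance = 1e-12)
  # mirroring a whole triplet leaves the ratio unchanged
  set.seed(7)
  for (i in 1:10) {
    N <- sample(1:12, 3, replace = TRUE)
    C <- vapply(N, function(n) sample(0:n, 1), 0L)
    a <- runif(1, 0.2, 3)
    expect_equal(lr_sym_triplet(C, N, a), lr_sym_triplet(N - C, N, a),
                 tolerance = 1e-12)
  }
  # concentrated compatible data: evidence grows with N
  a <- 0.8
  vals <- sapply(1:12, function(N)
    log(lr_sym_triplet(c(N, 0, N), c(N, N, N), a)))
  expect_true(all(diff(vals) > 0))
})

test_that("a-priori benchmarks are exact for any prior", {
  d0 <- triad_data(NULL, stimuli = sprintf("s%02d", 1:6))
  for (a in c(0.25, 1, 2)) for (h in c(0, 0.1, 0.5)) {
    p <- choice_prior(a, h)
    expect_equal(isym(d0, p)$value, log(3 / 4), tolerance = 1e-13)
    expect_equal(iumi(d0, p)$value, 0, tolerance = 1e-13)
    expect_equal(iaddtree(d0, p, h = 0)$value, log(2 / 3), tolerance = 1e-13)
  }
  # data confined to one triad per triplet cannot move Isym
  d1 <- triad_data(data.frame(ref = "s01", stim1 = "s02", stim2 = "s03",
                              C = 5, N = 5), stimuli = sprintf("s%02d", 1:4))
  expect_equal(isym(d1, choice_prior(0.5))$value, log(3 / 4), tolerance = 1e-13)
})

test_that("sign-configuration likelihood: empty-unit values and factorization", {
  p <- choice_prior(1)
  z3 <- rep(0L, 3)
  expect_equal(exp(l_q_polynomial(z3, z3, p, vsym_table(), h = 0)), 0.75)
  # ultrametric mass vanishes linearly in h with slope 3/4
  lum <- function(h) exp(l_q_polynomial(z3, z3, p, vumi_table(), h = h))
  s1 <- lum(1e-3) / 1e-3
  s2 <- lum(1e-4) / 1e-4
  expect_equal(s1, 3 / 4, tolerance = 2e-3)
  expect_equal(s2, 3 / 4, tolerance = 2e-4)
  expect_true(abs(s2 - 3 / 4) < abs(s1 - 3 / 4))  # linear convergence
  # an all-ones table factorizes into the product of beta integrals
  allones <- triadic:::.new_indicator_table("all", 3L, rep(1L, 27L))
  C <- c(3L, 1L, 0L); N <- c(5L, 4L, 2L); a <- 0.6
  expect_equal(l_q_polynomial(C, N, choice_prior(a), allones, h = 0),
               sum(lbeta(a + C, a + N - C) - lbeta(a, a)), tolerance = 1e-12)
  expect_error(l_q_polynomial(c(0, 0), c(0, 0), p, vsym_table()), "arity")
})

test_that("ultrametric ratio: positivity, limit behaviour, h_eval stability", {
  p <- choice_prior(1, 0.001)
  expect_error(lr_umi_triplet(c(0, 0, 0), c(0, 0, 0), p, h_eval = 0), "positive")
  # empty triplet: ratio / h -> 1
  for (h in c(1e-3, 1e-4)) {
    r <- lr_umi_triplet(c(0, 0, 0), c(0, 0, 0), p, h_eval = h)
    expect_equal(r / h, 1, tolerance = 3 * h)
  }
  expect_gt(lr_umi_triplet(c(5, 0, 2), c(5, 5, 4), p, h_eval = 0.001), 0)
  # index at small finite h approaches the exact limit linearly
  d <- toy_dataset(M = 6, N = 8, seed = 31)
  p6 <- fit_choice_prior(d, h = 0.001)
  v0 <- iumi(d, p6, h_eval = 0)$value
  v3 <- iumi(d, p6, h_eval = 1e-3)$value
  v4 <- iumi(d, p6, h_eval = 1e-4)$value
  expect_lt(abs(v3 - v4), 0.02)
  expect_lt(abs(v4 - v0), abs(v3 - v0))
})

test_that("additive-tree ratio is a likelihood ratio in [0, 1]", {
  p <- choice_prior(1)
  expect_equal(lr_addtree_tent(rep(0L, 6), rep(0L, 6), p, h = 0), 2 / 3,
               tolerance = 1e-13)
  set.seed(11)
  for (i in 1:10) {
    N <- sample(0:10, 6, replace = TRUE)
    C <- vapply(N, function(n) if (n == 0) 0L else sample(0:n, 1), 0L)
    for (h in c(0, 0.1)) {
      r <- lr_addtree_tent(C, N, choice_prior(runif(1, 0.3, 2)), h = h)
      expect_gte(r, 0); expect_lte(r, 1 + 1e-12)
    }
  }
})

test_that("closed-form unit likelihoods match Monte-Carlo integration", {
  set.seed(5)
  # one triplet and one tent, both priors with and without point mass
  C3 <- c(5L, 0L, 2L); N3 <- c(5L, 5L, 4L)
  C6 <- c(4L, 0L, 2L, 4L, 0L, 2L); N6 <- rep(4L, 6)
  for (h in c(0, 0.1)) {
    p <- choice_prior(1, h)
    cf <- exp(l_q_polynomial(C3, N3, p, vsym_table(), h = h))
    mc <- mc_region_likelihood(C3, N3, 1, h, sym_compatible, nsamp = 2e5)
    expect_lt(abs(cf - mc$mean), 3 * mc$se)
    cf6 <- exp(l_q_polynomial(C6, N6, p, vaddtree_tables()$addtree, h = h))
    mc6 <- mc_region_likelihood(C6, N6, 1, h, addtree_compatible, nsamp = 2e5)
    expect_lt(abs(cf6 - mc6$mean), 3 * mc6$se)
  }
})

test_that("index objects are means of per-unit contributions with methods", {
  d <- toy_dataset(M = 6, N = 4, seed = 12)
  fit <- triad_indices(d, h_eval = 0.001, surrogates = "flip_all")
  for (r in fit$indices) {
    expect_equal(r$value, mean(r$per_unit))
    expect_true(is.finite(r$se))
  }
  expect_true(all(fit$indices$sym$per_unit <= 0))
  expect_named(coef(fit), c("sym", "umi", "addtree"))
  s <- summary(fit)
  expect_s3_class(s, "data.frame")
  expect_equal(nrow(s), 3L)
  expect_output(print(fit), "symmetry")
  # min_observed filter restricts the averaged units
  full <- isym(d, fit$prior)
  obs2 <- isym(d, fit$prior, min_observed = 2)
  expect_lte(obs2$n_units, full$n_units)
})
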