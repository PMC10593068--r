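test_that("incomplete-beta building blocks have their closed-form values", {
  expect_equal(bnorm_half(1, 1), 0.5)
  for (a in c(0.1, 0.5, 1, 3, 25)) expect_equal(bnorm_half(a, a), 0.5)
  expect_equal(bnorm_half(3, 1), 0.125)  # integral of 3u^2 up to 1/2
  expect_error(bnorm_half(0, 1), "positive")
})

test_that("triad marginal log-likelihood matches closed forms and quadrature", {
  expect_equal(triad_marginal_loglik(1, 2, choice_prior(1)), log(1 / 3))
  expect_equal(triad_marginal_loglik(0, 0, choice_prior(0.4, 0.2)), 0)
  # point-mass-dominated limit
  expect_equal(triad_marginal_loglik(2, 4, choice_prior(1, 1 - 1e-12)),
               log(choose(4, 2) * 2^-4), tolerance = 1e-6)
  expect_error(triad_marginal_loglik(5, 4, choice_prior(1)), "C <= N")
  # quadrature oracle over a grid of tallies and shapes
  for (a in c(0.3, 1, 2.5)) {
    p <- choice_prior(a)
    for (N in c(1, 5, 20)) for (C in unique(c(0, N %/% 2, N))) {
      expect_equal(triad_marginal_loglik(C, N, p),
                   log(choose(N, C) * quad_marginal(C, N, a)),
                   tolerance = 1e-9)
    }
  }
})

test_that("segment weights: values, symmetry, additivity, conservation", {
  expect_equal(w_sigma(0, 3, 5, 2), 1 / 32)
  expect_equal(w_sigma(-1, 0, 0, 0.7), 0.5)
  expect_equal(w_sigma(1, 0, 0, 0.7), 0.5)
  expect_error(w_sigma(2, 1, 2, 1), "sigma")
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0.1, 3)
    N <- sample(0:25, 1)
    C <- sample(0:N, 1)
    wm <- w_sigma(-1, C, N, a); wp <- w_sigma(1, C, N, a)
    # mirror symmetry of the prior about 1/2
    expect_equal(wp, w_sigma(-1, N - C, N, a), tolerance = 1e-12)
    # the two halves sum to the full beta integral
    expect_equal(wm + wp, exp(lbeta(a + C, a + N - C) - lbeta(a, a)),
                 tolerance = 1e-12)
    # conservation against the marginal likelihood, mixture prior
    h <- runif(1, 0, 0.8)
    lhs <- (1 - h) * (wm + wp) + h * w_sigma(0, C, N, a)
    rhs <- exp(triad_marginal_loglik(C, N, choice_prior(a, h))) / choose(N, C)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # log-space path survives large N
  expect_true(is.finite(w_sigma(1, 900, 1000, 0.5, log = TRUE)))
})

test_that("shape fitting: degenerate data pushes a to the boundary", {
  uni <- triad_data(data.frame(ref = "a", stim1 = c("b", "c"), stim2 = c("c", "d"),
                               C = c(6, 6), N = c(6, 6)),
                    stimuli = letters[1:4])
  f <- fit_choice_prior(uni)
  expect_true(f$a < 2e-3)       # all-unanimous: mass at the extremes
  expect_true(isTRUE(f$boundary))
  spl <- triad_data(data.frame(ref = "a", stim1 = c("b", "c"), stim2 = c("c", "d"),
                               C = c(3, 3), N = c(6, 6)),
                    stimuli = letters[1:4])
  f2 <- fit_choice_prior(spl)
  expect_true(f2$a > 50)        # all-equivocal: mass at 1/2
  expect_error(fit_choice_prior(triad_data(NULL, letters[1:4])), "identifiable")
  n1 <- triad_data(data.frame(ref = "a", stim1 = "b", stim2 = "c", C = 1, N = 1),
                   stimuli = letters[1:3])
  expect_error(fit_choice_prior(n1), "N >= 2")
  expect_error(fit_choice_prior(n1, fit_h = TRUE), "N >= 4")
})

test_that("joint (a, h) fit recovers generating parameters", {
  set.seed(99)
  M <- 20L  # 3420 canonical triads
  d <- triad_data(NULL, stimuli = sprintf("s%02d", 1:M))
  n <- nrow(d$triads)
  a0 <- 0.5; h0 <- 0.3; N <- 8L
  R <- rbeta(n, a0, a0)
  R[runif(n) < h0] <- 0.5
  d$C <- rbinom(n, N, R)
  d$N <- rep.int(N, n)
  f <- fit_choice_prior(d, fit_h = TRUE)
  expect_true(f$converged)
  expect_lt(abs(f$a - a0), 0.15)
  expect_lt(abs(f$h - h0), 0.15)
  # fixed-h fit is also close on the same data
  f0 <- fit_choice_prior(d, h = h0)
  expect_lt(abs(f0$a - a0), 0.15)
  # with no equivocal tallies the fitted point mass collapses to zero
  d$C <- ifelse(rbinom(n, 1, 0.5) == 1, d$N, 0L)
  fh <- fit_choice_prior(d, fit_h = TRUE)
  expect_lt(fh$h, 0.02)
})
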