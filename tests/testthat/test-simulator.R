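test_that("geometries satisfy their defining metric properties", {
  # ratios of distances survive RMS normalization
  gl <- similarity_geometry("line", n_points = 15)
  expect_equal(gl$D[1, 15] / gl$D[1, 2], 14)
  gc <- similarity_geometry("circle", n_points = 15)
  expect_equal(max(gc$D) / min(gc$D[gc$D > 0]), 7)
  # unit RMS over unordered pairs
  for (g in c("tree_um", "tree_add", "tree_addwt", "tree_eucl", "line", "circle")) {
    D <- similarity_geometry(g)$D
    expect_equal(sqrt(mean(D[upper.tri(D)]^2)), 1, tolerance = 1e-12)
    expect_true(all(D[upper.tri(D)] > 0))
    expect_equal(D, t(D))
  }
  expect_true(ultrametric_holds(similarity_geometry("tree_um")$D))
  expect_true(four_point_holds(similarity_geometry("tree_add")$D))
  expect_true(four_point_holds(similarity_geometry("tree_addwt")$D))
  expect_true(four_point_holds(similarity_geometry("line")$D))
  expect_false(four_point_holds(similarity_geometry("circle", n_points = 15)$D))
  expect_error(similarity_geometry("two_ray", angle = 200), "angle")
})

test_that("exact ties bound the symmetry index of the ultrametric tree", {
  geo <- similarity_geometry("tree_um")
  d0 <- triad_data(NULL, geo$stimuli)
  D <- geo$D
  # equilateral triples: all three pairwise distances equal
  tri <- t(combn(length(geo$stimuli), 3L))
  eq <- abs(D[tri[, c(1, 2)]] - D[tri[, c(1, 3)]]) < 1e-9 &
        abs(D[tri[, c(1, 2)]] - D[tri[, c(2, 3)]]) < 1e-9
  expect_equal(sum(eq), 71L)
  # each equilateral triple is pinned at log(3/4) for any amount of data:
  # the infinite-data index cannot exceed 71/455 * log(3/4)
  ceiling_sym <- sum(eq) / nrow(tri) * log(3 / 4)
  dat <- simulate_triad_experiment(geo, 32, 0.0625, seed = 77)
  v <- isym(dat, fit_choice_prior(dat))$value
  expect_lt(v, ceiling_sym + 0.01)
  expect_gt(v, ceiling_sym - 0.03)
})

test_that("two-ray geometry: straight-line identity and rank agreement at 150 deg", {
  ge <- similarity_geometry("two_ray", angle = 180, metric = "euclidean")
  gg <- similarity_geometry("two_ray", angle = 180, metric = "graph")
  expect_equal(ge$D, gg$D, tolerance = 1e-12)
  # at 150 degrees the Euclidean and graph distances have concordant rank
  # orders (graph ties may split, but no strict inversion appears)
  g150 <- similarity_geometry("two_ray", angle = 150, metric = "euclidean")
  gg150 <- similarity_geometry("two_ray", angle = 150, metric = "graph")
  expect_true(ranks_concordant(gg150$D, g150$D))
  # an acute angle produces genuine inversions
  g30 <- similarity_geometry("two_ray", angle = 30)
  expect_false(ranks_concordant(gg150$D, g30$D))
})

test_that("simulated choice frequencies follow the probit decision rule", {
  # custom two-distance model: D(r,x) = 0.5, D(r,y) = 1.0
  model <- structure(list(stimuli = c("r", "x", "y"),
                          D = matrix(c(0, 0.5, 1, 0.5, 0, 0.7, 1, 0.7, 0), 3),
                          geometry = "custom", params = list()),
                     class = "distance_model")
  d <- simulate_triad_experiment(model, n_trials = 4000, sigma = 0.25, seed = 2)
  df <- as.data.frame(d)
  row <- df[df$ref == "r", ]
  expect_equal(row$C / row$N, pnorm((1 - 0.5) / 0.25), tolerance = 0.02)
  # ties come out at one half, large noise drives everything to one half
  gl <- similarity_geometry("line", n_points = 5)
  dl <- simulate_triad_experiment(gl, 512, sigma = 100, seed = 3)
  expect_equal(mean(dl$C / dl$N), 0.5, tolerance = 0.01)
  # reproducibility under a seed
  d1 <- simulate_triad_experiment(gl, 8, 0.25, seed = 10)
  d2 <- simulate_triad_experiment(gl, 8, 0.25, seed = 10)
  expect_identical(d1$C, d2$C)
})

test_that("empirical frequencies converge to the probit probabilities", {
  gl <- similarity_geometry("line", n_points = 5)
  d <- simulate_triad_experiment(gl, 512, sigma = 0.5, seed = 6)
  dd <- gl$D[cbind(d$triads$ref, d$triads$s2)] -
        gl$D[cbind(d$triads$ref, d$triads$s1)]
  p <- pnorm(dd / 0.5)
  # all observed proportions within binomial error of the decision rule
  expect_true(all(abs(d$C / d$N - p) < 4 * sqrt(p * (1 - p) / 512) + 1e-9))
})

test_that("ranking trials expand to pairwise judgments, transitively consistent", {
  j <- rank_trial_to_triads("r", paste0("c", 1:8))
  expect_equal(nrow(j), 28L)
  expect_true(all(j$ref == "r"))
  # the winner is always the higher-ranked comparison
  rk <- setNames(1:8, paste0("c", 1:8))
  expect_true(all(rk[j$chosen] < rk[j$other]))
  expect_equal(nrow(rank_trial_to_triads("r", c("a", "b"))), 1L)
  expect_error(rank_trial_to_triads("r", c("a", "a")), "distinct")
  expect_error(rank_trial_to_triads("r", c("r", "a")), "distinct")
})

test_that("odd-one-out trials yield two judgments, outlier never the reference", {
  j <- odd_one_out_to_triads(c("x", "y", "z"), outlier = "y")
  expect_equal(nrow(j), 2L)
  expect_true(all(j$other == "y"))
  expect_false("y" %in% j$ref)
  expect_setequal(j$ref, c("x", "z"))
  expect_equal(j$chosen[j$ref == "x"], "z")
  expect_error(odd_one_out_to_triads(c("x", "y", "z"), "w"), "outlier")
})
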