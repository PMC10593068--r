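# Independent oracles used across the suite.  These deliberately avoid the
# package's closed-form code paths: Monte-Carlo integration over the prior,
# adaptive quadrature, and brute-force metric checks.

# Monte-Carlo estimate of the sign-region likelihood L_q(T; h): draw choice
# probabilities from the mixture prior, weight by the Bernoulli likelihood,
# and keep draws whose sign configuration satisfies the predicate.
mc_region_likelihood <- function(C, N, a, h, predicate, nsamp = 1e6) {
  k <- length(C)
  R <- matrix(rbeta(nsamp * k, a, a), nsamp, k)
  if (h > 0) {
    pm <- matrix(runif(nsamp * k) < h, nsamp, k)
    R[pm] <- 0.5
  }
  sg <- matrix(0L, nsamp, k)
  sg[R > 0.5] <- 1L
  sg[R < 0.5] <- -1L
  lik <- rep(1, nsamp)
  for (j in seq_len(k)) lik <- lik * R[, j]^C[j] * (1 - R[, j])^(N[j] - C[j])
  v <- predicate(sg) * lik
  list(mean = mean(v), se = sd(v) / sqrt(nsamp))
}

# adaptive-quadrature marginal likelihood of one tally under the beta prior;
# substituting R = qbeta(u) removes the endpoint singularities for a < 1
quad_marginal <- function(C, N, a) {
  stats::integrate(function(u) {
    R <- stats::qbeta(u, a, a)
    R^C * (1 - R)^(N - C)
  }, 0, 1, rel.tol = 1e-11)$value
}

# TRUE when no strict inversion exists between two sets of pairwise
# distances: d1[p] < d1[q] never co-occurs with d2[p] > d2[q]
ranks_concordant <- function(D1, D2, tol = 1e-9) {
  u <- D1[upper.tri(D1)]; v <- D2[upper.tri(D2)]
  !any(outer(u, u, `<`) & outer(v, v, function(x, y) x > y + tol))
}

# brute-force metric property checks on a distance matrix
ultrametric_holds <- function(D, tol = 1e-9) {
  M <- nrow(D)
  for (tri in combn(M, 3, simplify = FALSE)) {
    d <- sort(c(D[tri[1], tri[2]], D[tri[1], tri[3]], D[tri[2], tri[3]]))
    if (d[3] > d[2] + tol) return(FALSE)
  }
  TRUE
}

four_point_holds <- function(D, tol = 1e-9) {
  M <- nrow(D)
  for (q in combn(M, 4, simplify = FALSE)) {
    s <- sort(c(D[q[1], q[2]] + D[q[3], q[4]],
                D[q[1], q[3]] + D[q[2], q[4]],
                D[q[1], q[4]] + D[q[2], q[3]]))
    if (s[3] > s[2] + tol) return(FALSE)
  }
  TRUE
}

# small deterministic dataset used in several tests
toy_dataset <- function(M = 5, N = 6, seed = 20) {
  geo <- similarity_geometry("line", n_points = M)
  simulate_triad_experiment(geo, n_trials = N, sigma = 0.5, seed = seed)
}
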