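# Surrogate null ensembles and jackknife standard errors.
#
# Because the prior on choice probabilities is symmetric about 1/2,
# exchanging any observed tally (C, N) for its mirror (N - C, N) yields a
# surrogate dataset exactly as likely a priori as the data.  The "flip any"
# ensemble flips each triad independently with probability 1/2; "flip all"
# flips whole triplets, preserving within-triplet pairwise correlations.
# Surrogate moments are computed exactly by enumerating the equally likely
# flip patterns of each unit separately.

# per-unit value function for a given index kind, evaluated under a slot-flip
# pattern (logical k-vector applied uniformly to all units)
.per_unit_fun <- function(data, prior, index, tr, tn, h_eval, h) {
  W <- if (index != "sym") .triad_logW(data$C, data$N, prior$a) else NULL
  switch(index,
    sym = function(pattern) {
      bflip <- matrix(pattern, nrow(tr$idx), 3L, byrow = TRUE)
      .sym_per_unit(data, prior$a, tr, bflip = bflip)
    },
    umi = function(pattern) {
      flips <- xor(matrix(tr$flips, nrow(tr$idx), 3L, byrow = TRUE),
                   matrix(pattern, nrow(tr$idx), 3L, byrow = TRUE))
      .umi_per_unit(W, tr$idx, flips, h_eval)
    },
    addtree = function(pattern) {
      flips <- xor(matrix(tn$flips, nrow(tn$idx), 6L, byrow = TRUE),
                   matrix(pattern, nrow(tn$idx), 6L, byrow = TRUE))
      .addtree_per_unit(W, tn$idx, flips, h)
    })
}

# flip patterns (rows) for a unit under each ensemble.  For flip-all on a
# tent, the six triads belong to four distinct triplets -- the base triplet
# (slots 4:6) and the three triplets through the vertex, each contributing
# one tripod slot -- so the 2^4 joint triplet flip states map to slot
# patterns (q1, q2, q3, q4, q4, q4).
.flip_patterns <- function(index, kind) {
  lgl <- c(FALSE, TRUE)
  if (kind == "flip_any") {
    k <- if (index == "addtree") 6L else 3L
    as.matrix(expand.grid(rep(list(lgl), k), KEEP.OUT.ATTRS = FALSE))
  } else if (index == "addtree") {
    q <- as.matrix(expand.grid(lgl, lgl, lgl, lgl, KEEP.OUT.ATTRS = FALSE))
    cbind(q[, 1L], q[, 2L], q[, 3L], q[, 4L], q[, 4L], q[, 4L])
  } else {
    rbind(rep(FALSE, 3L), rep(TRUE, 3L))
  }
}

#' Exact surrogate moments of an index
#'
#' Computes the exact mean and standard deviation of a compatibility index
#' under a sign-flip surrogate ensemble, by exhaustively enumerating the
#' equally likely flip patterns of each triplet or tent separately.  Dataset
#' variance sums per-unit variances as if units were independent: exact for
#' the triplet-based indices (triplets partition the triads), an
#' approximation for tents, which can share triads.
#'
#' The "flip all" ensemble leaves the symmetry index unchanged unit by unit
#' (the symmetric-compatibility region is invariant under jointly mirroring
#' a triplet), so its mean equals the data index and its sd is 0.
#'
#' @param data a [triad_data] object.
#' @param prior a [choice_prior].
#' @param index one of `"sym"`, `"umi"`, `"addtree"`.
#' @param kind `"flip_any"` (independent triad flips) or `"flip_all"`
#'   (joint triplet flips).
#' @param h_eval ultrametric evaluation point (see [iumi]).
#' @param h additive-tree point-mass weight (see [iaddtree]).
#' @param min_observed unit inclusion filter, as in the index functions.
#' @return list with `kind`, `index`, `mean`, `sd`, and the per-unit
#'   means/variances.
#' @export
surrogate_moments <- function(data, prior, index = c("sym", "umi", "addtree"),
                              kind = c("flip_any", "flip_all"),
                              h_eval = 0, h = 0, min_observed = 0L) {
  stopifnot(inherits(data, "triad_data"), inherits(prior, "choice_prior"))
  index <- match.arg(index)
  kind <- match.arg(kind)
  tr <- if (index != "addtree") .triplet_structure(data) else NULL
  tn <- if (index == "addtree") .tent_structure(data) else NULL
  idx <- if (index == "addtree") tn$idx else tr$idx
  keep <- .unit_filter(data, idx, min_observed)
  fun <- .per_unit_fun(data, prior, index, tr, tn, h_eval, h)
  pats <- .flip_patterns(index, kind)
  n <- sum(keep)
  np <- nrow(pats)
  vs <- matrix(NA_real_, np, n)
  for (p in seq_len(np)) vs[p, ] <- fun(pats[p, ])[keep]
  m1 <- colMeans(vs)
  # deviations from the per-unit mean: exact zero when all patterns agree
  vr <- colMeans(sweep(vs, 2L, m1)^2)
  structure(list(kind = kind, index = index,
                 mean = mean(m1), sd = sqrt(sum(vr)) / n,
                 unit_mean = m1, unit_var = vr, n_units = n),
            class = "surrogate_moments")
}

#' @export
print.surrogate_moments <- function(x, digits = 4, ...) {
  cat(sprintf("Surrogate (%s) moments of I%s: mean %.*f, sd %.*f over %d units\n",
              x$kind, x$index, digits, x$mean, digits, x$sd, x$n_units))
  invisible(x)
}

#' Jackknife standard error of an index
#'
#' Leave-one-unit-out standard error of a `triad_index`.  Each index is a
#' mean of per-unit log likelihood-ratio contributions, with the prior held
#' fixed across jackknife subsets; the estimate therefore reduces to the
#' classic delete-1 jackknife on the per-unit values.
#'
#' @param x a `triad_index` (from [isym], [iumi], [iaddtree]), or a numeric
#'   vector of per-unit contributions.
#' @return the jackknife standard error.
#' @export
jackknife_se <- function(x) {
  per <- if (inherits(x, "triad_index")) x$per_unit else as.numeric(x)
  n <- length(per)
  if (n < 2L) stop("jackknife requires at least 2 units")
  loo <- (sum(per) - per) / (n - 1)
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}
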