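# Likelihood-ratio indices of compatibility with symmetric, ultrametric, and
# additive-tree distance structures.
#
# Every index is a mean, over triplets or tents, of a per-unit log likelihood
# ratio comparing the posterior mass of the choice probabilities inside the
# compatible sign region to the mass in a reference region.  All likelihoods
# are sums, over the sign configurations marked by an indicator table, of
# products of per-triad segment weights W(sigma; C, N); everything is done in
# log space with log-sum-exp aggregation.

.logsumexp_rows <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  mx <- do.call(pmax, c(as.data.frame(m), na.rm = FALSE))
  r <- log(rowSums(exp(m - mx))) + mx
  r[is.infinite(mx) & mx < 0] <- -Inf
  r
}

# Per-unit log of L_q(T; h) = sum_sigma h^Z (1-h)^(k-Z) V(sigma) prod_i W_i,
# vectorized over units.
#
# W:     ntriad x 3 matrix of log W(sigma; C, N), canonical orientation
# idx:   nunit x k matrix of triad rows
# flips: length-k logical (unit orientation) or nunit x k logical matrix
#        (orientation xor surrogate flips); a flip reverses the sigma axis
# tab:   indicator_table
# h:     point-mass weight; at h = 0 only zero-free configurations count.
#        h = NA keeps all marked configurations with unit weight (used for
#        the exact ultrametric limit, where the h-weights cancel)
.unit_logL <- function(W, idx, flips, tab, h) {
  k <- ncol(idx); n <- nrow(idx)
  keep <- tab$value == 1L
  sig <- tab$sigma[keep, , drop = FALSE]
  Z <- rowSums(sig == 0L)
  if (is.na(h)) {
    wts <- numeric(nrow(sig))
  } else if (h == 0) {
    sel <- Z == 0L
    sig <- sig[sel, , drop = FALSE]
    wts <- numeric(nrow(sig))
  } else {
    wts <- Z * log(h) + (k - Z) * log1p(-h)
  }
  ncfg <- nrow(sig)
  if (ncfg == 0L) return(rep.int(-Inf, n))
  flipm <- if (is.matrix(flips)) flips else
    matrix(flips, n, k, byrow = TRUE)
  # B[, (j-1)*3 + s]: slot j's log W at sigma index s, orientation applied
  B <- matrix(0, n, 3L * k)
  for (j in seq_len(k)) {
    rows <- idx[, j]
    fl <- flipm[, j]
    for (s in 1:3) {
      col <- W[rows, s]
      if (any(fl)) col[fl] <- W[rows[fl], 4L - s]
      B[, (j - 1L) * 3L + s] <- col
    }
  }
  TM <- matrix(0, n, ncfg)
  for (cix in seq_len(ncfg)) {
    acc <- rep.int(wts[cix], n)
    for (j in seq_len(k))
      acc <- acc + B[, (j - 1L) * 3L + sig[cix, j] + 2L]
    TM[, cix] <- acc
  }
  .logsumexp_rows(TM)
}

# Cancellation-safe per-unit log LRsym from the below-1/2 posterior masses b:
# 1 - prod(1-b) - prod(b) = b1(1-b2) + b2(1-b3) + b3(1-b1), a sum of
# nonnegative products, so no catastrophic cancellation when all b ~ 1/2.
.lrsym_log <- function(b1, b2, b3) {
  log(b1 * (1 - b2) + b2 * (1 - b3) + b3 * (1 - b1))
}

# per-unit log LRsym for all triplets; bflip: optional nunit x 3 logical of
# extra sign flips (surrogates) on top of the unit orientation
.sym_per_unit <- function(data, a, tr, bflip = NULL) {
  b <- pbeta(0.5, a + data$C, a + data$N - data$C)
  k <- length(tr$flips)
  bm <- matrix(0, nrow(tr$idx), k)
  for (j in seq_len(k)) {
    v <- b[tr$idx[, j]]
    if (tr$flips[j]) v <- 1 - v
    bm[, j] <- v
  }
  if (!is.null(bflip)) bm[bflip] <- 1 - bm[bflip]
  .lrsym_log(bm[, 1L], bm[, 2L], bm[, 3L])
}

# per-unit contribution to Iumi: log LRumi(T; h) - log h at h = h_eval, or
# the exact h -> 0 limit when h_eval = 0:
#   lim [log LRumi - log h] = log(dLumi/dh|0) - log Lsym(T; 0),
# where dLumi/dh|0 keeps the Z = 1 configurations of Vumi (the Z = 0 set of
# Vumi is empty, so Lumi(T;0) = 0 and no second term survives).
.umi_per_unit <- function(W, idx, flips, h_eval) {
  vumi <- vumi_table(); vsym <- vsym_table()
  if (h_eval == 0) {
    keep <- vumi$value == 1L & rowSums(vumi$sigma == 0L) == 1L
    num_tab <- .new_indicator_table("umi_z1", 3L, as.integer(keep))
    num <- .unit_logL(W, idx, flips, num_tab, h = NA)
    den <- .unit_logL(W, idx, flips, vsym, h = 0)
    num - den
  } else {
    .unit_logL(W, idx, flips, vumi, h_eval) -
      .unit_logL(W, idx, flips, vsym, h_eval) - log(h_eval)
  }
}

.addtree_per_unit <- function(W, idx, flips, h) {
  tabs <- vaddtree_tables()
  num <- .unit_logL(W, idx, flips, tabs$addtree, h)
  den <- .unit_logL(W, idx, flips, vsymtent_table(), h)
  bad <- !is.finite(num)
  if (any(bad)) {
    warning(sum(bad), " tent(s) with underflowing numerator clamped")
    num[bad] <- log(.Machine$double.xmin)
  }
  num - den
}

# units with at least min_observed constituent triads observed
.unit_filter <- function(data, idx, min_observed) {
  if (min_observed <= 0L) rep.int(TRUE, nrow(idx))
  else rowSums(matrix(data$N[idx] > 0L, nrow(idx))) >= min_observed
}

.new_index <- function(kind, per_unit, apriori, prior, h_eval = NA_real_,
                       h = NA_real_, min_observed = 0L) {
  structure(list(kind = kind, value = mean(per_unit), per_unit = per_unit,
                 n_units = length(per_unit), apriori = apriori,
                 prior = prior, h_eval = h_eval, h = h,
                 min_observed = min_observed, se = NA_real_,
                 surrogates = list()),
            class = "triad_index")
}

#' Symmetry index
#'
#' `isym` is the mean, over triplets, of the log likelihood ratio comparing
#' the posterior mass of the triplet's choice probabilities inside the
#' symmetric-compatible region to the unrestricted posterior mass.  It lies
#' in (-Inf, 0]; with no data it equals `log(3/4)`, and values near 0 mean
#' nearly all posterior mass is compatible with a symmetric distance.  Only
#' the beta component of the prior enters.
#'
#' @param data a [triad_data] object.
#' @param prior a [choice_prior]; if `NULL`, fitted by [fit_choice_prior].
#' @param min_observed include only units with at least this many observed
#'   constituent triads (0, the default, averages over all units; empty units
#'   contribute the a-priori benchmark).
#' @return object of class `triad_index` with elements `value`, `per_unit`,
#'   `n_units`, `apriori`, `prior`.
#' @export
isym <- function(data, prior = NULL, min_observed = 0L) {
  stopifnot(inherits(data, "triad_data"))
  if (is.null(prior)) prior <- fit_choice_prior(data)
  tr <- .triplet_structure(data)
  if (nrow(tr$idx) == 0L) stop("no triplets: need at least 3 stimuli")
  keep <- .unit_filter(data, tr$idx, min_observed)
  if (!any(keep)) stop("no triplets pass the min_observed filter")
  per <- .sym_per_unit(data, prior$a, tr)[keep]
  .new_index("sym", per, log(3 / 4), prior, min_observed = min_observed)
}

#' Ultrametric index
#'
#' `iumi` measures compatibility with an ultrametric (strictly hierarchical)
#' distance.  Because ultrametric structure requires exact ties among choice
#' probabilities, the index is defined through a prior with a point mass of
#' weight `h` at 1/2, as the `h -> 0` limit of
#' `log LRumi(T; h) - log h` averaged over triplets.  `h_eval = 0` (default)
#' evaluates the limit exactly in closed form; `h_eval > 0` (e.g. 0.001)
#' evaluates at a small finite `h`, converging linearly to the limit.  The
#' a-priori value is 0; positive values indicate data more compatible with an
#' ultrametric than unstructured choice probabilities.
#'
#' @inheritParams isym
#' @param h_eval evaluation point for the point-mass weight; 0 for the exact
#'   limit.
#' @return a `triad_index`.
#' @export
iumi <- function(data, prior = NULL, h_eval = 0, min_observed = 0L) {
  stopifnot(inherits(data, "triad_data"))
  if (h_eval < 0 || h_eval >= 1) stop("h_eval must be in [0, 1)")
  if (is.null(prior))
    prior <- fit_choice_prior(data, h = max(h_eval, 0.001))
  tr <- .triplet_structure(data)
  if (nrow(tr$idx) == 0L) stop("no triplets: need at least 3 stimuli")
  keep <- .unit_filter(data, tr$idx, min_observed)
  if (!any(keep)) stop("no triplets pass the min_observed filter")
  W <- .triad_logW(data$C, data$N, prior$a)
  per <- .umi_per_unit(W, tr$idx, tr$flips, h_eval)[keep]
  .new_index("umi", per, 0, prior, h_eval = h_eval,
             min_observed = min_observed)
}

#' Additive-tree index
#'
#' `iaddtree` is the mean, over tents, of the log likelihood ratio comparing
#' posterior mass compatible with an additive-tree (four-point) structure to
#' the mass merely compatible with symmetry.  With no data it equals
#' `log(2/3)`; values near 0 indicate compatibility.  By default the pure
#' beta prior is used (`h = 0`); a positive `h` admits exact ties, which is
#' essential when the underlying geometry is ultrametric.
#'
#' @inheritParams isym
#' @param h point-mass weight at which the tent likelihoods are evaluated;
#'   defaults to the prior's `h`.
#' @return a `triad_index`.
#' @export
iaddtree <- function(data, prior = NULL, h = NULL, min_observed = 0L) {
  stopifnot(inherits(data, "triad_data"))
  if (is.null(prior)) prior <- fit_choice_prior(data)
  if (is.null(h)) h <- prior$h
  if (h < 0 || h >= 1) stop("h must be in [0, 1)")
  tn <- .tent_structure(data)
  if (nrow(tn$idx) == 0L) stop("no tents: need at least 4 stimuli")
  keep <- .unit_filter(data, tn$idx, min_observed)
  if (!any(keep)) stop("no tents pass the min_observed filter")
  W <- .triad_logW(data$C, data$N, prior$a)
  per <- .addtree_per_unit(W, tn$idx, tn$flips, h)[keep]
  .new_index("addtree", per, log(2 / 3), prior, h = h,
             min_observed = min_observed)
}

# ---- per-unit operations (documented building blocks) ----------------------

#' Per-triplet symmetry likelihood ratio
#'
#' For one triplet with oriented tallies `(C_i, N_i)`, the ratio of the
#' posterior mass compatible with a symmetric distance to the unrestricted
#' mass:
#' `1 - prod(1 - b_i) - prod(b_i)` with
#' `b_i = bnorm_half(a + C_i, a + N_i - C_i)`, computed in a
#' cancellation-safe expansion.  Equals 3/4 exactly when at most one triad
#' has observations.
#'
#' @param C,N integer vectors of length 3, tallies in triplet orientation.
#' @param a beta shape parameter.
#' @return likelihood ratio in (0, 1].
#' @export
lr_sym_triplet <- function(C, N, a) {
  stopifnot(length(C) == 3L, length(N) == 3L)
  if (any(C < 0) || any(C > N)) stop("need 0 <= C <= N")
  b <- pbeta(0.5, a + C, a + N - C)
  b[1L] * (1 - b[2L]) + b[2L] * (1 - b[3L]) + b[3L] * (1 - b[1L])
}

#' Sign-configuration likelihood of one unit
#'
#' Evaluates `L_q(T; h)`: the posterior-times-prior mass of the sign region
#' marked by an indicator table, i.e. the sum over marked sign vectors of
#' `h^Z (1-h)^(k-Z) prod_i W(sigma_i; C_i, N_i)` where `Z` counts zero
#' entries.  This is the common engine behind the ultrametric and
#' additive-tree indices.
#'
#' @param C,N oriented tallies, length equal to the table arity.
#' @param prior a [choice_prior] supplying the beta shape `a`.
#' @param table an `indicator_table` (see [vsym_table()] and friends).
#' @param h point-mass weight; defaults to the prior's `h`.
#' @return the log of `L_q(T; h)` (`-Inf` if no marked configuration
#'   contributes, e.g. the ultrametric table at `h = 0`).
#' @export
l_q_polynomial <- function(C, N, prior, table, h = NULL) {
  stopifnot(inherits(prior, "choice_prior"), inherits(table, "indicator_table"))
  if (length(C) != table$k || length(N) != table$k)
    stop("tally length must match the table arity k = ", table$k)
  if (is.null(h)) h <- prior$h
  W <- .triad_logW(C, N, prior$a)
  .unit_logL(W, matrix(seq_along(C), 1L), rep(FALSE, table$k), table, h)
}

#' Per-triplet ultrametric likelihood ratio
#'
#' The ratio `Lumi(T; h) / Lsym(T; h)` at a small positive `h`.  The ratio
#' vanishes identically at `h = 0` (ultrametric structure requires ties,
#' which carry prior mass proportional to `h`), so `h_eval` must be positive
#' here; the index [iumi] takes the limit.
#'
#' @param C,N oriented tallies of length 3.
#' @param prior a [choice_prior].
#' @param h_eval positive point-mass weight.
#' @return likelihood ratio (positive).
#' @export
lr_umi_triplet <- function(C, N, prior, h_eval = 0.001) {
  if (h_eval <= 0)
    stop("h_eval must be positive: the ratio is identically 0 at h = 0 ",
         "and the index is defined by the h -> 0 limit")
  exp(l_q_polynomial(C, N, prior, vumi_table(), h = h_eval) -
        l_q_polynomial(C, N, prior, vsym_table(), h = h_eval))
}

#' Per-tent additive-tree likelihood ratio
#'
#' The ratio `Laddtree(T; h) / Lsymtent(T; h)` for one tent's six oriented
#' tallies.  Lies in `[0, 1]` because the additive-tree sign region is a
#' subset of the tent-symmetry region.
#'
#' @param C,N oriented tallies of length 6 (tripod slots then base slots).
#' @param prior a [choice_prior].
#' @param h point-mass weight; defaults to the prior's `h`.
#' @return likelihood ratio in `[0, 1]`.
#' @export
lr_addtree_tent <- function(C, N, prior, h = NULL) {
  if (is.null(h)) h <- prior$h
  exp(l_q_polynomial(C, N, prior, vaddtree_tables()$addtree, h = h) -
        l_q_polynomial(C, N, prior, vsymtent_table(), h = h))
}

# ---- the fitting wrapper ----------------------------------------------------

#' Compute compatibility indices for a triadic judgment dataset
#'
#' The main entry point: fits the choice-probability prior (unless one is
#' supplied) and computes the requested likelihood-ratio indices, with
#' jackknife standard errors and, optionally, exact surrogate null moments.
#'
#' Prior policy, following the standard analysis: the beta shape `a` is
#' fitted by maximum likelihood with `h = 0` for the symmetry and
#' additive-tree indices, and refitted with `h = max(h_eval, 0.001)` for the
#' ultrametric index; `fit_h = TRUE` fits `(a, h)` jointly and evaluates the
#' additive-tree index at the fitted `h`.
#'
#' @param data a [triad_data] object.
#' @param which indices to compute, a subset of `"sym"`, `"umi"`, `"addtree"`.
#' @param prior optional [choice_prior] to use for all indices (skips
#'   fitting).
#' @param fit_h fit the point-mass weight `h` jointly with `a`.
#' @param h_eval evaluation point for the ultrametric limit (0 = exact).
#' @param min_observed minimum number of observed triads for a unit to enter
#'   an index average.
#' @param surrogates `NULL`, or a character vector from
#'   `c("flip_any", "flip_all")` naming surrogate ensembles whose exact
#'   moments to attach to each index.
#' @param jackknife attach leave-one-unit-out standard errors.
#' @return object of class `triad_indices`: a list of `triad_index` results
#'   (by kind) plus the prior(s) used.
#' @seealso [isym()], [iumi()], [iaddtree()], [surrogate_moments()]
#' @examples
#' geo <- similarity_geometry("line", n_points = 7)
#' set.seed(1)
#' d <- simulate_triad_experiment(geo, n_trials = 4, sigma = 0.25)
#' fit <- triad_indices(d, which = c("sym", "umi"))
#' fit
#' @export
triad_indices <- function(data, which = c("sym", "umi", "addtree"),
                          prior = NULL, fit_h = FALSE, h_eval = 0,
                          min_observed = 0L, surrogates = NULL,
                          jackknife = TRUE) {
  stopifnot(inherits(data, "triad_data"))
  which <- match.arg(which, c("sym", "umi", "addtree"), several.ok = TRUE)
  if (!is.null(surrogates))
    surrogates <- match.arg(surrogates, c("flip_any", "flip_all"),
                            several.ok = TRUE)
  base_prior <- prior
  if (is.null(base_prior))
    base_prior <- if (fit_h) fit_choice_prior(data, fit_h = TRUE)
                  else fit_choice_prior(data, h = 0)
  out <- list()
  for (kind in which) {
    res <- switch(kind,
      sym = isym(data, base_prior, min_observed = min_observed),
      umi = {
        up <- if (!is.null(prior) || fit_h) base_prior
              else fit_choice_prior(data, h = max(h_eval, 0.001))
        iumi(data, up, h_eval = h_eval, min_observed = min_observed)
      },
      addtree = iaddtree(data, base_prior,
                         h = if (fit_h) base_prior$h else
                               if (!is.null(prior)) prior$h else 0,
                         min_observed = min_observed))
    if (jackknife) res$se <- jackknife_se(res)
    for (kd in surrogates)
      res$surrogates[[kd]] <- surrogate_moments(
        data, res$prior, index = kind, kind = kd,
        h_eval = h_eval, h = if (kind == "addtree") res$h else 0,
        min_observed = min_observed)
    out[[kind]] <- res
  }
  structure(list(indices = out, prior = base_prior, data_summary = list(
    n_stimuli = length(data$stimuli), n_triads = nrow(data$triads),
    n_observed = sum(data$N > 0L), n_judgments = sum(data$N))),
    class = "triad_indices")
}

#' @export
print.triad_index <- function(x, digits = 4, ...) {
  lab <- switch(x$kind, sym = "symmetry (Isym)",
                umi = "ultrametric (Iumi)", addtree = "additive tree (Iaddtree)")
  cat(sprintf("%s: %.*f", lab, digits, x$value))
  if (is.finite(x$se)) cat(sprintf("  (jackknife SE %.*f)", digits, x$se))
  cat(sprintf("\n  a-priori benchmark %.*f over %d units\n",
              digits, x$apriori, x$n_units))
  for (kd in names(x$surrogates)) {
    s <- x$surrogates[[kd]]
    cat(sprintf("  surrogate %s: mean %.*f, sd %.*f\n",
                kd, digits, s$mean, digits, s$sd))
  }
  invisible(x)
}

#' @export
print.triad_indices <- function(x, digits = 4, ...) {
  cat("Triadic similarity compatibility indices\n")
  cat(sprintf("  %d stimuli, %d/%d triads observed, %d judgments\n",
              x$data_summary$n_stimuli, x$data_summary$n_observed,
              x$data_summary$n_triads, x$data_summary$n_judgments))
  cat(sprintf("  prior: a = %.4g, h = %.4g%s\n", x$prior$a, x$prior$h,
              if (isTRUE(x$prior$fitted)) " (maximum likelihood)" else ""))
  for (res in x$indices) print(res, digits = digits)
  invisible(x)
}

#' @export
summary.triad_indices <- function(object, ...) {
  rows <- lapply(object$indices, function(r) {
    data.frame(index = r$kind, value = r$value, se = r$se,
               apriori = r$apriori, n_units = r$n_units,
               a = r$prior$a, h = r$prior$h)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
coef.triad_indices <- function(object, ...) {
  vapply(object$indices, `[[`, 0, "value")
}

#' @export
plot.triad_indices <- function(x, ...) {
  ks <- names(x$indices)
  old <- graphics::par(mfrow = c(1, length(ks)))
  on.exit(graphics::par(old))
  for (k in ks) {
    r <- x$indices[[k]]
    graphics::hist(r$per_unit, breaks = 30, main = k,
                   xlab = "per-unit log LR", ...)
    graphics::abline(v = r$apriori, lty = 2)
    graphics::abline(v = r$value, col = 2)
  }
  invisible(x)
}
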