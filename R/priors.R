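# Priors on choice probabilities: a symmetric beta density with shape a,
# optionally mixed with a point mass of weight h at R = 1/2, and the
# incomplete-beta building blocks used by all indices.

#' Specify a choice-probability prior
#'
#' The prior on a choice probability R is
#' `(1 - h) * dbeta(R, a, a) + h * delta(R - 1/2)`:
#' a symmetric beta density of shape `a` mixed with a point mass of weight
#' `h` at 1/2.  Small `a` puts mass near 0 and 1 (near-certain judgments);
#' large `a` concentrates near 1/2; `a = 1` is flat.  The point mass models a
#' fraction of triads whose true choice probability is exactly 1/2, as a
#' strict hierarchy requires.
#'
#' @param a beta shape parameter, `a > 0`.
#' @param h point-mass weight at 1/2, `0 <= h < 1`.
#' @return object of class `choice_prior`.
#' @export
choice_prior <- function(a, h = 0) {
  a <- as.numeric(a); h <- as.numeric(h)
  if (!is.finite(a) || a <= 0) stop("a must be positive")
  if (!is.finite(h) || h < 0 || h >= 1) stop("h must be in [0, 1)")
  structure(list(a = a, h = h, loglik = NA_real_, converged = NA,
                 n_triads = NA_integer_, fitted = FALSE),
            class = "choice_prior")
}

#' Regularized incomplete beta function at 1/2
#'
#' `bnorm_half(p, q)` is the normalized incomplete beta
#' `B(1/2; p, q) / B(p, q)`, i.e. the posterior probability that a choice
#' probability lies below 1/2 when the posterior is `Beta(p, q)` with
#' `p = a + C`, `q = a + N - C`.  Computed via `pbeta`, which is stable for
#' large arguments.
#'
#' @param p,q positive shape parameters.
#' @return value in (0, 1); `bnorm_half(a, a) = 1/2` for any `a > 0`.
#' @export
bnorm_half <- function(p, q) {
  if (any(p <= 0) || any(q <= 0)) stop("shape parameters must be positive")
  pbeta(0.5, p, q)
}

#' Marginal log-likelihood of one triad's tally
#'
#' The log-probability of observing `C` choices of the first comparison in
#' `N` presentations, after integrating the Bernoulli likelihood over the
#' prior:
#' `log[ choose(N, C) * ((1-h) B(a+C, a+N-C)/B(a,a) + h 2^-N) ]`.
#' Vectorized over `C`, `N`.
#'
#' @param C,N tally counts, `0 <= C <= N`.
#' @param prior a [choice_prior].
#' @return log-probabilities (0 for an empty tally `C = N = 0`).
#' @export
triad_marginal_loglik <- function(C, N, prior) {
  stopifnot(inherits(prior, "choice_prior"))
  if (any(C < 0) || any(C > N)) stop("need 0 <= C <= N")
  lbet <- lbeta(prior$a + C, prior$a + N - C) - lbeta(prior$a, prior$a)
  lmass <- -N * log(2)
  mix <- if (prior$h == 0) lbet else {
    .logspace_add(log1p(-prior$h) + lbet, log(prior$h) + lmass)
  }
  lchoose(N, C) + mix
}

.logspace_add <- function(lx, ly) pmax(lx, ly) + log1p(exp(-abs(lx - ly)))

#' Prior-weighted posterior mass of one sign segment
#'
#' `w_sigma` is the integral of `R^C (1-R)^(N-C)` against the beta component
#' of the prior over one segment of `[0, 1]`: below 1/2 for `sigma = -1`,
#' above 1/2 for `sigma = +1`; for `sigma = 0` it is the Bernoulli likelihood
#' evaluated exactly at `R = 1/2`, i.e. `2^-N` (the weight multiplying the
#' point mass).  These are the per-triad factors of the sign-configuration
#' expansion of every index.
#'
#' @param sigma one of -1, 0, +1.
#' @param C,N tally counts (vectorized).
#' @param a beta shape parameter.
#' @param log if `TRUE` return the log weight (needed for large `N`).
#' @return nonnegative weights; `w_sigma(-1, 0, 0, a) = 1/2` for any `a`.
#' @export
w_sigma <- function(sigma, C, N, a, log = FALSE) {
  if (length(sigma) != 1L || !sigma %in% c(-1, 0, 1))
    stop("sigma must be -1, 0, or +1")
  if (any(C < 0) || any(C > N)) stop("need 0 <= C <= N")
  if (a <= 0) stop("a must be positive")
  lw <- if (sigma == 0) {
    -N * log(2)
  } else {
    lbeta(a + C, a + N - C) - lbeta(a, a) +
      pbeta(0.5, a + C, a + N - C, lower.tail = sigma < 0, log.p = TRUE)
  }
  if (log) lw else exp(lw)
}

# log W(sigma; C, N) for all canonical triads at once; columns are
# sigma = -1, 0, +1 in canonical orientation.  Flipping a triad's
# orientation (or a surrogate sign flip) reverses the column order.
.triad_logW <- function(C, N, a) {
  lb <- lbeta(a + C, a + N - C) - lbeta(a, a)
  cbind(pbeta(0.5, a + C, a + N - C, log.p = TRUE) + lb,
        -N * log(2),
        pbeta(0.5, a + C, a + N - C, lower.tail = FALSE, log.p = TRUE) + lb)
}

# ---- maximum-likelihood fitting --------------------------------------------

.prior_ll <- function(log10a, h, C, N) {
  a <- 10^log10a
  lbet <- lbeta(a + C, a + N - C) - lbeta(a, a)
  mix <- if (h == 0) lbet else
    .logspace_add(log1p(-h) + lbet, log(h) - N * log(2))
  sum(lchoose(N, C) + mix)
}

#' Fit the choice-probability prior by maximum likelihood
#'
#' Maximizes the marginal likelihood of the observed tallies over the beta
#' shape `a` (and optionally the point-mass weight `h`), treating each
#' triad's choice probability as an independent draw from the prior.  The
#' search is over `log10(a)` in `[-3, 2]`; the joint fit profiles `a` over a
#' grid of `h` and then refines both parameters.
#'
#' With `h` fixed at 0, at least one triad must have `N >= 2`: with a single
#' presentation per triad every observed proportion is 0 or 1 and the
#' likelihood does not depend on `a`.  The joint fit requires at least one
#' triad with `N >= 4`.
#'
#' @param data a [triad_data] object.
#' @param h fixed point-mass weight (ignored when `fit_h = TRUE`).
#' @param fit_h if `TRUE`, fit `h` jointly with `a`.
#' @param tol convergence tolerance on the log-likelihood scale.
#' @return a [choice_prior] with `loglik` (including the data-only binomial
#'   constant), `converged`, and `n_triads` filled in.
#' @export
fit_choice_prior <- function(data, h = 0, fit_h = FALSE, tol = 1e-8) {
  stopifnot(inherits(data, "triad_data"))
  keep <- data$N > 0L
  C <- data$C[keep]; N <- data$N[keep]
  if (length(N) == 0L) stop("no observed triads: the prior is not identifiable")
  if (fit_h) {
    if (!any(N >= 4L))
      stop("joint fit of (a, h) requires at least one triad with N >= 4")
  } else if (h == 0 && !any(N >= 2L)) {
    stop("with h = 0, fitting a requires at least one triad with N >= 2 ",
         "(all-binary observed proportions leave a undetermined)")
  }
  lo <- -3; hi <- 2
  if (!fit_h) {
    opt <- optimize(function(u) .prior_ll(u, h, C, N),
                    interval = c(lo, hi), maximum = TRUE, tol = tol)
    out <- choice_prior(10^opt$maximum, h)
    out$loglik <- opt$objective
    out$converged <- TRUE
    out$boundary <- opt$maximum < lo + 1e-3 || opt$maximum > hi - 1e-3
  } else {
    hgrid <- c(0, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 0.9)
    prof <- lapply(hgrid, function(hh) {
      o <- optimize(function(u) .prior_ll(u, hh, C, N),
                    interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
      list(h = hh, u = o$maximum, ll = o$objective)
    })
    best <- prof[[which.max(vapply(prof, `[[`, 0, "ll"))]]
    ref <- optim(c(best$u, best$h),
                 function(p) -.prior_ll(p[1L], p[2L], C, N),
                 method = "L-BFGS-B",
                 lower = c(lo, 0), upper = c(hi, 0.99),
                 control = list(factr = tol / .Machine$double.eps))
    out <- choice_prior(10^ref$par[1L], ref$par[2L])
    out$loglik <- -ref$value
    out$converged <- ref$convergence == 0L
    out$boundary <- ref$par[1L] < lo + 1e-3 || ref$par[1L] > hi - 1e-3
    if (!out$converged)
      warning("joint (a, h) fit did not converge: ", ref$message)
  }
  out$n_triads <- length(N)
  out$fitted <- TRUE
  out
}

#' @export
print.choice_prior <- function(x, ...) {
  cat("Choice-probability prior: beta(a, a)",
      if (x$h > 0) sprintf("+ point mass h at 1/2") else "", "\n")
  cat(sprintf("  a = %.6g   h = %.6g\n", x$a, x$h))
  if (isTRUE(x$fitted))
    cat(sprintf("  max log-likelihood = %.6g over %d observed triads%s\n",
                x$loglik, x$n_triads,
                if (isTRUE(x$boundary)) "  (at search boundary)" else ""))
  invisible(x)
}

#' @export
coef.choice_prior <- function(object, ...) c(a = object$a, h = object$h)

#' @export
logLik.choice_prior <- function(object, ...) {
  structure(object$loglik, df = if (object$h > 0) 2L else 1L,
            nobs = object$n_triads, class = "logLik")
}
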