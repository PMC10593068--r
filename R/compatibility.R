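# Indicator tables over sign configurations.
#
# For a triplet, sigma_i = sign(R_i - 1/2) over the oriented choice
# probabilities; for a tent there are six entries (tripod then base).  An
# indicator table V maps each sign vector in {-1,0,+1}^k to {0,1}, marking
# the configurations compatible with a distance property.  Tables are built
# by explicit enumeration of the defining patterns (never hand-typed entry
# lists) and are cross-checked in the test suite against direct evaluation
# of the ordinal compatibility conditions.

.sigma_grid <- function(k) {
  g <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), k),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  g
}

.sigma_key <- function(sigma) {
  # row index of a sign vector in .sigma_grid(k)
  k <- ncol(sigma)
  as.integer((sigma + 1L) %*% (3L^(seq_len(k) - 1L))) + 1L
}

.new_indicator_table <- function(name, k, value) {
  structure(list(name = name, k = k, sigma = .sigma_grid(k),
                 value = as.integer(value)),
            class = "indicator_table")
}

#' @export
print.indicator_table <- function(x, ...) {
  cat(sprintf("Indicator table '%s': k = %d, %d of %d sign vectors marked 1\n",
              x$name, x$k, sum(x$value), length(x$value)))
  invisible(x)
}

.table_cache <- new.env(parent = emptyenv())

#' Indicator table for compatibility with a symmetric distance
#'
#' Marks the sign vectors of a triplet's three choice probabilities that are
#' compatible with a symmetric distance: the three sign families with no zero
#' and mixed signs, the families with one zero whose two nonzero entries have
#' opposite signs, and the all-zero vector -- 13 of the 27 vectors in all.
#'
#' @return an `indicator_table` with `k = 3`.
#' @export
vsym_table <- function() {
  if (!is.null(.table_cache$sym)) return(.table_cache$sym)
  g <- .sigma_grid(3L)
  ones <- NULL
  # no zeros, both signs present: (e, e, -e) and its two cyclic rotations
  for (e in c(-1L, 1L))
    ones <- rbind(ones, c(e, e, -e), c(e, -e, e), c(-e, e, e))
  # one zero, the two nonzero entries of opposite sign
  for (e in c(-1L, 1L))
    ones <- rbind(ones, c(e, -e, 0L), c(0L, e, -e), c(-e, 0L, e))
  ones <- rbind(ones, c(0L, 0L, 0L))
  v <- integer(nrow(g))
  v[.sigma_key(ones)] <- 1L
  .table_cache$sym <- .new_indicator_table("sym", 3L, v)
  .table_cache$sym
}

#' Indicator table for compatibility with an ultrametric distance
#'
#' An ultrametric requires, within each triplet, two of the three
#' dis-similarities to be equal with the third no larger, which in sign space
#' is exactly the cyclic family (+1, -1, 0), (0, +1, -1), (-1, 0, +1), plus
#' the all-zero vector.
#'
#' @return an `indicator_table` with `k = 3`.
#' @export
vumi_table <- function() {
  if (!is.null(.table_cache$umi)) return(.table_cache$umi)
  g <- .sigma_grid(3L)
  ones <- rbind(c(1L, -1L, 0L), c(0L, 1L, -1L), c(-1L, 0L, 1L),
                c(0L, 0L, 0L))
  v <- integer(nrow(g))
  v[.sigma_key(ones)] <- 1L
  .table_cache$umi <- .new_indicator_table("umi", 3L, v)
  .table_cache$umi
}

#' Indicator table for symmetry over a tent
#'
#' The six choice probabilities of a tent are compatible with a symmetric
#' distance iff the tripod signs and the base signs each satisfy the
#' triplet symmetry condition: the table is the product of two k = 3
#' symmetry lookups.
#'
#' @return an `indicator_table` with `k = 6`.
#' @export
vsymtent_table <- function() {
  if (!is.null(.table_cache$symtent)) return(.table_cache$symtent)
  g <- .sigma_grid(6L)
  vs <- vsym_table()$value
  key3 <- function(m) as.integer((m + 1L) %*% 3L^(0:2)) + 1L
  v <- vs[key3(g[, 1:3])] * vs[key3(g[, 4:6])]
  .table_cache$symtent <- .new_indicator_table("symtent", 6L, v)
  .table_cache$symtent
}

# The two cyclic relabelings of the base {a,b,c}, acting on tent slots:
# V[a](sigma) = V[c](sigma[perm_a]), V[b](sigma) = V[c](sigma[perm_b]).
.addtree_perm_a <- c(2L, 3L, 1L, 5L, 6L, 4L)
.addtree_perm_b <- c(3L, 1L, 2L, 6L, 4L, 5L)

#' Indicator tables for compatibility with an additive-tree distance
#'
#' In a tent, an additive-tree (four-point) structure is falsified when the
#' largest tripod dis-similarity sits opposite the largest base
#' dis-similarity (with prescribed handling of ties).  `Vaddtree[c]` is zero
#' exactly on the 81 sign vectors with `(sigma1, sigma4)` in
#' `{(+1,-1), (+1,0), (0,-1)}` and `(sigma2, sigma5)` in
#' `{(-1,+1), (-1,0), (0,+1)}` (third and sixth entries free); the `[a]` and
#' `[b]` variants are its images under cyclic relabeling of the base, and
#' the full table is their product with the tent symmetry table.
#'
#' @return list of `indicator_table`s: `c`, `a`, `b` (per-relabeling
#'   falsifier complements) and `addtree` (their product with symmetry).
#' @export
vaddtree_tables <- function() {
  if (!is.null(.table_cache$addtree)) return(.table_cache$addtree)
  g <- .sigma_grid(6L)
  pair14 <- rbind(c(1L, -1L), c(1L, 0L), c(0L, -1L))
  pair25 <- rbind(c(-1L, 1L), c(-1L, 0L), c(0L, 1L))
  in_set <- function(u, v, set)
    Reduce(`|`, lapply(seq_len(nrow(set)),
                       function(i) u == set[i, 1L] & v == set[i, 2L]))
  vc <- as.integer(!(in_set(g[, 1L], g[, 4L], pair14) &
                     in_set(g[, 2L], g[, 5L], pair25)))
  key <- function(m) .sigma_key(m)
  va <- vc[key(g[, .addtree_perm_a, drop = FALSE])]
  vb <- vc[key(g[, .addtree_perm_b, drop = FALSE])]
  vfull <- vc * va * vb * vsymtent_table()$value
  .table_cache$addtree <- list(
    c = .new_indicator_table("addtree[c]", 6L, vc),
    a = .new_indicator_table("addtree[a]", 6L, va),
    b = .new_indicator_table("addtree[b]", 6L, vb),
    addtree = .new_indicator_table("addtree", 6L, vfull))
  .table_cache$addtree
}

.get_table <- function(name) {
  switch(name,
         sym = vsym_table(),
         umi = vumi_table(),
         symtent = vsymtent_table(),
         addtree = vaddtree_tables()$addtree,
         stop("unknown indicator table: ", name))
}

# ---- direct predicates ------------------------------------------------------
# Independent evaluations of the ordinal compatibility conditions, written
# from the inequality logic rather than the table construction; the test
# suite asserts exhaustive agreement with the tables.

#' Ordinal compatibility predicates for sign vectors
#'
#' Direct evaluation of the compatibility conditions from their inequality
#' logic.  `sym_compatible` tests, for a triplet sign vector, that either all
#' three entries are zero or at most one is zero with both signs represented
#' among the nonzero entries.  `umi_compatible` additionally requires exactly
#' the tie structure of an ultrametric.  `addtree_falsified` tests, for a
#' tent sign vector, whether any relabeling of the base triggers the
#' four-point falsifier; `addtree_compatible` is symmetry over the tent plus
#' the absence of any falsifier.
#'
#' @param sigma integer vector in `{-1, 0, +1}`, length 3 (triplet) or 6
#'   (tent; tripod entries first), or a matrix with such rows.
#' @return logical vector, one entry per row.
#' @export
sym_compatible <- function(sigma) {
  sigma <- rbind(sigma)
  if (ncol(sigma) != 3L) stop("triplet sign vectors have length 3")
  nhalf <- rowSums(sigma == 0L)
  nhalf == 3L |
    (nhalf <= 1L & rowSums(sigma > 0L) > 0L & rowSums(sigma < 0L) > 0L)
}

#' @rdname sym_compatible
#' @export
umi_compatible <- function(sigma) {
  sigma <- rbind(sigma)
  if (ncol(sigma) != 3L) stop("triplet sign vectors have length 3")
  # ultrametric = symmetric + one of the cyclic tie families
  # (R1 >= 1/2, R2 <= 1/2, R3 = 1/2) and its two rotations
  cond <- function(s) s[, 1L] >= 0L & s[, 2L] <= 0L & s[, 3L] == 0L
  fam <- cond(sigma) | cond(sigma[, c(2L, 3L, 1L), drop = FALSE]) |
    cond(sigma[, c(3L, 1L, 2L), drop = FALSE]) | rowSums(sigma == 0L) == 3L
  sym_compatible(sigma) & fam
}

# Falsifier for one labeling of the base {a,b,c}: with the tent orientation
# R1=R(z;b,c), R2=R(z;c,a), R3=R(z;a,b), R4=R(a;b,c), R5=R(b;c,a),
# R6=R(c;a,b), the four-point conditions read
#   R(z;c,b) <= 1/2  <=>  sigma1 >= 0       R(z;c,a) <= 1/2  <=> sigma2 <= 0
#   R(a;b,c) <= 1/2  <=>  sigma4 <= 0       R(b;a,c) <= 1/2  <=> sigma5 >= 0
# with strictness (sigma1 = +1 or sigma4 = -1) and (sigma2 = -1 or
# sigma5 = +1).
.addtree_falsifier_one <- function(s) {
  s[, 1L] >= 0L & s[, 2L] <= 0L & s[, 4L] <= 0L & s[, 5L] >= 0L &
    (s[, 1L] == 1L | s[, 4L] == -1L) & (s[, 2L] == -1L | s[, 5L] == 1L)
}

#' @rdname sym_compatible
#' @export
addtree_falsified <- function(sigma) {
  sigma <- rbind(sigma)
  if (ncol(sigma) != 6L) stop("tent sign vectors have length 6")
  .addtree_falsifier_one(sigma) |
    .addtree_falsifier_one(sigma[, .addtree_perm_a, drop = FALSE]) |
    .addtree_falsifier_one(sigma[, .addtree_perm_b, drop = FALSE])
}

#' @rdname sym_compatible
#' @export
addtree_compatible <- function(sigma) {
  sigma <- rbind(sigma)
  if (ncol(sigma) != 6L) stop("tent sign vectors have length 6")
  sym_compatible(sigma[, 1:3, drop = FALSE]) &
    sym_compatible(sigma[, 4:6, drop = FALSE]) &
    !addtree_falsified(sigma)
}
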