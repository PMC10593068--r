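# Core data structures: triadic judgment tallies, triplets, tents.
#
# A triad (r; x, y) asks which of the comparison stimuli x, y is more similar
# to the reference r.  Because a response to (r; y, x) is the complementary
# response to (r; x, y), each unordered comparison pair is stored once, in
# canonical orientation: the pair sorted by the label order, with C counting
# choices of the smaller label out of N presentations.

#' Construct a triadic judgment dataset
#'
#' Builds a `triad_data` object holding forced-choice tallies for every
#' canonical triad over a stimulus set.  A canonical triad is `(ref; s1, s2)`
#' with `s1 < s2` in the label order; `C` counts the trials on which `s1` was
#' judged closer to `ref`, out of `N` trials.  Rows given with `stim1 > stim2`
#' are mirrored into canonical form (`C` becomes `N - C`); duplicate canonical
#' triads are merged by summing counts, with a warning.  Triads not listed get
#' `C = N = 0` and contribute only prior mass to the indices.
#'
#' @param tallies data frame with columns `ref`, `stim1`, `stim2`, `C`, `N`
#'   (may be empty or `NULL` for a dataset with no observations).
#' @param stimuli character vector of stimulus labels; defaults to the labels
#'   occurring in `tallies`.
#' @return An object of class `triad_data` with elements `stimuli` (sorted
#'   labels), `triads` (integer data frame `ref`, `s1`, `s2` over all
#'   canonical triads), and count vectors `C`, `N`.
#' @examples
#' d <- triad_data(data.frame(ref = "a", stim1 = "b", stim2 = "c", C = 3, N = 5),
#'                 stimuli = c("a", "b", "c", "d"))
#' d
#' @export
triad_data <- function(tallies = NULL, stimuli = NULL) {
  have <- !is.null(tallies) && nrow(tallies) > 0L
  if (have) {
    req <- c("ref", "stim1", "stim2", "C", "N")
    if (!all(req %in% names(tallies)))
      stop("tallies must have columns ref, stim1, stim2, C, N")
    refl <- as.character(tallies$ref)
    s1l <- as.character(tallies$stim1)
    s2l <- as.character(tallies$stim2)
    C <- as.integer(tallies$C)
    N <- as.integer(tallies$N)
    bad <- which(refl == s1l | refl == s2l | s1l == s2l)
    if (length(bad))
      stop("degenerate triad (repeated stimulus) at row ", bad[1L])
    bad <- which(is.na(C) | is.na(N) | C < 0L | N < 0L | C > N)
    if (length(bad))
      stop("invalid counts (need 0 <= C <= N) at row ", bad[1L])
  }
  if (is.null(stimuli)) {
    if (!have) stop("need either tallies or an explicit stimulus set")
    stimuli <- unique(c(refl, s1l, s2l))
  }
  stimuli <- sort(unique(as.character(stimuli)))
  if (any(!nzchar(stimuli))) stop("stimulus labels must be non-empty strings")
  x <- .empty_triad_data(stimuli)
  if (have) {
    ref <- match(refl, stimuli)
    s1 <- match(s1l, stimuli)
    s2 <- match(s2l, stimuli)
    if (anyNA(ref) || anyNA(s1) || anyNA(s2))
      stop("tallies mention stimuli not in the stimulus set")
    # mirror rows stored in non-canonical order
    swap <- s1 > s2
    if (any(swap)) {
      tmp <- s1[swap]; s1[swap] <- s2[swap]; s2[swap] <- tmp
      C[swap] <- N[swap] - C[swap]
    }
    row <- x$index[cbind(ref, s1, s2)]
    if (anyDuplicated(row)) {
      warning("duplicate canonical triads merged by summing counts")
      C <- as.integer(tapply(C, row, sum))
      N <- as.integer(tapply(N, row, sum))
      row <- sort(unique(row))
    }
    x$C[row] <- C
    x$N[row] <- N
  }
  x
}

# Full canonical triad grid for M stimuli: for each reference, every
# unordered pair of the remaining stimuli, in a fixed deterministic order.
.empty_triad_data <- function(stimuli) {
  M <- length(stimuli)
  if (M < 3L) stop("need at least 3 stimuli")
  ref <- integer(0); s1 <- integer(0); s2 <- integer(0)
  for (r in seq_len(M)) {
    others <- setdiff(seq_len(M), r)
    pr <- combn(others, 2L)
    ref <- c(ref, rep.int(r, ncol(pr)))
    s1 <- c(s1, pr[1L, ])
    s2 <- c(s2, pr[2L, ])
  }
  index <- array(NA_integer_, dim = c(M, M, M))
  index[cbind(ref, s1, s2)] <- seq_along(ref)
  structure(list(
    stimuli = stimuli,
    triads = data.frame(ref = ref, s1 = s1, s2 = s2),
    C = integer(length(ref)),
    N = integer(length(ref)),
    index = index
  ), class = "triad_data")
}

#' Canonicalize a single triadic response
#'
#' Maps one raw response -- reference `ref`, comparisons `a` and `b`, and a
#' flag saying whether `a` was chosen as closer -- onto the canonical triad
#' and its count increments, merging mirror presentations.
#'
#' @param ref,a,b stimulus labels, all distinct.
#' @param chose_a logical; `TRUE` if `a` was judged closer to `ref`.
#' @return list with `ref`, `stim1`, `stim2` (canonical, `stim1 < stim2`),
#'   `dC` (1 if the canonical first comparison was chosen, else 0) and `dN = 1`.
#' @export
canonicalize_triad <- function(ref, a, b, chose_a) {
  ref <- as.character(ref); a <- as.character(a); b <- as.character(b)
  if (ref == a || ref == b || a == b)
    stop("invalid triad: stimuli must be distinct")
  if (a < b)
    list(ref = ref, stim1 = a, stim2 = b, dC = as.integer(chose_a), dN = 1L)
  else
    list(ref = ref, stim1 = b, stim2 = a, dC = as.integer(!chose_a), dN = 1L)
}

#' Tally raw single-triad judgments
#'
#' @param judgments data frame with columns `ref`, `chosen`, `other`: on each
#'   trial `chosen` was judged closer to `ref` than `other` was.
#' @param stimuli optional explicit stimulus set.
#' @return A [triad_data] object.
#' @export
tally_judgments <- function(judgments, stimuli = NULL) {
  if (is.null(stimuli))
    stimuli <- unique(c(as.character(judgments$ref),
                        as.character(judgments$chosen),
                        as.character(judgments$other)))
  if (nrow(judgments) == 0L) return(triad_data(NULL, stimuli))
  ref <- as.character(judgments$ref)
  ch <- as.character(judgments$chosen)
  ot <- as.character(judgments$other)
  bad <- which(ref == ch | ref == ot | ch == ot)
  if (length(bad)) stop("degenerate judgment at row ", bad[1L])
  s1 <- pmin(ch, ot)
  s2 <- pmax(ch, ot)
  key <- paste(ref, s1, s2, sep = "\r")
  C <- tapply(as.integer(ch == s1), key, sum)
  N <- tapply(rep.int(1L, length(key)), key, sum)
  parts <- do.call(rbind, strsplit(names(C), "\r", fixed = TRUE))
  triad_data(data.frame(ref = parts[, 1L], stim1 = parts[, 2L],
                        stim2 = parts[, 3L],
                        C = as.integer(C), N = as.integer(N)),
             stimuli = stimuli)
}

#' @export
print.triad_data <- function(x, ...) {
  cat("Triadic judgment dataset\n")
  cat("  stimuli:", length(x$stimuli), "   canonical triads:", nrow(x$triads), "\n")
  cat("  observed triads:", sum(x$N > 0L),
      "   total judgments:", sum(x$N), "\n")
  invisible(x)
}

#' @export
as.data.frame.triad_data <- function(x, ..., all = FALSE) {
  keep <- if (all) rep.int(TRUE, nrow(x$triads)) else x$N > 0L
  data.frame(ref = x$stimuli[x$triads$ref[keep]],
             stim1 = x$stimuli[x$triads$s1[keep]],
             stim2 = x$stimuli[x$triads$s2[keep]],
             C = x$C[keep], N = x$N[keep])
}

# ---- triplets and tents -----------------------------------------------------

# A triplet {x<y<z} carries the orientation R1=R(x;y,z), R2=R(y;z,x),
# R3=R(z;x,y).  In canonical storage R2's comparison pair is (x,z) with x
# first, so slot 2 is orientation-flipped.  A tent {w; a<b<c} carries
# R1=R(w;b,c), R2=R(w;c,a), R3=R(w;a,b) (tripod) and R4=R(a;b,c),
# R5=R(b;c,a), R6=R(c;a,b) (base); slots 2 and 5 are flipped.

.triplet_flips <- c(FALSE, TRUE, FALSE)
.tent_flips <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)

.triplet_structure <- function(x) {
  M <- length(x$stimuli)
  if (M < 3L) return(list(members = matrix(integer(0), 0L, 3L),
                          idx = matrix(integer(0), 0L, 3L),
                          flips = .triplet_flips))
  cmb <- t(combn(seq_len(M), 3L))
  idx <- cbind(x$index[cmb[, c(1L, 2L, 3L), drop = FALSE]],
               x$index[cmb[, c(2L, 1L, 3L), drop = FALSE]],
               x$index[cmb[, c(3L, 1L, 2L), drop = FALSE]])
  list(members = cmb, idx = idx, flips = .triplet_flips)
}

.tent_structure <- function(x) {
  M <- length(x$stimuli)
  if (M < 4L) return(list(vertex = integer(0),
                          base = matrix(integer(0), 0L, 3L),
                          idx = matrix(integer(0), 0L, 6L),
                          flips = .tent_flips))
  vx <- integer(0); base <- NULL
  for (w in seq_len(M)) {
    b <- t(combn(setdiff(seq_len(M), w), 3L))
    vx <- c(vx, rep.int(w, nrow(b)))
    base <- rbind(base, b)
  }
  a <- base[, 1L]; b <- base[, 2L]; cc <- base[, 3L]
  idx <- cbind(x$index[cbind(vx, b, cc)],
               x$index[cbind(vx, a, cc)],
               x$index[cbind(vx, a, b)],
               x$index[cbind(a, b, cc)],
               x$index[cbind(b, a, cc)],
               x$index[cbind(cc, a, b)])
  list(vertex = vx, base = base, idx = idx, flips = .tent_flips)
}

#' Enumerate all triplets of a dataset
#'
#' A triplet is the set of three triads formed from three stimuli, each
#' serving once as reference; triplets partition the set of canonical triads.
#' The orientation fixes `R1 = R(x;y,z)`, `R2 = R(y;z,x)`, `R3 = R(z;x,y)`
#' with `x < y < z` in the label order.
#'
#' @param x a [triad_data] object.
#' @return data frame with one row per triplet (columns `x`, `y`, `z`),
#'   in a deterministic order.
#' @export
enumerate_triplets <- function(x) {
  stopifnot(inherits(x, "triad_data"))
  tr <- .triplet_structure(x)
  m <- tr$members
  data.frame(x = x$stimuli[m[, 1L]], y = x$stimuli[m[, 2L]],
             z = x$stimuli[m[, 3L]])
}

#' Enumerate all tents of a dataset
#'
#' A tent `{w; a, b, c}` is a tripod (reference `w` compared against the pairs
#' of `a, b, c`) together with the base triplet on `{a, b, c}`; it has six
#' constituent triads.  All `M * choose(M-1, 3)` vertex/base combinations are
#' listed in a deterministic order.
#'
#' @param x a [triad_data] object.
#' @return data frame with columns `vertex`, `a`, `b`, `c`.
#' @export
enumerate_tents <- function(x) {
  stopifnot(inherits(x, "triad_data"))
  tn <- .tent_structure(x)
  if (length(tn$vertex) == 0L)
    return(data.frame(vertex = character(0), a = character(0),
                      b = character(0), c = character(0)))
  data.frame(vertex = x$stimuli[tn$vertex], a = x$stimuli[tn$base[, 1L]],
             b = x$stimuli[tn$base[, 2L]], c = x$stimuli[tn$base[, 3L]])
}

#' Tallies of a triplet or tent in its fixed orientation
#'
#' Re-expresses canonical tallies in the orientation of a unit: where the
#' unit's choice probability refers to the mirror of the stored triad, the
#' count is flipped to `N - C`.  Missing triads yield `(0, 0)`.
#'
#' @param x a [triad_data] object.
#' @param members character vector of 3 stimulus labels (a triplet) or 4
#'   labels (a tent, vertex first).
#' @return data frame with columns `C` and `N`, one row per oriented slot
#'   (3 for a triplet, 6 for a tent).
#' @export
oriented_tallies <- function(x, members) {
  stopifnot(inherits(x, "triad_data"))
  m <- match(as.character(members), x$stimuli)
  if (anyNA(m)) stop("unknown stimulus label")
  if (length(m) == 3L) {
    m <- sort(m)
    idx <- c(x$index[m[1L], m[2L], m[3L]],
             x$index[m[2L], m[1L], m[3L]],
             x$index[m[3L], m[1L], m[2L]])
    flips <- .triplet_flips
  } else if (length(m) == 4L) {
    w <- m[1L]; b3 <- sort(m[2:4])
    if (w %in% b3) stop("tent vertex must not be in the base")
    a <- b3[1L]; b <- b3[2L]; cc <- b3[3L]
    idx <- c(x$index[w, b, cc], x$index[w, a, cc], x$index[w, a, b],
             x$index[a, b, cc], x$index[b, a, cc], x$index[cc, a, b])
    flips <- .tent_flips
  } else stop("members must name a triplet (3) or a tent (4 labels)")
  C <- x$C[idx]; N <- x$N[idx]
  C[flips] <- N[flips] - C[flips]
  data.frame(C = C, N = N)
}
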