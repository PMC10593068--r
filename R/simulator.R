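# Synthetic triadic-judgment experiments over reference geometries.
#
# Stimuli are points in a known geometry; a trial on triad (r; x, y) judges
# x closer iff D(r,x) - D(r,y) + eps < 0 with eps ~ Normal(0, sigma^2),
# i.e. P(choose x) = Phi((D(r,y) - D(r,x)) / sigma).  Distance matrices are
# scaled to unit root-mean-square over unordered pairs, so sigma is
# expressed in units of the typical distance.

# Binary-heap indexing of the 15-node depth-3 complete binary tree:
# node 1 is the root, children of i are 2i and 2i+1, depth(i) = floor(log2 i).
.tree_depth <- function(i) floor(log2(i))

.tree_lca <- function(u, v) {
  while (u != v) {
    if (u > v) u <- u %/% 2L else v <- v %/% 2L
  }
  u
}

# path distance on the tree with per-link weights given by wt(depth of the
# deeper endpoint); computed as wdepth(u) + wdepth(v) - 2 * wdepth(lca)
.tree_path_dist <- function(M, wt) {
  wdepth <- numeric(M)
  for (i in 2:M) wdepth[i] <- wdepth[i %/% 2L] + wt(.tree_depth(i))
  D <- matrix(0, M, M)
  for (u in seq_len(M - 1L)) for (v in (u + 1L):M) {
    d <- wdepth[u] + wdepth[v] - 2 * wdepth[.tree_lca(u, v)]
    D[u, v] <- D[v, u] <- d
  }
  D
}

.geometry_names <- c("tree_um", "tree_add", "tree_addwt", "tree_eucl",
                     "line", "circle", "two_ray")

#' Build a reference stimulus geometry
#'
#' Constructs the distance model for one of the benchmark geometries used to
#' probe the indices:
#' \describe{
#'   \item{`tree_um`}{15 nodes of a depth-3 complete binary tree; distance =
#'     height of the first common ancestor, with heights doubling per level
#'     (2, 4, 8 from the deepest realizable meet up) -- an ultrametric, and
#'     the same drawn tree whose path lengths define `tree_addwt`.}
#'   \item{`tree_add`}{same tree; distance = number of links on the
#'     connecting path (an additive-tree metric).}
#'   \item{`tree_addwt`}{same tree with link weights `2^(3 - depth)` (links
#'     nearer the root are longer); distance = summed link weights (additive
#'     tree).}
#'   \item{`tree_eucl`}{same topology embedded in the plane (root at the
#'     origin, children offset horizontally by a spread that halves per
#'     level, unit vertical drop); distance = Euclidean (not additive-tree).}
#'   \item{`line`}{`n_points` equally spaced on a line; distance = steps
#'     (additive tree).}
#'   \item{`circle`}{`n_points` equally spaced on a cycle; distance =
#'     shortest arc (not additive-tree).}
#'   \item{`two_ray`}{two rays of `ray_points` unit-spaced points sharing an
#'     origin, meeting at `angle` degrees; distance Euclidean by default, or
#'     the angle-independent along-ray graph distance.}
#' }
#' All distances are scaled to unit RMS over unordered pairs.
#'
#' @param geometry one of the names above.
#' @param n_points number of stimuli for `line` / `circle` (default 15).
#' @param angle angle between the rays, degrees, in (0, 180].
#' @param ray_points points per ray for `two_ray` (default 6, i.e. 13
#'   stimuli with the shared origin).
#' @param metric for `two_ray`: `"euclidean"` or `"graph"`.
#' @return object of class `distance_model`: `stimuli`, normalized distance
#'   matrix `D`, `geometry`, `params`.
#' @export
similarity_geometry <- function(geometry = .geometry_names, n_points = 15L,
                                angle = 90, ray_points = 6L,
                                metric = c("euclidean", "graph")) {
  geometry <- match.arg(geometry)
  metric <- match.arg(metric)
  params <- list()
  if (geometry %in% c("tree_um", "tree_add", "tree_addwt", "tree_eucl")) {
    M <- 15L
    D <- switch(geometry,
      tree_um = {
        # height of the first common ancestor, doubling per level (2, 4, 8
        # from the deepest realizable meet up): the ultrametric of the same
        # drawn tree whose path lengths define tree_addwt
        D <- matrix(0, M, M)
        for (u in seq_len(M - 1L)) for (v in (u + 1L):M) {
          d <- 2^(3 - .tree_depth(.tree_lca(u, v)))
          D[u, v] <- D[v, u] <- d
        }
        D
      },
      tree_add = .tree_path_dist(M, function(depth) 1),
      tree_addwt = .tree_path_dist(M, function(depth) 2^(3 - depth)),
      tree_eucl = {
        xy <- matrix(0, M, 2L)
        for (i in 2:M) {
          par <- i %/% 2L
          off <- 2^(2 - .tree_depth(i)) * if (i %% 2L == 0L) -1 else 1
          xy[i, ] <- c(xy[par, 1L] + off, -.tree_depth(i))
        }
        as.matrix(dist(xy))
      })
  } else if (geometry == "line") {
    M <- as.integer(n_points)
    if (M < 3L) stop("need at least 3 points")
    D <- abs(outer(seq_len(M), seq_len(M), `-`))
    params$n_points <- M
  } else if (geometry == "circle") {
    M <- as.integer(n_points)
    if (M < 3L) stop("need at least 3 points")
    d <- abs(outer(seq_len(M), seq_len(M), `-`))
    D <- pmin(d, M - d)
    params$n_points <- M
  } else { # two_ray
    if (angle <= 0 || angle > 180) stop("angle must be in (0, 180] degrees")
    k <- as.integer(ray_points)
    M <- 2L * k + 1L
    pos <- c(0L, seq_len(k), seq_len(k))           # along-ray offsets
    ray <- c(0L, rep.int(1L, k), rep.int(2L, k))   # 0 = origin
    if (metric == "euclidean") {
      th <- angle * pi / 180
      xy <- cbind(ifelse(ray == 2L, pos * cos(th), pos),
                  ifelse(ray == 2L, pos * sin(th), 0))
      D <- as.matrix(dist(xy))
    } else {
      same <- outer(ray, ray, `==`) | outer(ray, ray, `*`) == 0L
      D <- ifelse(same, abs(outer(pos, pos, `-`)), outer(pos, pos, `+`))
    }
    params$angle <- angle; params$ray_points <- k; params$metric <- metric
  }
  dimnames(D) <- NULL
  rms <- sqrt(mean(D[upper.tri(D)]^2))
  structure(list(stimuli = sprintf("s%02d", seq_len(nrow(D))),
                 D = D / rms, geometry = geometry, params = params),
            class = "distance_model")
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf("Distance model '%s': %d stimuli, RMS-normalized distances\n",
              x$geometry, length(x$stimuli)))
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a triadic forced-choice experiment
#'
#' Presents every possible triad of the model's stimulus set `n_trials`
#' times.  Each trial compares the two reference-to-comparison distances
#' after adding Gaussian decision noise of standard deviation `sigma`, so the
#' probability of choosing the canonical first comparison is
#' `pnorm((D(r, s2) - D(r, s1)) / sigma)`; the per-triad tally is drawn
#' binomially, which is distributionally identical to drawing the trials one
#' at a time.
#'
#' @param model a `distance_model` from [similarity_geometry].
#' @param n_trials presentations per triad, `N >= 1`.
#' @param sigma decision-noise SD, in units of the RMS-normalized distance.
#' @param seed optional RNG seed for reproducibility.
#' @return a [triad_data] object.
#' @export
simulate_triad_experiment <- function(model, n_trials, sigma, seed = NULL) {
  stopifnot(inherits(model, "distance_model"))
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  x <- .empty_triad_data(model$stimuli)
  D <- model$D
  dd <- D[cbind(x$triads$ref, x$triads$s2)] -
        D[cbind(x$triads$ref, x$triads$s1)]
  p <- pnorm(dd / sigma)
  x$C <- rbinom(length(p), n_trials, p)
  x$N <- rep.int(n_trials, length(p))
  x
}

# ---- paradigm converters ----------------------------------------------------

#' Expand one ranking trial into triadic judgments
#'
#' In the ranking paradigm a trial presents a reference `ref` and `m`
#' comparison stimuli, ranked by similarity to the reference.  Each of the
#' `choose(m, 2)` comparison pairs yields one triadic judgment whose winner
#' is the higher-ranked stimulus (for `m = 8`, 28 judgments per trial).
#'
#' @param ref reference stimulus label.
#' @param ranking comparison labels in rank order, most similar first.
#' @return data frame of judgments with columns `ref`, `chosen`, `other`.
#' @export
rank_trial_to_triads <- function(ref, ranking) {
  ranking <- as.character(ranking)
  if (length(ranking) < 2L) stop("need at least 2 ranked comparisons")
  if (anyDuplicated(ranking) || ref %in% ranking)
    stop("ranking must be distinct comparisons, not including the reference")
  pr <- combn(seq_along(ranking), 2L)
  data.frame(ref = as.character(ref),
             chosen = ranking[pr[1L, ]],
             other = ranking[pr[2L, ]])
}

#' Expand one odd-one-out trial into triadic judgments
#'
#' Choosing `outlier` from a presented trio is read as two judgments: each
#' non-outlier is closer to the other non-outlier than to the outlier.  The
#' outlier therefore appears only as a comparison stimulus, never as a
#' reference.
#'
#' @param trio three distinct stimulus labels.
#' @param outlier the selected odd one out (must be in `trio`).
#' @return data frame of 2 judgments with columns `ref`, `chosen`, `other`.
#' @export
odd_one_out_to_triads <- function(trio, outlier) {
  trio <- as.character(trio)
  if (length(trio) != 3L || anyDuplicated(trio)) stop("trio must be 3 distinct stimuli")
  outlier <- as.character(outlier)
  if (!outlier %in% trio) stop("outlier must be one of the trio")
  rest <- setdiff(trio, outlier)
  data.frame(ref = rest, chosen = rev(rest), other = outlier)
}
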