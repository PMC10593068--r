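# File formats and the pipeline entry point.
#
# Tally CSV: columns ref,stim1,stim2,C,N (header required; stim1 < stim2 in
# canonical files, but mirrored rows are accepted and folded).  Raw judgment
# CSVs depend on the paradigm.  Results are written as JSON for auditability.

#' Read a triad-tally CSV
#'
#' @param path CSV with header `ref,stim1,stim2,C,N`.
#' @param stimuli optional explicit stimulus set (labels beyond those in the
#'   file are allowed and contribute prior-only units).
#' @return a [triad_data] object.  Rows in mirrored order are canonicalized
#'   (`C` becomes `N - C`); duplicated canonical triads are merged with a
#'   warning; malformed rows raise an error naming the row.
#' @export
read_tallies <- function(path, stimuli = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("ref", "stim1", "stim2", "C", "N")
  if (!all(req %in% names(df)))
    stop("expected header ref,stim1,stim2,C,N in ", path)
  triad_data(df, stimuli = stimuli)
}

#' Write a dataset as a canonical triad-tally CSV
#'
#' @param x a [triad_data] object.
#' @param path output path.
#' @param all write all canonical triads, including unobserved `(0, 0)` rows.
#' @export
write_tallies <- function(x, path, all = FALSE) {
  stopifnot(inherits(x, "triad_data"))
  write.csv(as.data.frame(x, all = all), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read raw judgment logs
#'
#' Supports three paradigms:
#' \describe{
#'   \item{`triad`}{columns `trial`, `ref`, `chosen`, `other`: one triadic
#'     judgment per row.}
#'   \item{`rank`}{columns `trial`, `ref`, `rank1`, `rank2`, ...: per trial,
#'     comparisons ranked by similarity to the reference; each pair of ranks
#'     yields one judgment.}
#'   \item{`odd_one_out`}{columns `trial`, `stim1`, `stim2`, `stim3`,
#'     `outlier`: each trial yields two judgments with the outlier as a
#'     comparison stimulus.}
#' }
#'
#' @param path CSV file.
#' @param paradigm one of `"triad"`, `"rank"`, `"odd_one_out"`.
#' @param stimuli optional explicit stimulus set.
#' @return a [triad_data] object.
#' @export
read_raw_judgments <- function(path, paradigm = c("triad", "rank", "odd_one_out"),
                               stimuli = NULL) {
  paradigm <- match.arg(paradigm)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("no judgments in ", path)
    if (is.null(stimuli)) stop("empty file and no stimulus set given")
    return(triad_data(NULL, stimuli))
  }
  jd <- switch(paradigm,
    triad = {
      req <- c("ref", "chosen", "other")
      if (!all(req %in% names(df))) stop("expected columns ref,chosen,other")
      df[req]
    },
    rank = {
      rk <- grep("^rank[0-9]+$", names(df), value = TRUE)
      if (!("ref" %in% names(df)) || length(rk) < 2L)
        stop("expected columns ref, rank1, rank2, ...")
      rk <- rk[order(as.integer(sub("rank", "", rk)))]
      out <- vector("list", nrow(df))
      for (i in seq_len(nrow(df))) {
        out[[i]] <- tryCatch(
          rank_trial_to_triads(df$ref[i], unlist(df[i, rk], use.names = FALSE)),
          error = function(e) stop("row ", i, ": ", conditionMessage(e),
                                   call. = FALSE))
      }
      do.call(rbind, out)
    },
    odd_one_out = {
      req <- c("stim1", "stim2", "stim3", "outlier")
      if (!all(req %in% names(df)))
        stop("expected columns stim1,stim2,stim3,outlier")
      out <- vector("list", nrow(df))
      for (i in seq_len(nrow(df))) {
        out[[i]] <- tryCatch(
          odd_one_out_to_triads(c(df$stim1[i], df$stim2[i], df$stim3[i]),
                                df$outlier[i]),
          error = function(e) stop("row ", i, ": ", conditionMessage(e),
                                   call. = FALSE))
      }
      do.call(rbind, out)
    })
  tally_judgments(jd, stimuli = stimuli)
}

#' Run the full analysis pipeline
#'
#' Reads (or accepts) a dataset, fits the prior according to the configured
#' policy, computes the requested indices with surrogates and jackknife
#' standard errors, and optionally writes a machine-readable JSON results
#' document carrying enough provenance (configuration, fitted prior, unit
#' counts, seed) to reproduce itself.
#'
#' @param config list with elements: `input` (tally CSV path) or `data`
#'   (a [triad_data]); `index` (subset of sym/umi/addtree, default all);
#'   `a` (`"auto"` or a number), `h` (`"auto"` or a number, default 0),
#'   `h_eval` (default 0 = exact ultrametric limit), `min_observed`,
#'   `surrogate` (`"none"`, `"flip_any"`, `"flip_all"`), `jackknife`
#'   (logical), `seed`, `out` (optional JSON output path).
#' @return the results document, invisibly, as a list.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(index = c("sym", "umi", "addtree"),
                                a = "auto", h = 0, h_eval = 0,
                                min_observed = 0L, surrogate = "none",
                                jackknife = TRUE, seed = NULL, out = NULL),
                           config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  data <- if (!is.null(cfg$data)) cfg$data else read_tallies(cfg$input)
  message(sprintf("pipeline: %d stimuli, %d observed triads, %d judgments",
                  length(data$stimuli), sum(data$N > 0L), sum(data$N)))
  fit_h <- identical(cfg$h, "auto")
  if (!fit_h && !(is.numeric(cfg$h) && is.finite(cfg$h)))
    stop("h must be a number or 'auto'")
  prior <- NULL
  if (!identical(cfg$a, "auto")) {
    if (fit_h) stop("h = 'auto' requires a = 'auto' (joint fit)")
    if (!(is.numeric(cfg$a) && is.finite(cfg$a)))
      stop("a must be a number or 'auto'")
    prior <- choice_prior(cfg$a, cfg$h)
  } else if (!fit_h && cfg$h > 0) {
    # fixed nonzero point mass with the shape fitted at that h
    prior <- fit_choice_prior(data, h = cfg$h)
  }
  surr <- if (identical(cfg$surrogate, "none")) NULL else cfg$surrogate
  res <- triad_indices(data, which = cfg$index, prior = prior,
                       fit_h = fit_h, h_eval = cfg$h_eval,
                       min_observed = cfg$min_observed,
                       surrogates = surr, jackknife = isTRUE(cfg$jackknife))
  message("pipeline: indices computed for ",
          paste(names(res$indices), collapse = ", "))
  doc <- results_document(res, cfg)
  if (!is.null(cfg$out)) {
    jsonlite::write_json(doc, cfg$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    message("pipeline: results written to ", cfg$out)
  }
  invisible(doc)
}

#' Serialize index results as a results document
#'
#' @param res a `triad_indices` object.
#' @param config the configuration that produced it (stored as provenance).
#' @return plain list, JSON-ready.
#' @export
results_document <- function(res, config = list()) {
  config$data <- NULL
  idx <- lapply(res$indices, function(r) {
    out <- list(kind = r$kind, value = r$value, apriori = r$apriori,
                n_units = r$n_units, se = r$se,
                prior = list(a = r$prior$a, h = r$prior$h),
                per_unit_summary = list(min = min(r$per_unit),
                                        mean = mean(r$per_unit),
                                        max = max(r$per_unit)))
    if (!is.na(r$h_eval)) out$h_eval <- r$h_eval
    if (!is.na(r$h)) out$h <- r$h
    if (length(r$surrogates))
      out$surrogate <- lapply(r$surrogates, function(s)
        list(kind = s$kind, mean = s$mean, sd = s$sd))
    out
  })
  list(tool = "triadic",
       version = as.character(utils::packageVersion("triadic")),
       config = config,
       prior = list(a = res$prior$a, h = res$prior$h,
                    loglik = res$prior$loglik,
                    fitted = isTRUE(res$prior$fitted)),
       data = res$data_summary,
       indices = idx)
}
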