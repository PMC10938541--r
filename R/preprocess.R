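# Repertoire preprocessing: exclusion of undersized repertoires and
# downsampling of the rest to a common UMI depth.
#
# Downsampling draws reads without replacement from the read-level multiset
# (each clone repeated `count` times), i.e. a multivariate-hypergeometric
# sample realized by actual draws rather than a parametric simulation.
# Frequencies are recomputed from the downsampled counts.

#' Exclude undersized repertoires
#'
#' @param repertoires list of `tcr_repertoire` objects.
#' @param min_umis exclusion threshold. The default, `NULL`, uses 10 times
#'   the 1st-percentile cohort depth, which separates a small number of
#'   extreme outliers from the bulk of a cohort whose depths span orders of
#'   magnitude.
#' @return list with `kept` (repertoires), `excluded` (data.frame of
#'   sample_id and total_umis) and `min_umis` (the threshold applied).
#'   Excluded samples are reported with a warning.
#' @export
exclusion_filter <- function(repertoires, min_umis = NULL) {
  depths <- vapply(repertoires, `[[`, numeric(1), "total_umis")
  if (is.null(min_umis)) {
    min_umis <- 10 * unname(stats::quantile(depths, 0.01, type = 1))
  }
  stopifnot(min_umis >= 1)
  keep <- depths >= min_umis
  if (!any(keep)) stop("exclusion filter removed every repertoire")
  excluded <- data.frame(
    sample_id = vapply(repertoires[!keep], `[[`, "", "sample_id"),
    total_umis = depths[!keep], stringsAsFactors = FALSE)
  if (nrow(excluded) > 0) {
    warning(sprintf("excluded %d undersized repertoire(s): %s",
                    nrow(excluded),
                    paste(sprintf("%s (%d UMIs)", excluded$sample_id,
                                  excluded$total_umis), collapse = ", ")))
  }
  list(kept = repertoires[keep], excluded = excluded, min_umis = min_umis)
}

#' Downsample one repertoire to a target UMI depth
#'
#' Draws `target` reads uniformly without replacement from the repertoire's
#' read multiset; per-clone downsampled counts therefore follow the
#' multivariate hypergeometric distribution. Clones reaching zero are
#' dropped; frequencies are recomputed.
#'
#' @param rep a `tcr_repertoire`.
#' @param target depth to downsample to (<= `total_umis`).
#' @param seed RNG seed making the draw reproducible.
#' @return a `tcr_repertoire` with `total_umis == target`.
#' @export
downsample <- function(rep, target, seed = 1) {
  stopifnot(inherits(rep, "tcr_repertoire"), target >= 1)
  if (target > rep$total_umis) {
    stop(sprintf("target %d exceeds repertoire size %d (%s)",
                 target, rep$total_umis, rep$sample_id))
  }
  if (target == rep$total_umis) return(rep)
  cl <- rep$clonotypes
  breaks <- cumsum(cl$count)
  new_count <- with_seed(seed, {
    draws <- sample.int(rep$total_umis, target)   # read indices, w/o replacement
    tabulate(findInterval(draws - 1L, breaks) + 1L, nbins = nrow(cl))
  })
  keep <- new_count > 0
  out <- cl[keep, , drop = FALSE]
  out$count <- new_count[keep]
  repertoire(rep$sample_id, out, rep$group)
}

#' Downsample a cohort to its smallest repertoire
#'
#' Applies [exclusion_filter()] first, then downsamples every retained
#' repertoire to the minimum retained depth, each with a per-sample substream
#' of `seed`.
#'
#' @param repertoires list of `tcr_repertoire` objects (>= 2).
#' @param seed base RNG seed.
#' @param min_umis passed to [exclusion_filter()].
#' @return list with `repertoires` (downsampled), `target` (common depth) and
#'   `excluded` (data.frame).
#' @export
downsample_cohort <- function(repertoires, seed = 1, min_umis = NULL) {
  stopifnot(length(repertoires) >= 2)
  flt <- exclusion_filter(repertoires, min_umis)
  depths <- vapply(flt$kept, `[[`, numeric(1), "total_umis")
  target <- min(depths)
  down <- lapply(seq_along(flt$kept), function(i) {
    downsample(flt$kept[[i]], target, seed = substream(seed, 1000L + i))
  })
  list(repertoires = down, target = target, excluded = flt$excluded)
}
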