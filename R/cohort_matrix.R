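# The clone-by-sample frequency matrix: the learning substrate.
#
# Rows are CDR3 amino-acid keys (the clone union over the cohort), columns
# are samples; cell (clone, sample) holds the clone's within-sample frequency
# (0 when absent). Row order is deterministic: sharing count descending, then
# summed frequency descending, then lexicographic — so outputs are byte-stable
# across runs.

#' Build the clone-by-sample frequency matrix
#'
#' @param repertoires list of aggregated `tcr_repertoire` objects with
#'   distinct sample ids.
#' @return object of class `cohort_matrix`: list with `values` (numeric
#'   matrix, clones x samples), `labels` (named character vector of group
#'   labels per sample).
#' @export
build_cohort_matrix <- function(repertoires) {
  stopifnot(length(repertoires) >= 1L)
  ids <- vapply(repertoires, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])
  }
  for (r in repertoires) {
    if (!is_aggregated(r)) {
      stop("repertoire ", r$sample_id, " is not aggregated; run aggregate_by_cdr3()")
    }
  }
  keys <- unique(unlist(lapply(repertoires, function(r) r$clonotypes$cdr3_aa),
                        use.names = FALSE))
  m <- matrix(0, nrow = length(keys), ncol = length(ids),
              dimnames = list(keys, ids))
  for (j in seq_along(repertoires)) {
    cl <- repertoires[[j]]$clonotypes
    m[match(cl$cdr3_aa, keys), j] <- cl$frequency
  }
  sharing <- rowSums(m > 0)
  total_freq <- rowSums(m)
  ord <- order(-sharing, -total_freq, keys)
  m <- m[ord, , drop = FALSE]
  labels <- vapply(repertoires, function(r) r$group, character(1))
  names(labels) <- ids
  structure(list(values = m, labels = labels), class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("cohort matrix: %d clones x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Restrict a cohort matrix to a subset of samples and/or clones
#'
#' Used to withhold test columns: feature selection and tuning only ever see
#' the training restriction.
#' @param x a `cohort_matrix`.
#' @param samples sample ids to keep (default all).
#' @param clones clone keys to keep, in the given order (default all).
#' @export
subset_cohort <- function(x, samples = NULL, clones = NULL) {
  stopifnot(inherits(x, "cohort_matrix"))
  m <- x$values
  labels <- x$labels
  if (!is.null(samples)) {
    stopifnot(all(samples %in% colnames(m)))
    m <- m[, samples, drop = FALSE]
    labels <- labels[samples]
  }
  if (!is.null(clones)) {
    stopifnot(all(clones %in% rownames(m)))
    m <- m[clones, , drop = FALSE]
  }
  structure(list(values = m, labels = labels), class = "cohort_matrix")
}

#' Feature table for model fitting: samples x clones
#' @noRd
design_matrix <- function(x, clones = NULL) {
  m <- if (is.null(clones)) x$values else x$values[clones, , drop = FALSE]
  t(m)
}

#' Write / read a cohort matrix as CSV
#'
#' Header row of sample ids, first column of clone keys; labels in a sidecar
#' two-column CSV next to the matrix.
#' @export
write_cohort_matrix <- function(x, path) {
  df <- data.frame(cdr3_aa = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- data.frame(sample_id = names(x$labels), group = unname(x$labels))
  utils::write.csv(meta, sub("\\.csv$", "_labels.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_matrix
#' @export
read_cohort_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- utils::read.csv(sub("\\.csv$", "_labels.csv", path),
                          stringsAsFactors = FALSE)
  labels <- meta$group
  names(labels) <- meta$sample_id
  structure(list(values = m, labels = labels[colnames(m)]),
            class = "cohort_matrix")
}
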