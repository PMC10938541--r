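# Repertoire container: one sample's clonotype table plus metadata.
#
# A clonotype is identified by its CDR3 amino-acid sequence; V/J genes and
# chain are carried as annotations. Counts are UMIs (transcript-level clone
# sizes); frequencies are within-sample relative abundances.

#' Construct a TCR repertoire
#'
#' @param sample_id sample identifier.
#' @param clonotypes data.frame with columns `cdr3_aa`, `v_gene`, `j_gene`,
#'   `chain` ("TRA"/"TRB"), `count` (positive integer UMI counts). A
#'   `frequency` column is (re)computed as `count / sum(count)`.
#' @param group group label: "OC", "HD" or "UNKNOWN".
#' @return object of class `tcr_repertoire`: list with `sample_id`, `group`,
#'   `clonotypes` (data.frame) and `total_umis`.
#' @export
repertoire <- function(sample_id, clonotypes, group = "UNKNOWN") {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  group <- match.arg(group, c("OC", "HD", "UNKNOWN"))
  required <- c("cdr3_aa", "v_gene", "j_gene", "chain", "count")
  missing_cols <- setdiff(required, names(clonotypes))
  if (length(missing_cols)) {
    stop("clonotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  cl <- clonotypes[required]
  cl$cdr3_aa <- as.character(cl$cdr3_aa)
  cl$count <- as.numeric(cl$count)
  if (nrow(cl) == 0L) stop("empty repertoire: no clonotypes for sample ", sample_id)
  if (any(cl$count < 1 | cl$count != round(cl$count))) {
    stop("counts must be positive integers")
  }
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cl$cdr3_aa)
  if (any(bad)) {
    stop("invalid CDR3 amino-acid sequence(s): ",
         paste(utils::head(cl$cdr3_aa[bad], 3), collapse = ", "))
  }
  total <- sum(cl$count)
  cl$frequency <- cl$count / total
  rownames(cl) <- NULL
  structure(
    list(sample_id = sample_id, group = group, clonotypes = cl,
         total_umis = total),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("TCR repertoire '%s' [%s]: %d clonotypes, %d UMIs\n",
              x$sample_id, x$group, nrow(x$clonotypes), x$total_umis))
  invisible(x)
}

#' Merge clonotypes sharing a CDR3 amino-acid sequence
#'
#' Clone identity throughout the package is the CDR3 amino-acid string alone;
#' entries differing only in V/J usage are merged, counts summed and the V/J
#' annotation of the merged record taken from the highest-count constituent.
#'
#' @param rep a `tcr_repertoire`.
#' @return a `tcr_repertoire` with one row per `cdr3_aa`; `total_umis` is
#'   preserved exactly.
#' @export
aggregate_by_cdr3 <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clonotypes
  if (!anyDuplicated(cl$cdr3_aa)) return(rep)
  # stable order so the max-count representative is deterministic under ties
  ord <- order(cl$cdr3_aa, -cl$count, cl$v_gene, cl$j_gene)
  cl <- cl[ord, ]
  first <- !duplicated(cl$cdr3_aa)
  agg_count <- rowsum(cl$count, cl$cdr3_aa)   # rowsum sorts by group name
  out <- cl[first, ]
  out$count <- agg_count[out$cdr3_aa, 1]
  repertoire(rep$sample_id, out, rep$group)
}

#' Test whether a repertoire is aggregated (unique per CDR3)
#' @noRd
is_aggregated <- function(rep) !anyDuplicated(rep$clonotypes$cdr3_aa)
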