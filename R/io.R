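# Clonotype-table and database I/O.
#
# Two tabular dialects are supported:
#   AIRR Rearrangement TSV: junction_aa, v_call, j_call, duplicate_count
#   MiXCR-style clonotype TSV: aaSeqCDR3, allVHitsWithScore,
#     allJHitsWithScore, cloneCount
# Nonproductive CDR3s (stop '*' or frameshift '_') are dropped at read time,
# a standard repertoire QC step.

airr_cols <- c("junction_aa", "v_call", "j_call", "duplicate_count")
mixcr_cols <- c("aaSeqCDR3", "allVHitsWithScore", "allJHitsWithScore", "cloneCount")

clean_gene <- function(g) {
  g <- sub("\\(.*$", "", sub(",.*$", "", toupper(trimws(as.character(g)))))
  sub("\\*.*$", "", g)
}

chain_from_gene <- function(g) {
  ifelse(grepl("^TRB", g), "TRB", ifelse(grepl("^TRA", g), "TRA", "TRA"))
}

#' Read a clonotype table into a repertoire
#'
#' @param path path to a tab-separated clonotype table.
#' @param dialect "AIRR" (AIRR Rearrangement columns) or "MIXCR"
#'   (MiXCR-style clonotype export columns).
#' @param sample_id sample identifier to attach.
#' @param group optional group label ("OC"/"HD"/"UNKNOWN").
#' @return a [repertoire()]; frequencies are `count / total_umis` computed
#'   over the rows retained after dropping empty or nonproductive CDR3s.
#' @export
read_clonotypes <- function(path, dialect = c("AIRR", "MIXCR"), sample_id,
                            group = "UNKNOWN") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- if (dialect == "AIRR") airr_cols else mixcr_cols
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s table %s lacks required column(s): %s",
                 dialect, path, paste(missing_cols, collapse = ", ")))
  }
  if (dialect == "AIRR") {
    cl <- data.frame(cdr3_aa = as.character(tab$junction_aa),
                     v_gene = clean_gene(tab$v_call),
                     j_gene = clean_gene(tab$j_call),
                     count = tab$duplicate_count,
                     stringsAsFactors = FALSE)
  } else {
    cl <- data.frame(cdr3_aa = as.character(tab$aaSeqCDR3),
                     v_gene = clean_gene(tab$allVHitsWithScore),
                     j_gene = clean_gene(tab$allJHitsWithScore),
                     count = tab$cloneCount,
                     stringsAsFactors = FALSE)
  }
  cl$chain <- chain_from_gene(cl$v_gene)
  keep <- !is.na(cl$cdr3_aa) & cl$cdr3_aa != "" &
    !grepl("[*_]", cl$cdr3_aa, fixed = FALSE)
  cl <- cl[keep, , drop = FALSE]
  if (nrow(cl) == 0L) {
    stop("no usable clonotype rows in ", path, " (all empty or nonproductive)")
  }
  repertoire(sample_id, cl, group)
}

#' Write a repertoire as a clonotype table
#'
#' Inverse of [read_clonotypes()]; round-trips `cdr3_aa`, `v_gene`, `j_gene`
#' and `count` in either dialect.
#'
#' @inheritParams read_clonotypes
#' @param rep a `tcr_repertoire`.
#' @export
write_clonotypes <- function(rep, path, dialect = c("AIRR", "MIXCR")) {
  dialect <- match.arg(dialect)
  cl <- rep$clonotypes
  if (dialect == "AIRR") {
    out <- data.frame(junction_aa = cl$cdr3_aa, v_call = cl$v_gene,
                      j_call = cl$j_gene, duplicate_count = cl$count)
  } else {
    out <- data.frame(aaSeqCDR3 = cl$cdr3_aa,
                      allVHitsWithScore = sprintf("%s*00(%d)", cl$v_gene,
                                                  round(cl$count)),
                      allJHitsWithScore = sprintf("%s*00(%d)", cl$j_gene,
                                                  round(cl$count)),
                      cloneCount = cl$count)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Two-column CSV (`sample_id`, `group`).
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(md)))
  md
}

#' Load a public clone-prevalence database table
#'
#' Fixture dialect: delimited table with columns `cdr3_aa`, `prevalence`
#' (number of database entries for that sequence) and optional `metadata`.
#' Rows are grouped by CDR3 with prevalences summed; an empty prevalence
#' counts as 1; malformed rows (bad CDR3 alphabet, negative prevalence) are
#' skipped with a warning giving the count.
#'
#' @param path path to the table (TSV or CSV by extension).
#' @param source label: "VDJDB_LIKE", "MCPAS_LIKE" or "TCGA_TIL_LIKE".
#' @return object of class `public_db`: data.frame (`cdr3_aa`, `prevalence`,
#'   `metadata`) ordered by prevalence descending then CDR3, with attribute
#'   `source`.
#' @export
load_public_db <- function(path, source = c("VDJDB_LIKE", "MCPAS_LIKE",
                                            "TCGA_TIL_LIKE")) {
  source <- match.arg(source)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           fill = TRUE, comment.char = "")
  stopifnot(all(c("cdr3_aa", "prevalence") %in% names(tab)))
  if (!"metadata" %in% names(tab)) tab$metadata <- ""
  public_db(tab, source)
}

#' Construct a public database from a raw record table
#'
#' @param records data.frame with `cdr3_aa`, `prevalence`, optional `metadata`.
#' @param source database source label.
#' @export
public_db <- function(records, source = "VDJDB_LIKE") {
  cdr3 <- as.character(records$cdr3_aa)
  prev <- suppressWarnings(as.numeric(records$prevalence))
  prev[is.na(prev) | records$prevalence %in% c("", NA)] <- 1
  ok <- !is.na(cdr3) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cdr3) & prev >= 0
  if (any(!ok)) {
    warning(sum(!ok), " malformed database row(s) skipped")
  }
  if (!any(ok)) stop("all database rows malformed")
  cdr3 <- cdr3[ok]; prev <- prev[ok]
  meta <- if ("metadata" %in% names(records)) as.character(records$metadata)[ok] else ""
  agg <- rowsum(prev, cdr3)
  first <- !duplicated(cdr3)
  out <- data.frame(cdr3_aa = cdr3[first],
                    prevalence = agg[cdr3[first], 1],
                    metadata = meta[first],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence, out$cdr3_aa), ]
  rownames(out) <- NULL
  structure(out, source = source, class = c("public_db", "data.frame"))
}

#' Write a public database fixture table
#' @export
write_public_db <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
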