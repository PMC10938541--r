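# Clone annotation: invariant T-cell subtype calls from V/J gene usage,
# public-database entry counts, and the tumor-infiltrating-lymphocyte (TIL)
# occurrence analysis with its bootstrap null.

#' Default invariant T-cell subtype rule table
#'
#' iNKT cells carry the canonical TRAV10-TRAJ18 alpha chain; MAIT cells carry
#' TRAV1-2-TRAJ33. Rules are matched on the gene core after normalization
#' (allele suffixes stripped, locus prefix optional), so "V10"/"TRAV10*01"
#' both match.
#' @export
subtype_rules <- function() {
  data.frame(v_core = c("V10", "V1-2"),
             j_core = c("J18", "J33"),
             locus = c("TRA", "TRA"),
             subtype = c("iNKT", "MAIT"),
             stringsAsFactors = FALSE)
}

#' Call invariant T-cell subtypes from V/J gene usage
#'
#' @param v_gene,j_gene character vectors of gene names (any of "TRAV10",
#'   "TRAV10*01", "V10" forms).
#' @param rules rule table; see [subtype_rules()].
#' @return data.frame: `v_gene`, `j_gene`, `subtype` ("iNKT", "MAIT" or
#'   "NONE"). Unparseable gene names yield "NONE" with a warning.
#' @export
annotate_subtype <- function(v_gene, j_gene, rules = subtype_rules()) {
  stopifnot(length(v_gene) == length(j_gene))
  v <- normalize_gene(v_gene)
  j <- normalize_gene(j_gene)
  bad <- is.na(v$core) | is.na(j$core)
  if (any(bad)) {
    warning(sum(bad), " unparseable gene name(s); assigned subtype NONE")
  }
  subtype <- rep("NONE", length(v_gene))
  for (r in seq_len(nrow(rules))) {
    hit <- !bad &
      v$core == rules$v_core[r] & j$core == rules$j_core[r] &
      (v$locus == "" | v$locus == rules$locus[r]) &
      (j$locus == "" | j$locus == rules$locus[r])
    subtype[hit] <- rules$subtype[r]
  }
  data.frame(v_gene = as.character(v_gene), j_gene = as.character(j_gene),
             subtype = subtype, stringsAsFactors = FALSE)
}

#' Annotate a clone set against cohort V/J usage
#'
#' Looks up each clone's V/J annotation in the cohort repertoires (from the
#' highest-count occurrence) and calls subtypes.
#' @param clones character vector of CDR3 keys.
#' @param repertoires list of `tcr_repertoire` objects.
#' @return data.frame: `cdr3_aa`, `v_gene`, `j_gene`, `subtype`.
#' @export
annotate_clones <- function(clones, repertoires) {
  all_cl <- do.call(rbind, lapply(repertoires, `[[`, "clonotypes"))
  all_cl <- all_cl[all_cl$cdr3_aa %in% clones, , drop = FALSE]
  out <- data.frame(cdr3_aa = clones, v_gene = NA_character_,
                    j_gene = NA_character_, stringsAsFactors = FALSE)
  if (nrow(all_cl) > 0) {
    all_cl <- all_cl[order(all_cl$cdr3_aa, -all_cl$count), ]
    rep_row <- all_cl[!duplicated(all_cl$cdr3_aa), ]
    i <- match(out$cdr3_aa, rep_row$cdr3_aa)
    out$v_gene <- rep_row$v_gene[i]
    out$j_gene <- rep_row$j_gene[i]
  }
  known <- !is.na(out$v_gene)
  out$subtype <- "NONE"
  if (any(known)) {
    out$subtype[known] <- annotate_subtype(out$v_gene[known],
                                           out$j_gene[known])$subtype
  }
  out
}

#' Database entry counts for a clone set
#'
#' @param clones character vector of CDR3 keys.
#' @param db a `public_db`.
#' @return named numeric vector: each clone's summed prevalence in the
#'   database (0 when absent).
#' @export
db_entry_counts <- function(clones, db) {
  i <- match(clones, db$cdr3_aa)
  out <- ifelse(is.na(i), 0, db$prevalence[i])
  stats::setNames(out, clones)
}

# tumor-sample index list per clone (precomputed by til_db())
til_index <- function(db) {
  if (!is.null(db$index)) return(db$index)
  n_per <- lengths(db$samples)
  split(rep(seq_along(db$samples), n_per),
        unlist(db$samples, use.names = FALSE))
}

#' Number of tumor samples containing at least one query clone
#'
#' @param query non-empty character vector of CDR3 keys.
#' @param db a `til_db`.
#' @return integer; each tumor sample counts at most once.
#' @export
count_samples_with_any <- function(query, db) {
  stopifnot(inherits(db, "til_db"))
  if (length(query) == 0) stop("empty query clone set")
  idx <- til_index(db)
  length(unique(unlist(idx[intersect(query, names(idx))], use.names = FALSE)))
}

#' Bootstrap occurrence null for a clone set in a TIL database
#'
#' Draws `B` random sets of `k` distinct clones uniformly from `universe`
#' (the cohort's full clone set), scores each by the number of tumor samples
#' containing at least one drawn clone, and reports the empirical p-value of
#' the observed count under the plus-one rule
#' p = (1 + #\{draws >= observed\}) / (B + 1), with ties counted against the
#' query so p is never exactly zero.
#'
#' @param k query-set size.
#' @param universe character vector of clone keys to draw from.
#' @param db a `til_db`.
#' @param observed observed occurrence count (e.g. from
#'   [count_samples_with_any()]).
#' @param B number of bootstrap draws.
#' @param seed RNG seed.
#' @return object of class `occurrence_null`: list with `observed`, `draws`,
#'   `B`, `k`, `p_value`.
#' @export
bootstrap_occurrence_null <- function(k, universe, db, observed, B = 1000,
                                      seed = 1) {
  stopifnot(B >= 1, k >= 1)
  universe <- unique(universe)
  if (k > length(universe)) stop("k exceeds universe size")
  idx <- til_index(db)
  map <- idx[universe]          # NULL for clones absent from the database
  draws <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      pick <- sample.int(length(universe), k)
      length(unique(unlist(map[pick], use.names = FALSE)))
    }, numeric(1))
  })
  p <- (1 + sum(draws >= observed)) / (B + 1)
  structure(list(observed = observed, draws = draws, B = B, k = k,
                 p_value = p),
            class = "occurrence_null")
}

#' @export
print.occurrence_null <- function(x, ...) {
  cat(sprintf(
    "occurrence null: observed %d vs %d draws of %d clones (null mean %.1f); p = %.4g\n",
    x$observed, x$B, x$k, mean(x$draws), x$p_value))
  invisible(x)
}

#' Per-cancer-type fraction of tumor samples containing a query clone
#'
#' @param query non-empty character vector of CDR3 keys.
#' @param db a `til_db`.
#' @return data.frame: `cancer_type`, `n_samples`, `n_positive`, `fraction`,
#'   ordered by fraction descending.
#' @export
per_cancer_breakdown <- function(query, db) {
  stopifnot(inherits(db, "til_db"))
  if (length(query) == 0) stop("empty query clone set")
  pos <- vapply(db$samples, function(cl) any(query %in% cl), logical(1))
  types <- unname(db$cancer_type)
  tab <- table(types)
  hit <- tapply(pos, types, sum)
  out <- data.frame(cancer_type = names(tab),
                    n_samples = as.integer(tab),
                    n_positive = as.integer(hit[names(tab)]),
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_positive / out$n_samples
  out <- out[order(-out$fraction, out$cancer_type), ]
  rownames(out) <- NULL
  out
}
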