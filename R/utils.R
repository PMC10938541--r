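# Internal helpers: RNG scoping, seed substreams, gene-name normalization.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards so library code does not clobber
#' the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a reproducible substream seed
#'
#' Mixes a base seed with a stream index so each pipeline component draws from
#' its own stream and can be regenerated in isolation. Result stays inside the
#' 32-bit integer range R's RNG seeds require.
#' @noRd
substream <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 69621 + 1) %% 2147483563
  as.integer(x)
}

#' Normalize an IMGT TR gene name
#'
#' Strips allele suffixes ("*01") and alignment scores ("(123.4)"), uppercases,
#' and splits the locus prefix from the segment core so that "V10", "TRAV10"
#' and "TRAV10*01" all compare equal on the core.
#'
#' @param gene character vector of gene names.
#' @return data.frame with columns `locus` ("TRA", "TRB" or "" when absent)
#'   and `core` (e.g. "V10", "J18"); `core` is `NA` when unparseable.
#' @export
normalize_gene <- function(gene) {
  g <- toupper(trimws(as.character(gene)))
  g <- sub("\\(.*$", "", g)   # MiXCR score annotation
  g <- sub("\\*.*$", "", g)   # allele
  g <- sub(",.*$", "", g)     # keep first hit of a comma-separated list
  locus <- ifelse(grepl("^TR[AB]", g), substr(g, 1, 3), "")
  core <- ifelse(locus != "", substring(g, 4), g)
  ok <- grepl("^[VJ][0-9]", core)
  core[!ok] <- NA_character_
  data.frame(locus = locus, core = core, stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' Thin wrapper over pROC with a fixed orientation: higher scores mean the
#' positive class. Returns 0.5 for a degenerate constant scorer.
#' @noRd
auc_score <- function(labels, scores, positive = "OC") {
  y <- as.integer(labels == positive)
  if (length(unique(y)) < 2L) stop("AUC needs both classes present")
  if (length(unique(scores)) < 2L) return(0.5)
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Stratified k-fold assignment
#' @noRd
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (g in unique(labels)) {
      idx <- which(labels == g)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Largest-remainder stratified allocation of `total` slots across groups
#' @noRd
stratified_allocation <- function(group_sizes, total) {
  exact <- group_sizes * total / sum(group_sizes)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  base
}
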