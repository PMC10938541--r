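# Clonotypic diversity statistics and group comparison.
#
# For clone frequencies p_i:
#   Gini (concentration) = sum_i (2i - n - 1) x_(i) / (n sum x), x ascending
#   Gini-Simpson         = 1 - sum p_i^2
#   inverse Simpson      = 1 / sum p_i^2
#   true diversity (Hill number of order q)
#                        = (sum p_i^q)^(1/(1-q)), q != 1
#                        = exp(-sum p_i log p_i), q = 1
# The default Hill order is q = 1 (exponential Shannon): "true diversity" is
# a Hill-number family and q = 2 would merely duplicate inverse Simpson,
# which is reported separately.

#' Diversity profile of one repertoire
#'
#' @param rep a non-empty `tcr_repertoire`.
#' @param q Hill order for true diversity (default 1).
#' @param rare_max clones with count <= `rare_max` count as rare (default 3).
#' @return one-row data.frame: `sample_id`, `group`, `unique_clonotypes`,
#'   `gini`, `gini_simpson`, `inv_simpson`, `true_diversity`, `q`,
#'   `top_prop` (frequency share of the 10 most abundant clones),
#'   `rare_prop` (frequency share of rare clones).
#' @export
diversity_profile <- function(rep, q = 1, rare_max = 3) {
  stopifnot(inherits(rep, "tcr_repertoire"), q >= 0)
  x <- rep$clonotypes$count
  if (length(x) == 0) stop("empty repertoire")
  n <- length(x)
  xs <- sort(x)
  gini <- sum((2 * seq_len(n) - n - 1) * xs) / (n * sum(xs))
  p <- x / sum(x)
  simpson <- sum(p^2)
  td <- if (abs(q - 1) < 1e-12) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
  data.frame(sample_id = rep$sample_id, group = rep$group,
             unique_clonotypes = n,
             gini = gini,
             gini_simpson = 1 - simpson,
             inv_simpson = 1 / simpson,
             true_diversity = td,
             q = q,
             top_prop = sum(sort(p, decreasing = TRUE)[seq_len(min(10, n))]),
             rare_prop = sum(p[x <= rare_max]),
             stringsAsFactors = FALSE)
}

#' Diversity profiles for a cohort
#'
#' @param repertoires list of `tcr_repertoire` objects.
#' @inheritParams diversity_profile
#' @return data.frame, one row per sample.
#' @export
diversity_profiles <- function(repertoires, q = 1, rare_max = 3) {
  do.call(rbind, lapply(repertoires, diversity_profile, q = q,
                        rare_max = rare_max))
}

#' Pairwise shared-clone counts
#'
#' @param repertoires list of aggregated `tcr_repertoire` objects (>= 2).
#' @return symmetric integer matrix; diagonal holds each sample's unique
#'   clonotype count, entry (i, j) the number of shared CDR3s.
#' @export
overlap_matrix <- function(repertoires) {
  stopifnot(length(repertoires) >= 2)
  sets <- lapply(repertoires, function(r) unique(r$clonotypes$cdr3_aa))
  ids <- vapply(repertoires, `[[`, "", "sample_id")
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, i] <- length(sets[[i]])
    for (j in seq_len(i - 1L)) {
      m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}

#' Compare a diversity metric between groups
#'
#' Two-sided Mann-Whitney U test on one metric between the two groups: exact
#' p for combined n <= 20 without ties, normal approximation (with tie
#' correction) otherwise.
#'
#' @param profiles data.frame from [diversity_profiles()] (or any data.frame
#'   with the metric column).
#' @param labels group label per row; defaults to `profiles$group`.
#' @param metric column name to compare.
#' @return data.frame: `metric`, `statistic` (Mann-Whitney U for the first
#'   group), `p_value`, `n1`, `n2`.
#' @export
compare_groups <- function(profiles, labels = profiles$group, metric) {
  stopifnot(metric %in% names(profiles))
  values <- profiles[[metric]]
  g <- unique(labels)
  if (length(g) != 2) stop("exactly two groups required, got ", length(g))
  x <- values[labels == g[1]]
  y <- values[labels == g[2]]
  if (length(x) == 0 || length(y) == 0) stop("a group is empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # zero-variance degenerate case: no evidence
  data.frame(metric = metric, statistic = unname(wt$statistic),
             p_value = min(1, p), n1 = length(x), n2 = length(y),
             stringsAsFactors = FALSE)
}
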