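# End-to-end orchestration of the two classification routes.
#
# Both routes share the preprocessing front end (aggregate -> exclude ->
# downsample -> clone-by-sample matrix) and the evaluation back end
# (multi-split tune/test, bootstrap, confusion, clone annotation). They
# differ in how candidate clones are found:
#   top-down:   600 most-shared clones -> SFM(LGB) -> 10 -> backward
#               SFS(gbm) -> 3, evaluated with a gradient-boosting model
#   top clones: top-10 CDR3s of three public databases -> union ->
#               cohort intersection -> backward SFS(LDA) -> 8 -> 4,
#               evaluated with a discriminant-analysis model
# Candidate discovery and selection run on the training partition of a
# primary split only; test columns are withheld until scoring.

#' Pipeline run configuration
#'
#' @param test_size held-out test samples per split.
#' @param n_splits random splits for the final evaluation.
#' @param bo_init,bo_iters Bayesian-optimization budget per tuned fit.
#' @param bootstrap_n bootstrap resamples in the evaluation report.
#' @param min_umis exclusion threshold (NULL = data-driven default, see
#'   [exclusion_filter()]).
#' @param candidate_scope compute the candidate clone pool on the primary
#'   split's training samples only ("train", default) or on the full matrix
#'   ("full").
#' @param seed base seed for every stochastic stage.
#' @param out_dir optional directory; when set, intermediate artifacts
#'   (matrix CSV, feature JSON, report JSON) are written there.
#' @export
run_config <- function(test_size = 20, n_splits = 10, bo_init = 10,
                       bo_iters = 40, bootstrap_n = 5, min_umis = NULL,
                       candidate_scope = c("train", "full"), seed = 1,
                       out_dir = NULL) {
  list(test_size = test_size, n_splits = n_splits, bo_init = bo_init,
       bo_iters = bo_iters, bootstrap_n = bootstrap_n, min_umis = min_umis,
       candidate_scope = match.arg(candidate_scope), seed = seed,
       out_dir = out_dir)
}

# shared front end: aggregate, exclude, downsample, build matrix
prepare_matrix <- function(repertoires, config) {
  reps <- lapply(repertoires, aggregate_by_cdr3)
  ds <- downsample_cohort(reps, seed = substream(config$seed, 2L),
                          min_umis = config$min_umis)
  mat <- build_cohort_matrix(ds$repertoires)
  list(matrix = mat, downsampled = ds$repertoires, target = ds$target,
       excluded = ds$excluded)
}

write_artifacts <- function(dir, route, mat, features, report) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_matrix(mat, file.path(dir, "cohort_matrix.csv"))
  jsonlite::write_json(
    list(route = route, selector = report$selector,
         clone_keys = report$feature_set),
    file.path(dir, paste0(route, "_features.json")), auto_unbox = TRUE)
  rep_out <- report[c("family", "selector", "route", "feature_set",
                      "hyperparameters", "per_split_auc", "mean_auc",
                      "bootstrap_scores", "bootstrap_mean", "n_splits",
                      "test_size", "seed")]
  rep_out$confusion <- as.list(report$confusion)
  rep_out$annotation <- report$annotation
  jsonlite::write_json(rep_out, file.path(dir, paste0(route, "_report.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$avg_roc, file.path(dir, paste0(route, "_roc.csv")),
                   row.names = FALSE)
}

#' Run the top-down classification route
#'
#' @param repertoires list of `tcr_repertoire` objects (raw; aggregation,
#'   exclusion and downsampling are applied here).
#' @param config a [run_config()].
#' @param n_common size of the initial most-shared candidate pool.
#' @param sfm_k features retained by the SFM step.
#' @param final_k features retained by backward SFS.
#' @param sfm_estimator,sfs_estimator selection estimators.
#' @param family model family evaluated on the final feature set.
#' @return a `model_report` with an `annotation` data.frame attached.
#' @export
run_topdown <- function(repertoires, config = run_config(),
                        n_common = 600, sfm_k = 10, final_k = 3,
                        sfm_estimator = "LGB", sfs_estimator = "gbm",
                        family = "gbm") {
  prep <- prepare_matrix(repertoires, config)
  mat <- prep$matrix
  primary <- split_cohort(mat, test_size = config$test_size,
                          seed = substream(config$seed, 3L))
  scope <- if (config$candidate_scope == "train") primary$train else mat
  candidates <- rank_common_clones(scope, min(n_common, nrow(scope$values)))
  sfm <- select_from_model(subset_cohort(primary$train, clones = candidates),
                           estimator = sfm_estimator, k = sfm_k,
                           seed = substream(config$seed, 4L))
  sfs <- backward_sfs(subset_cohort(primary$train, clones = sfm$clone_keys),
                      estimator = sfs_estimator, k = final_k,
                      seed = substream(config$seed, 5L))
  sfs$route <- "TOP_DOWN"
  report <- multi_split_evaluation(mat, sfs, family,
                                   n_splits = config$n_splits,
                                   test_size = config$test_size,
                                   bo_init = config$bo_init,
                                   bo_iters = config$bo_iters,
                                   bootstrap_n = config$bootstrap_n,
                                   seed = substream(config$seed, 6L))
  report$route <- "TOP_DOWN"
  report$selector <- paste0("SFM:", sfm_estimator, "+SFS:", sfs_estimator)
  report$excluded <- prep$excluded
  report$downsample_target <- prep$target
  report$annotation <- annotate_clones(report$feature_set, prep$downsampled)
  if (!is.null(config$out_dir)) {
    write_artifacts(config$out_dir, "topdown", mat, sfs, report)
  }
  report
}

#' Run the top-clones classification route
#'
#' @inheritParams run_topdown
#' @param dbs named list of three `public_db` objects.
#' @param n_per_db top-list length per database.
#' @param sfs_k1,sfs_k2 staged backward-SFS targets.
#' @param sfs_estimator elimination estimator.
#' @param family model family evaluated on the final feature set.
#' @export
run_topclones <- function(repertoires, dbs, config = run_config(),
                          n_per_db = 10, sfs_k1 = 8, sfs_k2 = 4,
                          sfs_estimator = "lda", family = "lda") {
  stopifnot(length(dbs) == 3)
  prep <- prepare_matrix(repertoires, config)
  mat <- prep$matrix
  primary <- split_cohort(mat, test_size = config$test_size,
                          seed = substream(config$seed, 3L))
  pool <- top_db_clones(dbs, n_per_db = n_per_db)
  scope <- if (config$candidate_scope == "train") primary$train else mat
  candidates <- intersect_with_cohort(pool, scope)
  if (length(candidates) < sfs_k2) {
    stop("only ", length(candidates),
         " database clones occur in the cohort; cannot select ", sfs_k2)
  }
  stage1 <- if (length(candidates) > sfs_k1) {
    backward_sfs(subset_cohort(primary$train, clones = candidates),
                 estimator = sfs_estimator, k = sfs_k1,
                 seed = substream(config$seed, 5L))$clone_keys
  } else candidates
  sfs <- backward_sfs(subset_cohort(primary$train, clones = stage1),
                      estimator = sfs_estimator, k = sfs_k2,
                      seed = substream(config$seed, 5L))
  sfs$route <- "TOP_CLONES"
  report <- multi_split_evaluation(mat, sfs, family,
                                   n_splits = config$n_splits,
                                   test_size = config$test_size,
                                   bo_init = config$bo_init,
                                   bo_iters = config$bo_iters,
                                   bootstrap_n = config$bootstrap_n,
                                   seed = substream(config$seed, 6L))
  report$route <- "TOP_CLONES"
  report$selector <- paste0("SFS:", sfs_estimator)
  report$excluded <- prep$excluded
  report$downsample_target <- prep$target
  report$candidate_union <- pool
  report$candidates_in_cohort <- candidates
  report$annotation <- annotate_clones(report$feature_set, prep$downsampled)
  if (!is.null(config$out_dir)) {
    write_artifacts(config$out_dir, "topclones", mat, sfs, report)
  }
  report
}
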