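# Feature selection: common-clone ranking, SFM, backward SFS, database tops.

test_that("common-clone ranking orders by sharing, then mass, then key", {
  reps <- list(make_rep(c(CAF = 1, CSF = 1, CTW = 2), "A"),
               make_rep(c(CAF = 1, CSF = 2, CGF = 1), "B"),
               make_rep(c(CAF = 1, CHF = 3), "C"),
               make_rep(c(CAF = 1), "D"))
  m <- build_cohort_matrix(reps)
  r <- rank_common_clones(m, 3)
  expect_equal(r[1], "CAF")      # in 4/4 samples
  expect_equal(r[2], "CSF")      # 2/4, more mass than the rest
  expect_error(rank_common_clones(m, 0), ">= 1")

  # full-sort oracle on a random matrix
  set.seed(9)
  mat <- toy_matrix(n_case = 8, n_control = 8, n_noise = 30, n_signal = 0)
  mat$values[mat$values < 0.25] <- 0
  got <- rank_common_clones(mat, nrow(mat$values))
  sharing <- rowSums(mat$values > 0)
  mass <- rowSums(mat$values)
  oracle <- rownames(mat$values)[order(-sharing, -mass, rownames(mat$values))]
  expect_equal(got, oracle)
})

test_that("SFM keeps the separating feature under every estimator", {
  for (est in c("LDA", "XGB", "LGB", "LINREG")) {
    hits <- vapply(1:5, function(s) {
      mat <- toy_matrix(n_case = 10, n_control = 10, n_noise = 6,
                        n_signal = 1, shift = 2, seed = s)
      fs <- select_from_model(mat, est, k = 1, seed = s)
      fs$clone_keys == "CSIG01F"
    }, logical(1))
    expect_true(all(hits), label = paste("estimator", est))
  }
  # k = candidate count is the identity up to order
  mat <- toy_matrix(seed = 3)
  fs <- select_from_model(mat, "LDA", k = nrow(mat$values))
  expect_setequal(fs$clone_keys, rownames(mat$values))
  expect_error(select_from_model(mat, "LDA", k = 99), "exceeds")
})

test_that("backward SFS eliminates the noise feature like exhaustive search", {
  set.seed(14)
  mat <- toy_matrix(n_case = 12, n_control = 12, n_noise = 1, n_signal = 3,
                    shift = 0.8, seed = 14)
  fs <- backward_sfs(mat, estimator = "lda", k = 3, seed = 2)
  expect_setequal(fs$clone_keys, c("CSIG01F", "CSIG02F", "CSIG03F"))

  # exhaustive-subset oracle: the best C(4,3) subset by the same CV score
  X <- t(mat$values); y <- unname(mat$labels)
  folds <- tcrstrat:::stratified_folds(y, 5, tcrstrat:::substream(2, 11L))
  subsets <- combn(colnames(X), 3, simplify = FALSE)
  scores <- vapply(subsets, function(fts) {
    tcrstrat:::cv_auc(X[, fts, drop = FALSE], y, "lda", folds,
                      tcrstrat:::substream(2, 13L))
  }, numeric(1))
  expect_setequal(fs$clone_keys, subsets[[which.max(scores)]])

  # k = current count is the identity
  fs_id <- backward_sfs(mat, estimator = "lda", k = 4, seed = 2)
  expect_setequal(fs_id$clone_keys, rownames(mat$values))
})

test_that("one removal under strict argmax matches direct evaluation", {
  mat <- toy_matrix(n_case = 10, n_control = 10, n_noise = 4, n_signal = 2,
                    shift = 0.7, seed = 8)
  seed <- 5
  fs <- backward_sfs(mat, estimator = "lda", k = nrow(mat$values) - 1,
                     seed = seed, tie_tol = 0)
  X <- t(mat$values); y <- unname(mat$labels)
  folds <- tcrstrat:::stratified_folds(y, 5, tcrstrat:::substream(seed, 11L))
  feats <- colnames(X)
  removal_scores <- vapply(seq_along(feats), function(i) {
    tcrstrat:::cv_auc(X[, feats[-i], drop = FALSE], y, "lda", folds,
                      tcrstrat:::substream(seed, 13L))
  }, numeric(1))
  best <- max(removal_scores)
  tied <- feats[removal_scores >= best - 1e-12]
  dropped <- setdiff(feats, fs$clone_keys)
  expect_true(dropped %in% tied)
  # the documented tie policy: weakest single-feature CV AUC, then
  # lexicographically last
  solo <- vapply(feats, function(f) {
    tcrstrat:::cv_auc(X[, f, drop = FALSE], y, "lda", folds,
                      tcrstrat:::substream(seed, 12L))
  }, numeric(1))
  weakest <- tied[solo[tied] <= min(solo[tied]) + 1e-12]
  expect_equal(dropped, max(weakest))
})

test_that("database top lists and cohort intersection behave as set operations", {
  mk_db <- function(keys, prev) {
    public_db(data.frame(cdr3_aa = keys, prevalence = prev))
  }
  aa_ok <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aa <- function(i) paste0("C", strrep(aa_ok[(i - 1) %% 20 + 1], 3),
                           strrep(aa_ok[(i - 1) %/% 20 + 1], 2), "F")
  d1 <- mk_db(sapply(1:12, aa), 12:1)
  d2 <- mk_db(sapply(13:24, aa), 12:1)
  d3 <- mk_db(sapply(c(1:5, 14:20), aa), 12:1)
  got <- top_db_clones(list(d1, d2, d3), n_per_db = 10)
  oracle <- union(union(head(d1$cdr3_aa, 10), head(d2$cdr3_aa, 10)),
                  head(d3$cdr3_aa, 10))
  expect_setequal(got, oracle)
  disjoint <- top_db_clones(list(d1, d2), n_per_db = 10)
  expect_length(disjoint, 20L)

  mat <- toy_matrix(seed = 2)
  expect_warning(none <- intersect_with_cohort(c("CXXXF", "CYYYF"), mat),
                 "no candidate")
  expect_length(none, 0L)
  all_in <- rownames(mat$values)[1:3]
  expect_equal(intersect_with_cohort(all_in, mat), all_in)
})

test_that("selection reads only training columns", {
  spec <- small_spec(n_case = 10, n_control = 10)
  cohort <- generate_cohort(spec)
  mat <- build_cohort_matrix(lapply(cohort, aggregate_by_cdr3))
  sp <- split_cohort(mat, test_size = 6, seed = 3)

  run_selection <- function(train) {
    cand <- rank_common_clones(train, 50)
    sfm <- select_from_model(subset_cohort(train, clones = cand), "LGB",
                             k = 8, seed = 4)
    backward_sfs(subset_cohort(train, clones = sfm$clone_keys), "gbm",
                 k = 3, seed = 4)$clone_keys
  }
  before <- run_selection(sp$train)
  # corrupt every test column: selection must not notice
  corrupted <- mat
  corrupted$values[, colnames(sp$test$values)] <-
    matrix(runif(nrow(mat$values) * ncol(sp$test$values)),
           nrow = nrow(mat$values))
  sp2 <- list(train = subset_cohort(corrupted,
                                    samples = colnames(sp$train$values)))
  expect_identical(run_selection(sp2$train), before)
})
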