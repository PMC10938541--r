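# Splitting, Bayesian tuning, bootstrap evaluation and model selection.

test_that("stratified splits partition the cohort and preserve class ratio", {
  spec <- small_spec(n_case = 9, n_control = 13)
  mat <- build_cohort_matrix(lapply(generate_cohort(spec), aggregate_by_cdr3))
  sp <- split_cohort(mat, test_size = 8, seed = 1)
  expect_equal(ncol(sp$test$values), 8L)
  expect_equal(ncol(sp$train$values), 14L)
  expect_setequal(c(colnames(sp$train$values), colnames(sp$test$values)),
                  colnames(mat$values))
  expect_length(intersect(colnames(sp$train$values),
                          colnames(sp$test$values)), 0L)
  # class ratio within one sample of proportional
  expect_equal(sum(sp$test$labels == "OC"), round(8 * 9 / 22))
  # determinism
  sp2 <- split_cohort(mat, test_size = 8, seed = 1)
  expect_identical(colnames(sp$test$values), colnames(sp2$test$values))
  expect_error(split_cohort(mat, test_size = 22), "below the sample count")
})

test_that("every model family separates an easy problem", {
  mat <- toy_matrix(n_case = 14, n_control = 14, n_noise = 2, n_signal = 2,
                    shift = 2, seed = 6)
  X <- t(mat$values); y <- unname(mat$labels)
  for (fam in names(model_families())) {
    fit <- fit_model(fam, X, y, seed = 3)
    auc <- tcrstrat:::auc_score(y, predict_scores(fit, X))
    expect_gte(auc, 0.9)
    cls <- predict_classes(fit, X)
    expect_true(all(cls %in% c("OC", "HD")))
  }
  expect_error(fit_model("nope", X, y), "unknown model family")
  expect_error(fit_model("lda", X, rep("OC", nrow(X))), "one class")
})

test_that("the optimizer finds the optimum of a concave grid objective", {
  space <- list(k = tcrstrat:::param_int(1, 20))
  hits <- vapply(1:20, function(s) {
    opt <- bayes_optimize(function(p, t) -(p$k - 7)^2, space,
                          bo_init = 10, bo_iters = 20, seed = s)
    opt$best_params$k == 7
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a one-point search space is chosen and refitted on all of train", {
  mat <- toy_matrix(n_case = 10, n_control = 10, shift = 2, seed = 4)
  space <- list(k = tcrstrat:::param_int(5, 5))
  tuned <- tune_and_fit(mat, "knn", bo_init = 2, bo_iters = 3, seed = 1,
                        search_space = space)
  expect_equal(tuned$params$k, 5L)
  expect_equal(nrow(tuned$model$fit$train), 20L)  # refit on the full train set
  # linearly separable features reach validation AUC 1 at the optimum
  tuned2 <- tune_and_fit(mat, "lda", bo_init = 3, bo_iters = 5, seed = 1)
  expect_equal(tuned2$val_auc, 1)
})

test_that("the optimizer reports per-trial failures and survives partial ones", {
  space <- list(a = tcrstrat:::param_num(0, 1))
  flaky <- function(p, t) if (p$a > 0.5) stop("boom") else p$a
  opt <- bayes_optimize(flaky, space, bo_init = 5, bo_iters = 10, seed = 2)
  expect_lte(opt$best_value, 0.5)
  expect_error(
    bayes_optimize(function(p, t) stop("always"), space, bo_init = 2,
                   bo_iters = 3, seed = 1),
    "all optimization trials failed")
})

test_that("bootstrap evaluation refits on resamples of the training size", {
  mat <- toy_matrix(n_case = 12, n_control = 12, shift = 2, seed = 5)
  sp <- split_cohort(mat, test_size = 8, seed = 2)
  be <- bootstrap_evaluate(sp$train, sp$test, "lda", n = 5, seed = 3)
  expect_length(be$scores, 5L)
  expect_equal(be$mean, mean(be$scores))
  expect_true(all(be$scores == 1))   # fully separable
  be2 <- bootstrap_evaluate(sp$train, sp$test, "lda", n = 5, seed = 3,
                            refit = FALSE)
  expect_length(unique(be2$scores), 1L)
})

test_that("multi-split reports are internally consistent and reproducible", {
  mat <- toy_matrix(n_case = 12, n_control = 12, n_noise = 3, n_signal = 2,
                    shift = 2, seed = 7)
  rep1 <- multi_split_evaluation(mat, c("CSIG01F", "CSIG02F"), "lda",
                                 n_splits = 3, test_size = 8, bo_init = 2,
                                 bo_iters = 3, seed = 9)
  expect_equal(rep1$mean_auc, mean(rep1$per_split_auc), tolerance = 1e-12)
  expect_true(all(rep1$per_split_auc >= 0 & rep1$per_split_auc <= 1))
  expect_equal(sum(rep1$confusion), ncol(mat$values))
  expect_equal(nrow(rep1$avg_roc), 101L)
  expect_true(all(diff(rep1$avg_roc$tpr) >= -1e-12))
  rep2 <- multi_split_evaluation(mat, c("CSIG01F", "CSIG02F"), "lda",
                                 n_splits = 3, test_size = 8, bo_init = 2,
                                 bo_iters = 3, seed = 9)
  expect_identical(rep1$per_split_auc, rep2$per_split_auc)
  expect_identical(rep1$hyperparameters, rep2$hyperparameters)
})

test_that("label-permuted cohorts score near chance", {
  mat <- toy_matrix(n_case = 12, n_control = 12, n_noise = 4, n_signal = 1,
                    shift = 2, seed = 10)
  set.seed(31)
  mat$labels[] <- sample(mat$labels)   # break the label-feature link
  rep <- multi_split_evaluation(mat, rownames(mat$values)[1:3], "lda",
                                n_splits = 10, test_size = 8, bo_init = 2,
                                bo_iters = 3, seed = 12)
  expect_gte(rep$mean_auc, 0.30)
  expect_lte(rep$mean_auc, 0.70)
})

test_that("model selection maximizes AUC with sensible tie-breaks", {
  mk <- function(auc, nfeat, fam) {
    structure(list(mean_auc = auc, feature_set = paste0("F", seq_len(nfeat)),
                   family = fam), class = "model_report")
  }
  expect_equal(select_best_model(list(mk(0.9, 3, "a")))$mean_auc, 0.9)
  # 32 enumerated reports: argmax equals brute force
  set.seed(8)
  aucs <- runif(32)
  reports <- lapply(seq_len(32), function(i) mk(aucs[i], i %% 5 + 1,
                                                letters[i %% 8 + 1]))
  expect_equal(select_best_model(reports)$mean_auc, max(aucs))
  # ties -> fewer features, then family name
  tied <- list(mk(0.9, 5, "b"), mk(0.9, 2, "c"), mk(0.9, 2, "a"))
  best <- select_best_model(tied)
  expect_equal(length(best$feature_set), 2L)
  expect_equal(best$family, "a")
})

test_that("a random scorer has AUC 0.5 on balanced labels", {
  set.seed(17)
  y <- rep(c("OC", "HD"), 20)
  aucs <- vapply(1:100, function(i) {
    tcrstrat:::auc_score(y, runif(length(y)))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
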