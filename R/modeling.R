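# Model search and evaluation: stratified splits, Bayesian hyperparameter
# tuning, bootstrap evaluation and AUC-based model selection.

#' Stratified train/test split of a cohort matrix
#'
#' Largest-remainder allocation keeps the test set's class ratio as close as
#' possible to the cohort's; partitions are disjoint and exhaustive.
#'
#' @param x a `cohort_matrix`.
#' @param test_size number of test samples.
#' @param seed RNG seed.
#' @return list of two `cohort_matrix` objects, `train` and `test`.
#' @export
split_cohort <- function(x, test_size = 20, seed = 1) {
  stopifnot(inherits(x, "cohort_matrix"))
  ids <- colnames(x$values)
  if (test_size >= length(ids)) stop("test_size must be below the sample count")
  groups <- unique(x$labels)
  sizes <- vapply(groups, function(g) sum(x$labels == g), 0L)
  alloc <- stratified_allocation(sizes, test_size)
  test_ids <- with_seed(seed, {
    unlist(lapply(seq_along(groups), function(i) {
      sample(ids[x$labels == groups[i]], alloc[i])
    }), use.names = FALSE)
  })
  train_ids <- setdiff(ids, test_ids)
  tr <- subset_cohort(x, samples = train_ids)
  te <- subset_cohort(x, samples = test_ids)
  if (length(unique(tr$labels)) < 2 || length(unique(te$labels)) < 2) {
    stop("a class is absent from one partition; adjust test_size")
  }
  list(train = tr, test = te)
}

#' Tune hyperparameters by Bayesian optimization and refit on the full train set
#'
#' Each trial draws a fresh stratified 80/20 sub-train/validation split of
#' the training samples (trial-indexed seed), fits the family on the
#' sub-train partition and scores validation AUC. After the search the best
#' configuration is refitted on the entire training set.
#'
#' @param x training `cohort_matrix`, already restricted to the model's
#'   features.
#' @param family model family name (see [model_families()]).
#' @param bo_init,bo_iters optimization budget (random starts / total
#'   evaluations).
#' @param seed RNG seed.
#' @param search_space optional override of the family's space.
#' @return list: `model` (a `tcr_fit` on the full training set), `params`,
#'   `val_auc` (best validation AUC), `history`.
#' @export
tune_and_fit <- function(x, family, bo_init = 10, bo_iters = 40, seed = 1,
                         search_space = NULL) {
  stopifnot(inherits(x, "cohort_matrix"))
  fams <- model_families()
  stopifnot(family %in% names(fams))
  space <- if (is.null(search_space)) fams[[family]]$space else search_space
  X <- design_matrix(x)
  y <- unname(x$labels)
  n_val <- max(2L, round(0.2 * length(y)))
  objective <- function(params, trial) {
    groups <- unique(y)
    sizes <- vapply(groups, function(g) sum(y == g), 0L)
    alloc <- stratified_allocation(sizes, n_val)
    val_idx <- with_seed(substream(seed, 200L + trial), {
      unlist(lapply(seq_along(groups), function(i) {
        sample(which(y == groups[i]), alloc[i])
      }))
    })
    fit <- fit_model(family, X[-val_idx, , drop = FALSE], y[-val_idx],
                     params = params, seed = substream(seed, 300L + trial))
    auc_score(y[val_idx], predict_scores(fit, X[val_idx, , drop = FALSE]))
  }
  opt <- bayes_optimize(objective, space, bo_init = bo_init,
                        bo_iters = bo_iters, seed = seed)
  final <- fit_model(family, X, y, params = opt$best_params,
                     seed = substream(seed, 400L))
  list(model = final, params = opt$best_params, val_auc = opt$best_value,
       history = opt$history)
}

#' Bootstrap evaluation of a tuned configuration
#'
#' Draws `n` resampled training sets (with replacement, each the size of the
#' original training set), refits the model on each and scores the fixed test
#' set. Resamples collapsing to one class are redrawn (at most 100 attempts).
#' Setting `refit = FALSE` instead fits once on the original training set and
#' scores the test set `n` times (the non-refitting reading of bootstrap
#' assessment).
#'
#' @param train,test `cohort_matrix` objects restricted to the model features.
#' @param family model family name.
#' @param params hyperparameters (e.g. from [tune_and_fit()]).
#' @param n number of bootstrap resamples.
#' @param seed RNG seed.
#' @param refit refit on each resample (default) or score one fit `n` times.
#' @return list: `scores` (n test AUCs), `mean`, `sd`.
#' @export
bootstrap_evaluate <- function(train, test, family, params = NULL, n = 5,
                               seed = 1, refit = TRUE) {
  stopifnot(n >= 1)
  Xtr <- design_matrix(train); ytr <- unname(train$labels)
  Xte <- design_matrix(test); yte <- unname(test$labels)
  scores <- vapply(seq_len(n), function(b) {
    if (!refit) {
      fit <- fit_model(family, Xtr, ytr, params, seed = substream(seed, 500L))
      return(auc_score(yte, predict_scores(fit, Xte)))
    }
    idx <- NULL
    for (attempt in seq_len(100L)) {
      idx <- with_seed(substream(seed, 500L + b * 101L + attempt), {
        sample.int(nrow(Xtr), nrow(Xtr), replace = TRUE)
      })
      if (length(unique(ytr[idx])) == 2) break
      if (attempt == 100L) stop("bootstrap resample kept collapsing to one class")
    }
    fit <- fit_model(family, Xtr[idx, , drop = FALSE], ytr[idx], params,
                     seed = substream(seed, 600L + b))
    auc_score(yte, predict_scores(fit, Xte))
  }, numeric(1))
  list(scores = scores, mean = mean(scores), sd = stats::sd(scores))
}

# step ROC of (labels, scores), interpolated onto an FPR grid (vertical
# averaging support)
roc_on_grid <- function(labels, scores, grid) {
  y <- as.integer(labels == POSITIVE_CLASS)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(1 - y) / sum(1 - y))
  vapply(grid, function(g) max(tpr[fpr <= g + 1e-12]), numeric(1))
}

#' Multi-split evaluation of a fixed feature set
#'
#' Repeats split -> tune -> test scoring over `n_splits` random stratified
#' splits and reports the per-split test AUCs, their mean, the vertically
#' averaged ROC on a 101-point FPR grid, a bootstrap evaluation and the
#' confusion matrix over the entire cohort (both computed on the first
#' split's tuned model).
#'
#' @param x full `cohort_matrix`.
#' @param features character vector of clone keys (or a `feature_set`).
#' @param family model family name.
#' @param n_splits number of random splits (>= 2).
#' @param test_size test-set size per split.
#' @param bo_init,bo_iters tuning budget per split.
#' @param bootstrap_n bootstrap resamples for the first split.
#' @param seed base seed.
#' @return object of class `model_report`.
#' @export
multi_split_evaluation <- function(x, features, family, n_splits = 10,
                                   test_size = 20, bo_init = 10,
                                   bo_iters = 40, bootstrap_n = 5, seed = 1) {
  stopifnot(inherits(x, "cohort_matrix"), n_splits >= 2)
  selector <- NA_character_
  route <- NA_character_
  if (inherits(features, "feature_set")) {
    selector <- features$selector
    route <- features$route
    features <- features$clone_keys
  }
  grid <- seq(0, 1, length.out = 101)
  per_split <- numeric(n_splits)
  tprs <- matrix(NA_real_, n_splits, length(grid))
  first <- NULL
  for (s in seq_len(n_splits)) {
    sp <- split_cohort(x, test_size = test_size, seed = substream(seed, 20L + s))
    tr <- subset_cohort(sp$train, clones = features)
    te <- subset_cohort(sp$test, clones = features)
    tuned <- tune_and_fit(tr, family, bo_init = bo_init, bo_iters = bo_iters,
                          seed = substream(seed, 40L + s))
    sc <- predict_scores(tuned$model, design_matrix(te))
    per_split[s] <- auc_score(unname(te$labels), sc)
    tprs[s, ] <- roc_on_grid(unname(te$labels), sc, grid)
    if (s == 1L) first <- list(train = tr, test = te, tuned = tuned)
  }
  boot <- bootstrap_evaluate(first$train, first$test, family,
                             params = first$tuned$params, n = bootstrap_n,
                             seed = substream(seed, 60L))
  full <- subset_cohort(x, clones = features)
  pred <- predict_classes(first$tuned$model, design_matrix(full))
  truth <- unname(full$labels)
  confusion <- c(TP = sum(pred == "OC" & truth == "OC"),
                 FP = sum(pred == "OC" & truth == "HD"),
                 TN = sum(pred == "HD" & truth == "HD"),
                 FN = sum(pred == "HD" & truth == "OC"))
  structure(list(
    family = family, selector = selector, route = route,
    feature_set = features,
    hyperparameters = first$tuned$params,
    per_split_auc = per_split,
    mean_auc = mean(per_split),
    avg_roc = data.frame(fpr = grid, tpr = colMeans(tprs)),
    bootstrap_scores = boot$scores,
    bootstrap_mean = boot$mean,
    confusion = confusion,
    n_splits = n_splits, test_size = test_size, seed = seed),
    class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model report: family=%s, %d features, mean AUC %.3f over %d splits\n",
              x$family, length(x$feature_set), x$mean_auc, x$n_splits))
  cat(sprintf("  per-split AUC: %s\n",
              paste(sprintf("%.3f", x$per_split_auc), collapse = " ")))
  cat(sprintf("  bootstrap (n=%d) mean AUC: %.3f\n",
              length(x$bootstrap_scores), x$bootstrap_mean))
  cat(sprintf("  confusion (full cohort): TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  if (!is.null(x$annotation)) {
    cat("  clones:\n")
    for (i in seq_len(nrow(x$annotation))) {
      a <- x$annotation[i, ]
      cat(sprintf("    %s (%s/%s) %s\n", a$cdr3_aa, a$v_gene, a$j_gene,
                  ifelse(a$subtype == "NONE", "", a$subtype)))
    }
  }
  invisible(x)
}

#' Select the best model report by mean AUC
#'
#' Ties go to the report with fewer features, then lexicographic family name.
#' @param reports list of `model_report` objects.
#' @export
select_best_model <- function(reports) {
  stopifnot(length(reports) >= 1)
  auc <- vapply(reports, `[[`, numeric(1), "mean_auc")
  nfeat <- vapply(reports, function(r) length(r$feature_set), 0L)
  fam <- vapply(reports, `[[`, character(1), "family")
  ord <- order(-auc, nfeat, fam)
  reports[[ord[1]]]
}
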