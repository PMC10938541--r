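# Feature selection: reducing the clone-by-sample matrix to a small
# discriminative clone set.
#
# Two routes:
#   top-down:   most-shared ("common") clones -> select-from-model (SFM)
#               importance filter -> backward sequential feature selection
#   top clones: most prevalent CDR3s in public databases -> intersection with
#               the cohort -> backward sequential feature selection
# Selection only ever sees the training restriction of the matrix; test
# columns are withheld by interface until final scoring.

#' Rank clones by how widely they are shared across samples
#'
#' "Common" means shared across many samples (not most abundant): clones are
#' ranked by the number of samples with nonzero frequency (descending), ties
#' by summed frequency (descending), then lexicographic. An alternative
#' abundance-first key is available via `key`.
#'
#' @param x a `cohort_matrix` (typically the training restriction).
#' @param k number of clone keys to return.
#' @param key "sharing" (default) or "abundance" (summed frequency first).
#' @return character vector of `k` clone keys, ranked.
#' @export
rank_common_clones <- function(x, k, key = c("sharing", "abundance")) {
  stopifnot(inherits(x, "cohort_matrix"))
  key <- match.arg(key)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(x$values)) stop("k exceeds number of clones")
  sharing <- rowSums(x$values > 0)
  total <- rowSums(x$values)
  keys <- rownames(x$values)
  ord <- if (key == "sharing") {
    order(-sharing, -total, keys)
  } else {
    order(-total, -sharing, keys)
  }
  keys[ord][seq_len(k)]
}

#' A selected feature set
#' @noRd
feature_set <- function(clone_keys, route, selector) {
  structure(list(clone_keys = clone_keys, route = route, selector = selector,
                 ranking = clone_keys),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature set (%s / %s): %d clones\n", x$route, x$selector,
              length(x$clone_keys)))
  cat(paste(" ", x$clone_keys, collapse = "\n"), "\n")
  invisible(x)
}

# importance vector (named, one entry per column of X) under an estimator
sfm_importance <- function(X, y, estimator, seed) {
  imp <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (estimator %in% c("LDA", "LINREG")) {
    std <- standardizer(X)
    Xs <- std$apply(X)
    dc <- drop_constant(Xs)
    if (ncol(dc$X) > 0) {
      if (estimator == "LDA") {
        m <- suppressWarnings(MASS::lda(dc$X, grouping = factor(y)))
        co <- m$scaling[, 1]
      } else {
        df <- data.frame(dc$X, check.names = FALSE)
        df$.y <- as.integer(y == POSITIVE_CLASS)
        m <- stats::lm(.y ~ ., data = df)
        co <- stats::coef(m)[-1]
        names(co) <- colnames(dc$X)
        co[is.na(co)] <- 0
      }
      imp[names(co)] <- abs(co)
    }
  } else if (estimator %in% c("XGB", "LGB")) {
    # column subsampling decorrelates gain: without it one of several
    # equally informative clones absorbs all importance and the rest rank
    # with the noise features
    params <- if (estimator == "XGB") {
      list(eta = 0.1, max_depth = 3, nrounds = 150, colsample_bytree = 0.4,
           reg_lambda = 1)
    } else {
      list(eta = 0.1, max_leaves = 8, nrounds = 150, min_child_weight = 1,
           colsample_bytree = 0.4)
    }
    fam <- if (estimator == "XGB") "xgb" else "lgb"
    fit <- fit_model(fam, X, y, params = params, seed = seed)
    it <- xgboost::xgb.importance(model = fit$fit$booster)
    if (nrow(it) > 0) imp[it$Feature] <- it$Gain
  } else {
    stop("unknown SFM estimator: ", estimator)
  }
  imp
}

#' Select-from-model (SFM) importance filter
#'
#' Fits an estimator on the training data and keeps the `k` features with
#' largest absolute importance: absolute standardized coefficients for
#' LDA/linear regression, gain importance for the tree ensembles. Ties are
#' broken lexicographically on the clone key.
#'
#' @param x a `cohort_matrix` restricted to the candidate clones and the
#'   training samples.
#' @param estimator "LDA", "XGB", "LGB" or "LINREG".
#' @param k number of features to retain.
#' @param seed estimator seed.
#' @return a `feature_set` whose `ranking` orders keys by importance.
#' @export
select_from_model <- function(x, estimator = c("LGB", "LDA", "XGB", "LINREG"),
                              k, seed = 1) {
  stopifnot(inherits(x, "cohort_matrix"))
  estimator <- match.arg(estimator)
  X <- design_matrix(x)
  y <- unname(x$labels)
  if (length(unique(y)) < 2) stop("degenerate labels: one class only")
  if (k > ncol(X)) stop("k exceeds candidate count")
  imp <- sfm_importance(X, y, estimator, seed)
  ord <- order(-imp, names(imp))
  feature_set(names(imp)[ord][seq_len(k)], route = "SFM", selector = estimator)
}

# stratified-CV fold AUCs of a family (default hyperparameters) on a
# feature subset
cv_auc_folds <- function(X, y, family, folds, seed) {
  ks <- sort(unique(folds))
  vapply(ks, function(f) {
    tr <- folds != f
    fit <- tryCatch(
      fit_model(family, X[tr, , drop = FALSE], y[tr], seed = substream(seed, f)),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    s <- predict_scores(fit, X[!tr, , drop = FALSE])
    if (length(unique(y[!tr])) < 2) return(NA_real_)
    auc_score(y[!tr], s)
  }, numeric(1))
}

cv_auc <- function(X, y, family, folds, seed) {
  mean(cv_auc_folds(X, y, family, folds, seed), na.rm = TRUE)
}

#' Backward sequential feature selection (backward SFS)
#'
#' Greedy backward elimination: repeatedly removes the feature whose removal
#' maximizes cross-validated AUC (stratified 5-fold by default) until `k`
#' features remain. Removal scores within one standard error of the best
#' (the one-SE convention familiar from regularization-path selection) are
#' treated as tied — cross-validated AUC differences below fold noise carry
#' no evidence — and the tied feature with the weakest single-feature
#' cross-validated AUC is removed first; remaining ties break on the
#' lexicographically last clone key. The procedure is deterministic given
#' the seed and prefers to keep individually informative clones. Set
#' `tie_tol = 0` for strict argmax elimination.
#'
#' @param x a `cohort_matrix` restricted to the current candidate clones and
#'   the training samples.
#' @param estimator model family name used as the elimination estimator
#'   (fitted at its default hyperparameters).
#' @param k target feature count.
#' @param n_folds cross-validation folds.
#' @param seed seed for fold assignment and estimator fits.
#' @param tie_tol tie tolerance on removal scores: "se" (default, one
#'   standard error of the best removal's fold AUCs) or a number (0 = strict
#'   argmax).
#' @return a `feature_set` with the `k` surviving keys (matrix row order).
#' @export
backward_sfs <- function(x, estimator = "gbm", k, n_folds = 5, seed = 1,
                         tie_tol = "se") {
  stopifnot(inherits(x, "cohort_matrix"), k >= 1)
  X <- design_matrix(x)
  y <- unname(x$labels)
  feats <- colnames(X)
  if (k > length(feats)) stop("k exceeds feature count")
  folds <- stratified_folds(y, n_folds, substream(seed, 11L))
  solo <- vapply(feats, function(f) {
    cv_auc(X[, f, drop = FALSE], y, estimator, folds,
           seed = substream(seed, 12L))
  }, numeric(1))
  while (length(feats) > k) {
    fold_scores <- lapply(seq_along(feats), function(i) {
      cv_auc_folds(X[, feats[-i], drop = FALSE], y, estimator, folds,
                   seed = substream(seed, 13L))
    })
    scores <- vapply(fold_scores, mean, numeric(1), na.rm = TRUE)
    if (!any(is.finite(scores))) stop("non-finite scores in backward SFS")
    best_i <- which.max(scores)
    tol <- if (identical(tie_tol, "se")) {
      fs <- fold_scores[[best_i]]
      stats::sd(fs, na.rm = TRUE) / sqrt(sum(is.finite(fs)))
    } else {
      tie_tol
    }
    if (!is.finite(tol)) tol <- 0
    cand <- which(scores >= scores[best_i] - max(tol, 1e-12))
    weakest <- min(solo[feats[cand]])
    cand <- cand[solo[feats[cand]] <= weakest + 1e-12]
    drop_i <- cand[which(feats[cand] == max(feats[cand]))[1]]  # lexicographically last key
    feats <- feats[-drop_i]
  }
  feature_set(feats, route = "SFS", selector = estimator)
}

#' Most prevalent CDR3s across public databases
#'
#' Per database, the `n_per_db` highest-prevalence CDR3s (prevalence
#' descending, lexicographic tiebreak — the order [public_db()] guarantees);
#' the union is deduplicated preserving first occurrence.
#'
#' @param dbs list of `public_db` objects.
#' @param n_per_db top-list length per database.
#' @return character vector of unique clone keys.
#' @export
top_db_clones <- function(dbs, n_per_db = 10) {
  stopifnot(length(dbs) >= 1, all(vapply(dbs, nrow, 0L) > 0))
  tops <- lapply(dbs, function(db) {
    utils::head(db$cdr3_aa, n_per_db)
  })
  unique(unlist(tops, use.names = FALSE))
}

#' Restrict a clone set to those observed in the cohort
#'
#' @param clones character vector of clone keys.
#' @param x a `cohort_matrix`.
#' @return the clones with nonzero frequency in at least one sample,
#'   order-preserved; warns when the intersection is empty.
#' @export
intersect_with_cohort <- function(clones, x) {
  stopifnot(inherits(x, "cohort_matrix"))
  present_keys <- rownames(x$values)[rowSums(x$values > 0) > 0]
  out <- clones[clones %in% present_keys]
  if (length(out) == 0) warning("no candidate clone occurs in the cohort")
  out
}
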