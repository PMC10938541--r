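# Classifier family registry.
#
# Eight families, each exposing the same minimal surface:
#   space   - named list of hyperparameter definitions for the optimizer
#   default - a mid-range hyperparameter configuration
#   fit(X, y, params, seed)   - X: samples x features numeric matrix,
#                               y: character labels ("OC" positive)
#   score(fit, X)             - numeric score, higher = more OC-like
#   threshold                 - score cut for class predictions
#
# Tree-boosting appears three times by design: a depth-wise gradient-boosting
# configuration ("gbm"), a feature-subsampling variant ("xgb") and a
# histogram/loss-guide (leaf-wise) grower ("lgb"), reflecting the common
# practice of searching over boosting library variants alongside classical
# learners.

POSITIVE_CLASS <- "OC"

param_num <- function(lo, hi, log = FALSE) {
  list(type = "num", range = c(lo, hi), log = log)
}
param_int <- function(lo, hi, log = FALSE) {
  list(type = "int", range = c(lo, hi), log = log)
}

# drop zero-variance columns; returns list(X, keep)
drop_constant <- function(X) {
  v <- apply(X, 2, stats::var)
  keep <- is.finite(v) & v > 0
  list(X = X[, keep, drop = FALSE], keep = keep)
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd,
       apply = function(Z) sweep(sweep(Z, 2, mu), 2, sd, "/"))
}

xgb_fit <- function(X, y, params, seed, extra = list()) {
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y == POSITIVE_CLASS))
  pars <- c(list(objective = "binary:logistic", nthread = 1,
                 seed = as.integer(seed %% .Machine$integer.max)),
            params[setdiff(names(params), "nrounds")], extra)
  booster <- xgboost::xgb.train(params = do.call(xgboost::xgb.params, pars),
                                data = dtrain, nrounds = params$nrounds,
                                verbose = 0)
  list(booster = booster, features = colnames(X))
}

xgb_score <- function(fit, X) {
  as.numeric(stats::predict(fit$booster,
                            xgboost::xgb.DMatrix(X[, fit$features, drop = FALSE])))
}

#' Registry of classifier families
#'
#' @return named list of family definitions (see source for the surface).
#' @export
model_families <- function() {
  fams <- list(
    lda = list(
      space = list(tol = param_num(1e-9, 1e-3, log = TRUE)),
      default = list(tol = 1e-6),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        std <- standardizer(X)   # unit scale so `tol` is scale-free
        dc <- drop_constant(std$apply(X))
        if (ncol(dc$X) == 0) {
          return(list(constant = mean(y == POSITIVE_CLASS)))
        }
        m <- suppressWarnings(MASS::lda(dc$X, grouping = factor(y),
                                        tol = params$tol))
        list(model = m, keep = colnames(dc$X), std = std)
      },
      score = function(fit, X) {
        if (!is.null(fit$constant)) return(rep(fit$constant, nrow(X)))
        Xs <- fit$std$apply(X)[, fit$keep, drop = FALSE]
        p <- stats::predict(fit$model, Xs)$posterior
        if (POSITIVE_CLASS %in% colnames(p)) p[, POSITIVE_CLASS] else 1 - p[, 1]
      }
    ),
    logreg = list(
      space = list(lambda = param_num(1e-4, 1, log = TRUE),
                   alpha = param_num(0, 1)),
      default = list(lambda = 0.01, alpha = 0.5),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        Xp <- if (ncol(X) < 2) cbind(X, .pad = 0) else X
        m <- glmnet::glmnet(Xp, factor(y), family = "binomial",
                            alpha = params$alpha, lambda = params$lambda,
                            standardize = TRUE)
        list(model = m, pad = ncol(X) < 2, features = colnames(X))
      },
      score = function(fit, X) {
        Xp <- X[, fit$features, drop = FALSE]
        if (fit$pad) Xp <- cbind(Xp, .pad = 0)
        p <- stats::predict(fit$model, Xp, type = "response")
        as.numeric(p[, 1])
      }
    ),
    gbm = list(
      space = list(eta = param_num(0.01, 0.5, log = TRUE),
                   max_depth = param_int(1, 6),
                   nrounds = param_int(20, 300),
                   subsample = param_num(0.5, 1),
                   colsample_bytree = param_num(0.3, 1)),
      default = list(eta = 0.1, max_depth = 3, nrounds = 100, subsample = 1,
                     colsample_bytree = 0.7),
      threshold = 0.5,
      fit = function(X, y, params, seed) xgb_fit(X, y, params, seed),
      score = xgb_score
    ),
    xgb = list(
      space = list(eta = param_num(0.01, 0.5, log = TRUE),
                   max_depth = param_int(1, 6),
                   nrounds = param_int(20, 300),
                   colsample_bytree = param_num(0.3, 1),
                   reg_lambda = param_num(1e-3, 10, log = TRUE)),
      default = list(eta = 0.1, max_depth = 3, nrounds = 100,
                     colsample_bytree = 1, reg_lambda = 1),
      threshold = 0.5,
      fit = function(X, y, params, seed) xgb_fit(X, y, params, seed),
      score = xgb_score
    ),
    lgb = list(
      space = list(eta = param_num(0.01, 0.5, log = TRUE),
                   max_leaves = param_int(2, 32),
                   nrounds = param_int(20, 300),
                   min_child_weight = param_num(0.5, 10, log = TRUE)),
      default = list(eta = 0.1, max_leaves = 8, nrounds = 100,
                     min_child_weight = 1),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        xgb_fit(X, y, params, seed,
                extra = list(tree_method = "hist", grow_policy = "lossguide",
                             max_depth = 0))
      },
      score = xgb_score
    ),
    rf = list(
      space = list(num.trees = param_int(100, 500),
                   mtry_frac = param_num(0.3, 1),
                   min.node.size = param_int(1, 10)),
      default = list(num.trees = 300, mtry_frac = 0.6, min.node.size = 2),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        df <- data.frame(X, check.names = FALSE)
        df$.y <- factor(y)
        m <- ranger::ranger(
          dependent.variable.name = ".y", data = df, probability = TRUE,
          num.trees = params$num.trees,
          mtry = max(1L, round(params$mtry_frac * ncol(X))),
          min.node.size = params$min.node.size,
          seed = as.integer(seed %% .Machine$integer.max),
          num.threads = 1)
        list(model = m, features = colnames(X))
      },
      score = function(fit, X) {
        p <- stats::predict(fit$model,
                            data.frame(X[, fit$features, drop = FALSE],
                                       check.names = FALSE))$predictions
        if (POSITIVE_CLASS %in% colnames(p)) p[, POSITIVE_CLASS] else 1 - p[, 1]
      }
    ),
    knn = list(
      space = list(k = param_int(1, 15)),
      default = list(k = 5),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        std <- standardizer(X)
        list(train = std$apply(X), y = factor(y), k = params$k, std = std,
             features = colnames(X))
      },
      score = function(fit, X) {
        k <- min(fit$k, nrow(fit$train))
        pred <- class::knn(fit$train,
                           fit$std$apply(X[, fit$features, drop = FALSE]),
                           cl = fit$y, k = k, prob = TRUE)
        pr <- attr(pred, "prob")
        ifelse(pred == POSITIVE_CLASS, pr, 1 - pr)
      }
    ),
    svm_linear = list(
      space = list(cost = param_num(1e-2, 1e2, log = TRUE)),
      default = list(cost = 1),
      threshold = 0,
      fit = function(X, y, params, seed) {
        std <- standardizer(X)
        m <- e1071::svm(std$apply(X), factor(y), kernel = "linear",
                        cost = params$cost, scale = FALSE)
        list(model = m, std = std, features = colnames(X))
      },
      score = function(fit, X) {
        p <- stats::predict(fit$model,
                            fit$std$apply(X[, fit$features, drop = FALSE]),
                            decision.values = TRUE)
        dv <- attr(p, "decision.values")
        sgn <- if (grepl(paste0("^", POSITIVE_CLASS, "/"), colnames(dv)[1])) 1 else -1
        sgn * as.numeric(dv[, 1])
      }
    )
  )
  fams
}

#' Fit one family with given hyperparameters
#'
#' @param family family name (see [model_families()]).
#' @param X samples x features numeric matrix.
#' @param y character labels ("OC"/"HD").
#' @param params hyperparameter list; defaults to the family default.
#' @param seed RNG seed for stochastic learners.
#' @return object of class `tcr_fit`.
#' @export
fit_model <- function(family, X, y, params = NULL, seed = 1) {
  fams <- model_families()
  if (!family %in% names(fams)) {
    stop("unknown model family: ", family, " (known: ",
         paste(names(fams), collapse = ", "), ")")
  }
  fam <- fams[[family]]
  if (is.null(params)) params <- fam$default
  if (length(unique(y)) < 2) stop("degenerate labels: one class only")
  fit <- with_seed(seed, fam$fit(X, y, params, seed))
  structure(list(family = family, params = params, fit = fit,
                 threshold = fam$threshold),
            class = "tcr_fit")
}

#' Score samples with a fitted model
#'
#' @param object a `tcr_fit`.
#' @param X samples x features matrix.
#' @return numeric score per sample; higher means more case-like.
#' @export
predict_scores <- function(object, X) {
  stopifnot(inherits(object, "tcr_fit"))
  model_families()[[object$family]]$score(object$fit, X)
}

#' Predicted class labels
#' @inheritParams predict_scores
#' @export
predict_classes <- function(object, X) {
  s <- predict_scores(object, X)
  ifelse(s > object$threshold, POSITIVE_CLASS, "HD")
}
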