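# Gaussian-process Bayesian optimization for hyperparameter search.
#
# A small, dependency-free optimizer: hyperparameters are encoded into the
# unit hypercube, a Gaussian-process surrogate with an RBF kernel is fitted
# to the observed objective values, and the next configuration maximizes
# expected improvement over a random candidate pool. Integer and
# log-scaled parameters are handled in the encoding. The default budget is
# 10 random starting points followed by model-guided proposals up to 40
# total evaluations.

encode_params <- function(params, space) {
  vapply(names(space), function(nm) {
    s <- space[[nm]]
    v <- params[[nm]]
    r <- if (s$log) log(s$range) else s$range
    if (diff(r) == 0) return(0.5)
    x <- if (s$log) log(v) else v
    (x - r[1]) / (r[2] - r[1])
  }, numeric(1))
}

decode_point <- function(u, space) {
  out <- list()
  for (i in seq_along(space)) {
    s <- space[[i]]
    r <- if (s$log) log(s$range) else s$range
    x <- r[1] + u[i] * (r[2] - r[1])
    if (s$log) x <- exp(x)
    if (s$type == "int") x <- as.integer(round(x))
    out[[names(space)[i]]] <- x
  }
  out
}

# GP posterior mean/sd at candidate points; X is n x d in [0,1]
gp_posterior <- function(X, y, Xc, lengthscale = 0.3, noise = 0.01) {
  mu_y <- mean(y); sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  sq <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  }
  K <- exp(-pmax(sq(X, X), 0) / (2 * lengthscale^2))
  diag(K) <- diag(K) + noise
  Kc <- exp(-pmax(sq(Xc, X), 0) / (2 * lengthscale^2))
  alpha <- solve(K, ys)
  mu <- as.numeric(Kc %*% alpha) * sd_y + mu_y
  v <- 1 - rowSums((Kc %*% solve(K)) * Kc)
  sd <- sqrt(pmax(v, 1e-12)) * sd_y
  list(mu = mu, sd = sd)
}

#' Bayesian optimization over a hyperparameter space
#'
#' Maximizes `objective` over `space` with `bo_init` random starting points
#' followed by expected-improvement proposals, `bo_iters` evaluations total.
#' Failed evaluations (errors or non-finite values) are recorded and treated
#' as very poor outcomes rather than aborting the search; if every
#' evaluation fails, an error carrying the per-trial log is thrown.
#'
#' @param objective function(params, trial) -> numeric value to maximize.
#' @param space named list of parameter definitions (`param_num`/`param_int`
#'   internals: type, range, log).
#' @param bo_init random initial evaluations (<= `bo_iters`).
#' @param bo_iters total evaluation budget.
#' @param seed RNG seed.
#' @param n_candidates size of the random candidate pool per proposal.
#' @return list: `best_params`, `best_value`, `history` (data.frame with one
#'   row per trial: encoded point columns, `value`).
#' @export
bayes_optimize <- function(objective, space, bo_init = 10, bo_iters = 40,
                           seed = 1, n_candidates = 256) {
  stopifnot(bo_init >= 1, bo_init <= bo_iters)
  d <- length(space)
  if (d == 0) {
    val <- objective(list(), 1L)
    return(list(best_params = list(), best_value = val,
                history = data.frame(trial = 1L, value = val)))
  }
  with_seed(substream(seed, 7L), {
    U <- matrix(NA_real_, bo_iters, d)
    vals <- rep(NA_real_, bo_iters)
    errs <- character(bo_iters)
    U[seq_len(bo_init), ] <- matrix(stats::runif(bo_init * d), bo_init, d)
    for (t in seq_len(bo_iters)) {
      if (t > bo_init) {
        ok <- is.finite(vals[seq_len(t - 1)])
        if (sum(ok) >= 2) {
          Xc <- matrix(stats::runif(n_candidates * d), n_candidates, d)
          seen <- vals[seq_len(t - 1)]
          post <- gp_posterior(U[seq_len(t - 1), , drop = FALSE][ok, , drop = FALSE],
                               seen[ok], Xc)
          best <- max(seen[ok])
          z <- (post$mu - best) / post$sd
          ei <- (post$mu - best) * stats::pnorm(z) + post$sd * stats::dnorm(z)
          U[t, ] <- Xc[which.max(ei), ]
        } else {
          U[t, ] <- stats::runif(d)
        }
      }
      params <- decode_point(U[t, ], space)
      res <- tryCatch(objective(params, t), error = function(e) e)
      if (inherits(res, "error")) {
        errs[t] <- conditionMessage(res)
      } else if (is.finite(res)) {
        vals[t] <- res
      } else {
        errs[t] <- "non-finite objective"
      }
    }
    if (!any(is.finite(vals))) {
      stop("all optimization trials failed:\n",
           paste(sprintf("  trial %d: %s", seq_len(bo_iters), errs),
                 collapse = "\n"))
    }
    best_t <- which.max(vals)
    hist <- data.frame(trial = seq_len(bo_iters), value = vals)
    list(best_params = decode_point(U[best_t, ], space),
         best_value = vals[best_t], history = hist)
  })
}
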