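# Sequential model-based (Bayesian) hyperparameter optimization: a Gaussian
#-process surrogate with an RBF kernel on the unit hypercube and expected
# improvement as the acquisition function, maximized over random candidate
# points. Small and dependency-free; adequate for the 1-4 dimensional
# spaces used here.

#' Sequential model-based optimization over a box
#'
#' Maximizes `objective` over a bounded (optionally log-scaled / integer)
#' box with a budget of function evaluations: an initial space-filling
#' random design followed by expected-improvement proposals from a Gaussian
#' -process surrogate. Deterministic given `seed`.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a scalar to maximize.
#' @param bounds named list; each element `c(lower, upper)`, optionally with
#'   attributes via [param_bounds()].
#' @param budget total number of objective evaluations (>= 1).
#' @param seed integer seed.
#' @return list with `par` (named list, best parameters), `value` and
#'   `history` (data.frame of all evaluations).
#' @export
smbo_optimize <- function(objective, bounds, budget = 25L, seed = 1L) {
  if (length(bounds) == 0L) abort("empty search space")
  if (budget < 1) abort("budget must be >= 1")
  d <- length(bounds)
  info <- lapply(bounds, function(b) {
    list(lower = b[[1L]], upper = b[[2L]],
         log = isTRUE(attr(b, "log")), integer = isTRUE(attr(b, "integer")))
  })
  from_unit <- function(u) {
    stats::setNames(lapply(seq_len(d), function(j) {
      b <- info[[j]]
      v <- if (b$log) {
        exp(log(b$lower) + u[j] * (log(b$upper) - log(b$lower)))
      } else {
        b$lower + u[j] * (b$upper - b$lower)
      }
      if (b$integer) v <- as.integer(round(v))
      v
    }), names(bounds))
  }

  withr::with_seed(as.integer(seed), {
    n0 <- min(budget, max(4L, budget %/% 3L))
    U <- matrix(stats::runif(n0 * d), n0, d)
    vals <- apply(U, 1L, function(u) objective(from_unit(u)))
    while (nrow(U) < budget) {
      u_next <- propose_ei(U, vals, n_cand = 256L * d)
      vals <- c(vals, objective(from_unit(u_next)))
      U <- rbind(U, u_next)
    }
    best <- which.max(vals)
    history <- as.data.frame(U)
    names(history) <- names(bounds)
    history$value <- vals
    list(par = from_unit(U[best, ]), value = vals[best], history = history)
  })
}

# expected-improvement proposal from a GP with fixed RBF kernel
# (lengthscale 0.3 on the unit cube, small observation noise)
propose_ei <- function(U, vals, n_cand, lengthscale = 0.3) {
  mu <- mean(vals)
  sdv <- stats::sd(vals)
  if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
  y <- (vals - mu) / sdv
  K <- rbf_kernel(U, U, lengthscale) + diag(1e-4, nrow(U))
  cK <- tryCatch(chol(K), error = function(e) chol(K + diag(1e-2, nrow(U))))
  alpha <- backsolve(cK, forwardsolve(t(cK), y))
  cand <- matrix(stats::runif(n_cand * ncol(U)), n_cand, ncol(U))
  Ks <- rbf_kernel(cand, U, lengthscale)
  pred_mu <- as.numeric(Ks %*% alpha)
  v <- forwardsolve(t(cK), t(Ks))
  pred_var <- pmax(1e-12, 1 - colSums(v^2))
  pred_sd <- sqrt(pred_var)
  best <- max(y)
  z <- (pred_mu - best - 0.01) / pred_sd
  ei <- (pred_mu - best - 0.01) * stats::pnorm(z) + pred_sd * stats::dnorm(z)
  cand[which.max(ei), ]
}

rbf_kernel <- function(A, B, ls) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-0.5 * pmax(d2, 0) / ls^2)
}

#' Declare one search-space dimension
#'
#' @param lower,upper box bounds.
#' @param log sample on a log scale.
#' @param integer round to integer values.
#' @return length-2 numeric with attributes, for use in [smbo_optimize()].
#' @export
param_bounds <- function(lower, upper, log = FALSE, integer = FALSE) {
  structure(c(lower, upper), log = log, integer = integer)
}

default_search_space <- function(kind) {
  if (kind == "gbm") {
    list(
      learning_rate = param_bounds(0.01, 0.3, log = TRUE),
      n_trees = param_bounds(50, 500, integer = TRUE),
      num_leaves = param_bounds(7, 63, integer = TRUE),
      lambda = param_bounds(0, 10)
    )
  } else {
    list(lambda = param_bounds(1e-4, 100, log = TRUE))
  }
}

#' Tune base-learner hyperparameters by Bayesian optimization
#'
#' Runs [smbo_optimize()] over the learner's default search space (gbm:
#' learning rate 0.01-0.3 log-scale, 50-500 trees, 7-63 leaves, L2 0-10;
#' logistic: ridge penalty 1e-4 to 100 log-scale), scoring each
#' configuration by AUROC on a single 80/20 validation split carved from
#' `(X, y)`. Returns the best evaluated configuration as a new spec.
#'
#' @param spec template [base_learner_spec()] (its kind fixes the space).
#' @param X,y training data.
#' @param budget number of configurations to evaluate (default 25).
#' @param seed integer seed (controls the split and the optimizer).
#' @param space optional custom search space.
#' @return a `base_learner_spec` with tuned hyperparameters; the tuning
#'   history is attached as attribute `tuning`.
#' @export
tune_hyperparameters <- function(spec, X, y, budget = 25L, seed = 1L,
                                 space = NULL) {
  stopifnot(inherits(spec, "base_learner_spec"))
  X <- check_xy(X, y)
  if (is.null(space)) space <- default_search_space(spec$kind)
  n <- nrow(X)
  val <- withr::with_seed(derive_seed(seed, "tune-split"), {
    idx <- sample.int(n)
    # stratified-ish: ensure both classes land in train and validation
    v <- idx[seq_len(max(2L, floor(0.2 * n)))]
    tries <- 0L
    while ((length(unique(y[v])) < 2L || length(unique(y[-v])) < 2L) &&
           tries < 50L) {
      idx <- sample.int(n)
      v <- idx[seq_len(max(2L, floor(0.2 * n)))]
      tries <- tries + 1L
    }
    v
  })
  objective <- function(par) {
    cand <- spec
    cand$hyper <- modifyList(cand$hyper, par)
    fit <- fit_base(cand, X[-val, , drop = FALSE], y[-val])
    auroc(predict(fit, X[val, , drop = FALSE]), y[val])
  }
  res <- smbo_optimize(objective, space, budget = budget,
                       seed = derive_seed(seed, "smbo"))
  out <- spec
  out$hyper <- modifyList(out$hyper, res$par)
  validate_spec(out)
  attr(out, "tuning") <- res$history
  out
}
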