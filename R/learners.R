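# Base learners: a ridge-penalized logistic classifier (the linear
# benchmark) and gradient-boosted trees (via the package's compiled
# booster). Both expose probabilities in [0, 1] through predict().

GBM_BOUNDS <- list(
  learning_rate = c(0.01, 0.3),
  n_trees = c(50, 500),
  num_leaves = c(7, 63),
  lambda = c(0, 10)
)
LOGISTIC_BOUNDS <- list(lambda = c(1e-4, 100))

#' Specify a base learner
#'
#' @param kind `"logistic"` (ridge-penalized logistic regression) or
#'   `"gbm"` (gradient-boosted trees).
#' @param ... hyperparameters. For `gbm`: `n_trees` (default 50),
#'   `learning_rate` (0.1), `num_leaves` (15; converted internally to a
#'   depth limit of `ceiling(log2(num_leaves))`), `lambda` (L2 leaf
#'   regularization, 1), `min_child_weight` (1). For `logistic`: `lambda`
#'   (ridge penalty, 0.01).
#' @param seed integer seed recorded in the spec.
#' @return an object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(kind = c("logistic", "gbm"), ..., seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    logistic = list(lambda = 0.01),
    gbm = list(n_trees = 50L, learning_rate = 0.1, num_leaves = 15L,
               lambda = 1, min_child_weight = 1)
  )
  hyper <- modifyList(defaults, list(...))
  spec <- structure(list(kind = kind, hyper = hyper, seed = as.integer(seed)),
                    class = "base_learner_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  bounds <- if (spec$kind == "gbm") GBM_BOUNDS else LOGISTIC_BOUNDS
  h <- spec$hyper
  if (spec$kind == "gbm") {
    if (h$n_trees < 1 || h$n_trees > 5000) abort("n_trees out of bounds [1, 5000]")
    if (h$learning_rate <= 0 || h$learning_rate > 1) abort("learning_rate out of bounds (0, 1]")
    if (h$num_leaves < 2 || h$num_leaves > 4096) abort("num_leaves out of bounds [2, 4096]")
    if (h$lambda < 0 || h$min_child_weight < 0) abort("regularization must be non-negative")
  } else {
    if (h$lambda < 0) abort("lambda must be non-negative")
  }
  invisible(spec)
}

check_xy <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) abort("X must be finite with no missing values")
  uy <- unique(y)
  if (!all(uy %in% c(0, 1))) abort("y must be binary 0/1")
  if (length(uy) < 2L) abort("y has a single class; cannot fit a classifier")
  X
}

#' Fit a base learner
#'
#' @param spec a [base_learner_spec()].
#' @param X numeric feature matrix (finite, no missing values).
#' @param y binary 0/1 vector with both classes present.
#' @return a fitted `base_learner`; use `predict(fit, X)` for scores in
#'   `[0, 1]`.
#' @export
fit_base <- function(spec, X, y) {
  stopifnot(inherits(spec, "base_learner_spec"))
  X <- check_xy(X, y)
  fit <- if (spec$kind == "logistic") {
    Xg <- X
    if (ncol(Xg) < 2L) {  # glmnet requires >= 2 predictors
      Xg <- cbind(Xg, `.pad` = 0)
    }
    lam <- spec$hyper$lambda
    # fit a short decreasing path ending at the requested penalty; glmnet's
    # warm starts make a single-lambda fit less reliable
    path <- sort(unique(lam * c(16, 8, 4, 2, 1)), decreasing = TRUE)
    g <- glmnet::glmnet(Xg, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 0, lambda = path, standardize = TRUE)
    list(glmnet = g, s = lam, padded = ncol(Xg) != ncol(X))
  } else {
    h <- spec$hyper
    max_depth <- max(1L, ceiling(log2(h$num_leaves)))
    gbm_train_cpp(X, as.numeric(y), as.integer(h$n_trees), h$learning_rate,
                  as.integer(max_depth), h$lambda, h$min_child_weight)
  }
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 n_features = ncol(X)),
            class = "base_learner")
}

#' @export
predict.base_learner <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("feature width mismatch: model expects %d, got %d",
                  object$n_features, ncol(X)))
  }
  p <- if (object$kind == "logistic") {
    Xg <- if (object$fit$padded) cbind(X, `.pad` = 0) else X
    as.numeric(predict(object$fit$glmnet, Xg, s = object$fit$s,
                       type = "response"))
  } else {
    as.numeric(gbm_predict_cpp(object$fit, X))
  }
  pmin(1, pmax(0, p))
}

#' @export
print.base_learner <- function(x, ...) {
  cat(sprintf("<base_learner:%s> %d features\n", x$kind, x$n_features))
  invisible(x)
}
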