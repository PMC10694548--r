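# Repeated multi-label stratified cross-validation and test-set metrics.
#
# Splits: 30 repeats x 5 folds by default (150 test evaluations). Fold
# assignment uses iterative multi-label stratification: labels are
# processed rarest-first and each positive example goes to the fold whose
# remaining demand for that label is largest, so every fold's per-disorder
# prevalence tracks the overall prevalence. Metrics are computed per split
# and then averaged over splits (never pooled).

#' Build a repeated multi-label stratified split plan
#'
#' @param Y binary label matrix (participants x disorders).
#' @param n_repeats,n_folds cross-validation geometry (defaults 30 x 5, i.e.
#'   150 train/test splits).
#' @param seed integer seed; fold assignments are deterministic given it.
#' @return an object of class `split_plan`: a list of splits, each with
#'   `repeat_idx`, `fold`, `train`, `test` (row indices); the per-disorder
#'   worst-case relative deviation of fold prevalence is attached as
#'   attribute `stratification_report`.
#' @export
make_splits <- function(Y, n_repeats = 30L, n_folds = 5L, seed = 1L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < n_folds) abort("fewer rows than folds")
  cases <- colSums(Y)
  too_rare <- which(cases < n_folds)
  if (length(too_rare)) {
    nm <- if (!is.null(colnames(Y))) colnames(Y)[too_rare[1L]] else
      as.character(too_rare[1L])
    abort(sprintf("disorder '%s' has %d cases, fewer than the %d folds",
                  nm, cases[too_rare[1L]], n_folds))
  }
  splits <- list()
  for (r in seq_len(n_repeats)) {
    folds <- withr::with_seed(derive_seed(seed, "splits", r), {
      iterative_stratification(Y, n_folds)
    })
    for (f in seq_len(n_folds)) {
      splits[[length(splits) + 1L]] <- list(
        repeat_idx = r, fold = f,
        train = which(folds != f), test = which(folds == f)
      )
    }
  }
  prev <- colMeans(Y)
  report <- vapply(seq_len(ncol(Y)), function(j) {
    dev <- vapply(splits, function(s) {
      abs(mean(Y[s$test, j]) - prev[j]) / prev[j]
    }, 0.0)
    max(dev)
  }, 0.0)
  names(report) <- colnames(Y)
  structure(splits, class = "split_plan",
            n_repeats = n_repeats, n_folds = n_folds, n = n,
            stratification_report = report)
}

# iterative stratification (rarest label first); returns fold id per row
iterative_stratification <- function(Y, k) {
  n <- nrow(Y)
  L <- ncol(Y)
  fold <- rep(NA_integer_, n)
  # desired remaining capacity per fold, overall and per label
  want_total <- rep(n / k, k)
  want_label <- matrix(rep(colSums(Y) / k, each = k), nrow = k)
  label_left <- colSums(Y)
  repeat {
    unassigned <- is.na(fold)
    if (!any(unassigned)) break
    remaining <- colSums(Y[unassigned, , drop = FALSE])
    eligible <- which(remaining > 0)
    if (length(eligible) == 0L) {
      # label-free rows: place by overall remaining capacity
      for (i in which(unassigned)[sample.int(sum(unassigned))]) {
        f <- pick_fold(want_total)
        fold[i] <- f
        want_total[f] <- want_total[f] - 1
      }
      break
    }
    l <- eligible[which.min(remaining[eligible])]
    rows <- which(unassigned & Y[, l] == 1)
    for (i in rows[sample.int(length(rows))]) {
      f <- pick_fold(want_label[, l], want_total)
      fold[i] <- f
      pos <- which(Y[i, ] == 1)
      want_label[f, pos] <- want_label[f, pos] - 1
      want_total[f] <- want_total[f] - 1
    }
  }
  fold
}

# fold with largest primary demand; ties by secondary demand, then random
pick_fold <- function(primary, secondary = NULL) {
  cand <- which(primary == max(primary))
  if (length(cand) > 1L && !is.null(secondary)) {
    cand <- cand[secondary[cand] == max(secondary[cand])]
  }
  if (length(cand) > 1L) cand <- sample(cand, 1L)
  cand[1L]
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d splits (%d repeats x %d folds) over n=%d\n",
              length(x), attr(x, "n_repeats"), attr(x, "n_folds"),
              attr(x, "n")))
  invisible(x)
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney computation: the probability that a random case outscores a
#' random control, with ties contributing 1/2.
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 vector; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n2 <- sum(labels == 0)
  if (n1 == 0L || n2 == 0L) abort("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Youden-index operating point
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over every
#' achievable threshold (midpoints between adjacent distinct scores plus the
#' two infinite boundaries), breaking ties toward the lower threshold. A
#' positive call is `score >= threshold`.
#'
#' @inheritParams auroc
#' @return list with `threshold`, `J`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`. Warns when the best J is not positive (scores
#'   uninformative or anti-predictive).
#' @export
youden_threshold <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n2 <- sum(labels == 0)
  if (n1 == 0L || n2 == 0L) abort("both classes must be present")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2, Inf)
  # positives called at score >= t: cumulative counts over descending t
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0.0)
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / n2, 0.0)
  J <- sens + spec - 1
  best <- which.max(J)           # which.max takes the first (lowest) maximum
  if (J[best] <= 0) {
    warning("maximum Youden J is not positive; scores are uninformative or anti-predictive")
  }
  list(threshold = thr[best], J = J[best], sensitivity = sens[best],
       specificity = spec[best],
       balanced_accuracy = (sens[best] + spec[best]) / 2)
}

#' Specify an evaluation model
#'
#' @param kind `"lrc"` (independent ridge-logistic per disorder),
#'   `"gbm_cce"` (ensemble of classifier chains of gradient-boosted trees)
#'   or `"gbm_independent"` (independent per-disorder boosted trees).
#' @param base optional [base_learner_spec()] overriding the default base
#'   learner.
#' @param n_chains chains in the ensemble (gbm_cce only; default 10).
#' @param tune tune base-learner hyperparameters once per disorder on the
#'   first training fold encountered (`FALSE` by default at desk scale).
#' @param tune_budget evaluations for the tuner.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(kind = c("lrc", "gbm_cce", "gbm_independent"),
                       base = NULL, n_chains = 10L, tune = FALSE,
                       tune_budget = 25L) {
  kind <- match.arg(kind)
  if (is.null(base)) {
    base <- if (kind == "lrc") base_learner_spec("logistic") else
      base_learner_spec("gbm")
  }
  structure(list(kind = kind, base = base, n_chains = as.integer(n_chains),
                 tune = tune, tune_budget = as.integer(tune_budget)),
            class = "model_spec")
}

fit_model <- function(ms, X, Y, seed) {
  base <- ms$base
  if (isTRUE(ms$tune)) {
    y_t <- Y[, which.max(colSums(Y))]  # tune against the most prevalent target
    base <- tune_hyperparameters(base, X, y_t, budget = ms$tune_budget,
                                 seed = derive_seed(seed, "tune"))
  }
  switch(ms$kind,
    lrc = fit_independent(base, X, Y, seed = seed),
    gbm_independent = fit_independent(base, X, Y, seed = seed),
    gbm_cce = fit_cce(base, X, Y, n_chains = ms$n_chains, seed = seed)
  )
}

predict_scores <- function(fit, X) {
  if (inherits(fit, "cce_model")) predict_cce(fit, X) else
    predict_independent(fit, X)
}

#' Cross-validated evaluation of a model
#'
#' For every split of the plan: optionally residualize (fitting the
#' residualizer on the training rows only, or once globally), fit a freshly
#' initialized model on the training rows, score the held-out fold, and
#' compute AUROC plus the Youden-point metrics per disorder. No state
#' crosses splits. Aggregates are the mean and min-max range over splits.
#'
#' @param features numeric feature matrix.
#' @param Y binary label matrix.
#' @param ms a [model_spec()].
#' @param splits a [make_splits()] plan.
#' @param residualization `"none"`, `"per_split"` (fit on each training
#'   portion; leakage-free default when confounders are given) or
#'   `"global"` (fit once on all rows).
#' @param confounders confounder data.frame (required unless `"none"`).
#' @param seed integer seed fanned out to per-split model fits.
#' @return an object of class `evaluation_result`: list with `per_split`
#'   (one row per split x disorder) and `summary` (per-disorder mean and
#'   range of every metric).
#' @export
evaluate_model <- function(features, Y, ms, splits,
                           residualization = c("none", "per_split", "global"),
                           confounders = NULL, seed = 1L) {
  residualization <- match.arg(residualization)
  X <- as.matrix(features)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), inherits(splits, "split_plan"),
            inherits(ms, "model_spec"))
  design <- NULL
  if (residualization != "none") {
    if (is.null(confounders)) abort("residualization requires confounders")
    design <- encode_confounders(confounders)
    if (residualization == "global") {
      r <- fit_residualizer(X, design)
      X <- apply_residualizer(r, X, design)
    }
  }
  disorders <- colnames(Y)
  if (is.null(disorders)) disorders <- sprintf("d%02d", seq_len(ncol(Y)))
  rows <- vector("list", length(splits))
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    Xtr <- X[sp$train, , drop = FALSE]
    Xte <- X[sp$test, , drop = FALSE]
    if (residualization == "per_split") {
      dtr <- design
      dtr$matrix <- design$matrix[sp$train, , drop = FALSE]
      dte <- design
      dte$matrix <- design$matrix[sp$test, , drop = FALSE]
      r <- fit_residualizer(Xtr, dtr)
      Xtr <- apply_residualizer(r, Xtr, dtr)
      Xte <- apply_residualizer(r, Xte, dte)
    }
    fit <- tryCatch(
      fit_model(ms, Xtr, Y[sp$train, , drop = FALSE],
                seed = derive_seed(seed, "split", si)),
      error = function(e) abort(sprintf("repeat %d fold %d: %s",
                                        sp$repeat_idx, sp$fold,
                                        conditionMessage(e)))
    )
    S <- predict_scores(fit, Xte)
    yte <- Y[sp$test, , drop = FALSE]
    rows[[si]] <- do.call(rbind, lapply(seq_along(disorders), function(j) {
      yj <- yte[, j]
      au <- auroc(S[, j], yj)
      yd <- suppressWarnings(youden_threshold(S[, j], yj))
      data.frame(repeat_idx = sp$repeat_idx, fold = sp$fold,
                 disorder = disorders[j], auroc = au,
                 threshold = yd$threshold, J = yd$J,
                 balanced_accuracy = yd$balanced_accuracy,
                 sensitivity = yd$sensitivity, specificity = yd$specificity,
                 n1 = sum(yj == 1), n2 = sum(yj == 0),
                 stringsAsFactors = FALSE)
    }))
  }
  per_split <- do.call(rbind, rows)
  structure(list(per_split = per_split,
                 summary = summarize_metrics(per_split),
                 model = ms$kind, residualization = residualization),
            class = "evaluation_result")
}

summarize_metrics <- function(per_split) {
  metrics <- c("auroc", "balanced_accuracy", "sensitivity", "specificity")
  out <- do.call(rbind, lapply(split(per_split, per_split$disorder), function(d) {
    row <- data.frame(disorder = d$disorder[1L], n_splits = nrow(d),
                      stringsAsFactors = FALSE)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      row[[paste0(m, "_min")]] <- min(d[[m]])
      row[[paste0(m, "_max")]] <- max(d[[m]])
    }
    row$mean_n1 <- mean(d$n1)
    row$mean_n2 <- mean(d$n2)
    row
  }))
  # keep canonical disorder order, not alphabetical
  out[match(unique(per_split$disorder), out$disorder), , drop = FALSE]
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> model=%s residualization=%s (%d split rows)\n",
              x$model, x$residualization, nrow(x$per_split)))
  print(x$summary[, c("disorder", "auroc_mean", "auroc_min", "auroc_max",
                      "balanced_accuracy_mean")], row.names = FALSE)
  invisible(x)
}
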