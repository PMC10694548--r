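make_label_matrix <- function(n, prevs, seed = 1) {
  withr::with_seed(seed, {
    Y <- vapply(prevs, function(p) rbinom(n, 1L, p), integer(n))
    colnames(Y) <- sprintf("d%02d", seq_along(prevs))
    Y
  })
}

test_that("default split plan has 150 splits partitioning each repeat", {
  Y <- make_label_matrix(200, c(0.3, 0.2))
  plan <- make_splits(Y, seed = 5)
  expect_s3_class(plan, "split_plan")
  expect_length(plan, 150L)
  for (r in c(1L, 17L, 30L)) {
    reps <- Filter(function(s) s$repeat_idx == r, plan)
    expect_length(reps, 5L)
    test_rows <- sort(unlist(lapply(reps, `[[`, "test")))
    expect_identical(test_rows, seq_len(200L))   # test folds partition rows
    for (s in reps) {
      expect_length(intersect(s$train, s$test), 0L)
      expect_identical(sort(c(s$train, s$test)), seq_len(200L))
    }
  }
})

test_that("splits are deterministic given the seed", {
  Y <- make_label_matrix(150, c(0.25, 0.1))
  p1 <- make_splits(Y, n_repeats = 2, seed = 9)
  p2 <- make_splits(Y, n_repeats = 2, seed = 9)
  expect_identical(p1[[3]], p2[[3]])
  p3 <- make_splits(Y, n_repeats = 2, seed = 10)
  expect_false(identical(p1[[1]]$test, p3[[1]]$test))
})

test_that("a disorder with fewer cases than folds is named in the error", {
  Y <- make_label_matrix(100, c(0.3, 0.3))
  Y[, 2] <- 0L
  Y[1:3, 2] <- 1L
  expect_error(make_splits(Y, n_folds = 5), "d02")
})

test_that("stratification keeps fold prevalence within 20% relative of overall", {
  Y <- make_label_matrix(5000, c(0.02, 0.1, 0.3), seed = 3)
  plan <- make_splits(Y, n_repeats = 2, n_folds = 5, seed = 4)
  prev <- colMeans(Y)
  for (s in plan) {
    fold_prev <- colMeans(Y[s$test, , drop = FALSE])
    expect_true(all(abs(fold_prev - prev) / prev <= 0.20))
  }
  expect_true(all(attr(plan, "stratification_report") <= 0.20))
})

test_that("rank-based AUROC matches brute-force pair counting", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  for (rep in 1:20) {
    withr::with_seed(100 + rep, {
      y <- rbinom(30, 1, 0.4)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- round(rnorm(30), 1)  # rounding forces ties
    })
    expect_equal(auroc(s, y), brute(s, y), tolerance = 1e-12)
  }
  expect_error(auroc(rnorm(5), rep(1, 5)), "both classes")
})

test_that("Youden threshold matches an exhaustive scan and its identities hold", {
  perfect <- youden_threshold(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$J, 1)
  expect_equal(perfect$balanced_accuracy, 1)

  exhaustive <- function(s, y) {
    thr <- c(-Inf, sort(unique(s)) + 1e-9, Inf)
    thr <- sort(unique(c(thr, sort(unique(s)) - 1e-9)))
    J <- vapply(thr, function(t) {
      mean(s[y == 1] >= t) + mean(s[y == 0] < t) - 1
    }, 0.0)
    max(J)
  }
  for (rep in 1:20) {
    withr::with_seed(200 + rep, {
      y <- rbinom(6, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- round(runif(6), 1)
    })
    got <- suppressWarnings(youden_threshold(s, y))
    expect_equal(got$J, exhaustive(s, y), tolerance = 1e-12)
    expect_equal(got$J, got$sensitivity + got$specificity - 1,
                 tolerance = 1e-12)
    expect_equal(got$balanced_accuracy,
                 (got$sensitivity + got$specificity) / 2, tolerance = 1e-12)
    # tie-break toward the lower threshold: no lower threshold does as well
    lower <- s[s < got$threshold]
    if (length(lower)) {
      for (t in unique(lower)) {
        Jt <- mean(s[y == 1] >= t) + mean(s[y == 0] < t) - 1
        expect_lt(Jt, got$J)
      }
    }
  }
})

test_that("anti-predictive scores land at the degenerate boundary with a warning", {
  s <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(res <- youden_threshold(s, y), "anti-predictive")
  expect_true(is.infinite(res$threshold))
  expect_equal(res$J, 0)
})

test_that("evaluate_model bookkeeping, constant-score behavior and summary recomputation", {
  Y <- make_label_matrix(300, c(0.3, 0.15), seed = 6)
  X <- withr::with_seed(7, matrix(rnorm(300 * 6), 300, 6))
  plan <- make_splits(Y, n_repeats = 2, n_folds = 5, seed = 8)
  # an unsplittable boosted stump emits one constant score -> pure ties,
  # hence AUROC exactly 0.5 on every split
  ms <- model_spec("gbm_independent",
                   base = base_learner_spec("gbm", n_trees = 1,
                                            min_child_weight = 1e9))
  ev <- evaluate_model(X, Y, ms, plan, seed = 9)
  expect_identical(nrow(ev$per_split), length(plan) * ncol(Y))
  expect_equal(mean(ev$per_split$auroc), 0.5, tolerance = 1e-12)
  # summary is exactly reproducible from the per-split table
  agg <- tapply(ev$per_split$auroc, ev$per_split$disorder, mean)
  expect_equal(as.numeric(agg[ev$summary$disorder]), ev$summary$auroc_mean,
               tolerance = 1e-12)
  agg_max <- tapply(ev$per_split$auroc, ev$per_split$disorder, max)
  expect_equal(as.numeric(agg_max[ev$summary$disorder]), ev$summary$auroc_max,
               tolerance = 1e-12)
  expect_true(all(ev$per_split$auroc >= 0 & ev$per_split$auroc <= 1))
  expect_equal(ev$per_split$balanced_accuracy,
               (ev$per_split$sensitivity + ev$per_split$specificity) / 2,
               tolerance = 1e-12)
  expect_equal(ev$per_split$J,
               ev$per_split$sensitivity + ev$per_split$specificity - 1,
               tolerance = 1e-12)
})

test_that("results do not depend on test-row order within a split (no leakage)", {
  Y <- make_label_matrix(200, c(0.3), seed = 11)
  X <- withr::with_seed(12, matrix(rnorm(200 * 4), 200, 4))
  plan <- make_splits(Y, n_repeats = 1, n_folds = 5, seed = 13)
  ms <- model_spec("lrc")
  ev1 <- evaluate_model(X, Y, ms, plan, seed = 14)
  plan_shuffled <- plan
  for (i in seq_along(plan_shuffled)) {
    plan_shuffled[[i]]$test <- rev(plan_shuffled[[i]]$test)
  }
  ev2 <- evaluate_model(X, Y, ms, plan_shuffled, seed = 14)
  expect_equal(ev1$per_split$auroc, ev2$per_split$auroc, tolerance = 1e-12)
  expect_equal(ev1$per_split$threshold, ev2$per_split$threshold,
               tolerance = 1e-12)
})
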