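test_that("logistic learner separates a separable toy set", {
  set.seed(1)
  X <- matrix(c(rnorm(50, -2), rnorm(50, 2), rnorm(100)), 100, 2)
  y <- rep(c(0, 1), each = 50)
  f <- fit_base(base_learner_spec("logistic", lambda = 1e-4), X, y)
  s <- predict(f, X)
  expect_equal(auroc(s, y), 1.0)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("label-independent features give chance-level held-out AUROC", {
  set.seed(2)
  n <- 2000
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, 0.3)
  tr <- 1:1000
  for (kind in c("logistic", "gbm")) {
    f <- fit_base(base_learner_spec(kind), X[tr, ], y[tr])
    expect_lt(abs(auroc(predict(f, X[-tr, ]), y[-tr]) - 0.5), 0.05)
  }
})

test_that("GBM learns XOR where the logistic model cannot", {
  set.seed(3)
  n <- 1200
  X <- matrix(rnorm(n * 6), n, 6)
  y <- as.numeric(xor(X[, 1] > 0, X[, 2] > 0))
  tr <- 1:800
  gbm <- fit_base(base_learner_spec("gbm"), X[tr, ], y[tr])
  lrc <- fit_base(base_learner_spec("logistic"), X[tr, ], y[tr])
  expect_gt(auroc(predict(gbm, X[-tr, ]), y[-tr]), 0.95)
  expect_lt(abs(auroc(predict(lrc, X[-tr, ]), y[-tr]) - 0.5), 0.08)
})

test_that("single-class targets and invalid hyperparameters error", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_base(base_learner_spec("gbm"), X, rep(1, 20)),
               "single class")
  expect_error(fit_base(base_learner_spec("logistic"), X, rep(0, 20)),
               "single class")
  expect_error(base_learner_spec("gbm", learning_rate = 2), "learning_rate")
  expect_error(base_learner_spec("gbm", n_trees = 0), "n_trees")
  expect_error(base_learner_spec("logistic", lambda = -1), "lambda")
  X[1, 1] <- NA
  expect_error(fit_base(base_learner_spec("gbm"), X, rep(c(0, 1), 10)),
               "finite")
})

test_that("prediction is deterministic and row-order equivariant", {
  set.seed(4)
  X <- matrix(rnorm(300 * 8), 300, 8)
  y <- rbinom(300, 1, plogis(X[, 1]))
  for (kind in c("logistic", "gbm")) {
    f1 <- fit_base(base_learner_spec(kind), X, y)
    f2 <- fit_base(base_learner_spec(kind), X, y)
    s <- predict(f1, X)
    expect_identical(s, predict(f2, X))
    perm <- sample(nrow(X))
    expect_equal(predict(f1, X[perm, ]), s[perm], tolerance = 1e-12)
  }
})

test_that("a one-disorder chain is exactly the base learner", {
  set.seed(5)
  X <- matrix(rnorm(200 * 4), 200, 4)
  Y <- matrix(rbinom(200, 1, plogis(X[, 1])), ncol = 1,
              dimnames = list(NULL, "d01"))
  spec <- base_learner_spec("gbm", n_trees = 20)
  ch <- fit_chain(spec, X, Y, ordering = 1L, seed = 9)
  base <- fit_base(spec, X, Y[, 1])
  expect_equal(predict_chain(ch, X)[, 1], predict(base, X),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("chain members see the expected input widths", {
  set.seed(6)
  X <- matrix(rnorm(150 * 3), 150, 3)
  Y <- matrix(rbinom(450, 1, 0.4), 150, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  ch <- fit_chain(base_learner_spec("gbm", n_trees = 5), X, Y,
                  ordering = c(3, 1, 2), seed = 1)
  expect_identical(vapply(ch$members, `[[`, 0L, "n_features"), c(3L, 4L, 5L))
  # the member for disorder 1 is second in this ordering: width features + 1
  expect_identical(ch$members[[which(ch$ordering == 1)]]$n_features, 4L)
  expect_error(fit_chain(base_learner_spec("gbm"), X, Y, ordering = c(1, 1, 2)),
               "permutation")
  expect_error(predict_chain(ch, X[, 1:2]), "width mismatch")
})

test_that("sequential chain inference agrees with a brute-force oracle", {
  set.seed(7)
  X <- matrix(rnorm(120 * 4), 120, 4)
  Y <- matrix(0L, 120, 3, dimnames = list(NULL, c("a", "b", "c")))
  Y[, 1] <- rbinom(120, 1, plogis(2 * X[, 1]))
  Y[, 2] <- rbinom(120, 1, plogis(2 * X[, 2] + Y[, 1]))
  Y[, 3] <- rbinom(120, 1, plogis(Y[, 2] * 2 - 1))
  ordering <- c(2, 3, 1)
  ch <- fit_chain(base_learner_spec("gbm", n_trees = 10), X, Y, ordering,
                  seed = 3)
  Xnew <- X[1:5, , drop = FALSE]
  got <- predict_chain(ch, Xnew)
  # oracle: re-implement sequential inference member by member
  oracle <- matrix(NA_real_, 5, 3)
  inputs <- Xnew
  for (i in seq_along(ordering)) {
    s <- predict(ch$members[[i]], inputs)
    oracle[, ordering[i]] <- s
    inputs <- cbind(inputs, as.numeric(s >= 0.5))
  }
  expect_equal(got, oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("CCE structure: orderings cover all disorders; one chain equals the chain", {
  set.seed(8)
  X <- matrix(rnorm(200 * 3), 200, 3)
  Y <- matrix(rbinom(600, 1, 0.35), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  spec <- base_learner_spec("gbm", n_trees = 5)
  cce <- fit_cce(spec, X, Y, n_chains = 4, seed = 11)
  expect_length(cce$chains, 4L)
  for (ch in cce$chains) expect_setequal(ch$ordering, 1:3)
  one <- fit_cce(spec, X, Y, n_chains = 1, seed = 11)
  expect_equal(predict_cce(one, X), predict_chain(one$chains[[1]], X),
               tolerance = 1e-12)
  expect_error(fit_cce(spec, X, Y, n_chains = 0), "n_chains")
  # reference configuration: 10 chains of 10 members
  Y10 <- do.call(cbind, lapply(1:10, function(i) rbinom(200, 1, 0.4)))
  colnames(Y10) <- sprintf("d%02d", 1:10)
  cce10 <- fit_cce(base_learner_spec("gbm", n_trees = 2), X, Y10,
                   n_chains = 10, seed = 2)
  expect_length(cce10$chains, 10L)
  expect_true(all(vapply(cce10$chains, function(c) length(c$members), 0L) == 10L))
})

test_that("ensemble averaging reduces score variance across seeds", {
  set.seed(9)
  X <- matrix(rnorm(300 * 5), 300, 5)
  Y <- matrix(0L, 300, 2, dimnames = list(NULL, c("a", "b")))
  Y[, 1] <- rbinom(300, 1, plogis(X[, 1]))
  Y[, 2] <- rbinom(300, 1, plogis(X[, 2] + Y[, 1]))
  te <- 251:300
  tr <- 1:250
  spec <- base_learner_spec("gbm", n_trees = 10)
  single <- sapply(1:8, function(s) {
    ch <- fit_cce(spec, X[tr, ], Y[tr, ], n_chains = 1, seed = s)
    predict_cce(ch, X[te, ])[, 2]
  })
  ens <- sapply(1:8, function(s) {
    m <- fit_cce(spec, X[tr, ], Y[tr, ], n_chains = 6, seed = 100 + s)
    predict_cce(m, X[te, ])[, 2]
  })
  v_single <- mean(apply(single, 1, var))
  v_ens <- mean(apply(ens, 1, var))
  expect_lte(v_ens, v_single)
})
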