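test_that("identical (scenario, seed) yields identical cohorts", {
  s <- scenario_preset("paper_like", n_families = 120)
  c1 <- generate_cohort(s, seed = 7)
  c2 <- generate_cohort(s, seed = 7)
  expect_identical(c1, c2)
  c3 <- generate_cohort(s, seed = 8)
  expect_false(identical(c1$features, c3$features))
})

test_that("zero prevalence yields no true disorders and only informant false positives", {
  s <- scenario_preset("null", n_families = 400, sibling_rate = 0,
                       n_disorders = 2, n_features = 5,
                       prevalences = c(0, 0),
                       liability_corr = diag(2),
                       informant_sensitivity = c(parent = 0.8, self = 0.8),
                       informant_specificity = c(parent = 0.9, self = 0.9),
                       missing_feature_rate = 0, missing_diagnosis_rate = 0)
  co <- generate_cohort(s, seed = 3)
  expect_true(all(co$labels_truth == 0))
  pos <- with(co$reports, current == 1 | past == 1 | remission == 1)
  # false-positive reports appear at rate 1 - specificity = 0.1
  expect_lt(abs(mean(pos) - 0.1), 0.03)
  expect_gt(mean(pos), 0)
})

test_that("empirical prevalence matches configuration within a 99% binomial CI", {
  prevs <- c(0.05, 0.15, 0.3)
  s <- scenario_preset("null", n_families = 5000, sibling_rate = 0,
                       n_disorders = 3, n_features = 4, prevalences = prevs,
                       liability_corr = diag(3), missing_feature_rate = 0)
  co <- generate_cohort(s, seed = 11)
  n <- nrow(co$labels_truth)
  for (j in seq_along(prevs)) {
    ci <- qbinom(c(0.005, 0.995), n, prevs[j]) / n
    emp <- mean(co$labels_truth[, j])
    expect_gte(emp, ci[1])
    expect_lte(emp, ci[2])
  }
})

test_that("liability correlation controls label co-occurrence", {
  base <- list(n_families = 6000, sibling_rate = 0, n_disorders = 2,
               n_features = 4, prevalences = c(0.2, 0.2),
               missing_feature_rate = 0, family_liability_sd = 0)
  indep <- do.call(scenario_preset,
                   c("null", base, list(liability_corr = diag(2))))
  dep <- do.call(scenario_preset,
                 c("null", base,
                   list(liability_corr = matrix(c(1, .8, .8, 1), 2))))
  Yi <- generate_cohort(indep, seed = 5)$labels_truth
  Yd <- generate_cohort(dep, seed = 5)$labels_truth
  co_i <- mean(Yi[, 1] & Yi[, 2])
  co_d <- mean(Yd[, 1] & Yd[, 2])
  marg <- mean(Yi[, 1]) * mean(Yi[, 2])
  # independent: co-occurrence equals the product of marginals (4 MC sds)
  tol <- 4 * sqrt(marg * (1 - marg) / nrow(Yi))
  expect_lt(abs(co_i - marg), tol)
  # correlated: strictly in excess (rho = 0.8 roughly triples it)
  expect_gt(co_d, marg + tol)
})

test_that("parent-self agreement matches the closed form given sens/spec/prevalence", {
  sens <- 0.7
  spec <- 0.95
  p <- 0.25
  s <- scenario_preset("null", n_families = 8000, sibling_rate = 0,
                       n_disorders = 2, n_features = 2,
                       prevalences = c(p, p), liability_corr = diag(2),
                       informant_sensitivity = c(parent = sens, self = sens),
                       informant_specificity = c(parent = spec, self = spec),
                       missing_feature_rate = 0, missing_diagnosis_rate = 0)
  co <- generate_cohort(s, seed = 13)
  r <- co$reports[co$reports$code == "d01", ]
  pos <- r$current == 1 | r$past == 1 | r$remission == 1
  parent <- pos[r$informant == "parent"]
  self <- pos[r$informant == "self"]
  agree <- mean(parent == self)
  # informants are conditionally independent given the true label
  expected <- p * (sens^2 + (1 - sens)^2) +
    (1 - p) * (spec^2 + (1 - spec)^2)
  expect_lt(abs(agree - expected), 0.02)
})

test_that("feature missingness is all-or-none and at the configured rate", {
  s <- scenario_preset("null", n_families = 2000, sibling_rate = 0,
                       n_features = 6, missing_feature_rate = 0.2)
  co <- generate_cohort(s, seed = 2)
  miss_per_row <- rowSums(is.na(co$features))
  expect_true(all(miss_per_row %in% c(0L, ncol(co$features))))
  expect_lt(abs(mean(miss_per_row > 0) - 0.2), 0.03)
})

test_that("siblings share family-level confounders and family ids", {
  s <- scenario_preset("paper_like", n_families = 400, sibling_rate = 0.5)
  co <- generate_cohort(s, seed = 9)
  fam <- co$participants$family_id
  expect_gt(sum(duplicated(fam)), 0)
  dup <- fam[duplicated(fam)][1]
  idx <- which(fam == dup)
  expect_length(idx, 2L)
  for (col in c("site", "marriage", "educ", "ethnicity")) {
    expect_identical(co$confounders[[col]][idx[1]],
                     co$confounders[[col]][idx[2]])
  }
})

test_that("cohort CSV round trip preserves the analysis content", {
  dir <- withr::local_tempdir()
  s <- scenario_preset("paper_like", n_families = 60)
  co <- generate_cohort(s, seed = 21)
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("features.csv", "confounders.csv", "reports.csv",
                    "labels_truth.csv", "participants.csv"))
  back <- read_cohort(dir)
  expect_equal(back$features, co$features, tolerance = 1e-12)
  expect_identical(back$labels_truth, co$labels_truth)
  expect_identical(back$participants, co$participants)
  # reports: same label derivation before/after
  la <- comorbidcv:::derive_labels(co$reports, co$definitions,
                                   co$participants$participant_id)
  lb <- comorbidcv:::derive_labels(back$reports, back$definitions,
                                   back$participants$participant_id)
  expect_identical(la, lb)
})
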