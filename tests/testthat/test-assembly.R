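test_that("OR rule: any informant, any time state", {
  r <- reports_of(
    report_row("P1", "adhd", "parent", current = 1),
    report_row("P1", "adhd", "self")
  )
  expect_identical(or_rule_label(r, "adhd"), 1L)

  r0 <- reports_of(report_row("P1", "adhd", "parent"),
                   report_row("P1", "adhd", "self"))
  expect_identical(or_rule_label(r0, "adhd"), 0L)

  # a past-only self report counts: lifetime history, not current state
  rp <- reports_of(report_row("P1", "adhd", "parent"),
                   report_row("P1", "adhd", "self", past = 1))
  expect_identical(or_rule_label(rp, "adhd"), 1L)
  rr <- reports_of(report_row("P1", "adhd", "parent", remission = 1),
                   report_row("P1", "adhd", "self"))
  expect_identical(or_rule_label(rr, "adhd"), 1L)
})

test_that("OR rule: missingness semantics", {
  # one informant missing, other observed negative -> informative absence
  r <- reports_of(report_row("P1", "adhd", "parent", missing = TRUE),
                  report_row("P1", "adhd", "self"))
  expect_identical(or_rule_label(r, "adhd"), 0L)
  # all in-scope reports missing -> missing-label signal
  r2 <- reports_of(report_row("P1", "adhd", "parent", missing = TRUE),
                   report_row("P1", "adhd", "self", missing = TRUE))
  expect_identical(or_rule_label(r2, "adhd"), NA_integer_)
  # parent-only scope ignores a positive self report
  r3 <- reports_of(report_row("P1", "halluc", "parent"),
                   report_row("P1", "halluc", "self", current = 1))
  expect_identical(or_rule_label(r3, "halluc", scope = "parent_only"), 0L)
  expect_error(or_rule_label(r3, "nosuchcode"), "no reports")
})

test_that("composite labels OR their components", {
  defs <- default_disorder_definitions()
  child <- all_negative_reports("P1")
  # bipolar-I alone makes the bipolar composite positive
  bd1 <- child
  bd1[bd1$code == "bd1" & bd1$informant == "parent", "current"] <- 1
  expect_identical(composite_label(bd1, defs$bd), 1L)
  expect_identical(composite_label(child, defs$bd), 0L)
  # all psychotic components absent -> 0
  expect_identical(composite_label(child, defs$ps), 0L)
  # the unspecified schizophrenia-spectrum flag alone suffices
  uss <- child
  uss[uss$code == "uss" & uss$informant == "parent", "past"] <- 1
  expect_identical(composite_label(uss, defs$ps), 1L)
})

test_that("OR rule and composites are monotone in every report flag", {
  defs <- default_disorder_definitions()
  set.seed(42)
  for (rep in 1:25) {
    child <- all_negative_reports("P1")
    flags <- c("current", "past", "remission")
    k <- sample(nrow(child), sample(0:4, 1))
    for (i in k) child[i, sample(flags, 1)] <- 1
    labs <- vapply(defs, function(d) composite_label(child, d), integer(1))
    # set one extra flag: no label may flip 1 -> 0
    child2 <- child
    j <- sample(nrow(child2), 1)
    child2[j, sample(flags, 1)] <- 1
    labs2 <- vapply(defs, function(d) composite_label(child2, d), integer(1))
    expect_true(all(labs2 >= labs))
  }
})

test_that("selection flow: hand-counted ledger on a constructed fixture", {
  co <- toy_cohort(n = 10)
  # 3 with missing features
  co$features[c(2, 5, 9), ] <- NA_real_
  # 2 others with a missing diagnosis (all adhd reports missing)
  co <- set_missing_report(co, "P003", "adhd")
  co <- set_missing_report(co, "P007", "gad")
  sel <- apply_selection(co, seed = 1)
  led <- selection_ledger(sel)
  expect_identical(led$removed, c(3L, 2L, 0L))
  expect_identical(led$remaining, c(7L, 5L, 5L))
  expect_identical(nrow(sel$participants), 5L)
})

test_that("exactly one child per family is retained, chosen at random", {
  co <- toy_cohort(n = 6, families = c("F1", "F1", "F2", "F3", "F3", "F4"))
  sel <- apply_selection(co, seed = 3)
  expect_identical(nrow(sel$participants), 4L)
  expect_false(any(duplicated(sel$participants$family_id)))
  # the choice is genuinely random across seeds
  picks <- vapply(1:20, function(s) {
    apply_selection(co, seed = s)$participants$participant_id[1]
  }, "")
  expect_setequal(unique(picks), c("P001", "P002"))
})

test_that("selection is the identity on clean singleton cohorts and idempotent", {
  co <- toy_cohort(n = 5)
  sel <- apply_selection(co, seed = 2)
  expect_identical(sel$participants, co$participants)
  expect_identical(sel$features, co$features)
  expect_identical(selection_ledger(sel)$removed, c(0L, 0L, 0L))
  sel2 <- apply_selection(sel, seed = 99)
  expect_identical(sel2$participants, sel$participants)
  expect_identical(selection_ledger(sel2)$removed, c(0L, 0L, 0L))
})

test_that("selection errors name the emptying step", {
  co <- toy_cohort(n = 3)
  co$features[, ] <- NA_real_
  expect_error(apply_selection(co, seed = 1), "missing-features")
  co2 <- toy_cohort(n = 2)
  for (p in co2$participants$participant_id) {
    co2 <- set_missing_report(co2, p, "adhd")
  }
  expect_error(apply_selection(co2, seed = 1), "missing-diagnosis")
})

test_that("label matrix construction, prevalence and patterns", {
  co <- toy_cohort(n = 2)
  co <- set_positive(co, "P001", "adhd")
  sel <- apply_selection(co, seed = 1)
  Y <- build_label_matrix(sel)
  expect_identical(dim(Y), c(2L, 10L))
  expect_identical(colnames(Y),
                   c("mdd", "bd", "ps", "adhd", "odd", "cd", "ptsd", "ocd",
                     "gad", "sad"))
  expect_identical(sum(Y), 1L)
  expect_identical(Y["P001", "adhd"], 1L)

  # every child positive for ADHD and ODD -> a single pattern at frequency 1
  co2 <- toy_cohort(n = 4)
  for (p in co2$participants$participant_id) {
    co2 <- set_positive(co2, p, "adhd")
    co2 <- set_positive(co2, p, "odd", informant = "self", state = "past")
  }
  Y2 <- build_label_matrix(apply_selection(co2, seed = 1))
  pat <- attr(Y2, "patterns")
  expect_identical(nrow(pat), 1L)
  expect_identical(pat$frequency, 1)
  expect_identical(pat$pattern, "0001100000")
})

test_that("unknown component code is named in the error", {
  co <- toy_cohort(n = 2)
  defs <- default_disorder_definitions()
  defs$extra <- disorder_definition("extra", components = "wobble")
  expect_error(build_label_matrix(apply_selection(co, seed = 1), defs),
               "wobble")
})

test_that("no-disorder is the most frequent pattern in a paper-like cohort", {
  co <- generate_cohort(scenario_preset("paper_like", n_families = 1200),
                        seed = 31)
  sel <- apply_selection(co, seed = 32)
  Y <- build_label_matrix(sel)
  pat <- attr(Y, "patterns")
  expect_identical(pat$pattern[1], strrep("0", 10))
  expect_gt(pat$frequency[1], 0.4)
})
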