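# Shared fixture builders. Everything is generated in code; no data files.

# one report row
report_row <- function(pid, code, informant, current = 0, past = 0,
                       remission = 0, missing = FALSE) {
  data.frame(participant_id = pid, code = code, informant = informant,
             current = if (missing) NA else current,
             past = if (missing) NA else past,
             remission = if (missing) NA else remission,
             missing = missing, stringsAsFactors = FALSE)
}

reports_of <- function(...) do.call(rbind, list(...))

# complete negative report set for one child over the canonical codes
all_negative_reports <- function(pid, defs = default_disorder_definitions()) {
  rows <- list()
  for (def in defs) {
    informants <- if (def$scope == "parent_only") "parent" else c("parent", "self")
    for (code in def$components) {
      for (inf in informants) {
        rows[[length(rows) + 1L]] <- report_row(pid, code, inf)
      }
    }
  }
  do.call(rbind, rows)
}

# a hand-built cohort: n singleton children with complete data, canonical
# disorder codes, all labels negative unless modified by the caller
toy_cohort <- function(n = 6, n_features = 4, families = NULL) {
  pid <- sprintf("P%03d", seq_len(n))
  if (is.null(families)) families <- sprintf("F%03d", seq_len(n))
  X <- matrix(seq_len(n * n_features) / 10, n, n_features,
              dimnames = list(pid, sprintf("f%03d", seq_len(n_features))))
  defs <- default_disorder_definitions()
  reports <- do.call(rbind, lapply(pid, all_negative_reports))
  Y <- matrix(0L, n, length(defs), dimnames = list(pid, names(defs)))
  structure(
    list(
      participants = data.frame(participant_id = pid, family_id = families,
                                stringsAsFactors = FALSE),
      confounders = data.frame(
        participant_id = pid, age = seq(9, 10, length.out = n),
        sex = rep(c("F", "M"), length.out = n),
        marriage = rep(c("married", "unmarried"), length.out = n),
        site = rep(c("site01", "site02"), length.out = n),
        educ = rep(c("hs_ged", "bachelor"), length.out = n),
        ethnicity = rep(c("white", "black"), length.out = n),
        stv = seq(1e6, 1.2e6, length.out = n), stringsAsFactors = FALSE),
      features = X, reports = reports, labels_truth = Y,
      definitions = defs
    ),
    class = "cohort"
  )
}

# mark one child's reports positive for a component code
set_positive <- function(cohort, pid, code, informant = "parent",
                         state = "current") {
  i <- cohort$reports$participant_id == pid & cohort$reports$code == code &
    cohort$reports$informant == informant
  cohort$reports[i, state] <- 1
  cohort
}

# mark all reports of one child for a code (optionally one informant) missing
set_missing_report <- function(cohort, pid, code, informant = NULL) {
  i <- cohort$reports$participant_id == pid & cohort$reports$code == code
  if (!is.null(informant)) i <- i & cohort$reports$informant == informant
  cohort$reports[i, c("current", "past", "remission")] <- NA
  cohort$reports[i, "missing"] <- TRUE
  cohort
}

# small fast scenario used across model/evaluation tests
small_scenario <- function(n_families = 350, n_disorders = 3,
                           n_features = 12, prevalences = c(0.25, 0.2, 0.15),
                           ...) {
  scenario_preset("signal", n_families = n_families, sibling_rate = 0,
                  n_disorders = n_disorders, n_features = n_features,
                  prevalences = prevalences, missing_feature_rate = 0,
                  missing_diagnosis_rate = 0, ...)
}

# the dependent-disorder world used for the comorbidity-mechanism checks:
# disorder 1 ("A") has a strong concentrated feature signature and is nearly
# perfectly predictable; disorder 2 ("B") is a noisy copy of A (latent
# correlation 0.9) with only a weak signature of its own
dependent_label_scenario <- function(n_families = 850) {
  n_features <- 60
  D <- matrix(0, 2, n_features)
  D[1, 1:12] <- 2.0
  D[2, 55:60] <- 0.5
  scenario_preset("signal", n_families = n_families, sibling_rate = 0,
                  n_disorders = 2, n_features = n_features,
                  prevalences = c(0.3, 0.3),
                  liability_corr = matrix(c(1, 0.9, 0.9, 1), 2),
                  disorder_effects = D,
                  missing_feature_rate = 0, missing_diagnosis_rate = 0)
}
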