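# Participant selection and label derivation.
#
# Selection removes, in this fixed order: children with missing feature
# vectors, children with any underivable diagnosis, then all but one
# randomly chosen child per family. Labels follow the OR rule: a disorder is
# present when any in-scope informant reports any component code in any
# time state (current, past, in remission).

#' OR-rule label for one component code
#'
#' A component diagnosis is present when at least one in-scope informant
#' reports it in at least one time state. A missing report from one
#' informant alongside a valid report from the other counts as informative
#' absence for that informant; the label is missing (`NA`) only when every
#' in-scope report for the code is missing.
#'
#' @param reports data.frame of reports for one child (columns `code`,
#'   `informant`, `current`, `past`, `remission`, `missing`).
#' @param code component diagnosis code to evaluate.
#' @param scope `"both"` or `"parent_only"`.
#' @return `1L`, `0L`, or `NA` (missing-label signal).
#' @export
or_rule_label <- function(reports, code, scope = c("both", "parent_only")) {
  scope <- match.arg(scope)
  r <- reports[reports$code == code, , drop = FALSE]
  if (scope == "parent_only") r <- r[r$informant == "parent", , drop = FALSE]
  if (nrow(r) == 0L) abort(sprintf("no reports for code '%s'", code))
  observed <- !r$missing
  if (!any(observed)) return(NA_integer_)
  flags <- as.matrix(r[observed, c("current", "past", "remission")])
  as.integer(any(flags == 1))
}

#' Composite label over component codes
#'
#' The OR over [or_rule_label()] of every component code of a
#' [disorder_definition()]; monotone in every component. Positive components
#' dominate missing ones; the composite is `NA` only when no component is
#' positive and at least one component is entirely unobserved.
#'
#' @param reports data.frame of one child's reports.
#' @param definition a [disorder_definition()].
#' @return `1L`, `0L`, or `NA`.
#' @export
composite_label <- function(reports, definition) {
  stopifnot(inherits(definition, "disorder_definition"))
  labs <- vapply(definition$components, function(code) {
    or_rule_label(reports, code, scope = definition$scope)
  }, integer(1))
  if (any(labs == 1L, na.rm = TRUE)) return(1L)
  if (anyNA(labs)) return(NA_integer_)
  0L
}

# vectorized label derivation for all participants at once; returns an
# integer matrix (participants x targets) with NA where underivable
derive_labels <- function(reports, definitions, participant_ids) {
  n <- length(participant_ids)
  out <- matrix(NA_integer_, n, length(definitions),
                dimnames = list(participant_ids, names(definitions)))
  pid_idx <- match(reports$participant_id, participant_ids)
  positive <- !reports$missing &
    (reports$current == 1 | reports$past == 1 | reports$remission == 1)
  positive[is.na(positive)] <- FALSE
  for (d in seq_along(definitions)) {
    def <- definitions[[d]]
    in_scope <- reports$code %in% def$components
    if (!any(in_scope)) abort(sprintf("unknown component code '%s'",
                                      def$components[1L]))
    missing_codes <- setdiff(def$components, unique(reports$code))
    if (length(missing_codes)) {
      abort(sprintf("unknown component code '%s'", missing_codes[1L]))
    }
    if (def$scope == "parent_only") {
      in_scope <- in_scope & reports$informant == "parent"
    }
    idx <- which(in_scope)
    pos_by_pid <- rowsum(as.numeric(positive[idx]), group = pid_idx[idx],
                         reorder = FALSE)
    pids <- as.integer(rownames(pos_by_pid))
    # a component is fully missing when it has no observed report in scope
    fully_missing <- rep(FALSE, n)
    for (code in def$components) {
      ci <- which(reports$code == code &
                    (def$scope != "parent_only" | reports$informant == "parent"))
      obs <- rowsum(as.numeric(!reports$missing[ci]), group = pid_idx[ci],
                    reorder = FALSE)
      obs_pids <- as.integer(rownames(obs))
      fully_missing[obs_pids[obs[, 1L] == 0]] <- TRUE
      # participants with no report rows at all for this code
      fully_missing[setdiff(seq_len(n), obs_pids)] <- TRUE
    }
    lab <- integer(n)
    lab[pids] <- as.integer(pos_by_pid[, 1L] > 0)
    lab[lab == 0L & fully_missing] <- NA_integer_
    out[, d] <- lab
  }
  out
}

#' Apply the participant-selection flow
#'
#' Three ordered filters: (1) drop participants whose feature vector is
#' missing (features are all-or-none); (2) drop participants with any
#' missing diagnosis among the targets; (3) retain exactly one
#' uniformly-random child per family. The per-step removal counts are
#' attached as the `selection_ledger` attribute (see
#' [selection_ledger()]).
#'
#' @param cohort a `cohort`.
#' @param seed integer seed for the random sibling choice.
#' @param definitions disorder definitions (default: the cohort's).
#' @return the filtered `cohort` with a `selection_ledger` attribute.
#' @export
apply_selection <- function(cohort, seed, definitions = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort$participants) == 0L) abort("cohort is empty")
  if (is.null(definitions)) definitions <- cohort$definitions
  pid <- cohort$participants$participant_id

  keep1 <- !is.na(cohort$features[, 1L])
  n_feat_removed <- sum(!keep1)
  if (!any(keep1)) abort("no participants left after the missing-features step")

  labels <- derive_labels(cohort$reports, definitions, pid)
  keep2 <- keep1 & rowSums(is.na(labels)) == 0L
  n_diag_removed <- sum(keep1) - sum(keep2)
  if (!any(keep2)) abort("no participants left after the missing-diagnosis step")

  fam <- cohort$participants$family_id
  idx <- which(keep2)
  chosen <- withr::with_seed(as.integer(seed), {
    shuffled <- sample(idx)                 # uniform pick via random order
    shuffled[!duplicated(fam[shuffled])]
  })
  chosen <- sort(chosen)
  n_sib_removed <- length(idx) - length(chosen)

  out <- subset_cohort(cohort, chosen)
  attr(out, "selection_ledger") <- data.frame(
    step = c("missing_features", "missing_diagnosis", "sibling_exclusion"),
    removed = c(n_feat_removed, n_diag_removed, n_sib_removed),
    remaining = c(sum(keep1), sum(keep2), length(chosen))
  )
  out
}

#' Selection ledger of a filtered cohort
#'
#' @param cohort a `cohort` returned by [apply_selection()].
#' @return data.frame with columns `step`, `removed`, `remaining`.
#' @export
selection_ledger <- function(cohort) {
  led <- attr(cohort, "selection_ledger")
  if (is.null(led)) abort("cohort has no selection ledger; run apply_selection()")
  led
}

subset_cohort <- function(cohort, idx) {
  pid <- cohort$participants$participant_id[idx]
  structure(
    list(
      participants = cohort$participants[idx, , drop = FALSE],
      confounders = cohort$confounders[idx, , drop = FALSE],
      features = cohort$features[idx, , drop = FALSE],
      reports = cohort$reports[cohort$reports$participant_id %in% pid, ,
                               drop = FALSE],
      labels_truth = cohort$labels_truth[idx, , drop = FALSE],
      definitions = cohort$definitions
    ),
    class = "cohort"
  )
}

#' Build the binary label matrix
#'
#' One row per participant, one column per target in the documented disorder
#' order. Requires a cohort that already passed [apply_selection()] (no
#' missing labels). Per-disorder prevalence and the co-occurrence pattern
#' table are attached as attributes.
#'
#' @param cohort a selected `cohort`.
#' @param definitions disorder definitions (default: the cohort's).
#' @return integer matrix of class `label_matrix` with attributes
#'   `prevalence` (named vector) and `patterns` (data.frame of disorder
#'   patterns, counts and frequencies, most frequent first).
#' @export
build_label_matrix <- function(cohort, definitions = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(definitions)) definitions <- cohort$definitions
  Y <- derive_labels(cohort$reports, definitions,
                     cohort$participants$participant_id)
  if (anyNA(Y)) {
    abort("label matrix contains missing labels; run apply_selection() first")
  }
  class(Y) <- c("label_matrix", class(Y))
  attr(Y, "prevalence") <- colMeans(Y)
  attr(Y, "patterns") <- label_patterns(Y)
  Y
}

#' Co-occurrence pattern table of a label matrix
#'
#' @param Y binary label matrix.
#' @return data.frame with columns `pattern` (one character per disorder, in
#'   column order), `count` and `frequency`, sorted by frequency.
#' @export
label_patterns <- function(Y) {
  pat <- row_patterns(Y)
  tab <- sort(table(pat), decreasing = TRUE)
  data.frame(pattern = names(tab), count = as.integer(tab),
             frequency = as.numeric(tab) / nrow(Y), row.names = NULL)
}
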