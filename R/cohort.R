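# Cohort generation under the latent-liability model.
#
# Liability for disorder j of child i:
#   L_ij = (z_i' Gamma)_j + a_{f(i)} + eps_ij,   eps_i ~ MVN(0, R)
# with z_i the encoded confounder record, Gamma the confounder-to-liability
# loadings, a_f a family random effect shared by siblings and R the
# liability correlation matrix. The disorder is present when L_ij exceeds a
# threshold t_j solved numerically so that the population prevalence equals
# the configured target *after* the confounder shifts.
#
# Features: X = Z B + Y D + noise, all linear. Reports: each informant sees
# each component diagnosis through a fixed sensitivity/specificity channel.

# probability that a positive report carries each time-state flag
TIME_STATE_PROBS <- c(current = 0.6, past = 0.3, remission = 0.1)

#' Generate a synthetic cohort
#'
#' Draws families, sociodemographic confounders, correlated ground-truth
#' disorder labels via a thresholded Gaussian liability model, morphometric
#' features as a linear function of confounders and disorders plus noise,
#' and two-informant diagnostic reports with configurable
#' sensitivity/specificity and missingness. Deterministic given
#' `(scenario, seed)`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed integer seed.
#' @return an object of class `cohort`: a list with elements
#'   `participants` (data.frame: `participant_id`, `family_id`),
#'   `confounders` (data.frame with the seven confounder columns),
#'   `features` (numeric matrix, rows = participants; all-`NA` rows mark
#'   missing imaging), `reports` (long data.frame of per-code informant
#'   reports with time-state flags), `labels_truth` (binary matrix of
#'   ground-truth disorders, simulation audit only) and `definitions`.
#' @export
#' @examples
#' co <- generate_cohort(scenario_preset("null", n_families = 80), seed = 1)
#' nrow(co$features)
generate_cohort <- function(scenario, seed) {
  validate_scenario(scenario)
  stopifnot(is_count(seed) || (is.numeric(seed) && seed == floor(seed)))
  withr::with_seed(as.integer(seed), generate_cohort_impl(scenario))
}

generate_cohort_impl <- function(s) {
  n_fam <- s$n_families
  family_id <- sprintf("F%05d", seq_len(n_fam))
  n_children <- 1L + stats::rbinom(n_fam, 1L, s$sibling_rate)
  fam_of <- rep(seq_len(n_fam), n_children)
  n <- length(fam_of)
  pid <- sprintf("P%06d", seq_len(n))

  # family-level confounders are shared by siblings; age, sex and head size
  # are child-level
  sites <- site_labels(s$n_sites)
  fam_site <- sample(sites, n_fam, replace = TRUE)
  fam_marriage <- sample(c("married", "unmarried"), n_fam, replace = TRUE,
                         prob = c(0.697, 0.303))
  fam_educ <- sample(EDUC_LEVELS, n_fam, replace = TRUE,
                     prob = c(0.039, 0.082, 0.258, 0.263, 0.358))
  fam_ethnicity <- sample(ETHNICITY_LEVELS, n_fam, replace = TRUE,
                          prob = c(0.023, 0.110, 0.212, 0.554, 0.101))
  confounders <- data.frame(
    participant_id = pid,
    age = round(pmin(11, pmax(8.9, stats::rnorm(n, 9.9, 0.6))), 2),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.477, 0.523)),
    marriage = fam_marriage[fam_of],
    site = fam_site[fam_of],
    educ = fam_educ[fam_of],
    ethnicity = fam_ethnicity[fam_of],
    stv = round(stats::rnorm(n, 1.1e6, 1e5)),
    stringsAsFactors = FALSE
  )

  design <- encode_confounders(
    confounders[, -1L],
    levels = list(sex = c("F", "M"), marriage = c("married", "unmarried"),
                  site = sites, educ = EDUC_LEVELS,
                  ethnicity = ETHNICITY_LEVELS)
  )
  Z <- design$matrix[, -1L, drop = FALSE]   # drop intercept
  stopifnot(identical(colnames(Z), confounder_effect_rows(s$n_sites)))

  k <- s$n_disorders
  shift <- Z %*% s$confounder_label_effects
  a_fam <- stats::rnorm(n_fam, 0, s$family_liability_sd)
  eps <- matrix(stats::rnorm(n * k), n, k) %*% chol(s$liability_corr)
  liab <- shift + a_fam[fam_of] + eps

  thresholds <- vapply(seq_len(k), function(j) {
    solve_threshold(shift[, j], s$prevalences[[j]],
                    sd = sqrt(1 + s$family_liability_sd^2))
  }, 0.0)
  Y <- matrix(0L, n, k, dimnames = list(pid, s$disorder_names))
  for (j in seq_len(k)) Y[, j] <- as.integer(liab[, j] > thresholds[j])

  X <- Z %*% s$confounder_effects + Y %*% s$disorder_effects +
    s$noise_sd * matrix(stats::rnorm(n * s$n_features), n, s$n_features)
  dimnames(X) <- list(pid, sprintf("f%03d", seq_len(s$n_features)))
  if (s$missing_feature_rate > 0) {
    miss <- stats::runif(n) < s$missing_feature_rate
    X[miss, ] <- NA_real_
  }

  defs <- definitions_for(s$disorder_names)
  reports <- simulate_reports(Y, defs, s)

  structure(
    list(
      participants = data.frame(participant_id = pid,
                                family_id = family_id[fam_of],
                                stringsAsFactors = FALSE),
      confounders = confounders,
      features = X,
      reports = reports,
      labels_truth = Y,
      definitions = defs
    ),
    class = "cohort"
  )
}

# threshold t with P(N(shift_i, sd^2) > t) averaged over i equal to prev;
# prev = 0 degenerates to +Inf (disorder never present)
solve_threshold <- function(shift, prev, sd) {
  if (prev <= 0) return(Inf)
  f <- function(t) mean(stats::pnorm(t, mean = shift, sd = sd)) - (1 - prev)
  lo <- min(shift) - 8 * sd
  hi <- max(shift) + 8 * sd
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# draw the long report table for every (participant, component, informant)
simulate_reports <- function(Y, defs, s) {
  pid <- rownames(Y)
  n <- nrow(Y)
  blocks <- lapply(defs, function(def) {
    y <- Y[, def$target]
    # component-level truth: composites split their positives over a
    # non-empty random subset of components
    m <- length(def$components)
    comp_truth <- matrix(0L, n, m, dimnames = list(NULL, def$components))
    if (m == 1L) {
      comp_truth[, 1L] <- y
    } else {
      pos <- which(y == 1L)
      if (length(pos)) {
        draw <- matrix(stats::rbinom(length(pos) * m, 1L, 0.7), ncol = m)
        none <- rowSums(draw) == 0L
        if (any(none)) {
          draw[cbind(which(none),
                     sample.int(m, sum(none), replace = TRUE))] <- 1L
        }
        comp_truth[pos, ] <- draw
      }
    }
    informants <- if (def$scope == "parent_only") "parent" else c("parent", "self")
    grid <- expand.grid(comp = seq_len(m), informant = informants,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sub <- lapply(seq_len(nrow(grid)), function(g) {
      comp <- def$components[grid$comp[g]]
      inf <- grid$informant[g]
      truth <- comp_truth[, grid$comp[g]]
      sens <- s$informant_sensitivity[[inf]]
      spec <- s$informant_specificity[[inf]]
      p_pos <- ifelse(truth == 1L, sens, 1 - spec)
      positive <- stats::rbinom(n, 1L, p_pos)
      missing <- stats::runif(n) < s$missing_diagnosis_rate
      state <- sample(names(TIME_STATE_PROBS), n, replace = TRUE,
                      prob = TIME_STATE_PROBS)
      data.frame(
        participant_id = pid,
        code = comp,
        informant = inf,
        current = ifelse(missing, NA, as.integer(positive == 1L & state == "current")),
        past = ifelse(missing, NA, as.integer(positive == 1L & state == "past")),
        remission = ifelse(missing, NA, as.integer(positive == 1L & state == "remission")),
        missing = missing,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, sub)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$participants)
  cat(sprintf("<cohort> %d participants, %d families, %d features, %d disorders\n",
              n, length(unique(x$participants$family_id)),
              ncol(x$features), ncol(x$labels_truth)))
  cat(sprintf("  missing feature rows: %d | report rows: %d\n",
              sum(is.na(x$features[, 1L])), nrow(x$reports)))
  invisible(x)
}

#' Write a cohort to aligned CSV tables
#'
#' Writes `features.csv`, `confounders.csv`, `reports.csv` (long format) and
#' `labels_truth.csv` into a directory. All tables carry a header row and a
#' `participant_id` first column.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feat <- data.frame(participant_id = rownames(cohort$features),
                     cohort$features, check.names = FALSE)
  write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(cohort$confounders, file.path(dir, "confounders.csv"),
            row.names = FALSE)
  # long time-state format: one row per (participant, code, informant, state)
  rep_long <- do.call(rbind, lapply(c("current", "past", "remission"), function(st) {
    data.frame(participant_id = cohort$reports$participant_id,
               code = cohort$reports$code,
               informant = cohort$reports$informant,
               state = st,
               value = cohort$reports[[st]],
               stringsAsFactors = FALSE)
  }))
  write.csv(rep_long, file.path(dir, "reports.csv"), row.names = FALSE)
  lab <- data.frame(participant_id = rownames(cohort$labels_truth),
                    cohort$labels_truth, check.names = FALSE)
  write.csv(lab, file.path(dir, "labels_truth.csv"), row.names = FALSE)
  fam <- cohort$participants
  write.csv(fam, file.path(dir, "participants.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the CSV tables.
#' @param definitions disorder definitions; defaults to the canonical set
#'   when the truth labels carry the canonical names.
#' @return a `cohort`.
#' @export
read_cohort <- function(dir, definitions = NULL) {
  feat <- read.csv(file.path(dir, "features.csv"), check.names = FALSE)
  X <- as.matrix(feat[, -1L, drop = FALSE])
  rownames(X) <- feat$participant_id
  confounders <- read.csv(file.path(dir, "confounders.csv"),
                          stringsAsFactors = FALSE)
  rep_long <- read.csv(file.path(dir, "reports.csv"), stringsAsFactors = FALSE)
  key <- c("participant_id", "code", "informant")
  wide <- rep_long[rep_long$state == "current", key]
  for (st in c("current", "past", "remission")) {
    v <- rep_long[rep_long$state == st, ]
    stopifnot(identical(unname(as.matrix(v[, key])),
                        unname(as.matrix(wide[, key]))))
    wide[[st]] <- v$value
  }
  wide$missing <- is.na(wide$current)
  lab <- read.csv(file.path(dir, "labels_truth.csv"), check.names = FALSE)
  Y <- as.matrix(lab[, -1L, drop = FALSE])
  rownames(Y) <- lab$participant_id
  storage.mode(Y) <- "integer"
  parts <- read.csv(file.path(dir, "participants.csv"), stringsAsFactors = FALSE)
  if (is.null(definitions)) definitions <- definitions_for(colnames(Y))
  structure(
    list(participants = parts, confounders = confounders, features = X,
         reports = wide, labels_truth = Y, definitions = definitions),
    class = "cohort"
  )
}
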