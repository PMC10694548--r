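# Pipeline orchestration: simulate -> assemble -> (residualize) ->
# evaluate -> permutation test -> report, with every stage reading and
# writing CSVs in a run directory so each is independently invokable, and
# all randomness fanned out from one master seed.

#' Assemble a pipeline run configuration
#'
#' @param preset scenario preset name (see [scenario_preset()]).
#' @param scenario_overrides named list of overrides for the preset.
#' @param models subset of `c("lrc", "gbm_cce", "gbm_independent")`.
#' @param residualization `"none"`, `"per_split"` or `"global"`.
#' @param profile `"desk"` (default: 2 repeats x 5 folds, B = 99, ~1000
#'   children) or `"paper"` (30 x 5, B = 500 — cluster-scale cost at full
#'   n; a warning is printed).
#' @param n_repeats,n_folds,B optional explicit overrides of the profile.
#' @param alpha family-wise alpha.
#' @param m number of tests for Bonferroni correction; default
#'   `length(models) * n_disorders`, resolved at run time.
#' @param tune,tune_budget hyperparameter tuning switch and budget.
#' @param seed master seed.
#' @param outdir run directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(preset = "paper_like", scenario_overrides = list(),
                       models = c("lrc", "gbm_cce"),
                       residualization = c("per_split", "none", "global"),
                       profile = c("desk", "paper"),
                       n_repeats = NULL, n_folds = NULL, B = NULL,
                       alpha = 0.05, m = NULL, tune = FALSE,
                       tune_budget = 25L, seed = 1L, outdir = "run") {
  profile <- match.arg(profile)
  residualization <- match.arg(residualization)
  models <- match.arg(models, c("lrc", "gbm_cce", "gbm_independent"),
                      several.ok = TRUE)
  defaults <- if (profile == "paper") {
    list(n_repeats = 30L, n_folds = 5L, B = 500L)
  } else {
    list(n_repeats = 2L, n_folds = 5L, B = 99L)
  }
  if (profile == "desk" && is.null(scenario_overrides$n_families)) {
    scenario_overrides$n_families <- 1000L
  }
  structure(list(
    preset = preset, scenario_overrides = scenario_overrides,
    models = models, residualization = residualization, profile = profile,
    n_repeats = if (is.null(n_repeats)) defaults$n_repeats else as.integer(n_repeats),
    n_folds = if (is.null(n_folds)) defaults$n_folds else as.integer(n_folds),
    B = if (is.null(B)) defaults$B else as.integer(B),
    alpha = alpha, m = m, tune = tune, tune_budget = as.integer(tune_budget),
    seed = as.integer(seed), outdir = outdir
  ), class = "run_config")
}

config_scenario <- function(config) {
  do.call(scenario_preset, c(list(config$preset), config$scenario_overrides))
}

#' Planned evaluation count of a configuration
#'
#' One "job" is a single model fit+test on one cross-validation split; the
#' permutation test multiplies the grid by `B + 1` full pipeline runs.
#'
#' @param config a [run_config()].
#' @return data.frame with the arithmetic of the planned grid.
#' @export
plan_jobs <- function(config) {
  scen <- config_scenario(config)
  splits <- config$n_repeats * config$n_folds
  data.frame(
    models = length(config$models),
    disorders = scen$n_disorders,
    permutation_runs = config$B + 1L,
    splits_per_run = splits,
    total_split_evaluations = length(config$models) * (config$B + 1L) * splits,
    permutation_tests = length(config$models) * scen$n_disorders
  )
}

log_line <- function(dir, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message("[comorbidcv] ", msg)
  cat(msg, "\n", sep = "", file = file.path(dir, "run.log"), append = TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate, assemble, residualize (global mode only), evaluate,
#' permutation test and report in order, logging to `run.log`. Re-running
#' with the same configuration reproduces all CSVs byte-identically.
#'
#' @param config a [run_config()].
#' @param dry_run only report the planned job counts, execute nothing.
#' @return the run directory, invisibly (or the [plan_jobs()] table when
#'   `dry_run`).
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  plan <- plan_jobs(config)
  if (config$profile == "paper") {
    warning(sprintf(paste0("paper profile: %d split evaluations planned; ",
                           "this is cluster-scale at full n"),
                    plan$total_split_evaluations))
  }
  if (dry_run) return(plan)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(config$outdir, "run.log"))
  log_line(config$outdir, "plan: %d models x %d disorders, %d+1 runs x %d splits",
           plan$models, plan$disorders, config$B, plan$splits_per_run)
  stage_simulate(config)
  stage_assemble(config)
  stage_residualize(config)
  stage_evaluate(config)
  stage_permtest(config)
  stage_report(config)
  write_manifest(config)
  invisible(config$outdir)
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  scen <- config_scenario(config)
  co <- generate_cohort(scen, seed = derive_seed(config$seed, "cohort"))
  write_cohort(co, file.path(config$outdir, "cohort"))
  meta <- list(preset = config$preset, overrides = config$scenario_overrides,
               n_features = scen$n_features, n_disorders = scen$n_disorders,
               n_sites = scen$n_sites,
               prevalences = as.list(scen$prevalences))
  jsonlite::write_json(meta, file.path(config$outdir, "scenario.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line(config$outdir, "simulate: %d participants (%s preset)",
           nrow(co$participants), config$preset)
  invisible(co)
}

#' @rdname run_pipeline
#' @export
stage_assemble <- function(config) {
  dir <- config$outdir
  co <- read_cohort(file.path(dir, "cohort"))
  sel <- apply_selection(co, seed = derive_seed(config$seed, "selection"))
  write_cohort(sel, file.path(dir, "selected"))
  write.csv(selection_ledger(sel), file.path(dir, "selection_ledger.csv"),
            row.names = FALSE)
  Y <- build_label_matrix(sel)
  lab <- data.frame(participant_id = sel$participants$participant_id,
                    unclass(Y)[, , drop = FALSE], check.names = FALSE)
  write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  led <- selection_ledger(sel)
  log_line(dir, "assemble: removed %s; %d retained",
           paste(led$removed, collapse = "/"), nrow(sel$participants))
  invisible(sel)
}

#' @rdname run_pipeline
#' @export
stage_residualize <- function(config) {
  dir <- config$outdir
  log_line(dir, "residualization mode: %s", config$residualization)
  if (config$residualization != "global") return(invisible(NULL))
  sel <- read_cohort(file.path(dir, "selected"))
  design <- encode_confounders(sel$confounders[, -1L])
  r <- fit_residualizer(sel$features, design)
  Xr <- apply_residualizer(r, sel$features, design)
  out <- data.frame(participant_id = rownames(Xr), Xr, check.names = FALSE)
  write.csv(out, file.path(dir, "features_residualized.csv"),
            row.names = FALSE)
  invisible(Xr)
}

read_model_inputs <- function(config) {
  dir <- config$outdir
  sel <- read_cohort(file.path(dir, "selected"))
  lab <- read.csv(file.path(dir, "labels.csv"), check.names = FALSE)
  Y <- as.matrix(lab[, -1L, drop = FALSE])
  rownames(Y) <- lab$participant_id
  X <- sel$features
  resid <- config$residualization
  confounders <- sel$confounders[, -1L]
  if (resid == "global") {
    fr <- read.csv(file.path(dir, "features_residualized.csv"),
                   check.names = FALSE)
    X <- as.matrix(fr[, -1L, drop = FALSE])
    rownames(X) <- fr$participant_id
    resid <- "none"   # already residualized
  }
  list(X = X, Y = Y, confounders = confounders, resid = resid)
}

model_spec_for <- function(config, name) {
  model_spec(name, tune = config$tune, tune_budget = config$tune_budget)
}

#' @rdname run_pipeline
#' @export
stage_evaluate <- function(config) {
  dir <- config$outdir
  inp <- read_model_inputs(config)
  plan <- make_splits(inp$Y, n_repeats = config$n_repeats,
                      n_folds = config$n_folds,
                      seed = derive_seed(config$seed, "splits"))
  split_rows <- do.call(rbind, lapply(seq_along(plan), function(i) {
    sp <- plan[[i]]
    rbind(
      data.frame(split = i, repeat_idx = sp$repeat_idx, fold = sp$fold,
                 role = "train",
                 participant_id = rownames(inp$Y)[sp$train]),
      data.frame(split = i, repeat_idx = sp$repeat_idx, fold = sp$fold,
                 role = "test",
                 participant_id = rownames(inp$Y)[sp$test])
    )
  }))
  write.csv(split_rows, file.path(dir, "splits.csv"), row.names = FALSE)
  per_split <- list()
  summaries <- list()
  for (mname in config$models) {
    ev <- evaluate_model(inp$X, inp$Y, model_spec_for(config, mname), plan,
                         residualization = inp$resid,
                         confounders = inp$confounders,
                         seed = derive_seed(config$seed, "eval", mname))
    ps <- ev$per_split
    ps$model <- mname
    per_split[[mname]] <- ps
    sm <- ev$summary
    sm$model <- mname
    summaries[[mname]] <- sm
    log_line(dir, "evaluate[%s]: mean AUROC %.3f over %d splits", mname,
             mean(ps$auroc), length(plan))
  }
  write.csv(do.call(rbind, per_split), file.path(dir, "metrics_per_split.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, summaries), file.path(dir, "metrics_summary.csv"),
            row.names = FALSE)
  invisible(NULL)
}

#' @rdname run_pipeline
#' @export
stage_permtest <- function(config) {
  dir <- config$outdir
  inp <- read_model_inputs(config)
  m <- if (is.null(config$m)) length(config$models) * ncol(inp$Y) else config$m
  tabs <- list()
  nulls <- list()
  for (mname in config$models) {
    cfg <- permutation_config(B = config$B, alpha = config$alpha, m = m,
                              seed = derive_seed(config$seed, "permtest", mname))
    pr <- permutation_test(inp$X, inp$Y, model_spec_for(config, mname), cfg,
                           n_repeats = config$n_repeats,
                           n_folds = config$n_folds,
                           residualization = inp$resid,
                           confounders = inp$confounders)
    tab <- pr$table
    tab$model <- mname
    tabs[[mname]] <- tab
    nd <- as.data.frame(pr$null)
    long <- data.frame(
      model = mname,
      disorder = rep(colnames(pr$null), each = nrow(pr$null)),
      replicate = rep(seq_len(nrow(pr$null)), times = ncol(pr$null)),
      mean_auroc = as.vector(pr$null)
    )
    nulls[[mname]] <- long
    log_line(dir, "permtest[%s]: %d significant at alpha_adj=%.4g", mname,
             sum(tab$significant), tab$alpha_adjusted[1L])
  }
  write.csv(do.call(rbind, tabs), file.path(dir, "pvalues.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, nulls), file.path(dir, "null_distribution.csv"),
            row.names = FALSE)
  invisible(NULL)
}

#' @rdname run_pipeline
#' @export
stage_report <- function(config) {
  make_report(config$outdir)
}

write_manifest <- function(config) {
  cfg <- unclass(config)
  manifest <- list(
    package = "comorbidcv",
    version = as.character(utils::packageVersion("comorbidcv")),
    config = cfg,
    config_hash = derive_seed(1L, paste(deparse(cfg), collapse = "")),
    stage_seeds = list(
      cohort = derive_seed(config$seed, "cohort"),
      selection = derive_seed(config$seed, "selection"),
      splits = derive_seed(config$seed, "splits")
    )
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Summarize a completed run
#'
#' Emits a summary table in the layout of the headline results table (best
#' model per disorder; mean and min-max range of AUROC, balanced accuracy,
#' sensitivity, specificity; permutation p and significance flag) and a
#' CSV export contrasting observed mean AUROCs with their permutation null
#' distributions (the violin-plot raw material).
#'
#' @param dir a run directory produced by [run_pipeline()].
#' @return list with data.frames `summary` and `figure_export` (also
#'   written to `report_summary.csv` and `figure5_export.csv`).
#' @export
make_report <- function(dir) {
  needed <- c("metrics_per_split.csv", "metrics_summary.csv", "pvalues.csv",
              "null_distribution.csv")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing)) {
    abort(sprintf("incomplete run; missing stage outputs: %s",
                  paste(missing, collapse = ", ")))
  }
  per_split <- read.csv(file.path(dir, "metrics_per_split.csv"),
                        stringsAsFactors = FALSE)
  pvals <- read.csv(file.path(dir, "pvalues.csv"), stringsAsFactors = FALSE)
  agg <- function(d) {
    data.frame(
      auroc_mean = mean(d$auroc), auroc_min = min(d$auroc),
      auroc_max = max(d$auroc),
      balanced_accuracy_mean = mean(d$balanced_accuracy),
      balanced_accuracy_min = min(d$balanced_accuracy),
      balanced_accuracy_max = max(d$balanced_accuracy),
      sensitivity_mean = mean(d$sensitivity),
      sensitivity_min = min(d$sensitivity),
      sensitivity_max = max(d$sensitivity),
      specificity_mean = mean(d$specificity),
      specificity_min = min(d$specificity),
      specificity_max = max(d$specificity)
    )
  }
  grp <- split(per_split, list(per_split$model, per_split$disorder),
               drop = TRUE)
  long <- do.call(rbind, lapply(grp, function(d) {
    cbind(data.frame(model = d$model[1L], disorder = d$disorder[1L],
                     stringsAsFactors = FALSE), agg(d))
  }))
  rownames(long) <- NULL
  # best model per disorder by mean AUROC
  best <- do.call(rbind, lapply(split(long, long$disorder), function(d) {
    d[which.max(d$auroc_mean), , drop = FALSE]
  }))
  best <- merge(best, pvals[, c("model", "disorder", "p", "significant")],
                by = c("model", "disorder"), all.x = TRUE, sort = FALSE)
  best <- best[order(match(best$disorder, unique(per_split$disorder))), ]
  names(best)[names(best) == "model"] <- "best_model"
  rownames(best) <- NULL
  null_dist <- read.csv(file.path(dir, "null_distribution.csv"),
                        stringsAsFactors = FALSE)
  observed <- data.frame(model = long$model, disorder = long$disorder,
                         replicate = NA_integer_,
                         mean_auroc = long$auroc_mean, kind = "observed")
  null_dist$kind <- "null"
  figure_export <- rbind(observed,
                         null_dist[, c("model", "disorder", "replicate",
                                       "mean_auroc", "kind")])
  write.csv(best, file.path(dir, "report_summary.csv"), row.names = FALSE)
  write.csv(figure_export, file.path(dir, "figure5_export.csv"),
            row.names = FALSE)
  list(summary = best, figure_export = figure_export, by_model = long)
}
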