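# Permutation-based significance of cross-validated mean AUROC.
#
# The null hypothesis is that the model discovered no relationship between
# features and labels. Each replicate permutes the row order of the whole
# label matrix against the features (preserving column marginals and the
# co-occurrence pattern multiset, destroying every feature-label path —
# including the indirect ones a classifier chain could exploit), then
# reruns the full cross-validated evaluation with a fresh split plan.

#' Permutation-test configuration
#'
#' @param B permutation replicates (default 500).
#' @param alpha family-wise significance level (default 0.05).
#' @param m number of tests for Bonferroni correction (default 20: two
#'   models times ten disorders).
#' @param seed integer seed.
#' @param p_convention `"plus_one_over_B"` (default; p = (count+1)/B clamped
#'   to 1, reproducing the minimum attainable p of 1/B) or
#'   `"plus_one_both"` (p = (count+1)/(B+1)).
#' @return an object of class `permutation_config`.
#' @export
permutation_config <- function(B = 500L, alpha = 0.05, m = 20L, seed = 1L,
                               p_convention = c("plus_one_over_B",
                                                "plus_one_both")) {
  if (B < 1) abort("B must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (m < 1) abort("m must be >= 1")
  structure(list(B = as.integer(B), alpha = alpha, m = as.integer(m),
                 seed = as.integer(seed),
                 p_convention = match.arg(p_convention)),
            class = "permutation_config")
}

#' Permute the label matrix against the features
#'
#' Applies one uniform random permutation to the row order of the whole
#' label matrix. Column prevalences and the multiset of row patterns are
#' invariant; all feature-label association is destroyed.
#'
#' @param Y binary label matrix.
#' @param seed integer seed.
#' @return permuted label matrix.
#' @export
permute_labels <- function(Y, seed) {
  Y <- as.matrix(Y)
  if (nrow(Y) == 0L) abort("label matrix is empty")
  perm <- withr::with_seed(as.integer(seed), sample.int(nrow(Y)))
  out <- Y[perm, , drop = FALSE]
  rownames(out) <- rownames(Y)
  out
}

# p-value from exceedance count under the configured convention
permutation_pvalue <- function(count, B, convention = "plus_one_over_B") {
  p <- if (convention == "plus_one_both") (count + 1) / (B + 1) else
    (count + 1) / B
  pmin(1, p)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_adjust(0.05, 20)  # 0.0025
bonferroni_adjust <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)")
  }
  if (!is_count(m)) abort("m must be a positive integer")
  alpha / m
}

#' Permutation test of cross-validated mean AUROC
#'
#' Runs the full evaluation once on the original labels and once per each
#' of `B` independently row-permuted label matrices, each with a fresh
#' split plan; the per-disorder p-value is the exceedance probability of
#' the observed mean AUROC in its null distribution (ties count against
#' significance).
#'
#' @inheritParams evaluate_model
#' @param config a [permutation_config()].
#' @param n_repeats,n_folds split-plan geometry used for every run.
#' @return an object of class `permutation_result`: data.frame `table`
#'   (disorder, observed mean AUROC, exceedance count, p, adjusted alpha,
#'   significance flag) plus the `B x n_disorders` matrix `null` of
#'   permuted mean AUROCs and the observed `evaluation_result`.
#' @export
permutation_test <- function(features, Y, ms, config,
                             n_repeats = 1L, n_folds = 5L,
                             residualization = "none", confounders = NULL) {
  stopifnot(inherits(config, "permutation_config"))
  Y <- as.matrix(Y)
  run_once <- function(labels, tag) {
    plan <- make_splits(labels, n_repeats = n_repeats, n_folds = n_folds,
                        seed = derive_seed(config$seed, "plan", tag))
    ev <- evaluate_model(features, labels, ms, plan,
                         residualization = residualization,
                         confounders = confounders,
                         seed = derive_seed(config$seed, "model", tag))
    ev
  }
  observed_ev <- run_once(Y, "observed")
  observed <- observed_ev$summary$auroc_mean
  names(observed) <- observed_ev$summary$disorder

  null <- matrix(NA_real_, config$B, ncol(Y),
                 dimnames = list(NULL, names(observed)))
  for (b in seq_len(config$B)) {
    Yp <- permute_labels(Y, seed = derive_seed(config$seed, "perm", b))
    ev <- tryCatch(run_once(Yp, b),
                   error = function(e) abort(sprintf("permutation %d: %s", b,
                                                     conditionMessage(e))))
    null[b, ev$summary$disorder] <- ev$summary$auroc_mean
  }
  count <- colSums(null >= rep(observed, each = config$B))
  p <- permutation_pvalue(count, config$B, config$p_convention)
  alpha_adj <- bonferroni_adjust(config$alpha, config$m)
  structure(
    list(table = data.frame(disorder = names(observed),
                            observed = unname(observed),
                            count = unname(count), p = unname(p),
                            alpha_adjusted = alpha_adj,
                            significant = unname(p <= alpha_adj),
                            stringsAsFactors = FALSE),
         null = null, observed_evaluation = observed_ev, config = config),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> B=%d, alpha_adj=%.4g\n",
              x$config$B, x$table$alpha_adjusted[1L]))
  print(x$table, row.names = FALSE)
  invisible(x)
}
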