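# Classifier chains and their ensemble.
#
# A chain fixes a random ordering of the disorders and trains one base
# learner per disorder, feeding each member the features plus the labels of
# all disorders earlier in the ordering (true labels at training time;
# thresholded predictions at inference time, following the original chain
# formulation). The ensemble (CCE) averages the per-disorder scores of
# several chains with independently drawn orderings.

#' Fit a single classifier chain
#'
#' Member `i` is trained to predict disorder `ordering[i]` from the features
#' augmented with the *true* labels of `ordering[1..i-1]` (training-time
#' teacher forcing).
#'
#' @param spec a [base_learner_spec()] used for every member.
#' @param X feature matrix.
#' @param Y binary label matrix (columns = disorders in canonical order).
#' @param ordering permutation of `seq_len(ncol(Y))`.
#' @param seed integer seed (fanned out to members).
#' @return an object of class `chain_model`.
#' @export
fit_chain <- function(spec, X, Y, ordering = seq_len(ncol(Y)), seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  L <- ncol(Y)
  if (!setequal(ordering, seq_len(L)) || length(ordering) != L) {
    abort("ordering must be a permutation of the disorder indices")
  }
  members <- vector("list", L)
  for (i in seq_len(L)) {
    target <- ordering[i]
    prev <- ordering[seq_len(i - 1L)]
    Xi <- cbind(X, Y[, prev, drop = FALSE])
    mspec <- spec
    mspec$seed <- derive_seed(seed, "chain-member", i)
    members[[i]] <- tryCatch(
      fit_base(mspec, Xi, Y[, target]),
      error = function(e) abort(sprintf("chain member %d (disorder %d): %s",
                                        i, target, conditionMessage(e)))
    )
  }
  structure(list(ordering = as.integer(ordering), members = members,
                 n_features = ncol(X), n_disorders = L,
                 disorder_names = colnames(Y)),
            class = "chain_model")
}

#' Predict with a classifier chain
#'
#' Sequential inference: member `i` receives the hard labels (score >= 0.5)
#' predicted by the preceding members (or their probabilities when
#' `hard = FALSE`). Scores are returned re-indexed to the canonical disorder
#' order.
#'
#' @param chain a `chain_model`.
#' @param X feature matrix of width `n_features`.
#' @param hard pass thresholded predictions (default) or probabilities down
#'   the chain.
#' @return score matrix (`nrow(X)` x `n_disorders`), canonical column order.
#' @export
predict_chain <- function(chain, X, hard = TRUE) {
  stopifnot(inherits(chain, "chain_model"))
  X <- as.matrix(X)
  if (ncol(X) != chain$n_features) {
    abort(sprintf("feature width mismatch: chain expects %d, got %d",
                  chain$n_features, ncol(X)))
  }
  n <- nrow(X)
  L <- chain$n_disorders
  scores <- matrix(NA_real_, n, L)
  prev_inputs <- matrix(0, n, 0L)
  for (i in seq_len(L)) {
    s <- predict(chain$members[[i]], cbind(X, prev_inputs))
    scores[, chain$ordering[i]] <- s
    feed <- if (hard) as.numeric(s >= 0.5) else s
    prev_inputs <- cbind(prev_inputs, feed)
  }
  colnames(scores) <- chain$disorder_names
  scores
}

#' Fit an ensemble of classifier chains (CCE)
#'
#' Draws `n_chains` independent uniform orderings (seeded) and fits one
#' chain per ordering; prediction is the arithmetic mean of the chains'
#' score matrices.
#'
#' @inheritParams fit_chain
#' @param n_chains number of chains (default 10, matching the reference
#'   configuration of 10 chains of 10 members).
#' @return an object of class `cce_model`.
#' @export
fit_cce <- function(spec, X, Y, n_chains = 10L, seed = 1L) {
  if (n_chains < 1) abort("n_chains must be >= 1")
  L <- ncol(as.matrix(Y))
  orderings <- withr::with_seed(derive_seed(seed, "orderings"), {
    lapply(seq_len(n_chains), function(i) sample.int(L))
  })
  chains <- lapply(seq_len(n_chains), function(c) {
    fit_chain(spec, X, Y, orderings[[c]], seed = derive_seed(seed, "chain", c))
  })
  structure(list(chains = chains, n_chains = as.integer(n_chains),
                 n_features = ncol(as.matrix(X)), n_disorders = L,
                 disorder_names = colnames(Y)),
            class = "cce_model")
}

#' Predict with a chain ensemble
#'
#' @param model a `cce_model`.
#' @param X feature matrix.
#' @param hard passed to [predict_chain()].
#' @return mean score matrix over chains, canonical column order.
#' @export
predict_cce <- function(model, X, hard = TRUE) {
  stopifnot(inherits(model, "cce_model"))
  acc <- NULL
  for (ch in model$chains) {
    s <- predict_chain(ch, X, hard = hard)
    acc <- if (is.null(acc)) s else acc + s
  }
  acc / model$n_chains
}

#' Fit independent per-disorder learners
#'
#' The no-interdependency counterpart of the chain ensemble: one base
#' learner per disorder, features only.
#'
#' @inheritParams fit_chain
#' @return an object of class `independent_model`.
#' @export
fit_independent <- function(spec, X, Y, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  members <- lapply(seq_len(ncol(Y)), function(j) {
    mspec <- spec
    mspec$seed <- derive_seed(seed, "independent", j)
    fit_base(mspec, X, Y[, j])
  })
  structure(list(members = members, n_features = ncol(X),
                 n_disorders = ncol(Y), disorder_names = colnames(Y)),
            class = "independent_model")
}

#' @rdname fit_independent
#' @param model an `independent_model`.
#' @export
predict_independent <- function(model, X) {
  stopifnot(inherits(model, "independent_model"))
  out <- vapply(model$members, function(m) predict(m, X),
                numeric(nrow(as.matrix(X))))
  out <- matrix(out, nrow = nrow(as.matrix(X)))
  colnames(out) <- model$disorder_names
  out
}
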