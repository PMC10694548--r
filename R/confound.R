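# Linear confound removal: encode the seven sociodemographic confounders
# into a design matrix (continuous standardized, categoricals one-hot with
# the first level dropped, intercept appended) and residualize each feature
# by ordinary least squares.

#' Encode a confounder table into a design matrix
#'
#' Continuous columns are standardized (mean 0, sd 1); categorical columns
#' are one-hot encoded with the first level dropped; an intercept column is
#' prepended. When `reference` is supplied (a design returned by a previous
#' call), its centers, scales and level sets are reused so new rows are
#' encoded on the fitting scale; an unseen categorical level is an error.
#'
#' @param table data.frame of confounders (no `participant_id` column, no
#'   missing values).
#' @param reference optional `confounder_design` whose encoding map is
#'   reused.
#' @param levels optional named list of explicit level sets for categorical
#'   columns (levels absent from the data then yield all-zero dummies; used
#'   by the cohort generator to keep effect-matrix rows aligned).
#' @return an object of class `confounder_design` with elements `matrix`
#'   (n x p, first column `(Intercept)`), `columns` and `encoding`.
#' @export
encode_confounders <- function(table, reference = NULL, levels = NULL) {
  stopifnot(is.data.frame(table))
  if (anyNA(table)) abort("confounder table contains missing values")
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "confounder_design"))
    enc <- reference$encoding
    if (!all(names(enc) %in% names(table))) {
      abort("confounder table lacks columns present in the fitted design")
    }
  } else {
    enc <- lapply(stats::setNames(names(table), names(table)), function(cn) {
      x <- table[[cn]]
      if (is.numeric(x)) {
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0) {
          abort(sprintf("continuous confounder '%s' is constant", cn))
        }
        list(type = "continuous", center = mean(x), scale = s)
      } else {
        lv <- if (!is.null(levels[[cn]])) levels[[cn]] else
          if (is.factor(x)) base::levels(x) else sort(unique(as.character(x)))
        list(type = "categorical", levels = lv)
      }
    })
  }
  cols <- list(`(Intercept)` = rep(1, nrow(table)))
  for (cn in names(enc)) {
    e <- enc[[cn]]
    x <- table[[cn]]
    if (e$type == "continuous") {
      cols[[cn]] <- (x - e$center) / e$scale
    } else {
      x <- as.character(x)
      bad <- setdiff(unique(x), e$levels)
      if (length(bad)) {
        abort(sprintf("unseen level '%s' in confounder column '%s'",
                      bad[1L], cn))
      }
      for (lv in e$levels[-1L]) {
        cols[[paste0(cn, lv)]] <- as.numeric(x == lv)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(table)
  structure(list(matrix = m, columns = colnames(m), encoding = enc),
            class = "confounder_design")
}

#' @export
print.confounder_design <- function(x, ...) {
  cat(sprintf("<confounder_design> %d rows x %d columns (incl. intercept)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Fit a least-squares residualizer
#'
#' Regresses every feature on the encoded confounder design by OLS and
#' stores the coefficient matrix, so confounder contributions can be
#' subtracted from this or held-out data. A rank-deficient design is an
#' error, not a silent pseudo-inverse.
#'
#' @param features numeric matrix (participants x features), no missing
#'   values.
#' @param design a `confounder_design` row-aligned with `features`.
#' @return an object of class `residualizer` with the `p x k` coefficient
#'   matrix and a description of the fitting data.
#' @export
fit_residualizer <- function(features, design) {
  stopifnot(inherits(design, "confounder_design"), is.matrix(features))
  Z <- design$matrix
  if (nrow(Z) != nrow(features)) abort("features and design are not row-aligned")
  if (nrow(Z) < ncol(Z)) abort("fewer rows than design columns")
  if (anyNA(features)) abort("features contain missing values; filter first")
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    abort(sprintf("confounder design is rank-deficient (rank %d < %d columns)",
                  qz$rank, ncol(Z)))
  }
  coefs <- qr.coef(qz, features)
  structure(
    list(coefficients = coefs,
         fitted_on = list(n = nrow(Z), columns = design$columns)),
    class = "residualizer"
  )
}

#' Apply a fitted residualizer
#'
#' Subtracts the predicted confounder contribution from the features. Does
#' not re-fit: coefficients come from [fit_residualizer()], so applying to
#' held-out rows is leakage-free.
#'
#' @param r a `residualizer`.
#' @param features numeric matrix to residualize.
#' @param design `confounder_design` for these rows, encoded with the same
#'   reference map as the fitting design.
#' @return residualized feature matrix of identical dimensions.
#' @export
apply_residualizer <- function(r, features, design) {
  stopifnot(inherits(r, "residualizer"), inherits(design, "confounder_design"))
  if (!identical(design$columns, r$fitted_on$columns)) {
    abort("design columns do not match the columns the residualizer was fitted on")
  }
  if (nrow(design$matrix) != nrow(features)) {
    abort("features and design are not row-aligned")
  }
  out <- features - design$matrix %*% r$coefficients
  dimnames(out) <- dimnames(features)
  out
}

#' @export
print.residualizer <- function(x, ...) {
  cat(sprintf("<residualizer> %d design columns -> %d features (fit on n=%d)\n",
              nrow(x$coefficients), ncol(x$coefficients), x$fitted_on$n))
  invisible(x)
}
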