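#' @useDynLib comorbidcv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm qnorm rnorm rbinom runif uniroot quantile var sd
#'   t.test cor coef predict
#' @importFrom utils read.csv write.csv modifyList head
NULL

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package fans out from a single master seed through
#' this function: each stage/replicate names itself (e.g. `"splits"`, repeat
#' index) and receives a deterministic 31-bit seed. The derivation is a plain
#' iterated polynomial hash of the decimal rendering of the arguments, so it
#' is stable across platforms and R versions.
#'
#' @param seed integer master seed.
#' @param ... further atomic components (strings or integers) naming the
#'   consumer of the derived seed.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "splits", 3L)
derive_seed <- function(seed, ...) {
  parts <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(parts)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h %% 2147483645L + 1L)
}

# internal: stop() with a consistent error class so callers can test on it
abort <- function(msg, class = "comorbidcv_error", ...) {
  stop(structure(
    class = c(class, "comorbidcv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x <= 1)
}

# columns of a matrix as a single pattern string per row ("0101..." keys)
row_patterns <- function(Y) {
  apply(Y, 1L, paste, collapse = "")
}
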