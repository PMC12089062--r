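#' Inverse-logit and logit
#'
#' Thin wrappers over [stats::plogis()] and [stats::qlogis()] used throughout
#' the package; exported because cline parameters live on the logit scale.
#'
#' @param x Numeric vector (logits for `invlogit`, probabilities for `logit`).
#' @return Numeric vector.
#' @export
invlogit <- function(x) stats::plogis(x)

#' @rdname invlogit
#' @export
logit <- function(x) stats::qlogis(x)

#' Standardize a covariate to mean 0, SD 1
#'
#' Centers and scales a numeric vector, returning the constants needed to map
#' new values onto the same standardized scale (and back). The SD uses the
#' usual n - 1 denominator. All model fitting in this package standardizes
#' distance and temperature covariates first, so cline coefficients are per
#' SD of the covariate.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return A list with `values` (standardized vector), `mean`, and `sd`.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    abort("`values` must be a numeric vector of length >= 2.")
  }
  if (any(!is.finite(values))) abort("`values` must be finite.")
  m <- mean(values)
  s <- sd(values)
  if (s == 0) abort("`values` is constant; cannot standardize.")
  list(values = (values - m) / s, mean = m, sd = s)
}

#' Apply stored standardization constants
#'
#' @param values Numeric vector on the raw scale.
#' @param standardizer A list with `mean` and `sd`, as produced by
#'   [standardize()].
#' @return Numeric vector on the standardized scale.
#' @export
apply_standardizer <- function(values, standardizer) {
  stopifnot(is.list(standardizer), is.numeric(standardizer$mean),
            is.numeric(standardizer$sd), standardizer$sd > 0)
  (values - standardizer$mean) / standardizer$sd
}

# seed -> reproducible stream of sub-seeds, kept below 2^31
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
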