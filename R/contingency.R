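validate_table <- function(table) {
  tab <- unclass(as.matrix(table))
  if (!all(dim(tab) == c(2L, 2L))) abort("Need a 2x2 table.")
  if (any(tab < 0) || any(!is.finite(tab))) {
    abort("Cells must be nonnegative and finite.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Every row and column margin must be positive.")
  }
  tab
}

#' Expected counts under independence
#'
#' `E[i, j] = row_i * col_j / N`; expected margins equal observed margins
#' exactly.
#'
#' @param table A 2x2 table (e.g. [make_citizen_table()]).
#' @return Numeric 2x2 matrix of expected counts.
#' @examples
#' expected_counts(make_citizen_table(12705, 174, 96025, 1581))
#' @export
expected_counts <- function(table) {
  tab <- validate_table(table)
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Pearson chi-square with Yates continuity correction
#'
#' `sum((|O - E| - c)^2 / E)` with the continuity term clamped at
#' `c = min(0.5, min |O - E|)`, the convention used by R's
#' `chisq.test()`; the clamp makes a table with `O = E` score exactly 0.
#'
#' @param table A 2x2 table.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return The test statistic (1 df for a 2x2 table).
#' @examples
#' yates_chi2(make_citizen_table(12705, 174, 96025, 1581))
#' @export
yates_chi2 <- function(table, correct = TRUE) {
  tab <- validate_table(table)
  E <- expected_counts(tab)
  cc <- if (correct) min(0.5, abs(tab - E)) else 0
  sum((abs(tab - E) - cc)^2 / E)
}

#' Cramer's V effect size
#'
#' `V = sqrt(chi2 / (N * min(r - 1, c - 1)))` using the uncorrected
#' chi-square statistic (the usual convention).
#'
#' @param table A 2x2 table.
#' @return V in \[0, 1\].
#' @examples
#' cramers_v(make_citizen_table(12705, 174, 96025, 1581))
#' @export
cramers_v <- function(table) {
  tab <- validate_table(table)
  chi2 <- yates_chi2(tab, correct = FALSE)
  k <- min(dim(tab)) - 1
  sqrt(chi2 / (sum(tab) * k))
}

#' Morph-by-mortality association test
#'
#' Bundles the Yates-corrected chi-square statistic, its p-value (1 df),
#' Cramer's V, and the observed/expected dead counts per morph into a
#' one-row tibble.
#'
#' @param table A 2x2 table (rows dead/alive, columns melanic/gray).
#' @return A tibble with `chi2`, `df`, `p_value`, `cramers_v`,
#'   `dead_melanic_obs`, `dead_melanic_exp`, `dead_gray_obs`,
#'   `dead_gray_exp`, `n`.
#' @export
morph_mortality_test <- function(table) {
  tab <- validate_table(table)
  E <- expected_counts(tab)
  chi2 <- yates_chi2(tab)
  tibble::tibble(
    chi2 = chi2, df = 1L, p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
    cramers_v = cramers_v(tab),
    dead_melanic_obs = tab[1, 1], dead_melanic_exp = E[1, 1],
    dead_gray_obs = tab[1, 2], dead_gray_exp = E[1, 2],
    n = sum(tab)
  )
}

#' Agresti-Coull binomial confidence interval
#'
#' Adds `z^2 / 2` pseudo-successes and `z^2` pseudo-trials before applying
#' the Wald formula: with `ntilde = n + z^2` and
#' `ptilde = (x + z^2 / 2) / ntilde`, the interval is
#' `ptilde +/- z * sqrt(ptilde (1 - ptilde) / ntilde)`, truncated to
#' \[0, 1\].
#'
#' @param successes Number of successes (0..n); vectorized.
#' @param n Number of trials.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A tibble with `estimate` (`x / n`), `lower`, `upper`.
#' @examples
#' agresti_coull_interval(10, 100)
#' @export
agresti_coull_interval <- function(successes, n, level = 0.95) {
  if (any(level <= 0 | level >= 1)) abort("`level` must be in (0, 1).")
  if (any(successes < 0 | successes > n) || any(n < 1)) {
    abort("Need 0 <= successes <= n and n >= 1.")
  }
  z <- qnorm(1 - (1 - level) / 2)
  ntilde <- n + z^2
  ptilde <- (successes + z^2 / 2) / ntilde
  half <- z * sqrt(ptilde * (1 - ptilde) / ntilde)
  tibble::tibble(estimate = successes / n,
                 lower = pmax(0, ptilde - half),
                 upper = pmin(1, ptilde + half))
}

#' Filter crowdsourced classifications by vote agreement
#'
#' Keeps images whose classification reached a minimum agreement among a
#' minimum number of classifiers — the standard screen applied to
#' citizen-science photo classifications before tabulation.
#'
#' @param votes Data frame with one row per image: a `n_classifiers`
#'   column and one vote-count column per category (e.g. `melanic`,
#'   `gray`).
#' @param categories Names of the vote-count columns.
#' @param min_agreement Minimum winning-vote share (default 0.8).
#' @param min_classifiers Minimum number of classifiers (default 10).
#' @return The filtered tibble with a `label` column giving the winning
#'   category.
#' @export
filter_classifications <- function(votes, categories,
                                   min_agreement = 0.8,
                                   min_classifiers = 10L) {
  votes <- tibble::as_tibble(votes)
  if (!"n_classifiers" %in% names(votes)) {
    abort("`votes` needs an `n_classifiers` column.")
  }
  miss <- setdiff(categories, names(votes))
  if (length(miss)) {
    abort(paste0("Missing vote columns: ", paste(miss, collapse = ", ")))
  }
  vm <- as.matrix(votes[, categories, drop = FALSE])
  top <- apply(vm, 1, max)
  share <- top / votes$n_classifiers
  keep <- votes$n_classifiers >= min_classifiers & share >= min_agreement
  out <- votes[keep, , drop = FALSE]
  out$label <- categories[apply(vm[keep, , drop = FALSE], 1, which.max)]
  out
}
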