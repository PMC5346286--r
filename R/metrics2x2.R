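#' 2x2 contingency counts for a binary predictor and binary effect
#'
#' The four cell counts behind every effect estimate the package
#' reports. Rows are predictor status (exposed / predictor-positive
#' first), columns are effect status (effect present first):
#' `a` = predictor-positive with effect, `b` = predictor-positive
#' without effect, `c` = predictor-negative with effect,
#' `d` = predictor-negative without effect.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `odacta_counts`, a named list with
#'   elements `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' counts_2x2(1381, 16094, 14367, 659426)
counts_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort_odacta("2x2 cell counts must be non-negative integers.",
                 "odacta_counts_error")
  }
  counts <- as.list(stats::setNames(as.integer(round(counts)), names(counts)))
  structure(counts, class = "odacta_counts")
}

#' @export
print.odacta_counts <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("predictor+", "predictor-"),
                              c("effect+", "effect-")))
  print(m)
  invisible(x)
}

#' Complete a 2x2 table from its three published cells
#'
#' Published screening tables print only three cells (`a`, `b`, `c`);
#' the fourth is implied by the stratum totals. Two completions are
#' supported: from the unexposed-group total (naive exposed-vs-unexposed
#' comparisons, where `d = unexposed_total - c`) or from the cohort size
#' and case total of a within-cohort predictor row, where
#' `d = cohort_n - a - b - c` (and `a + c` must equal `cases` when
#' supplied).
#'
#' @param a,b,c The three published cell counts (see [counts_2x2()]).
#' @param unexposed_total Total size of the predictor-negative
#'   (unexposed) group, if that is how the table is margined.
#' @param cohort_n Total cohort size, for within-cohort predictor rows.
#' @param cases Optional number of effect-positive subjects; checked
#'   against `a + c` when given.
#' @return An `odacta_counts` object.
#' @export
#' @examples
#' complete_counts(1381, 16094, 14367, unexposed_total = 673793)
#' complete_counts(161, 8006, 49, cohort_n = 15634, cases = 210)
complete_counts <- function(a, b, c, unexposed_total = NULL,
                            cohort_n = NULL, cases = NULL) {
  if (!is.null(cases) && a + c != cases) {
    abort_odacta(
      sprintf("a + c = %d does not match the stated case total %d.",
              a + c, cases),
      "odacta_counts_error")
  }
  if (!is.null(unexposed_total)) {
    d <- unexposed_total - c
  } else if (!is.null(cohort_n)) {
    d <- cohort_n - a - b - c
  } else {
    abort_odacta("Supply either `unexposed_total` or `cohort_n`.",
                 "odacta_counts_error")
  }
  if (d < 0) {
    abort_odacta("Implied fourth cell is negative; counts and totals disagree.",
                 "odacta_counts_error")
  }
  counts_2x2(a, b, c, d)
}

#' Effect metrics for a 2x2 table
#'
#' Computes the full set of binary effect metrics from the cell counts:
#' sensitivity, specificity, positive and negative predictive value
#' (all percentages), risk ratio, attributable risk (risk difference
#' between predictor strata, as a proportion), number needed to harm
#' (NNH = 1/attributable risk), and the effect strength for sensitivity
#' (ESS), a chance- and maximum-corrected accuracy measure that for two
#' classes equals sensitivity + specificity - 100 (0 = chance,
#' 100 = perfect discrimination).
#'
#' Degenerate margins yield infinities rather than silent `NaN`s: the
#' risk ratio is `Inf` when no predictor-negative subject has the
#' effect, and NNH is `Inf` (harm undetectable) when the attributable
#' risk is zero. Metrics whose defining margin is empty are `NA`.
#'
#' All values are returned at full precision; use [round_half_up()]
#' when formatting for presentation.
#'
#' @param counts An `odacta_counts` object, or anything coercible via
#'   [counts_2x2()] when `a`, `b`, `c`, `d` are passed positionally.
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `risk_ratio`,
#'   `attributable_risk`, `nnh`, `ess`.
#' @export
#' @examples
#' metrics_from_counts(counts_2x2(1381, 16094, 14367, 659426))
metrics_from_counts <- function(counts) {
  if (!inherits(counts, "odacta_counts")) {
    abort_odacta("`counts` must be created with counts_2x2() or complete_counts().",
                 "odacta_counts_error")
  }
  a <- counts$a; b <- counts$b; c <- counts$c; d <- counts$d
  frac <- function(num, den) if (den > 0) num / den else NA_real_

  sens <- 100 * frac(a, a + c)
  spec <- 100 * frac(d, b + d)
  ppv  <- 100 * frac(a, a + b)
  npv  <- 100 * frac(d, c + d)

  risk_pos <- frac(a, a + b)
  risk_neg <- frac(c, c + d)
  ar <- risk_pos - risk_neg
  rr <- if (is.na(risk_neg)) {
    NA_real_
  } else if (risk_neg == 0) {
    if (isTRUE(risk_pos > 0)) Inf else NA_real_
  } else {
    risk_pos / risk_neg
  }
  nnh <- if (is.na(ar)) NA_real_ else if (ar == 0) Inf else 1 / ar

  tibble::tibble(
    a = a, b = b, c = c, d = d,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    risk_ratio = rr, attributable_risk = ar, nnh = nnh,
    ess = sens + spec - 100
  )
}

#' Format an effect-metric row the way published screens print it
#'
#' Percentages and NNH are rounded (half away from zero) to one
#' decimal; the risk ratio to `rr_digits` decimals.
#'
#' @param metrics A tibble from [metrics_from_counts()].
#' @param rr_digits Decimal places for the risk ratio (published naive
#'   comparisons use 3, predictor screens 1).
#' @return A tibble with the same columns, rounded.
#' @export
format_metrics <- function(metrics, rr_digits = 1) {
  dplyr::mutate(
    metrics,
    dplyr::across(dplyr::any_of(c("sensitivity", "specificity", "ppv",
                                  "npv", "nnh", "ess")),
                  ~ round_half_up(.x, 1)),
    dplyr::across(dplyr::any_of("risk_ratio"), ~ round_half_up(.x, rr_digits))
  )
}
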