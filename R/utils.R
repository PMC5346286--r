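#' Round half away from zero
#'
#' Presentation-layer rounding used for all reported effect metrics.
#' Unlike [base::round()], which rounds half to even, values exactly
#' halfway between two representable numbers round away from zero
#' (17.35 -> 17.4), matching the convention of printed epidemiologic
#' tables. Internal computations are never rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.5, 0) # 3, where round(2.5) gives 2
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Whole-day difference between two Date vectors.
days_between <- function(from, to) {
  as.integer(round(as.numeric(to) - as.numeric(from)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_odacta <- function(msg, class) {
  rlang::abort(msg, class = c(class, "odacta_error"))
}
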