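#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded up (away from zero),
#' the convention used for the cohort percentage tables, rather than base R's
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @examples
#' round_half_up(0.125, 2)  # 0.13
#' round(0.125, 2)          # 0.12 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, rounded half-up to two decimals
#'
#' Helper used throughout the cohort summaries so that every reported
#' percentage carries its numerator and denominator and can be audited.
#'
#' @param numerator,denominator nonnegative counts; `denominator` > 0 unless
#'   both are 0, in which case the percentage is `NA`.
#' @param digits decimal places (default 2).
#' @return a list with `pct`, `numerator`, `denominator`.
#' @examples
#' percentage(37, 92)$pct  # 40.22
#' @export
percentage <- function(numerator, denominator, digits = 2) {
  stopifnot(numerator >= 0, denominator >= 0, numerator <= denominator)
  pct <- if (denominator == 0) NA_real_ else
    round_half_up(100 * numerator / denominator, digits)
  list(pct = pct, numerator = numerator, denominator = denominator)
}

# longest run of TRUE in a logical vector (NA treated as FALSE)
longest_true_run <- function(x) {
  x <- !is.na(x) & x
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# stop with a consistent prefix for user input problems
input_error <- function(...) stop(..., call. = FALSE)
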