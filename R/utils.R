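#' Round half away from zero
#'
#' Display rounding used for reported percentages: ties are rounded away from
#' zero (so 90.05 -> 90.1), unlike base R's round-half-to-even. Full precision
#' is always retained internally; this is for display only.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5), 0)
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Relative standard deviation in percent
#'
#' @param x Numeric vector.
#' @return `100 * sd(x) / mean(x)`.
#' @export
rsd_pct <- function(x) 100 * stats::sd(x) / mean(x)
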