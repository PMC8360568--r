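#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching how printed
#' dose/percent tables are typically rounded (base R's `round()` rounds ties
#' to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
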