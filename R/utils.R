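#' Round half away from zero
#'
#' Commercial rounding as used in published health-account tables: ties are
#' rounded away from zero rather than to the nearest even digit
#' (`round(0.5)` is 0 in R, `round_half_away(0.5)` is 1).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_away(c(2.5, -2.5, 2.625), c(0, 0, 2))
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a share the way sub-account tables print it
#'
#' Rounds half away from zero to `digits` decimals and trims a trailing
#' ".0", so 76.02 renders "76" and 18.74 renders "18.7".
#'
#' @param x Numeric vector of percentages.
#' @param digits Decimals to round to before trimming (default 1).
#' @return Character vector.
#' @export
format_share <- function(x, digits = 1) {
  r <- round_half_away(x, digits)
  out <- formatC(r, format = "f", digits = digits)
  sub("\\.0+$", "", out)
}

#' Format an amount in thousands with a comma separator
#' @param x Numeric vector (already on the scale to print).
#' @return Character vector like "35,463".
#' @export
format_amount <- function(x) {
  formatC(round_half_away(x, 0), format = "d", big.mark = ",")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix naming the pipeline stage
abort_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
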