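#' Monetary normalization context
#'
#' Holds everything needed to put nominal local-currency amounts from
#' different years on a common footing: an annual inflation series, the
#' base year whose price level all amounts are expressed in, and the
#' purchasing-power-parity conversion factor (local-currency units per
#' international dollar in the base year).
#'
#' The inflation convention is fixed, not configurable: the rate recorded
#' for year *y* moves money from year *y − 1* prices to year *y* prices.
#' An amount from an earlier year is inflated forward through every year up
#' to the base year; amounts from after the base year are not supported.
#'
#' @param inflation Named numeric vector or list, names are years, values
#'   annual inflation rates as fractions (0.12 for 12 %). Rates must
#'   exceed −1.
#' @param base_year Integer year whose constant prices are the target.
#' @param ppp_factor Positive number: local-currency units per
#'   international dollar in the base year.
#' @return An object of class `rhs_monetary_context`.
#' @export
#' @examples
#' ctx <- monetary_context(c("2011" = 0.096, "2012" = 0.18), 2012, 505)
#' deflate_to_base(100, 2010, ctx)
monetary_context <- function(inflation, base_year, ppp_factor) {
  infl <- unlist(inflation)
  if (is.null(names(infl)) && length(infl) > 0) {
    abort_stage("monetary", "inflation series must be named by year")
  }
  if (any(infl <= -1)) {
    abort_stage("monetary", "inflation rates must be greater than -1")
  }
  if (!is.numeric(ppp_factor) || length(ppp_factor) != 1 || ppp_factor <= 0) {
    abort_stage("monetary", "ppp_factor must be a single positive number")
  }
  structure(
    list(inflation = stats::setNames(as.numeric(infl),
                                     as.integer(names(infl))),
         base_year = as.integer(base_year),
         ppp_factor = as.numeric(ppp_factor)),
    class = "rhs_monetary_context"
  )
}

#' @export
print.rhs_monetary_context <- function(x, ...) {
  cat("<rhs_monetary_context>\n")
  cat("  base year :", x$base_year, "\n")
  cat("  ppp factor:", x$ppp_factor, "local currency units / Int$\n")
  cat("  inflation :", paste(sprintf("%s: %.1f%%", names(x$inflation),
                                     100 * x$inflation), collapse = ", "), "\n")
  invisible(x)
}

# cumulative inflation factor carrying year-y money to base-year prices
deflation_factor <- function(year, ctx) {
  vapply(as.integer(year), function(y) {
    if (y > ctx$base_year) {
      abort_stage("monetary", sprintf(
        "year %d is after the base year %d; only forward inflation to the base year is supported",
        y, ctx$base_year))
    }
    if (y == ctx$base_year) return(1)
    need <- seq(y + 1L, ctx$base_year)
    have <- as.integer(names(ctx$inflation))
    miss <- setdiff(need, have)
    if (length(miss) > 0) {
      abort_stage("monetary", sprintf("missing inflation rate for year %d",
                                      miss[1]))
    }
    prod(1 + ctx$inflation[as.character(need)])
  }, numeric(1))
}

#' Deflate a nominal amount to constant base-year prices
#'
#' Multiplies a nominal local-currency amount by the chained inflation
#' factors of every year between its own year and the base year:
#' `amount * prod(1 + inflation[y])` for `y` in `(year, base_year]`. At the
#' base year this is the identity.
#'
#' @param amount Numeric vector of nominal local-currency amounts.
#' @param year Integer vector (recycled) of the years the amounts were paid
#'   out in.
#' @param ctx A [monetary_context()].
#' @return Numeric vector of amounts in constant base-year local currency.
#' @export
deflate_to_base <- function(amount, year, ctx) {
  amount * deflation_factor(year, ctx)
}

#' Convert constant base-year amounts to international dollars
#'
#' Divides by the purchasing-power-parity factor of the context.
#'
#' @param amount_constant Numeric vector in constant base-year local
#'   currency.
#' @inheritParams deflate_to_base
#' @return Numeric vector in base-year international dollars.
#' @export
to_intl_dollars <- function(amount_constant, ctx) {
  amount_constant / ctx$ppp_factor
}

#' Full monetary adjustment: nominal to constant international dollars
#'
#' The fixed pipeline order: deflate to constant base-year local currency,
#' then convert by purchasing-power parity. Both steps are linear, so the
#' adjustment commutes with summation and conservation audits can be run
#' at any currency stage.
#'
#' @inheritParams deflate_to_base
#' @return Numeric vector in constant base-year international dollars.
#' @export
adjust_to_intl <- function(amount, year, ctx) {
  to_intl_dollars(deflate_to_base(amount, year, ctx), ctx)
}
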