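#' Percentage share, table-rounded
#'
#' `100 * part / whole`, rounded half away from zero — the rounding that
#' reproduces published sub-account tables, where e.g. 14.88 % prints as
#' 15 at integer precision.
#'
#' @param part,whole Numeric vectors; `whole` must be positive.
#' @param decimals Decimals to round to (default 1; summary tables use 0).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' share_percent(31292, 41163, 0)  # 76
#' share_percent(18239, 35463, 1)  # 51.4
share_percent <- function(part, whole, decimals = 1) {
  if (any(whole <= 0)) abort_stage("reporting", "whole must be positive")
  round_half_away(100 * part / whole, decimals)
}

#' Percentage growth between two values
#'
#' @param v_from,v_to Numeric; `v_from` must be positive.
#' @param decimals Decimals to round to (default 0).
#' @return Numeric percentage change.
#' @export
#' @examples
#' growth_percent(35463, 41163)       # 16
#' growth_percent(40110, 41163, 1)    # 2.6
growth_percent <- function(v_from, v_to, decimals = 0) {
  if (any(v_from <= 0)) abort_stage("reporting", "v_from must be positive")
  round_half_away(100 * (v_to - v_from) / v_from, decimals)
}

#' Demographic parameters for per-capita indicators
#'
#' Women of childbearing age (15-49) are taken as a fixed fraction of the
#' population and expected deliveries as another; years without a
#' population figure are projected from the nearest anchored year with the
#' average annual growth rate. Defaults follow the 2008 Burundi census
#' figures used throughout the bundled fixture (23.7 % WCBA, deliveries
#' 5 % of population, 2.4 % annual growth).
#'
#' @param population_by_year Named numeric vector, names are years.
#' @param wcba_fraction,delivery_fraction,annual_growth Dimensionless
#'   fractions in `[0, 1]`.
#' @return An object of class `rhs_demography`.
#' @export
demography_params <- function(population_by_year = c("2012" = 9859000),
                              wcba_fraction = 0.237,
                              delivery_fraction = 0.05,
                              annual_growth = 0.024) {
  pop <- unlist(population_by_year)
  stopifnot(all(pop > 0),
            wcba_fraction >= 0, wcba_fraction <= 1,
            delivery_fraction >= 0, delivery_fraction <= 1)
  structure(list(population_by_year = stats::setNames(as.numeric(pop),
                                                      names(pop)),
                 wcba_fraction = wcba_fraction,
                 delivery_fraction = delivery_fraction,
                 annual_growth = annual_growth),
            class = "rhs_demography")
}

#' Population for a year, projecting when not anchored
#'
#' @param demo A [demography_params()] object.
#' @param year Integer vector of years.
#' @return Numeric population estimates.
#' @export
population_for_year <- function(demo, year) {
  anchors <- as.integer(names(demo$population_by_year))
  vapply(as.integer(year), function(y) {
    if (y %in% anchors) return(demo$population_by_year[[as.character(y)]])
    nearest <- anchors[which.min(abs(anchors - y))]
    demo$population_by_year[[as.character(nearest)]] *
      (1 + demo$annual_growth)^(y - nearest)
  }, numeric(1))
}

#' Per-capita reproductive-health spending indicators
#'
#' Divides RH expenditure by the estimated number of women of
#' childbearing age and by expected deliveries for the year.
#'
#' @param rh_total RH expenditure for the year (same currency unit the
#'   result should be expressed in per person).
#' @param year Integer year.
#' @param demo A [demography_params()] object.
#' @return A tibble `year, population, wcba, deliveries, per_wcba,
#'   per_delivery`.
#' @export
#' @examples
#' demo <- demography_params(c("2012" = 1e7))
#' per_capita_indicators(47.4e6, 2012, demo)$per_wcba  # 20
per_capita_indicators <- function(rh_total, year, demo) {
  pop <- population_for_year(demo, year)
  if (any(pop <= 0)) abort_stage("reporting", "population must be positive")
  wcba <- pop * demo$wcba_fraction
  deliv <- pop * demo$delivery_fraction
  tibble::tibble(year = as.integer(year), population = pop, wcba = wcba,
                 deliveries = deliv, per_wcba = rh_total / wcba,
                 per_delivery = rh_total / deliv)
}

#' GDP implied by an expenditure total and its GDP share
#'
#' @param rh_total Expenditure total.
#' @param rh_share_of_gdp The same expenditure as a percent of GDP.
#' @return Implied GDP in the units of `rh_total`.
#' @export
#' @examples
#' implied_gdp(41163, 0.57)  # about 7.22 million (thousands in, thousands out)
implied_gdp <- function(rh_total, rh_share_of_gdp) {
  if (any(rh_share_of_gdp <= 0)) {
    abort_stage("reporting", "GDP share must be positive")
  }
  rh_total / (rh_share_of_gdp / 100)
}

provider_row_labels <- function() {
  c(PHC_CLINIC = "Primary Health Care Clinics",
    REF_HOSPITAL_1_2 = "Primary and Secondary Reference Hospitals",
    REF_HOSPITAL_3 = "Tertiary Reference Hospitals",
    ADMIN_MOH = "Ministry of Public Health and Fight Against AIDS Administration",
    ADMIN_MFP = "Social Security Administration")
}

function_row_labels <- function() {
  c(FAMILY_PLANNING = "Family Planning",
    MATERNAL_HEALTH = "Maternal Health",
    ADMIN_MOH = "Public Administration (except MFP)",
    ADMIN_MFP = "Social Security Administration (MFP)")
}

# shared renderer: amounts per (label, year) plus RH totals -> table tibble
render_share_table <- function(df, rh_total_by_year, decimals = 1) {
  df |>
    dplyr::inner_join(rh_total_by_year, by = "year") |>
    dplyr::mutate(
      share = share_percent(.data$amount, .data$rh_total, decimals),
      cell = paste0(format_amount(.data$amount), " (",
                    format_share(.data$share, decimals), ")")) |>
    dplyr::select("label", "year", "amount", "share", "cell")
}

cube_of <- function(x) if (inherits(x, "rhs_allocation")) x$cube else x

#' Published-style report tables
#'
#' Build the three cross-tabulations of reproductive-health expenditure —
#' by financing agent, by health provider, and by health function — with
#' the conventional "amount (share)" cells. Amounts are reported in
#' thousands of constant international dollars (rounded half away from
#' zero at this final rendering step only); parenthetical shares are each
#' row's percentage of the year's total RH expenditure, which includes the
#' administration cells and excludes the non-RH residual.
#'
#' @param x An `rhs_allocation` or a cube tibble
#'   (`year, agent_id, tier, fn, amount`).
#' @param years Optional years to include.
#' @param scale Multiplier taking cube amounts to thousands (default
#'   `1e-3` for a cube in dollars; use `1` for a cube already in
#'   thousands).
#' @param decimals Share precision (default 1 decimal, trailing ".0"
#'   trimmed at formatting).
#' @param tax Taxonomy supplying agent display names.
#' @return A tibble `label, year, amount, share, cell`, one row per
#'   taxonomy member and year.
#' @name report_tables
NULL

#' @describeIn report_tables RH expenditure by financing agent.
#' @export
build_agent_table <- function(x, years = NULL, scale = 1e-3, decimals = 1,
                              tax = taxonomy()) {
  cube <- cube_of(x)
  if (!is.null(years)) cube <- dplyr::filter(cube, .data$year %in% years)
  rh <- rh_totals(cube) |> dplyr::mutate(rh_total = .data$rh_total * scale)
  cube |>
    dplyr::filter(.data$fn != "OTHER_HEALTH") |>
    dplyr::group_by(.data$year, .data$agent_id) |>
    dplyr::summarise(amount = sum(.data$amount) * scale, .groups = "drop") |>
    dplyr::left_join(tax$agents, by = "agent_id") |>
    dplyr::mutate(label = dplyr::coalesce(.data$display_name,
                                          .data$agent_id)) |>
    render_share_table(rh, decimals)
}

#' @describeIn report_tables RH expenditure by health provider; the two
#'   national administrations appear as separate provider rows.
#' @export
build_provider_table <- function(x, years = NULL, scale = 1e-3,
                                 decimals = 1, tax = taxonomy()) {
  cube <- cube_of(x)
  if (!is.null(years)) cube <- dplyr::filter(cube, .data$year %in% years)
  rh <- rh_totals(cube) |> dplyr::mutate(rh_total = .data$rh_total * scale)
  labs <- provider_row_labels()
  cube |>
    dplyr::filter(.data$fn != "OTHER_HEALTH") |>
    dplyr::mutate(key = ifelse(.data$tier == "ADMIN_NATIONAL",
                               .data$fn, .data$tier)) |>
    dplyr::group_by(.data$year, .data$key) |>
    dplyr::summarise(amount = sum(.data$amount) * scale, .groups = "drop") |>
    dplyr::mutate(label = unname(labs[.data$key])) |>
    render_share_table(rh, decimals)
}

#' @describeIn report_tables RH expenditure by health function.
#' @export
build_function_table <- function(x, years = NULL, scale = 1e-3,
                                 decimals = 1, tax = taxonomy()) {
  cube <- cube_of(x)
  if (!is.null(years)) cube <- dplyr::filter(cube, .data$year %in% years)
  rh <- rh_totals(cube) |> dplyr::mutate(rh_total = .data$rh_total * scale)
  labs <- function_row_labels()
  cube |>
    dplyr::filter(.data$fn != "OTHER_HEALTH") |>
    dplyr::group_by(.data$year, .data$fn) |>
    dplyr::summarise(amount = sum(.data$amount) * scale, .groups = "drop") |>
    dplyr::mutate(label = unname(labs[.data$fn])) |>
    render_share_table(rh, decimals)
}

#' Health and reproductive-health summary indicators
#'
#' The top-level summary: RH expenditure against total public health
#' expenditure (integer-percent shares, as in published summary tables),
#' the non-RH remainder, growth against the first year, and optionally
#' the share of GDP.
#'
#' @param rh_total_by_year Tibble `year, rh_total` (e.g. from
#'   [rh_totals()]), or an `rhs_allocation`.
#' @param health_total_by_year Tibble `year, health_total` in the same
#'   currency unit.
#' @param gdp_by_year Optional tibble `year, gdp` in the same unit.
#' @return A tibble per year with amounts, shares and growth.
#' @export
summary_indicators <- function(rh_total_by_year, health_total_by_year,
                               gdp_by_year = NULL) {
  if (inherits(rh_total_by_year, "rhs_allocation")) {
    rh_total_by_year <- rh_totals(rh_total_by_year)
  }
  out <- rh_total_by_year |>
    dplyr::inner_join(health_total_by_year, by = "year") |>
    dplyr::arrange(.data$year) |>
    dplyr::mutate(
      other_health = .data$health_total - .data$rh_total,
      rh_share_of_health = share_percent(.data$rh_total,
                                         .data$health_total, 0),
      other_share_of_health = share_percent(.data$other_health,
                                            .data$health_total, 0),
      growth_vs_first = c(NA_real_,
                          if (dplyr::n() > 1)
                            growth_percent(.data$rh_total[1],
                                           .data$rh_total[-1], 0)))
  if (!is.null(gdp_by_year)) {
    out <- out |>
      dplyr::left_join(gdp_by_year, by = "year") |>
      dplyr::mutate(rh_share_of_gdp = share_percent(.data$rh_total,
                                                    .data$gdp, 2))
  }
  out
}

#' Render a report table as aligned text
#'
#' Pivots a [build_agent_table()]-style tibble to one row per label with a
#' column per year, and formats it as aligned monospace text.
#'
#' @param tbl Tibble with `label, year, cell` columns.
#' @param title Optional heading line.
#' @return A character scalar (lines joined with newlines).
#' @export
render_table_text <- function(tbl, title = NULL) {
  wide <- tbl |>
    dplyr::select("label", "year", "cell") |>
    tidyr::pivot_wider(names_from = "year", values_from = "cell")
  cols <- names(wide)
  widths <- vapply(cols, function(cn) {
    max(nchar(c(cn, as.character(wide[[cn]]))), na.rm = TRUE)
  }, numeric(1))
  pad <- function(x, w, right = FALSE) {
    formatC(x, width = w, flag = if (right) "" else "-")
  }
  header <- paste(mapply(pad, cols, widths, right = c(FALSE,
    rep(TRUE, length(cols) - 1))), collapse = "  ")
  rows <- apply(wide, 1, function(r) {
    paste(mapply(pad, as.character(r), widths,
                 right = c(FALSE, rep(TRUE, length(cols) - 1))),
          collapse = "  ")
  })
  paste(c(title, header, rows), collapse = "\n")
}
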