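#' Published Burundi 2010-2012 sub-account tables
#'
#' The published reproductive-health sub-account results for Burundi
#' 2010-2012, entered from the printed tables as a first-class fixture:
#' the raw ledgers behind them are not public, so these tables are the
#' bridge between the allocation engine's conventions and a real
#' sub-account. Amounts are in thousands of constant 2012 international
#' dollars; `share_printed` columns carry the published parenthetical
#' percentages so every derived number can be recomputed and compared.
#'
#' @return A list of tibbles: `summary` (health vs RH totals and GDP
#'   shares), `agents`, `providers`, `functions` (the three
#'   cross-tabulations), `moh_categories` (health-ministry spending by
#'   category, with `total_printed` attribute rows), `facility_shares`
#'   (percentage composition of facility expenditure by tier), plus the
#'   census `demography` used for per-capita indicators.
#' @export
#' @examples
#' fx <- burundi_printed()
#' fx$summary
burundi_printed <- function() {
  years <- 2010:2012

  summary <- tibble::tibble(
    year = years,
    rh_total = c(35463, 40110, 41163),
    rh_share_printed = c(15, 17, 19),
    other_health = c(202871, 196556, 178995),
    other_share_printed = c(85, 83, 81),
    health_total = c(238334, 236667, 220158),
    rh_gdp_share_printed = c(0.59, 0.62, 0.57)
  )

  agents <- tibble::tibble(
    year = rep(years, times = 6),
    agent_id = rep(c("MSPLS", "MFP", "MHER", "MPS", "MND", "MNS"), each = 3),
    amount = c(25874, 30565, 31292,
               7453, 7515, 7909,
               576, 517, 582,
               697, 649, 587,
               818, 809, 747,
               45, 55, 46),
    share_printed = c(73, 76.2, 76,
                      21, 18.7, 19.2,
                      1.6, 1.3, 1.4,
                      2, 1.6, 1.4,
                      2.3, 2, 1.8,
                      0.1, 0.1, 0.1)
  )

  providers <- tibble::tibble(
    year = rep(years, times = 5),
    key = rep(c("PHC_CLINIC", "REF_HOSPITAL_1_2", "REF_HOSPITAL_3",
                "ADMIN_MOH", "ADMIN_MFP"), each = 3),
    amount = c(18239, 18776, 21599,
               6215, 12372, 9243,
               4898, 2850, 3889,
               3131, 3216, 3383,
               2981, 2896, 3048),
    share_printed = c(51.4, 46.8, 52.5,
                      17.5, 30.8, 22.5,
                      13.8, 7.1, 9.4,
                      8.8, 8, 8.2,
                      8.4, 7.2, 7.4)
  )

  functions <- tibble::tibble(
    year = rep(years, times = 4),
    fn = rep(c("FAMILY_PLANNING", "MATERNAL_HEALTH",
               "ADMIN_MOH", "ADMIN_MFP"), each = 3),
    amount = c(1765, 3679, 5102,
               27586, 30319, 29630,
               3131, 3216, 3383,
               2981, 2896, 3048),
    share_printed = c(5, 9.2, 12.4,
                      77.8, 75.6, 72,
                      8.8, 8, 8.2,
                      8.4, 7.2, 7.4)
  )

  moh_categories <- tibble::tibble(
    year = rep(years, times = 8),
    category = rep(c("construction_equipment", "hospital_endowment",
                     "national_rh_programme", "pbf_subsidies",
                     "salaries_peripheral", "central_administration",
                     "medical_health_card", "contraceptives"), each = 3),
    amount = c(6350, 6323, 1166,
               1361, 1202, 1203,
               526, 648, 568,
               4281, 9851, 14404,
               10665, 9799, 10581,
               2618, 2652, 2820,
               73, 90, 75,
               NA, NA, 474),
    share_printed = c(24.5, 20.7, 3.7,
                      5.3, 3.9, 3.8,
                      2, 2.1, 1.8,
                      16.5, 32.2, 46,
                      41.2, 32.1, 33.8,
                      10.1, 8.7, 9,
                      0.3, 0.3, 0.2,
                      NA, NA, 1.5),
    total_printed = rep(c(25874, 30565, 31292), times = 8)
  )

  facility_shares <- tibble::tibble(
    year = rep(years, each = 3),
    tier = rep(facility_tiers(), times = 3),
    maternal = c(24.7, 13.3, 10.1,
                 26.6, 13.1, 9.3,
                 25.8, 13.2, 9.8),
    family_planning = c(2.04, 0.1, 0.3,
                        2.4, 0.1, 0.2,
                        2.2, 0.2, 0.2),
    rh_total_printed = c(26.8, 13.4, 10.4,
                         28.9, 13.3, 9.5,
                         28.0, 13.3, 10.0),
    other_printed = c(73.2, 86.6, 89.6,
                      71.1, 86.7, 90.5,
                      72, 86.7, 90)
  )

  list(summary = summary, agents = agents, providers = providers,
       functions = functions, moh_categories = moh_categories,
       facility_shares = facility_shares,
       demography = demography_params())
}

#' Target facility share matrix from the published composition table
#'
#' Turns a year's column of the published facility-composition table into
#' a share matrix usable as a calibration target: maternal and
#' family-planning shares as printed (fractions), the non-RH residual as
#' one minus their sum, since the printed rows themselves only agree up
#' to rounding.
#'
#' @param year One of 2010, 2011, 2012.
#' @return A tibble `year, tier, fn, share` whose rows sum to one exactly.
#' @export
burundi_share_targets <- function(year = 2012) {
  fx <- burundi_printed()$facility_shares
  fx <- fx[fx$year == year, ]
  if (nrow(fx) == 0) abort_stage("fixture", "no published shares for year ", year)
  dplyr::bind_rows(
    dplyr::transmute(fx, year = .data$year, tier = .data$tier,
                     fn = "MATERNAL_HEALTH", share = .data$maternal / 100),
    dplyr::transmute(fx, year = .data$year, tier = .data$tier,
                     fn = "FAMILY_PLANNING", share = .data$family_planning / 100),
    dplyr::transmute(fx, year = .data$year, tier = .data$tier,
                     fn = "OTHER_HEALTH",
                     share = 1 - (.data$maternal + .data$family_planning) / 100)
  ) |> dplyr::arrange(.data$tier, .data$fn)
}

#' Verify every derived number of the published tables
#'
#' Recomputes from the printed absolute amounts each figure the published
#' tables derive from them — parenthetical percentage shares, growth
#' rates, the GDP growth implied by the GDP shares, and the cross-table
#' sum identities — and compares with what was printed. Column sums are
#' allowed the published tables' own rounding slack (agent and function
#' tables sum exactly to the RH totals; the provider table is off by one
#' thousand in one year).
#'
#' @param fixture A fixture list as returned by [burundi_printed()]
#'   (possibly perturbed, e.g. for fault-injection testing).
#' @return A tibble `target, pass, detail`, one row per check.
#' @export
verify_printed_tables <- function(fixture = burundi_printed()) {
  fx <- fixture
  res <- list()
  add <- function(target, pass, detail = "") {
    res[[length(res) + 1]] <<- tibble::tibble(
      target = target, pass = pass, detail = detail)
  }
  rh <- fx$summary |> dplyr::select("year", rh_total = "rh_total")

  s <- fx$summary
  add("summary_health_shares",
      all(share_percent(s$rh_total, s$health_total, 0) == s$rh_share_printed) &&
      all(share_percent(s$other_health, s$health_total, 0) ==
            s$other_share_printed),
      "RH and non-RH shares of total public health expenditure")
  add("summary_totals_consistent",
      all(abs(s$rh_total + s$other_health - s$health_total) <= 1),
      "RH + other = total within rounding")
  add("rh_growth_2010_2012",
      growth_percent(s$rh_total[s$year == 2010],
                     s$rh_total[s$year == 2012], 0) == 16,
      "16 % growth of RH expenditure 2010-2012")
  add("rh_growth_2011_2012",
      growth_percent(s$rh_total[s$year == 2011],
                     s$rh_total[s$year == 2012], 1) == 2.6,
      "2.6 % growth of RH expenditure 2011-2012")
  gdp <- implied_gdp(s$rh_total, s$rh_gdp_share_printed)
  add("gdp_growth_2010_2012",
      growth_percent(gdp[s$year == 2010], gdp[s$year == 2012], 0) == 20,
      "GDP implied by the printed GDP shares grew 20 %")

  chk_shares <- function(df, denom_by_year) {
    d <- df |> dplyr::inner_join(denom_by_year, by = "year") |>
      dplyr::filter(!is.na(.data$amount))
    all(share_percent(d$amount, d$denom, 1) == d$share_printed)
  }
  add("agent_table_shares",
      chk_shares(fx$agents, dplyr::rename(rh, denom = "rh_total")),
      "every agent-table parenthetical share")
  add("provider_table_shares",
      chk_shares(fx$providers, dplyr::rename(rh, denom = "rh_total")),
      "every provider-table parenthetical share")
  add("function_table_shares",
      chk_shares(fx$functions, dplyr::rename(rh, denom = "rh_total")),
      "every function-table parenthetical share")
  add("moh_category_shares",
      chk_shares(fx$moh_categories,
                 dplyr::distinct(fx$moh_categories, .data$year,
                                 denom = .data$total_printed)),
      "every health-ministry category share")

  sums <- function(df) {
    df |> dplyr::filter(!is.na(.data$amount)) |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(total = sum(.data$amount), .groups = "drop") |>
      dplyr::inner_join(rh, by = "year")
  }
  a <- sums(fx$agents)
  add("agent_sums_equal_rh_totals", all(a$total == a$rh_total),
      "agent column sums equal the published RH totals")
  p <- sums(fx$providers)
  add("provider_sums_within_1", all(abs(p$total - p$rh_total) <= 1),
      "provider column sums equal the RH totals within 1 thousand")
  f <- sums(fx$functions)
  add("function_sums_equal_rh_totals", all(f$total == f$rh_total),
      "function column sums equal the published RH totals")
  m <- fx$moh_categories |> dplyr::filter(!is.na(.data$amount)) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(total = sum(.data$amount),
                     printed = .data$total_printed[1], .groups = "drop")
  add("moh_category_sums_within_1", all(abs(m$total - m$printed) <= 1),
      "health-ministry category sums equal the agent total within 1 thousand")

  fs <- fx$facility_shares
  add("facility_share_rows_sum_100",
      all(abs(fs$maternal + fs$family_planning + fs$other_printed - 100)
          <= 0.15) &&
      all(abs(fs$maternal + fs$family_planning - fs$rh_total_printed)
          <= 0.15),
      "facility composition rows sum to 100 within printed rounding")

  dplyr::bind_rows(res)
}
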