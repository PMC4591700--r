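#' Bottom-up facility expenditure totals
#'
#' Estimates total expenditure at each facility tier as the sum over
#' services of volume times unit cost (`T = sum(Vhs * C)`). The estimate
#' covers all financing sources reaching the facility; the allocation
#' engine only uses the *proportions* between tiers and functions, so the
#' currency stage of the unit costs is irrelevant.
#'
#' @param volumes Tibble of service volumes (`year, tier, service_code,
#'   volume`), facility tiers only.
#' @param costs Tibble of unit costs (`service_code, cost, fn`).
#' @param years Optional integer vector restricting the years computed.
#' @return A tibble `year, tier, total`, one row per facility tier present.
#' @export
#' @examples
#' v <- tibble::tibble(year = 2012L, tier = "PHC_CLINIC",
#'                     service_code = c("a", "b"), volume = c(10, 5))
#' c <- tibble::tibble(service_code = c("a", "b"), cost = c(2, 3),
#'                     fn = c("MATERNAL_HEALTH", "OTHER_HEALTH"))
#' estimate_tier_totals(v, c)  # 10*2 + 5*3 = 35
estimate_tier_totals <- function(volumes, costs, years = NULL) {
  if (!is.null(years)) volumes <- dplyr::filter(volumes, .data$year %in% years)
  miss <- setdiff(unique(volumes$service_code), costs$service_code)
  if (length(miss) > 0) {
    abort_stage("allocation", "no unit cost for service_code: ",
                paste(miss, collapse = ", "))
  }
  bad_tier <- setdiff(unique(volumes$tier), facility_tiers())
  if (length(bad_tier) > 0) {
    abort_stage("allocation", "volumes recorded for non-facility tier: ",
                paste(bad_tier, collapse = ", "))
  }
  volumes |>
    dplyr::inner_join(costs, by = "service_code") |>
    dplyr::group_by(.data$year, .data$tier) |>
    dplyr::summarise(total = sum(.data$volume * .data$cost), .groups = "drop")
}

#' Facility expenditure share matrix
#'
#' Splits each tier's bottom-up total across the three facility functions
#' (maternal health, family planning, other health activities):
#' `share(tier, fn) = sum over services of fn of volume*cost / T_tier`.
#' Rows sum to one. A tier whose total is zero has an undefined
#' composition; its shares are returned as `NA` and any downstream attempt
#' to allocate funds to it is an error.
#'
#' @inheritParams estimate_tier_totals
#' @param service_functions Optional tibble `service_code, fn` overriding
#'   the function column of `costs`.
#' @return A tibble `year, tier, fn, share` covering every facility tier
#'   present and all three facility functions.
#' @export
compute_share_matrix <- function(volumes, costs, service_functions = NULL,
                                 years = NULL) {
  if (!is.null(service_functions)) {
    costs <- costs |>
      dplyr::select(-dplyr::any_of("fn")) |>
      dplyr::inner_join(service_functions, by = "service_code")
  }
  if (!is.null(years)) volumes <- dplyr::filter(volumes, .data$year %in% years)
  miss <- setdiff(unique(volumes$service_code), costs$service_code)
  if (length(miss) > 0) {
    abort_stage("allocation", "no unit cost for service_code: ",
                paste(miss, collapse = ", "))
  }
  spend <- volumes |>
    dplyr::inner_join(costs, by = "service_code") |>
    dplyr::group_by(.data$year, .data$tier, .data$fn) |>
    dplyr::summarise(amount = sum(.data$volume * .data$cost),
                     .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("year"), !!rlang::sym("tier")),
      fn = facility_functions(), fill = list(amount = 0))
  spend |>
    dplyr::group_by(.data$year, .data$tier) |>
    dplyr::mutate(share = if (sum(.data$amount) > 0) {
      .data$amount / sum(.data$amount)
    } else {
      NA_real_
    }) |>
    dplyr::ungroup() |>
    dplyr::select("year", "tier", "fn", "share")
}

#' Tier weights from bottom-up totals
#'
#' Converts tier totals into the distribution factors used to parcel
#' non-earmarked public funds across facility tiers: each tier's weight is
#' its share of the summed bottom-up totals for that year.
#'
#' @param tier_totals Output of [estimate_tier_totals()].
#' @return A tibble `year, tier, weight`; weights sum to one within year.
#' @export
tier_weights_from_totals <- function(tier_totals) {
  tier_totals |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(weight = .data$total / sum(.data$total)) |>
    dplyr::ungroup() |>
    dplyr::select("year", "tier", "weight")
}

new_partial_allocation <- function(year = integer(), agent_id = character(),
                                   tier = character(), fn = character(),
                                   amount = numeric(), category = character(),
                                   strategy = character()) {
  tibble::tibble(year = as.integer(year), agent_id = agent_id, tier = tier,
                 fn = fn, amount = amount, category = category,
                 strategy = strategy)
}

#' Strategy 1: pass-through of earmarked funds
#'
#' Funds explicitly earmarked for a reproductive-health function are taken
#' at the full amount paid out in the year, without splitting: each entry
#' maps one-to-one onto a cell of the allocation cube at its hinted
#' function and tier.
#'
#' @param entries Ledger slice with `earmark == "EARMARKED_RH"`; `amount`
#'   may already be monetary-adjusted.
#' @param default_tier Tier assigned to earmarked entries without a
#'   `tier_hint` (national RH programme spending; defaults to
#'   `"PHC_CLINIC"`).
#' @return A partial allocation tibble `year, agent_id, tier, fn, amount,
#'   category, strategy`.
#' @export
allocate_earmarked <- function(entries, default_tier = "PHC_CLINIC") {
  if (nrow(entries) == 0) return(new_partial_allocation())
  if (any(is.na(entries$function_hint))) {
    abort_stage("allocation", "earmarked entry without function_hint")
  }
  entries |>
    dplyr::transmute(
      year = as.integer(.data$year), agent_id = .data$agent_id,
      tier = dplyr::coalesce(.data$tier_hint, default_tier),
      fn = .data$function_hint, amount = .data$amount,
      category = .data$category, strategy = "earmarked")
}

#' Strategy 2: distribution-factor allocation of facility funds
#'
#' Non-earmarked funds sent to health providers are parcelled out in two
#' steps: across facility tiers by the tier weights (unless the entry
#' carries a `tier_hint`, which pins it to that tier), then within each
#' tier across functions by the tier's share-matrix row. The allocated
#' amounts sum exactly to the input amounts because both factor vectors
#' sum to one.
#'
#' @param entries Ledger slice with `earmark == "FACILITY_NONEARMARKED"`.
#' @param tier_weights Tibble `year, tier, weight` (see
#'   [tier_weights_from_totals()]).
#' @param share_matrix Tibble `year, tier, fn, share` (see
#'   [compute_share_matrix()]).
#' @return A partial allocation tibble.
#' @export
allocate_facility_funds <- function(entries, tier_weights, share_matrix) {
  if (nrow(entries) == 0) return(new_partial_allocation())
  hinted <- entries |>
    dplyr::filter(!is.na(.data$tier_hint)) |>
    dplyr::transmute(year = as.integer(.data$year),
                     agent_id = .data$agent_id, tier = .data$tier_hint,
                     weight = 1, amount = .data$amount,
                     category = .data$category)
  pooled <- entries |>
    dplyr::filter(is.na(.data$tier_hint)) |>
    dplyr::mutate(year = as.integer(.data$year))
  pooled_weighted <- NULL
  if (nrow(pooled) > 0) {
    missing_years <- setdiff(unique(pooled$year), unique(tier_weights$year))
    if (length(missing_years) > 0) {
      abort_stage("allocation", "no tier weights for year(s): ",
                  paste(missing_years, collapse = ", "))
    }
    pooled_weighted <- pooled |>
      dplyr::select("year", "agent_id", "amount", "category") |>
      dplyr::inner_join(tier_weights, by = "year",
                        relationship = "many-to-many")
  }
  spread <- dplyr::bind_rows(hinted, pooled_weighted) |>
    dplyr::inner_join(share_matrix, by = c("year", "tier"),
                      relationship = "many-to-many")
  undef <- spread |> dplyr::filter(is.na(.data$share), .data$weight > 0)
  if (nrow(undef) > 0) {
    abort_stage("allocation",
                "cannot allocate funds to tier with undefined share row: ",
                paste(unique(undef$tier), collapse = ", "))
  }
  covered <- spread |>
    dplyr::distinct(.data$year, .data$agent_id, .data$category)
  lost <- dplyr::anti_join(
    dplyr::mutate(entries, year = as.integer(.data$year)), covered,
    by = c("year", "agent_id", "category"))
  if (nrow(lost) > 0 && any(lost$amount > 0)) {
    abort_stage("allocation", "facility entry could not be allocated (no ",
                "share row for its year/tier): year ",
                lost$year[1], ", tier ", lost$tier_hint[1] %||% "<pooled>")
  }
  spread |>
    dplyr::group_by(.data$year, .data$agent_id, .data$tier, .data$fn,
                    .data$category) |>
    dplyr::summarise(
      amount = sum(.data$amount * .data$weight * .data$share),
      .groups = "drop") |>
    dplyr::mutate(strategy = "facility") |>
    dplyr::select("year", "agent_id", "tier", "fn", "amount", "category",
                  "strategy")
}

#' Strategy 3 distribution factor
#'
#' The fraction of national administrative spending attributable to
#' reproductive health: total direct public expenditure on reproductive
#' health divided by total direct public expenditure, where "direct" means
#' all funds used for the provision of services (the strategy 1 and 2
#' allocations to facility tiers); administrative cells never enter the
#' denominator.
#'
#' @param direct_rh_total Direct RH expenditure (maternal health + family
#'   planning cells of strategies 1 and 2).
#' @param direct_total All direct expenditure (every strategy 1 and 2
#'   cell, including the non-RH residual).
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' admin_distribution_factor(30, 120)  # 0.25
admin_distribution_factor <- function(direct_rh_total, direct_total) {
  if (any(direct_total <= 0)) {
    abort_stage("allocation",
                "direct total is zero: no basis for the admin distribution factor")
  }
  f <- direct_rh_total / direct_total
  if (any(f < 0 | f > 1)) {
    abort_stage("allocation", "admin distribution factor outside [0, 1]")
  }
  f
}

#' Strategy 3: apportion national administrative funds
#'
#' Each national-level administrative entry contributes
#' `amount * factor` to the reproductive-health administration cell of its
#' agent (`ADMIN_MFP` for the social-security fund, `ADMIN_MOH` otherwise)
#' and `amount * (1 - factor)` to the non-RH residual; both land on the
#' `ADMIN_NATIONAL` tier, so the full amount is conserved while only the
#' RH-attributable part enters RH totals.
#'
#' @param entries Ledger slice with `earmark == "ADMIN_NATIONAL"`.
#' @param factor_by_year Tibble `year, factor` from
#'   [admin_distribution_factor()], or a single number applied to all
#'   years.
#' @param mfp_agent `agent_id` of the social-security fund whose
#'   administration is reported separately (default `"MFP"`).
#' @return A partial allocation tibble.
#' @export
allocate_admin <- function(entries, factor_by_year, mfp_agent = "MFP") {
  if (nrow(entries) == 0) return(new_partial_allocation())
  if (is.numeric(factor_by_year) && is.null(dim(factor_by_year))) {
    factor_by_year <- tibble::tibble(
      year = as.integer(unique(entries$year)),
      factor = as.numeric(factor_by_year))
  }
  withf <- entries |>
    dplyr::mutate(year = as.integer(.data$year)) |>
    dplyr::inner_join(factor_by_year, by = "year")
  if (nrow(withf) < nrow(entries)) {
    abort_stage("allocation", "missing admin distribution factor for year(s): ",
                paste(setdiff(unique(entries$year), factor_by_year$year),
                      collapse = ", "))
  }
  rh <- withf |>
    dplyr::transmute(
      year = .data$year, agent_id = .data$agent_id, tier = "ADMIN_NATIONAL",
      fn = ifelse(.data$agent_id == mfp_agent, "ADMIN_MFP", "ADMIN_MOH"),
      amount = .data$amount * .data$factor, category = .data$category,
      strategy = "admin")
  residual <- withf |>
    dplyr::transmute(
      year = .data$year, agent_id = .data$agent_id, tier = "ADMIN_NATIONAL",
      fn = "OTHER_HEALTH", amount = .data$amount * (1 - .data$factor),
      category = .data$category, strategy = "admin")
  dplyr::bind_rows(rh, residual)
}

#' Run the full sub-account allocation pipeline
#'
#' Composes the three estimation strategies with the monetary module:
#' validates the ledger, adjusts every entry to constant base-year
#' international dollars, passes earmarked funds through (strategy 1),
#' apportions non-earmarked facility funds by bottom-up distribution
#' factors (strategy 2), derives the direct-RH ratio from the resulting
#' facility cells and apportions national administrative funds with it
#' (strategy 3). The pipeline is deterministic and conserves money: for
#' every agent-year the cube (including the non-RH residual) sums to the
#' agent's adjusted ledger total.
#'
#' @param ledger Ledger tibble (see [read_ledger()]).
#' @param volumes Service-volume tibble.
#' @param costs Unit-cost tibble.
#' @param ctx A [monetary_context()].
#' @param tax A [taxonomy()].
#' @param default_earmark_tier Tier for earmarked entries without a hint.
#' @param mfp_agent Agent whose administration is reported separately.
#' @return An object of class `rhs_allocation`: a list with the allocation
#'   `cube` (tibble `year, agent_id, tier, fn, amount` in constant
#'   international dollars), the per-category `detail` (provenance of
#'   every cell), the `share_matrix`, `tier_totals`, `tier_weights`,
#'   `admin_factor` by year, the conservation `audit`, and the monetary
#'   context.
#' @export
run_pipeline <- function(ledger, volumes, costs, ctx, tax = taxonomy(),
                         default_earmark_tier = "PHC_CLINIC",
                         mfp_agent = "MFP") {
  ledger <- resolve_agents(ledger, tax)
  viol <- validate_ledger(ledger, tax)
  if (nrow(viol) > 0) {
    abort_stage("validate", sprintf(
      "ledger has %d violation(s); first: row %d, %s (%s)",
      nrow(viol), viol$row[1], viol$problem[1], viol$field[1]))
  }
  ledger <- dplyr::mutate(
    ledger, year = as.integer(.data$year),
    amount = adjust_to_intl(.data$amount, .data$year, ctx))

  tier_totals <- estimate_tier_totals(volumes, costs)
  shares <- compute_share_matrix(volumes, costs)
  weights <- tier_weights_from_totals(tier_totals)

  s1 <- allocate_earmarked(
    dplyr::filter(ledger, .data$earmark == "EARMARKED_RH"),
    default_tier = default_earmark_tier)
  s2 <- allocate_facility_funds(
    dplyr::filter(ledger, .data$earmark == "FACILITY_NONEARMARKED"),
    weights, shares)
  direct <- dplyr::bind_rows(s1, s2)

  admin_entries <- dplyr::filter(ledger, .data$earmark == "ADMIN_NATIONAL")
  admin_factor <- tibble::tibble(year = integer(), factor = numeric())
  s3 <- new_partial_allocation()
  if (nrow(admin_entries) > 0) {
    admin_factor <- direct |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(
        direct_rh = sum(.data$amount[.data$fn %in% rh_functions()]),
        direct_total = sum(.data$amount), .groups = "drop")
    missing_years <- setdiff(unique(admin_entries$year), admin_factor$year)
    if (length(missing_years) > 0) {
      abort_stage("allocation",
                  "administrative funds in year(s) with no direct expenditures: ",
                  paste(missing_years, collapse = ", "))
    }
    admin_factor <- admin_factor |>
      dplyr::mutate(factor = admin_distribution_factor(.data$direct_rh,
                                                       .data$direct_total)) |>
      dplyr::select("year", "factor")
    s3 <- allocate_admin(admin_entries, admin_factor, mfp_agent = mfp_agent)
  }

  detail <- dplyr::bind_rows(direct, s3)
  cube <- detail |>
    dplyr::group_by(.data$year, .data$agent_id, .data$tier, .data$fn) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop")

  audit <- dplyr::full_join(
    ledger |>
      dplyr::group_by(.data$year, .data$agent_id) |>
      dplyr::summarise(ledger_total = sum(.data$amount), .groups = "drop"),
    cube |>
      dplyr::group_by(.data$year, .data$agent_id) |>
      dplyr::summarise(cube_total = sum(.data$amount), .groups = "drop"),
    by = c("year", "agent_id")) |>
    dplyr::mutate(
      ledger_total = dplyr::coalesce(.data$ledger_total, 0),
      cube_total = dplyr::coalesce(.data$cube_total, 0),
      gap = .data$cube_total - .data$ledger_total,
      ok = abs(.data$gap) <= 1e-9 * pmax(1, abs(.data$ledger_total)))

  structure(
    list(cube = cube, detail = detail, share_matrix = shares,
         tier_totals = tier_totals, tier_weights = weights,
         admin_factor = admin_factor, audit = audit, ctx = ctx,
         years = sort(unique(ledger$year))),
    class = "rhs_allocation")
}

#' Reproductive-health totals of an allocation cube
#'
#' Sums all cube cells except the non-RH residual (`OTHER_HEALTH`);
#' administration cells count towards RH, matching the published-table
#' convention.
#'
#' @param cube Allocation cube tibble or `rhs_allocation` object.
#' @return Tibble `year, rh_total`.
#' @export
rh_totals <- function(cube) {
  if (inherits(cube, "rhs_allocation")) cube <- cube$cube
  cube |>
    dplyr::filter(.data$fn != "OTHER_HEALTH") |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(rh_total = sum(.data$amount), .groups = "drop")
}
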