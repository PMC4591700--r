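# shared in-code fixtures: tiny ledgers/volumes built fresh per test

ledger_row <- function(year = 2012L, agent_id = "MSPLS", amount = 100,
                       earmark = "FACILITY_NONEARMARKED",
                       function_hint = NA_character_,
                       tier_hint = NA_character_, category = "salaries") {
  tibble::tibble(year = as.integer(year), agent_id = agent_id,
                 amount = amount, earmark = earmark,
                 function_hint = function_hint, tier_hint = tier_hint,
                 category = category)
}

# one tier whose spending is 28 maternal / 7 family planning / 65 other
toy_single_tier <- function(year = 2012L, tier = "PHC_CLINIC") {
  list(
    volumes = tibble::tibble(
      year = as.integer(year), tier = tier,
      service_code = c("mh", "fp", "oth"), volume = c(28, 7, 65)),
    costs = tibble::tibble(
      service_code = c("mh", "fp", "oth"), cost = c(1, 1, 1),
      fn = c("MATERNAL_HEALTH", "FAMILY_PLANNING", "OTHER_HEALTH"))
  )
}

# three tiers with bottom-up totals in given proportions, single-function
# composition per service
toy_three_tiers <- function(year = 2012L, totals = c(47, 37, 16)) {
  tiers <- facility_tiers()
  list(
    volumes = tibble::tibble(
      year = as.integer(year), tier = rep(tiers, each = 3),
      service_code = rep(c("mh", "fp", "oth"), times = 3),
      volume = as.numeric(rbind(
        totals * 0.25, totals * 0.05, totals * 0.70))),
    costs = tibble::tibble(
      service_code = c("mh", "fp", "oth"), cost = c(1, 1, 1),
      fn = c("MATERNAL_HEALTH", "FAMILY_PLANNING", "OTHER_HEALTH"))
  )
}

flat_ctx <- function(base_year = 2012L) {
  monetary_context(stats::setNames(numeric(0), character(0)),
                   base_year, 1)
}

expect_cubes_equal <- function(got, want, tolerance = testthat_tolerance()) {
  key <- c("year", "agent_id", "tier", "fn")
  j <- dplyr::full_join(want, got, by = key, suffix = c("_want", "_got"))
  expect_false(any(is.na(j$amount_want)), label = "unexpected extra cells")
  expect_false(any(is.na(j$amount_got)), label = "missing cells")
  expect_equal(j$amount_got, j$amount_want, tolerance = tolerance)
}
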