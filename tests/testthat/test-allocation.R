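test_that("tier totals are the volume-times-cost sums", {
  v <- tibble::tibble(year = 2012L, tier = "PHC_CLINIC",
                      service_code = c("a", "b"), volume = c(10, 5))
  k <- tibble::tibble(service_code = c("a", "b"), cost = c(2, 3),
                      fn = c("MATERNAL_HEALTH", "OTHER_HEALTH"))
  tt <- estimate_tier_totals(v, k)
  expect_equal(tt$total, 35)

  v0 <- dplyr::mutate(v, volume = 0)
  expect_equal(estimate_tier_totals(v0, k)$total, 0)
})

test_that("a missing unit cost is an error naming the service", {
  v <- tibble::tibble(year = 2012L, tier = "PHC_CLINIC",
                      service_code = "mystery", volume = 1)
  k <- tibble::tibble(service_code = "a", cost = 1, fn = "OTHER_HEALTH")
  expect_error(estimate_tier_totals(v, k), "mystery")
  expect_error(compute_share_matrix(v, k), "mystery")
})

test_that("share matrix rows are spending fractions summing to one", {
  toy <- toy_single_tier()
  sm <- compute_share_matrix(toy$volumes, toy$costs)
  expect_equal(sm$share[sm$fn == "MATERNAL_HEALTH"], 0.28)
  expect_equal(sm$share[sm$fn == "FAMILY_PLANNING"], 0.07)
  expect_equal(sm$share[sm$fn == "OTHER_HEALTH"], 0.65)
  expect_equal(sum(sm$share), 1)
})

test_that("a tier offering only maternal services has row (1, 0, 0)", {
  v <- tibble::tibble(year = 2012L, tier = "REF_HOSPITAL_3",
                      service_code = "mh", volume = 12)
  k <- tibble::tibble(service_code = "mh", cost = 7,
                      fn = "MATERNAL_HEALTH")
  sm <- compute_share_matrix(v, k)
  expect_equal(sm$share[sm$fn == "MATERNAL_HEALTH"], 1)
  expect_equal(sm$share[sm$fn == "FAMILY_PLANNING"], 0)
  expect_equal(sm$share[sm$fn == "OTHER_HEALTH"], 0)
})

test_that("a zero-total tier has undefined shares and refuses funds", {
  toy <- toy_single_tier()
  v <- dplyr::bind_rows(
    toy$volumes,
    tibble::tibble(year = 2012L, tier = "REF_HOSPITAL_3",
                   service_code = "mh", volume = 0))
  sm <- compute_share_matrix(v, toy$costs)
  expect_true(all(is.na(sm$share[sm$tier == "REF_HOSPITAL_3"])))

  entry <- ledger_row(tier_hint = "REF_HOSPITAL_3")
  w <- tibble::tibble(year = 2012L, tier = "REF_HOSPITAL_3", weight = 1)
  expect_error(allocate_facility_funds(entry, w, sm), "undefined share")
})

test_that("earmarked funds pass through one-to-one without splitting", {
  expect_identical(nrow(allocate_earmarked(ledger_row()[0, ])), 0L)

  e <- ledger_row(agent_id = "MSPLS", amount = 568,
                  earmark = "EARMARKED_RH",
                  function_hint = "FAMILY_PLANNING",
                  category = "national_rh_programme")
  out <- allocate_earmarked(e)
  expect_identical(nrow(out), 1L)
  expect_equal(out$amount, 568)
  expect_identical(out$fn, "FAMILY_PLANNING")
  expect_identical(out$tier, "PHC_CLINIC")  # configured default tier

  two <- allocate_earmarked(dplyr::bind_rows(e, e))
  agg <- dplyr::count(two, .data$year, .data$agent_id, .data$tier, .data$fn,
                      wt = .data$amount)
  expect_equal(agg$n, 1136)
})

test_that("facility funds split by tier weight then share row, conserving totals", {
  toy <- toy_single_tier()
  sm <- compute_share_matrix(toy$volumes, toy$costs)
  w <- tibble::tibble(year = 2012L, tier = "PHC_CLINIC", weight = 1)

  out <- allocate_facility_funds(ledger_row(amount = 100), w, sm)
  expect_equal(sort(out$amount), c(7, 28, 65))

  out0 <- allocate_facility_funds(ledger_row(amount = 0), w, sm)
  expect_equal(sum(out0$amount), 0)

  # conservation across many random entries and three tiers
  toy3 <- toy_three_tiers()
  sm3 <- compute_share_matrix(toy3$volumes, toy3$costs)
  w3 <- tier_weights_from_totals(estimate_tier_totals(toy3$volumes,
                                                      toy3$costs))
  set.seed(99)
  entries <- dplyr::bind_rows(lapply(1:25, function(i) {
    ledger_row(agent_id = sample(default_agents()$agent_id, 1),
               amount = runif(1, 0, 1e7),
               category = sample(c("salaries", "equipment"), 1))
  }))
  out3 <- allocate_facility_funds(entries, w3, sm3)
  expect_equal(sum(out3$amount), sum(entries$amount))
})

test_that("a tier hint pins the whole entry to that tier", {
  toy3 <- toy_three_tiers()
  sm3 <- compute_share_matrix(toy3$volumes, toy3$costs)
  w3 <- tier_weights_from_totals(estimate_tier_totals(toy3$volumes,
                                                      toy3$costs))
  e <- ledger_row(amount = 1000, tier_hint = "REF_HOSPITAL_3")
  out <- allocate_facility_funds(e, w3, sm3)
  expect_true(all(out$tier == "REF_HOSPITAL_3"))
  expect_equal(sum(out$amount), 1000)
})

test_that("the admin distribution factor is the direct-RH ratio", {
  expect_equal(admin_distribution_factor(0, 120), 0)
  expect_equal(admin_distribution_factor(120, 120), 1)
  expect_equal(admin_distribution_factor(30, 120), 0.25)
  expect_error(admin_distribution_factor(1, 0), "no basis")
})

test_that("admin funds split into an RH-attributable part and a residual", {
  e <- ledger_row(agent_id = "MSPLS", amount = 1000,
                  earmark = "ADMIN_NATIONAL",
                  category = "central_administration")
  out <- allocate_admin(e, 0.25)
  expect_equal(out$amount[out$fn == "ADMIN_MOH"], 250)
  expect_equal(out$amount[out$fn == "OTHER_HEALTH"], 750)
  expect_true(all(out$tier == "ADMIN_NATIONAL"))

  none <- allocate_admin(e, 0)
  expect_equal(none$amount[none$fn == "ADMIN_MOH"], 0)

  mfp <- allocate_admin(
    ledger_row(agent_id = "MFP", amount = 100,
               earmark = "ADMIN_NATIONAL", category = "admin"), 0.5)
  expect_identical(sort(unique(mfp$fn)), c("ADMIN_MFP", "OTHER_HEALTH"))
})

test_that("a ledger with only earmarked entries is pure pass-through", {
  led <- dplyr::bind_rows(
    ledger_row(amount = 100, earmark = "EARMARKED_RH",
               function_hint = "MATERNAL_HEALTH"),
    ledger_row(amount = 50, earmark = "EARMARKED_RH",
               function_hint = "FAMILY_PLANNING"))
  toy <- toy_single_tier()
  alloc <- run_pipeline(led, toy$volumes, toy$costs, flat_ctx())
  expect_identical(nrow(alloc$cube), 2L)
  expect_equal(sum(alloc$cube$amount), 150)
  expect_true(all(alloc$audit$ok))
})

test_that("the pipeline is homogeneous: doubling the ledger doubles the cube", {
  scn <- generate_scenario(seed = 5)
  a1 <- run_pipeline(scn$ledger, scn$volumes, scn$unit_costs, scn$ctx)
  led2 <- dplyr::mutate(scn$ledger, amount = 2 * .data$amount)
  a2 <- run_pipeline(led2, scn$volumes, scn$unit_costs, scn$ctx)
  j <- dplyr::inner_join(a1$cube, a2$cube,
                         by = c("year", "agent_id", "tier", "fn"),
                         suffix = c("_1", "_2"))
  expect_identical(nrow(j), nrow(a1$cube))
  expect_equal(j$amount_2, 2 * j$amount_1)
})

test_that("raising maternal volume never lowers the tier's maternal share", {
  toy <- toy_single_tier()
  base <- compute_share_matrix(toy$volumes, toy$costs)
  m0 <- base$share[base$fn == "MATERNAL_HEALTH"]
  for (extra in c(1, 10, 100, 1000)) {
    v <- toy$volumes
    v$volume[v$service_code == "mh"] <- v$volume[v$service_code == "mh"] +
      extra
    m1 <- compute_share_matrix(v, toy$costs)
    expect_gte(m1$share[m1$fn == "MATERNAL_HEALTH"], m0)
    m0 <- m1$share[m1$fn == "MATERNAL_HEALTH"]
  }
})

test_that("pooled facility funds land on tiers in bottom-up proportions", {
  toy3 <- toy_three_tiers(totals = c(47, 37, 16))
  entries <- ledger_row(amount = 1e6)
  w3 <- tier_weights_from_totals(estimate_tier_totals(toy3$volumes,
                                                      toy3$costs))
  sm3 <- compute_share_matrix(toy3$volumes, toy3$costs)
  out <- allocate_facility_funds(entries, w3, sm3)
  marg <- out |>
    dplyr::count(.data$tier, wt = .data$amount, name = "amount") |>
    dplyr::mutate(p = .data$amount / sum(.data$amount)) |>
    dplyr::arrange(dplyr::desc(.data$p))
  expect_equal(marg$p, c(0.47, 0.37, 0.16))
})

test_that("an invalid ledger stops the pipeline with a stage-labelled error", {
  toy <- toy_single_tier()
  led <- ledger_row(amount = -1)
  expect_error(run_pipeline(led, toy$volumes, toy$costs, flat_ctx()),
               "\\[validate\\]")
})
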