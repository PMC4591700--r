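test_that("an empty ledger validates vacuously", {
  empty <- ledger_row()[0, ]
  expect_identical(nrow(validate_ledger(empty)), 0L)
})

test_that("validation flags the accounting rule breaches row by row", {
  led <- dplyr::bind_rows(
    ledger_row(earmark = "EARMARKED_RH", function_hint = NA),      # 1
    ledger_row(amount = -5),                                       # 2
    ledger_row(agent_id = "NOT_AN_AGENCY"),                        # 3
    ledger_row(earmark = "ADMIN_NATIONAL", tier_hint = "PHC_CLINIC"), # 4
    ledger_row(tier_hint = "ADMIN_NATIONAL"),                      # 5
    ledger_row(earmark = "EARMARKED_RH",
               function_hint = "FAMILY_PLANNING")                  # valid
  )
  v <- validate_ledger(led)
  expect_setequal(v$row, 1:5)
  expect_identical(v$field[v$row == 1], "function_hint")
  expect_identical(v$field[v$row == 2], "amount")
  expect_identical(v$field[v$row == 3], "agent_id")
  expect_true(all(v$field[v$row %in% 4:5] == "tier_hint"))
})

test_that("an earmarked entry hinting a non-RH function is rejected", {
  led <- ledger_row(earmark = "EARMARKED_RH", function_hint = "OTHER_HEALTH")
  v <- validate_ledger(led)
  expect_identical(v$field, "function_hint")
})

test_that("agent aliases resolve to the canonical taxonomy id", {
  led <- ledger_row(agent_id = "Ministry of National Education")
  expect_identical(nrow(validate_ledger(led)), 0L)
  expect_identical(resolve_agents(led)$agent_id, "MHER")
})

test_that("generated scenario ledgers are valid by construction", {
  scn <- generate_scenario(seed = 1)
  expect_identical(nrow(validate_ledger(scn$ledger)), 0L)
})

test_that("ledger, volume and unit-cost CSVs round-trip every field", {
  led <- dplyr::bind_rows(
    ledger_row(amount = 1234567.89, category = "PBF subsidies"),
    ledger_row(earmark = "EARMARKED_RH", function_hint = "MATERNAL_HEALTH",
               tier_hint = "REF_HOSPITAL_3", amount = 0.01))
  p <- withr::local_tempfile(fileext = ".csv")
  write_ledger(led, p)
  expect_identical(as.data.frame(read_ledger(p)), as.data.frame(led))

  scn <- generate_scenario(seed = 3)
  pv <- withr::local_tempfile(fileext = ".csv")
  write_volumes(scn$volumes, pv)
  expect_identical(as.data.frame(read_volumes(pv)),
                   as.data.frame(scn$volumes))
  pc <- withr::local_tempfile(fileext = ".csv")
  write_unit_costs(scn$unit_costs, pc)
  expect_identical(as.data.frame(read_unit_costs(pc)),
                   as.data.frame(scn$unit_costs))
})

test_that("every code in a generated scenario resolves to the taxonomy", {
  scn <- generate_scenario(seed = 2)
  tax <- taxonomy()
  expect_true(all(scn$ledger$agent_id %in% tax$agents$agent_id))
  expect_true(all(scn$ledger$earmark %in% earmark_codes()))
  expect_true(all(stats::na.omit(scn$ledger$tier_hint) %in% tier_codes()))
  expect_true(all(scn$volumes$tier %in% facility_tiers()))
  expect_true(all(scn$unit_costs$fn %in% facility_functions()))
  expect_true(all(scn$volumes$service_code %in%
                    scn$unit_costs$service_code))
})

test_that("taxonomy YAML round-trips and rejects unknown functions", {
  tax <- taxonomy()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_taxonomy(tax, p)
  back <- read_taxonomy(p)
  expect_identical(back$agents, tax$agents)
  expect_identical(back$service_functions, tax$service_functions)

  bad <- default_service_functions()
  bad$fn[1] <- "DENTISTRY"
  expect_error(taxonomy(service_functions = bad), "unknown facility function")
})

test_that("unparseable or incomplete input files raise named errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,agent_id,amount,earmark,function_hint,tier_hint,category",
               "2012,MSPLS,not_a_number,EARMARKED_RH,,,x"), p)
  expect_error(read_ledger(p), "row 1.*amount")
  expect_error(read_ledger(file.path(tempdir(), "nope.csv")), "not found")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,tier", "2012,PHC_CLINIC"), p2)
  expect_error(read_volumes(p2), "missing column")
})
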