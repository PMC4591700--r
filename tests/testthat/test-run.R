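# file-level entry points: simulate, run, verify-tables, validate

write_run_yaml <- function(dir, scn, out = "out") {
  cfg <- list(
    paths = list(ledger = "ledger.csv", volumes = "volumes.csv",
                 unit_costs = "unit_costs.csv"),
    monetary = list(base_year = scn$ctx$base_year,
                    ppp_factor = scn$ctx$ppp_factor,
                    inflation = as.list(scn$ctx$inflation)),
    output_dir = out)
  path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, path)
  path
}

test_that("rhs_run produces the full output set and a passing audit", {
  d <- withr::local_tempdir()
  scn <- rhs_simulate(13, d, quiet = TRUE)
  res <- rhs_run(write_run_yaml(d, scn), quiet = TRUE)
  expect_true(res$ok)
  out <- file.path(d, "out")
  expect_setequal(list.files(out),
                  c("cube.csv", "cube.json", "indicators.json", "run.log",
                    "table_agent.csv", "table_agent.txt", "table_fn.csv",
                    "table_fn.txt", "table_provider.csv",
                    "table_provider.txt"))
  expect_match(paste(readLines(file.path(out, "run.log")), collapse = " "),
               "conservation passed")

  # the written cube equals the recovered ground truth in thousands
  cube <- readr::read_csv(file.path(out, "cube.csv"),
                          show_col_types = FALSE)
  gt <- scn$ground_truth
  j <- dplyr::inner_join(cube, gt,
                         by = c("year", "agent_id", "tier", "fn"))
  expect_identical(nrow(j), nrow(gt))
  expect_equal(j$amount_intl_thousands, j$amount / 1e3)
})

test_that("identical inputs produce byte-identical outputs", {
  d <- withr::local_tempdir()
  scn <- rhs_simulate(21, d, quiet = TRUE)
  cfgp <- write_run_yaml(d, scn)
  rhs_run(cfgp, out_dir = file.path(d, "o1"), quiet = TRUE)
  rhs_run(cfgp, out_dir = file.path(d, "o2"), quiet = TRUE)
  for (f in list.files(file.path(d, "o1"))) {
    expect_identical(readLines(file.path(d, "o1", f), warn = FALSE),
                     readLines(file.path(d, "o2", f), warn = FALSE),
                     label = f)
  }
})

test_that("a missing input file fails before any computation, naming the path", {
  d <- withr::local_tempdir()
  scn <- rhs_simulate(3, d, quiet = TRUE)
  file.remove(file.path(d, "unit_costs.csv"))
  expect_error(rhs_run(write_run_yaml(d, scn), quiet = TRUE),
               "unit_costs\\.csv")
})

test_that("verify-tables passes on the intact fixture and isolates corruption", {
  checks <- rhs_verify_tables(quiet = TRUE)
  expect_true(all(checks$pass))
  expect_true(attr(checks, "ok"))

  fx <- burundi_printed()
  fx$agents$amount[fx$agents$agent_id == "MSPLS" & fx$agents$year == 2012] <-
    fx$agents$amount[fx$agents$agent_id == "MSPLS" &
                       fx$agents$year == 2012] + 1000
  bad <- rhs_verify_tables(fx, quiet = TRUE)
  expect_false(bad$pass[bad$target == "agent_table_shares"])
  expect_false(bad$pass[bad$target == "agent_sums_equal_rh_totals"])
  expect_true(bad$pass[bad$target == "provider_table_shares"])
  expect_true(bad$pass[bad$target == "function_table_shares"])
  expect_true(bad$pass[bad$target == "rh_growth_2010_2012"])
})

test_that("rhs_validate reports violations from a ledger file", {
  d <- withr::local_tempdir()
  led <- dplyr::bind_rows(
    ledger_row(),
    ledger_row(earmark = "EARMARKED_RH", function_hint = NA))
  p <- file.path(d, "ledger.csv")
  write_ledger(led, p)
  viol <- rhs_validate(p, quiet = TRUE)
  expect_identical(nrow(viol), 1L)
  expect_identical(viol$row, 2L)

  ok <- rhs_validate({
    p2 <- file.path(d, "ok.csv")
    write_ledger(ledger_row(), p2)
    p2
  }, quiet = TRUE)
  expect_identical(nrow(ok), 0L)
})

test_that("tidy, glance and autoplot expose the allocation result", {
  scn <- generate_scenario(seed = 2)
  alloc <- run_pipeline(scn$ledger, scn$volumes, scn$unit_costs, scn$ctx)
  td <- tidy(alloc)
  expect_identical(nrow(td), nrow(alloc$cube))
  expect_true(all(c("is_rh", "amount") %in% names(td)))
  gl <- glance(alloc)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$conserved)
  expect_equal(gl$total_allocated, sum(alloc$cube$amount))
  p <- autoplot(alloc)
  expect_s3_class(p, "ggplot")
  p2 <- plot_share_matrix(alloc$share_matrix)
  expect_s3_class(p2, "ggplot")
})
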