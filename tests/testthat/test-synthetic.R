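test_that("generation is deterministic given the seed", {
  a <- generate_scenario(seed = 4)
  b <- generate_scenario(seed = 4)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$ground_truth, b$ground_truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(a, d1)
  write_scenario(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }

  c_ <- generate_scenario(seed = 5)
  expect_false(identical(a$ledger$amount, c_$ledger$amount))
})

test_that("the implied share matrix hits the calibration targets", {
  scn <- generate_scenario(seed = 1)
  sm <- compute_share_matrix(scn$volumes, scn$unit_costs)
  j <- dplyr::inner_join(sm, scn$config$target_shares,
                         by = c("tier", "fn"), suffix = c("_got", "_want"))
  expect_identical(nrow(j), nrow(sm))
  expect_lt(max(abs(j$share_got - j$share_want)), 1e-6)
})

test_that("the ledger's earmark-class mix matches the configured mix", {
  cfg <- scenario_config()
  scn <- generate_scenario(cfg, seed = 8)
  mix <- scn$ledger |>
    dplyr::count(.data$earmark, wt = .data$amount, name = "amount") |>
    dplyr::mutate(p = .data$amount / sum(.data$amount))
  want <- cfg$earmark_mix[mix$earmark]
  expect_equal(mix$p, unname(want), tolerance = 1e-6)
})

test_that("the pipeline recovers the constructed ground truth", {
  scn <- generate_scenario(seed = 1)
  alloc <- run_pipeline(scn$ledger, scn$volumes, scn$unit_costs, scn$ctx)
  expect_cubes_equal(alloc$cube, scn$ground_truth)
  expect_true(all(alloc$audit$ok))
})

test_that("a zero family-planning target yields zero FP spending end-to-end", {
  targets <- burundi_share_targets(2012) |>
    dplyr::select("tier", "fn", "share")
  targets$share[targets$fn == "OTHER_HEALTH"] <-
    targets$share[targets$fn == "OTHER_HEALTH"] +
    targets$share[targets$fn == "FAMILY_PLANNING"]
  targets$share[targets$fn == "FAMILY_PLANNING"] <- 0
  scn <- generate_scenario(scenario_config(target_shares = targets), seed = 2)
  alloc <- run_pipeline(scn$ledger, scn$volumes, scn$unit_costs, scn$ctx)
  # only the earmarked FP programme line remains; facility FP is zero
  fac_fp <- dplyr::filter(alloc$detail, .data$fn == "FAMILY_PLANNING",
                          .data$strategy == "facility")
  expect_equal(sum(fac_fp$amount), 0)
})

test_that("infeasible targets are a config error", {
  targets <- tibble::tibble(
    tier = rep(facility_tiers(), each = 3),
    fn = rep(facility_functions(), times = 3),
    share = rep(c(0.3, 0.2, 0.5), times = 3))
  no_fp_costs <- dplyr::filter(default_unit_costs(),
                               .data$fn != "FAMILY_PLANNING")
  expect_error(scenario_config(target_shares = targets,
                               unit_costs = no_fp_costs),
               "no service mapped")
})

test_that("perturbation at noise zero is the identity and negative noise errors", {
  scn <- generate_scenario(seed = 6)
  expect_identical(perturb_scenario(scn, 0), scn)
  expect_error(perturb_scenario(scn, -0.1), "non-negative")
})

test_that("perturbed scenarios stay internally consistent and noise shrinks the error", {
  scn <- generate_scenario(seed = 6)
  w0 <- tier_weights_from_totals(scn$tier_totals)

  mae <- function(noise, reps, seed0) {
    errs <- vapply(seq_len(reps), function(r) {
      p <- perturb_scenario(scn, noise, seed = seed0 + r)
      w <- tier_weights_from_totals(
        estimate_tier_totals(p$volumes, p$unit_costs))
      j <- dplyr::inner_join(w, w0, by = c("year", "tier"),
                             suffix = c("_p", "_0"))
      mean(abs(j$weight_p - j$weight_0))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(mae(0.02, 5, 100), mae(0.3, 5, 200))

  # the pipeline still recovers the recomputed ground truth exactly
  p <- perturb_scenario(scn, 0.1)
  alloc <- run_pipeline(p$ledger, p$volumes, p$unit_costs, p$ctx)
  expect_cubes_equal(alloc$cube, p$ground_truth)
})

test_that("scenario directories round-trip through write and read", {
  scn <- generate_scenario(seed = 9)
  d <- withr::local_tempdir()
  write_scenario(scn, d)
  expect_identical(readLines(file.path(d, "ledger.csv"), n = 1), "# seed: 9")
  back <- read_scenario(d)
  expect_equal(as.data.frame(back$ledger), as.data.frame(scn$ledger))
  expect_equal(as.data.frame(back$volumes), as.data.frame(scn$volumes))
  expect_equal(as.data.frame(back$ground_truth),
               as.data.frame(scn$ground_truth))
  expect_identical(back$seed, 9L)
  expect_equal(back$ctx$inflation, scn$ctx$inflation)
})
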