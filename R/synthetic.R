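#' Default unit-cost catalogue for synthetic scenarios
#'
#' Local-currency costs per service unit on the scale of a low-income
#' three-tier system (thousands of francs for deliveries and inpatient
#' days, less for consultations).
#'
#' @return Tibble `service_code, cost, fn`.
#' @export
default_unit_costs <- function() {
  tibble::tibble(
    service_code = c("delivery", "anc_visit", "postnatal_visit",
                     "fp_consult", "contraceptive_supply",
                     "outpatient_visit", "inpatient_day"),
    cost = c(15000, 3000, 2500, 1200, 800, 2500, 20000),
    fn = c("MATERNAL_HEALTH", "MATERNAL_HEALTH", "MATERNAL_HEALTH",
           "FAMILY_PLANNING", "FAMILY_PLANNING",
           "OTHER_HEALTH", "OTHER_HEALTH")
  )
}

#' Synthetic scenario configuration
#'
#' Defines the study conditions a generated scenario emulates: a
#' three-tier provider system financed by six public agents over three
#' years, with the three earmark classes of ledger entries. Defaults
#' echo the published Burundi sub-account: a public health budget of
#' 100 billion nominal francs growing 5 % a year, facility totals split
#' 0.47/0.37/0.16 across tiers, the 2012 published facility composition
#' as the target share matrix, 2 % of the budget earmarked for RH, 12 %
#' national administration, health-ministry-dominated agent mix, Burundi-
#' scale inflation and a PPP factor of 505 francs per international
#' dollar.
#'
#' @param years Integer vector of study years.
#' @param budget Nominal local-currency public health budget in the first
#'   year.
#' @param budget_growth Annual nominal growth of the budget.
#' @param facility_sector_total First-year total facility expenditure (all
#'   financing sources) implied by volumes times unit costs; only its
#'   split across tiers and functions matters downstream.
#' @param tier_split Named fractions over the three facility tiers,
#'   summing to one.
#' @param target_shares Tibble `tier, fn, share`; each tier's row over the
#'   three facility functions must sum to one.
#' @param earmark_mix Named fractions over the three earmark classes,
#'   summing to one.
#' @param agent_mix Named fractions over the six agents, summing to one.
#' @param unit_costs Unit-cost tibble (`service_code, cost, fn`).
#' @param inflation Named annual inflation rates covering every year after
#'   the first; defaults to the Burundi-scale 9.6 % / 18 % for the default
#'   years, 12 % otherwise.
#' @param ppp_factor Local-currency units per international dollar in the
#'   base (last) year.
#' @return A list of class `rhs_scenario_config`.
#' @export
scenario_config <- function(years = 2010:2012,
                            budget = 1e11,
                            budget_growth = 0.05,
                            facility_sector_total = 1.6e11,
                            tier_split = c(PHC_CLINIC = 0.47,
                                           REF_HOSPITAL_1_2 = 0.37,
                                           REF_HOSPITAL_3 = 0.16),
                            target_shares = NULL,
                            earmark_mix = c(EARMARKED_RH = 0.02,
                                            FACILITY_NONEARMARKED = 0.86,
                                            ADMIN_NATIONAL = 0.12),
                            agent_mix = c(MSPLS = 0.73, MFP = 0.19,
                                          MHER = 0.02, MPS = 0.02,
                                          MND = 0.03, MNS = 0.01),
                            unit_costs = default_unit_costs(),
                            inflation = NULL,
                            ppp_factor = 505) {
  if (is.null(target_shares)) {
    target_shares <- burundi_share_targets(2012) |>
      dplyr::select("tier", "fn", "share")
  }
  if (is.null(inflation)) {
    later <- as.character(years[-1])
    inflation <- if (identical(as.integer(years), 2010:2012)) {
      c("2011" = 0.096, "2012" = 0.18)
    } else {
      stats::setNames(rep(0.12, length(later)), later)
    }
  }
  stopifnot(abs(sum(tier_split) - 1) < 1e-9,
            abs(sum(earmark_mix) - 1) < 1e-9,
            abs(sum(agent_mix) - 1) < 1e-9)
  rowsum_ok <- target_shares |>
    dplyr::group_by(.data$tier) |>
    dplyr::summarise(s = sum(.data$share), .groups = "drop")
  if (any(abs(rowsum_ok$s - 1) > 1e-9)) {
    abort_stage("synthetic", "target share rows must sum to 1")
  }
  fns_available <- unique(unit_costs$fn)
  fns_needed <- unique(target_shares$fn[target_shares$share > 0])
  missing_fn <- setdiff(fns_needed, fns_available)
  if (length(missing_fn) > 0) {
    abort_stage("synthetic", "target share requires function(s) with no ",
                "service mapped to them: ", paste(missing_fn, collapse = ", "))
  }
  structure(
    list(years = as.integer(years), budget = budget,
         budget_growth = budget_growth,
         facility_sector_total = facility_sector_total,
         tier_split = tier_split, target_shares = target_shares,
         earmark_mix = earmark_mix, agent_mix = agent_mix,
         unit_costs = unit_costs, inflation = inflation,
         ppp_factor = ppp_factor),
    class = "rhs_scenario_config")
}

# split an integer total across k parts by fractions, last part absorbs
# the rounding remainder so the parts sum exactly
split_integer <- function(total, fractions) {
  parts <- floor(total * fractions[-length(fractions)] + 0.5)
  c(parts, total - sum(parts))
}

#' Generate a synthetic scenario with known ground truth
#'
#' Builds a complete, internally consistent input set — service volumes
#' back-solved from the target share matrix and tier split given fixed
#' unit costs, a transaction ledger matching the earmark and agent mixes,
#' and a monetary context — together with the allocation cube the inputs
#' imply, computed by construction with plain per-entry arithmetic. The
#' pipeline is expected to recover this cube exactly (to double
#' rounding), which is the package's main end-to-end oracle. A single
#' pseudo-random stream (category splits of facility funds) is drawn from
#' `seed`; everything else is deterministic back-solving.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; the same seed always reproduces the same
#'   scenario byte for byte.
#' @return A list of class `rhs_scenario`: `ledger`, `volumes`,
#'   `unit_costs`, `ctx`, `ground_truth` (cube tibble), `implied_shares`,
#'   `config`, `seed`.
#' @export
generate_scenario <- function(config = scenario_config(), seed = 1) {
  old <- save_rng_state()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  years <- config$years
  base_year <- max(years)
  ctx <- monetary_context(config$inflation, base_year, config$ppp_factor)
  costs <- config$unit_costs

  # --- volumes: deterministic back-solve from targets -----------------
  vol <- list()
  for (i in seq_along(years)) {
    y <- years[i]
    sector <- config$facility_sector_total * (1 + config$budget_growth)^(i - 1)
    for (t in names(config$tier_split)) {
      t_total <- sector * config$tier_split[[t]]
      for (f in facility_functions()) {
        share <- config$target_shares$share[
          config$target_shares$tier == t & config$target_shares$fn == f]
        if (length(share) == 0) share <- 0
        svc <- costs[costs$fn == f, ]
        if (nrow(svc) == 0) next
        per_svc <- t_total * share / nrow(svc)
        vol[[length(vol) + 1]] <- tibble::tibble(
          year = y, tier = t, service_code = svc$service_code,
          volume = floor(per_svc / svc$cost + 0.5))
      }
    }
  }
  volumes <- dplyr::bind_rows(vol) |>
    dplyr::arrange(.data$year, .data$tier, .data$service_code)

  # --- ledger: integer amounts, class and agent mixes exact -----------
  agents <- names(config$agent_mix)
  led <- list()
  for (i in seq_along(years)) {
    y <- years[i]
    b <- floor(config$budget * (1 + config$budget_growth)^(i - 1) + 0.5)
    class_amt <- split_integer(b, config$earmark_mix)
    names(class_amt) <- names(config$earmark_mix)

    em <- split_integer(class_amt[["EARMARKED_RH"]], c(0.65, 0.35))
    led[[length(led) + 1]] <- tibble::tibble(
      year = y, agent_id = "MSPLS", amount = em,
      earmark = "EARMARKED_RH",
      function_hint = c("MATERNAL_HEALTH", "FAMILY_PLANNING"),
      tier_hint = NA_character_,
      category = c("national_rh_programme", "national_rh_programme_fp"))

    fac_by_agent <- split_integer(class_amt[["FACILITY_NONEARMARKED"]],
                                  config$agent_mix)
    for (k in seq_along(agents)) {
      a <- agents[k]
      cats <- c("salaries", "pbf_subsidies", "construction_equipment")
      frac <- stats::runif(length(cats))
      frac <- frac / sum(frac)
      amts <- split_integer(fac_by_agent[k], frac)
      # the higher-education ministry funds the teaching hospital directly
      hint <- if (a == "MHER") "REF_HOSPITAL_3" else NA_character_
      led[[length(led) + 1]] <- tibble::tibble(
        year = y, agent_id = a, amount = amts,
        earmark = "FACILITY_NONEARMARKED", function_hint = NA_character_,
        tier_hint = hint, category = cats)
    }

    adm <- split_integer(class_amt[["ADMIN_NATIONAL"]], c(0.6, 0.4))
    led[[length(led) + 1]] <- tibble::tibble(
      year = y, agent_id = c("MSPLS", "MFP"), amount = adm,
      earmark = "ADMIN_NATIONAL", function_hint = NA_character_,
      tier_hint = NA_character_, category = "central_administration")
  }
  ledger <- dplyr::bind_rows(led) |>
    dplyr::mutate(year = as.integer(.data$year))

  gt <- construct_ground_truth(ledger, volumes, costs, ctx)

  structure(
    list(ledger = ledger, volumes = volumes, unit_costs = costs, ctx = ctx,
         ground_truth = gt$cube, implied_shares = gt$shares,
         tier_totals = gt$tier_totals, admin_factor = gt$admin_factor,
         config = config, seed = seed),
    class = "rhs_scenario")
}

# restore RNG state helper: returns a closure restoring the state at call
save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
  }
}

#' @export
print.rhs_scenario <- function(x, ...) {
  cat("<rhs_scenario> seed", x$seed, "\n")
  cat("  years  :", paste(range(x$config$years), collapse = "-"), "\n")
  cat("  ledger :", nrow(x$ledger), "entries,",
      format(sum(x$ledger$amount), big.mark = ","),
      "nominal local currency units\n")
  cat("  volumes:", nrow(x$volumes), "service-volume records\n")
  invisible(x)
}

#' Construction-based ground-truth allocation
#'
#' Computes the allocation cube an input set implies using plain
#' per-entry arithmetic loops (no grouped pipeline code): each ledger row
#' is adjusted and allocated independently, then cells are summed. Used
#' as the generator's ground truth and as the brute-force oracle the
#' pipeline is checked against.
#'
#' @inheritParams run_pipeline
#' @return A list: `cube`, `shares`, `tier_totals`, `admin_factor`.
#' @export
construct_ground_truth <- function(ledger, volumes, costs, ctx,
                                   default_earmark_tier = "PHC_CLINIC",
                                   mfp_agent = "MFP") {
  cost_by_svc <- stats::setNames(costs$cost, costs$service_code)
  fn_by_svc <- stats::setNames(costs$fn, costs$service_code)
  years <- sort(unique(ledger$year))

  # tier totals and shares per year, by simple accumulation
  tt <- list(); sh <- list()
  for (y in years) {
    vy <- volumes[volumes$year == y, ]
    for (t in unique(vy$tier)) {
      vt <- vy[vy$tier == t, ]
      spend_f <- c(MATERNAL_HEALTH = 0, FAMILY_PLANNING = 0, OTHER_HEALTH = 0)
      for (j in seq_len(nrow(vt))) {
        s <- vt$service_code[j]
        spend_f[[fn_by_svc[[s]]]] <- spend_f[[fn_by_svc[[s]]]] +
          vt$volume[j] * cost_by_svc[[s]]
      }
      tot <- sum(spend_f)
      tt[[length(tt) + 1]] <- tibble::tibble(year = y, tier = t, total = tot)
      sh[[length(sh) + 1]] <- tibble::tibble(
        year = y, tier = t, fn = names(spend_f),
        share = if (tot > 0) unname(spend_f) / tot else NA_real_)
    }
  }
  tier_totals <- dplyr::bind_rows(tt)
  shares <- dplyr::bind_rows(sh)

  cells <- new.env(parent = emptyenv())
  addc <- function(y, a, t, f, amt) {
    key <- paste(y, a, t, f, sep = "\r")
    cells[[key]] <- (cells[[key]] %||% 0) + amt
  }

  adj <- function(amount, y) {
    f <- 1
    if (y < ctx$base_year) {
      for (yy in seq(y + 1, ctx$base_year)) {
        f <- f * (1 + ctx$inflation[[as.character(yy)]])
      }
    }
    amount * f / ctx$ppp_factor
  }

  direct_rh <- stats::setNames(rep(0, length(years)), years)
  direct_tot <- stats::setNames(rep(0, length(years)), years)

  non_admin <- ledger[ledger$earmark != "ADMIN_NATIONAL", ]
  for (i in seq_len(nrow(non_admin))) {
    e <- non_admin[i, ]
    a <- adj(e$amount, e$year)
    ykey <- as.character(e$year)
    if (e$earmark == "EARMARKED_RH") {
      t <- if (is.na(e$tier_hint)) default_earmark_tier else e$tier_hint
      addc(e$year, e$agent_id, t, e$function_hint, a)
      direct_rh[[ykey]] <- direct_rh[[ykey]] + a
      direct_tot[[ykey]] <- direct_tot[[ykey]] + a
    } else {
      yt <- tier_totals[tier_totals$year == e$year, ]
      ys <- shares[shares$year == e$year, ]
      if (is.na(e$tier_hint)) {
        w <- stats::setNames(yt$total / sum(yt$total), yt$tier)
      } else {
        w <- stats::setNames(1, e$tier_hint)
      }
      for (t in names(w)) {
        for (f in facility_functions()) {
          s <- ys$share[ys$tier == t & ys$fn == f]
          if (length(s) == 0 || is.na(s)) {
            abort_stage("oracle", "undefined share for tier ", t)
          }
          amt <- a * w[[t]] * s
          addc(e$year, e$agent_id, t, f, amt)
          direct_tot[[ykey]] <- direct_tot[[ykey]] + amt
          if (f %in% rh_functions()) {
            direct_rh[[ykey]] <- direct_rh[[ykey]] + amt
          }
        }
      }
    }
  }

  admin <- ledger[ledger$earmark == "ADMIN_NATIONAL", ]
  factors <- tibble::tibble(year = integer(), factor = numeric())
  if (nrow(admin) > 0) {
    factors <- tibble::tibble(
      year = as.integer(names(direct_tot)),
      factor = unname(direct_rh / direct_tot))
    for (i in seq_len(nrow(admin))) {
      e <- admin[i, ]
      a <- adj(e$amount, e$year)
      fac <- factors$factor[factors$year == e$year]
      f_rh <- if (e$agent_id == mfp_agent) "ADMIN_MFP" else "ADMIN_MOH"
      addc(e$year, e$agent_id, "ADMIN_NATIONAL", f_rh, a * fac)
      addc(e$year, e$agent_id, "ADMIN_NATIONAL", "OTHER_HEALTH",
           a * (1 - fac))
    }
  }

  keys <- ls(cells)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  cube <- tibble::tibble(
    year = as.integer(vapply(parts, `[[`, "", 1)),
    agent_id = vapply(parts, `[[`, "", 2),
    tier = vapply(parts, `[[`, "", 3),
    fn = vapply(parts, `[[`, "", 4),
    amount = vapply(keys, function(k) cells[[k]], numeric(1),
                    USE.NAMES = FALSE)) |>
    dplyr::arrange(.data$year, .data$agent_id, .data$tier, .data$fn)

  list(cube = cube, shares = shares, tier_totals = tier_totals,
       admin_factor = factors)
}

#' Perturb a scenario's service volumes
#'
#' Multiplies every service volume by independent log-normal noise
#' (median one) and recomputes the implied ground truth, supporting
#' robustness studies of the distribution factors. Noise level zero
#' returns the scenario unchanged.
#'
#' @param scenario An `rhs_scenario`.
#' @param noise_level Standard deviation of the log-normal noise on the
#'   log scale; must be non-negative.
#' @param seed Seed for the noise stream (defaults to the scenario seed
#'   plus one).
#' @return A perturbed `rhs_scenario`.
#' @export
perturb_scenario <- function(scenario, noise_level, seed = scenario$seed + 1) {
  if (!is.numeric(noise_level) || noise_level < 0) {
    abort_stage("synthetic", "noise_level must be non-negative")
  }
  if (noise_level == 0) return(scenario)
  old <- save_rng_state()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  volumes <- scenario$volumes |>
    dplyr::mutate(volume = floor(.data$volume *
      stats::rlnorm(dplyr::n(), 0, noise_level) + 0.5))
  gt <- construct_ground_truth(scenario$ledger, volumes,
                               scenario$unit_costs, scenario$ctx)
  out <- scenario
  out$volumes <- volumes
  out$ground_truth <- gt$cube
  out$implied_shares <- gt$shares
  out$tier_totals <- gt$tier_totals
  out$admin_factor <- gt$admin_factor
  out
}

#' Write or read a scenario directory
#'
#' Writes the full input-file set (`ledger.csv`, `volumes.csv`,
#' `unit_costs.csv`, `config.yaml`) plus `ground_truth.csv` into a
#' directory; every CSV starts with a `# seed: N` comment line. Reading
#' the directory back reproduces the scenario inputs.
#'
#' @param scenario An `rhs_scenario`.
#' @param dir Directory path (created if needed).
#' @return `write_scenario()` returns `dir` invisibly; `read_scenario()`
#'   returns a list with `ledger`, `volumes`, `unit_costs`, `ctx`,
#'   `ground_truth`, `seed`.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# seed: %d", scenario$seed)
  wr <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(stamp, path)
    readr::write_csv(df, path, na = "", append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  wr(scenario$ledger, "ledger.csv")
  wr(scenario$volumes, "volumes.csv")
  wr(scenario$unit_costs, "unit_costs.csv")
  wr(scenario$ground_truth, "ground_truth.csv")
  yaml::write_yaml(list(
    seed = scenario$seed,
    monetary = list(
      base_year = scenario$ctx$base_year,
      ppp_factor = scenario$ctx$ppp_factor,
      inflation = as.list(scenario$ctx$inflation)),
    years = as.integer(scenario$config$years)),
    file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  rd <- function(file, types) {
    readr::read_csv(file.path(dir, file), col_types = types, comment = "#",
                    progress = FALSE)
  }
  list(
    ledger = rd("ledger.csv", ledger_cols()),
    volumes = rd("volumes.csv", readr::cols(
      year = readr::col_integer(), tier = readr::col_character(),
      service_code = readr::col_character(), volume = readr::col_double())),
    unit_costs = rd("unit_costs.csv", readr::cols(
      service_code = readr::col_character(), cost = readr::col_double(),
      fn = readr::col_character())),
    ground_truth = rd("ground_truth.csv", readr::cols(
      year = readr::col_integer(), agent_id = readr::col_character(),
      tier = readr::col_character(), fn = readr::col_character(),
      amount = readr::col_double())),
    ctx = monetary_context(unlist(cfg$monetary$inflation),
                           cfg$monetary$base_year,
                           cfg$monetary$ppp_factor),
    seed = as.integer(cfg$seed))
}
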