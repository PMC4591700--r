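#' Read a run configuration
#'
#' A run configuration names the input files (relative paths are resolved
#' against the config file's directory), the monetary context, the
#' demographic parameters and optional auxiliary totals (total public
#' health expenditure and GDP by year, already in the reporting unit) for
#' the summary indicators. Every referenced file must exist and parse
#' before any computation starts.
#'
#' @param path Path to a YAML config file.
#' @return A list of class `rhs_run_config` with parsed inputs attached.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_stage("config", "config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(root, p)
    p
  }
  paths <- cfg$paths %||% list()
  for (key in c("ledger", "volumes", "unit_costs")) {
    if (is.null(paths[[key]])) {
      abort_stage("config", "missing required path: ", key)
    }
  }
  ledger_path <- resolve(paths$ledger)
  volumes_path <- resolve(paths$volumes)
  costs_path <- resolve(paths$unit_costs)
  tax <- if (!is.null(paths$taxonomy)) {
    read_taxonomy(resolve(paths$taxonomy))
  } else {
    taxonomy()
  }
  mon <- cfg$monetary
  if (is.null(mon)) abort_stage("config", "missing monetary section")
  ctx <- monetary_context(unlist(mon$inflation %||% list()),
                          mon$base_year, mon$ppp_factor)
  demo <- if (!is.null(cfg$demography)) {
    demography_params(
      population_by_year = unlist(cfg$demography$population_by_year),
      wcba_fraction = cfg$demography$wcba_fraction %||% 0.237,
      delivery_fraction = cfg$demography$delivery_fraction %||% 0.05,
      annual_growth = cfg$demography$annual_growth %||% 0.024)
  } else {
    demography_params()
  }
  as_year_tbl <- function(x, col) {
    if (is.null(x)) return(NULL)
    v <- unlist(x)
    out <- tibble::tibble(year = as.integer(names(v)),
                          value = as.numeric(v))
    names(out)[2] <- col
    out
  }
  structure(list(
    ledger = read_ledger(ledger_path),
    volumes = read_volumes(volumes_path),
    unit_costs = read_unit_costs(costs_path),
    tax = tax, ctx = ctx, demography = demo,
    health_total_by_year = as_year_tbl(cfg$aux$health_total_by_year,
                                       "health_total"),
    gdp_by_year = as_year_tbl(cfg$aux$gdp_by_year, "gdp"),
    decimals = cfg$report$decimals %||% 1,
    default_earmark_tier = cfg$default_earmark_tier %||% "PHC_CLINIC",
    output_dir = resolve(cfg$output_dir %||% "rhsa_output")),
    class = "rhs_run_config")
}

#' Run the sub-account pipeline from a configuration file
#'
#' Loads and validates all inputs, runs [run_pipeline()], and writes the
#' outputs into the output directory: the allocation cube as long-format
#' CSV (`cube.csv`, amounts in thousands of constant international
#' dollars) and JSON (`cube.json`), the three report tables as CSV and
#' aligned text, `indicators.json`, and a deterministic `run.log` with
#' the conservation audit (no timestamps, so identical inputs produce
#' byte-identical outputs). Progress goes to `stderr`.
#'
#' @param config Path to a YAML run config, or an `rhs_run_config`.
#' @param out_dir Output directory (overrides the config).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the `rhs_allocation`, the indicator
#'   tibble and `ok` (`TRUE` iff the conservation audit passed).
#' @export
rhs_run <- function(config, out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("rhsa: ", ...)
  if (!inherits(config, "rhs_run_config")) {
    say("reading configuration")
    config <- read_run_config(config)
  }
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  logline <- function(...) log_lines <<- c(log_lines, paste0(...))

  say("validating ledger")
  viol <- validate_ledger(resolve_agents(config$ledger, config$tax),
                          config$tax)
  logline("stage validate: ", nrow(viol), " violation(s)")
  if (nrow(viol) > 0) {
    readr::write_csv(viol, file.path(out_dir, "violations.csv"),
                     progress = FALSE)
    abort_stage("validate", "ledger has ", nrow(viol),
                " violation(s); see violations.csv")
  }

  say("allocating")
  alloc <- run_pipeline(config$ledger, config$volumes, config$unit_costs,
                        config$ctx, tax = config$tax,
                        default_earmark_tier = config$default_earmark_tier)
  logline("stage allocate: ", nrow(alloc$cube), " cube cells over years ",
          paste(alloc$years, collapse = ", "))

  say("writing outputs to ", out_dir)
  cube_out <- alloc$cube |>
    dplyr::transmute(year = .data$year, agent_id = .data$agent_id,
                     tier = .data$tier, fn = .data$fn,
                     amount_intl_thousands = .data$amount / 1e3)
  readr::write_csv(cube_out, file.path(out_dir, "cube.csv"),
                   progress = FALSE)
  jsonlite::write_json(cube_out, file.path(out_dir, "cube.json"),
                       dataframe = "rows", digits = NA)

  dec <- config$decimals
  tabs <- list(
    agent = build_agent_table(alloc, decimals = dec, tax = config$tax),
    provider = build_provider_table(alloc, decimals = dec,
                                    tax = config$tax),
    fn = build_function_table(alloc, decimals = dec, tax = config$tax))
  titles <- c(agent = "RH expenditure by financing agent (thousand Int$)",
              provider = "RH expenditure by health provider (thousand Int$)",
              fn = "RH expenditure by health function (thousand Int$)")
  for (nm in names(tabs)) {
    readr::write_csv(tabs[[nm]],
                     file.path(out_dir, paste0("table_", nm, ".csv")),
                     progress = FALSE)
    writeLines(render_table_text(tabs[[nm]], title = titles[[nm]]),
               file.path(out_dir, paste0("table_", nm, ".txt")))
  }

  rh <- rh_totals(alloc)
  percap <- per_capita_indicators(rh$rh_total, rh$year, config$demography)
  indicators <- dplyr::left_join(rh, percap, by = "year")
  if (!is.null(config$health_total_by_year)) {
    summ <- summary_indicators(
      rh |> dplyr::mutate(rh_total = .data$rh_total / 1e3),
      config$health_total_by_year, config$gdp_by_year)
    indicators <- dplyr::left_join(
      indicators, dplyr::select(summ, -"rh_total"), by = "year")
  }
  jsonlite::write_json(indicators, file.path(out_dir, "indicators.json"),
                       dataframe = "rows", digits = NA, na = "null")

  ok <- all(alloc$audit$ok)
  logline("stage audit: conservation ",
          if (ok) "passed" else "FAILED",
          " (max gap ", format(max(abs(alloc$audit$gap))), " Int$)")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  say("conservation audit ", if (ok) "passed" else "FAILED")
  invisible(list(allocation = alloc, indicators = indicators, ok = ok))
}

#' Generate and write a synthetic scenario (simulate command)
#'
#' @param seed Integer seed.
#' @param out_dir Directory to write the scenario files into.
#' @param config A [scenario_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the `rhs_scenario`.
#' @export
rhs_simulate <- function(seed, out_dir, config = scenario_config(),
                         quiet = FALSE) {
  scn <- generate_scenario(config, seed = seed)
  write_scenario(scn, out_dir)
  if (!quiet) {
    message("rhsa: wrote scenario (seed ", seed, ") to ", out_dir)
  }
  invisible(scn)
}

#' Verify the bundled published tables (verify-tables command)
#'
#' Runs [verify_printed_tables()] on the bundled fixture (or a supplied
#' one) and prints one pass/fail line per check.
#'
#' @param fixture A fixture list, defaulting to [burundi_printed()].
#' @param quiet Suppress the printed report.
#' @return Invisibly, the check tibble; attribute `ok` is `TRUE` iff all
#'   checks passed.
#' @export
rhs_verify_tables <- function(fixture = burundi_printed(), quiet = FALSE) {
  checks <- verify_printed_tables(fixture)
  if (!quiet) {
    for (i in seq_len(nrow(checks))) {
      message(sprintf("%-32s %s", checks$target[i],
                      if (checks$pass[i]) "PASS" else "FAIL"))
    }
    message(sum(checks$pass), "/", nrow(checks), " checks passed")
  }
  attr(checks, "ok") <- all(checks$pass)
  invisible(checks)
}

#' Validate a ledger file (validate command)
#'
#' @param ledger_path Path to a ledger CSV.
#' @param tax A [taxonomy()].
#' @param quiet Suppress messages.
#' @return Invisibly, the violations tibble (zero rows iff valid).
#' @export
rhs_validate <- function(ledger_path, tax = taxonomy(), quiet = FALSE) {
  ledger <- read_ledger(ledger_path)
  viol <- validate_ledger(ledger, tax)
  if (!quiet) {
    if (nrow(viol) == 0) {
      message("rhsa: ledger valid (", nrow(ledger), " entries)")
    } else {
      message("rhsa: ", nrow(viol), " violation(s):")
      for (i in seq_len(nrow(viol))) {
        message(sprintf("  row %d [%s]: %s", viol$row[i], viol$field[i],
                        viol$problem[i]))
      }
    }
  }
  invisible(viol)
}
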