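#' Read and write sub-account input files
#'
#' All inputs are plain UTF-8 CSV with a header row and "." as decimal
#' separator. A ledger holds one public transaction per row on a cash
#' basis (an entry belongs to the year it was paid out); volumes hold the
#' annual count of each service delivered by each facility tier; unit
#' costs hold the local-currency cost per service unit and the function
#' the service belongs to.
#'
#' @param path File path.
#' @return A tibble with typed columns; parsing problems raise an error
#'   naming the row and field.
#' @name io
NULL

ledger_cols <- function() {
  readr::cols(
    year = readr::col_integer(),
    agent_id = readr::col_character(),
    amount = readr::col_double(),
    earmark = readr::col_character(),
    function_hint = readr::col_character(),
    tier_hint = readr::col_character(),
    category = readr::col_character()
  )
}

# translate a readr parsing problem into an error naming the data row
# (file row minus header) and the offending field
raise_parse_problem <- function(df, path, what) {
  pr <- readr::problems(df)
  if (nrow(pr) == 0) return(invisible(df))
  col <- pr$col[1]
  field <- if (is.numeric(col) && col <= ncol(df)) names(df)[col]
           else as.character(col)
  abort_stage("io", sprintf("unparseable %s row in %s: row %d, field '%s'",
                            what, path, max(1L, pr$row[1] - 1L), field))
}

require_columns <- function(df, cols, path, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort_stage("io", sprintf("%s file %s is missing column(s): %s",
                              what, path, paste(miss, collapse = ", ")))
  }
  df
}

#' @describeIn io Read a transaction ledger
#'   (columns `year, agent_id, amount, earmark, function_hint, tier_hint,
#'   category`).
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) abort_stage("io", "ledger file not found: ", path)
  df <- suppressWarnings(
    readr::read_csv(path, col_types = ledger_cols(), comment = "#",
                    progress = FALSE))
  raise_parse_problem(df, path, "ledger")
  require_columns(df, c("year", "agent_id", "amount", "earmark",
                        "function_hint", "tier_hint", "category"),
                  path, "ledger")
  tibble::as_tibble(df)
}

#' @describeIn io Write a ledger (inverse of `read_ledger`; a round trip
#'   preserves every field).
#' @param df Tibble to write.
#' @export
write_ledger <- function(df, path) {
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' @describeIn io Read service volumes
#'   (columns `year, tier, service_code, volume`).
#' @export
read_volumes <- function(path) {
  if (!file.exists(path)) abort_stage("io", "volumes file not found: ", path)
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(),
    tier = readr::col_character(),
    service_code = readr::col_character(),
    volume = readr::col_double()
  ), comment = "#", progress = FALSE))
  raise_parse_problem(df, path, "volumes")
  require_columns(df, c("year", "tier", "service_code", "volume"),
                  path, "volumes")
  tibble::as_tibble(df)
}

#' @describeIn io Write service volumes.
#' @export
write_volumes <- function(df, path) {
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' @describeIn io Read unit costs (columns `service_code, cost, fn`).
#' @export
read_unit_costs <- function(path) {
  if (!file.exists(path)) abort_stage("io", "unit-cost file not found: ", path)
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    service_code = readr::col_character(),
    cost = readr::col_double(),
    fn = readr::col_character()
  ), comment = "#", progress = FALSE))
  raise_parse_problem(df, path, "unit-cost")
  require_columns(df, c("service_code", "cost", "fn"), path, "unit costs")
  tibble::as_tibble(df)
}

#' @describeIn io Write unit costs.
#' @export
write_unit_costs <- function(df, path) {
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a transaction ledger
#'
#' Checks the accounting preconditions every allocation strategy relies
#' on: non-negative amounts, a reproductive-health `function_hint` on every
#' earmarked entry, known agents / tiers / earmark classes, and national
#' administrative entries not carrying a facility earmark.
#'
#' @param ledger A ledger tibble (see [read_ledger()]).
#' @param tax An [taxonomy()] object providing the agent list.
#' @return A tibble of violations with columns `row`, `field`, `problem`;
#'   zero rows when the ledger is valid.
#' @export
#' @examples
#' validate_ledger(tibble::tibble(
#'   year = 2012L, agent_id = "MSPLS", amount = 100,
#'   earmark = "EARMARKED_RH", function_hint = NA_character_,
#'   tier_hint = NA_character_, category = "programme"
#' ))
validate_ledger <- function(ledger, tax = taxonomy()) {
  v <- list()
  add <- function(rows, field, problem) {
    if (length(rows) > 0) {
      v[[length(v) + 1]] <<- tibble::tibble(row = rows, field = field,
                                            problem = problem)
    }
  }
  if (nrow(ledger) == 0) {
    return(tibble::tibble(row = integer(), field = character(),
                          problem = character()))
  }
  idx <- seq_len(nrow(ledger))

  add(idx[is.na(ledger$amount) | ledger$amount < 0], "amount",
      "amount is missing or negative")
  canonical <- ifelse(ledger$agent_id %in% names(tax$aliases),
                      unname(tax$aliases[ledger$agent_id]), ledger$agent_id)
  add(idx[!canonical %in% tax$agents$agent_id], "agent_id", "unknown agent")
  add(idx[!ledger$earmark %in% earmark_codes()], "earmark",
      "unknown earmark class")

  earm <- ledger$earmark == "EARMARKED_RH"
  add(idx[earm & (is.na(ledger$function_hint) |
                  !ledger$function_hint %in% rh_functions())],
      "function_hint",
      "earmarked entry requires a reproductive-health function_hint")
  add(idx[!is.na(ledger$tier_hint) & !ledger$tier_hint %in% tier_codes()],
      "tier_hint", "unknown provider tier")
  add(idx[ledger$earmark == "ADMIN_NATIONAL" & !is.na(ledger$tier_hint) &
          ledger$tier_hint != "ADMIN_NATIONAL"],
      "tier_hint", "national admin entry cannot target a facility tier")
  add(idx[ledger$earmark != "ADMIN_NATIONAL" & !is.na(ledger$tier_hint) &
          ledger$tier_hint == "ADMIN_NATIONAL"],
      "tier_hint",
      "only admin-class entries may target the ADMIN_NATIONAL tier")
  add(idx[is.na(ledger$year)], "year", "missing year")

  if (length(v) == 0) {
    tibble::tibble(row = integer(), field = character(), problem = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(v), .data$row)
  }
}

#' Canonicalize agent identifiers in a ledger
#'
#' Replaces aliased agent labels (e.g. an older ministry name) with the
#' canonical `agent_id` of the taxonomy.
#'
#' @inheritParams validate_ledger
#' @return The ledger with `agent_id` canonicalized.
#' @export
resolve_agents <- function(ledger, tax = taxonomy()) {
  dplyr::mutate(ledger, agent_id = ifelse(
    .data$agent_id %in% names(tax$aliases),
    unname(tax$aliases[.data$agent_id]), .data$agent_id))
}
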