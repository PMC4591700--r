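#' Classification taxonomies for the sub-account
#'
#' The sub-account cross-classifies every expenditure by health *function*
#' (what the money buys), health *provider tier* (who finally receives it)
#' and *financing agent* (which public institution manages it). These
#' helpers return the closed code lists every other function validates
#' against.
#'
#' @return Character vector of codes.
#' @name taxonomy
NULL

#' @describeIn taxonomy All five function codes. `MATERNAL_HEALTH` and
#'   `FAMILY_PLANNING` are the reproductive-health service functions;
#'   `ADMIN_MOH` and `ADMIN_MFP` are national administration attributable to
#'   reproductive health (health ministry and social-security fund
#'   respectively); `OTHER_HEALTH` is the non-RH residual.
#' @export
function_codes <- function() {
  c("MATERNAL_HEALTH", "FAMILY_PLANNING", "OTHER_HEALTH",
    "ADMIN_MOH", "ADMIN_MFP")
}

#' @describeIn taxonomy The reproductive-health service functions.
#' @export
rh_functions <- function() c("MATERNAL_HEALTH", "FAMILY_PLANNING")

#' @describeIn taxonomy The administration functions. Report tables present
#'   these as separate rows; they count towards RH totals, unlike
#'   `OTHER_HEALTH`.
#' @export
admin_functions <- function() c("ADMIN_MOH", "ADMIN_MFP")

#' @describeIn taxonomy The functions a facility share matrix is defined
#'   over (service functions plus the non-RH residual).
#' @export
facility_functions <- function() {
  c("MATERNAL_HEALTH", "FAMILY_PLANNING", "OTHER_HEALTH")
}

#' @describeIn taxonomy All provider tiers: primary health care clinics,
#'   primary/secondary referral hospitals, third-tier referral hospitals,
#'   and the national administrative offices.
#' @export
tier_codes <- function() {
  c("PHC_CLINIC", "REF_HOSPITAL_1_2", "REF_HOSPITAL_3", "ADMIN_NATIONAL")
}

#' @describeIn taxonomy The three facility tiers (service-delivering
#'   providers; `ADMIN_NATIONAL` excluded).
#' @export
facility_tiers <- function() {
  c("PHC_CLINIC", "REF_HOSPITAL_1_2", "REF_HOSPITAL_3")
}

#' @describeIn taxonomy The three earmark classes a ledger entry can carry:
#'   funds earmarked for an RH function, non-earmarked funds sent to health
#'   providers, and national administrative funds.
#' @export
earmark_codes <- function() {
  c("EARMARKED_RH", "FACILITY_NONEARMARKED", "ADMIN_NATIONAL")
}

#' Default financing-agent taxonomy
#'
#' The six public agencies that receive and manage health funds in the
#' default (Burundi-like) taxonomy: the health ministry (MSPLS), the civil
#' service mutual insurance (MFP), and four further ministries. The higher
#' education ministry is the name used in published results tables;
#' "Ministry of National Education" is accepted as an alias.
#'
#' @return A tibble with columns `agent_id` and `display_name`.
#' @export
#' @examples
#' default_agents()
default_agents <- function() {
  tibble::tibble(
    agent_id = c("MSPLS", "MFP", "MHER", "MPS", "MND", "MNS"),
    display_name = c(
      "Ministry of Public Health and Fight against AIDS",
      "Civil Service Mutual Insurance (MFP)",
      "Ministry of Higher Education and Research",
      "Ministry of Public Security",
      "Ministry of National Defense",
      "Ministry of National Solidarity, Human and Gender Rights"
    )
  )
}

#' Aliases accepted for agent identifiers
#'
#' Maps alternative names onto canonical `agent_id`s. Used when reading
#' ledgers whose agent labels follow older naming.
#'
#' @return Named character vector: names are aliases, values canonical ids.
#' @export
agent_aliases <- function() {
  c("Ministry of National Education" = "MHER",
    "MEN" = "MHER")
}

#' Default service catalogue
#'
#' The published tables never enumerate the individual services behind the
#' bottom-up facility estimates, so the default catalogue is a configurable
#' stand-in: a small set of maternal-health, family-planning and other
#' services with the function each maps to.
#'
#' @return A tibble with columns `service_code` and `fn`.
#' @export
default_service_functions <- function() {
  tibble::tibble(
    service_code = c(
      "delivery", "anc_visit", "postnatal_visit",
      "fp_consult", "contraceptive_supply",
      "outpatient_visit", "inpatient_day"
    ),
    fn = c(
      "MATERNAL_HEALTH", "MATERNAL_HEALTH", "MATERNAL_HEALTH",
      "FAMILY_PLANNING", "FAMILY_PLANNING",
      "OTHER_HEALTH", "OTHER_HEALTH"
    )
  )
}

#' Assemble a taxonomy object
#'
#' @param agents Tibble with `agent_id`, `display_name` columns.
#' @param service_functions Tibble with `service_code`, `fn` columns mapping
#'   each service to a facility function.
#' @param aliases Named character vector of agent aliases.
#' @return A list with class `rhs_taxonomy`.
#' @export
taxonomy <- function(agents = default_agents(),
                     service_functions = default_service_functions(),
                     aliases = agent_aliases()) {
  stopifnot(all(c("agent_id", "display_name") %in% names(agents)),
            all(c("service_code", "fn") %in% names(service_functions)))
  bad <- setdiff(service_functions$fn, facility_functions())
  if (length(bad) > 0) {
    abort_stage("taxonomy", "unknown facility function(s): ",
                paste(bad, collapse = ", "))
  }
  structure(
    list(agents = tibble::as_tibble(agents),
         service_functions = tibble::as_tibble(service_functions),
         aliases = aliases,
         tiers = tier_codes(),
         functions = function_codes()),
    class = "rhs_taxonomy"
  )
}

#' @export
print.rhs_taxonomy <- function(x, ...) {
  cat("<rhs_taxonomy>\n")
  cat("  agents:   ", paste(x$agents$agent_id, collapse = ", "), "\n")
  cat("  tiers:    ", paste(x$tiers, collapse = ", "), "\n")
  cat("  functions:", paste(x$functions, collapse = ", "), "\n")
  cat("  services: ", nrow(x$service_functions), "mapped\n")
  invisible(x)
}

#' Read or write a taxonomy as YAML
#'
#' @param path File path.
#' @return `read_taxonomy()` returns an `rhs_taxonomy`; `write_taxonomy()`
#'   returns `path` invisibly.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) {
    abort_stage("io", "taxonomy file not found: ", path)
  }
  y <- yaml::read_yaml(path)
  taxonomy(
    agents = tibble::tibble(
      agent_id = vapply(y$agents, function(a) a$agent_id, character(1)),
      display_name = vapply(y$agents, function(a) a$display_name, character(1))
    ),
    service_functions = tibble::tibble(
      service_code = vapply(y$service_functions, function(s) s$service_code,
                            character(1)),
      fn = vapply(y$service_functions, function(s) s$fn, character(1))
    ),
    aliases = unlist(y$aliases %||% list()) %||% character(0)
  )
}

#' @rdname read_taxonomy
#' @param tax An `rhs_taxonomy` object.
#' @export
write_taxonomy <- function(tax, path) {
  y <- list(
    agents = purrr::pmap(tax$agents, function(agent_id, display_name) {
      list(agent_id = agent_id, display_name = display_name)
    }),
    service_functions = purrr::pmap(tax$service_functions,
                                    function(service_code, fn) {
      list(service_code = service_code, fn = fn)
    }),
    aliases = as.list(tax$aliases)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
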