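#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' @export
print.rhs_allocation <- function(x, ...) {
  cat("<rhs_allocation>\n")
  cat("  years       :", paste(x$years, collapse = ", "), "\n")
  rh <- rh_totals(x)
  cat("  RH totals   :",
      paste(sprintf("%d: %s", rh$year, format_amount(rh$rh_total)),
            collapse = "; "), "Int$\n")
  cat("  cube cells  :", nrow(x$cube), "\n")
  cat("  conservation:",
      if (all(x$audit$ok)) "ok" else "FAILED", "\n")
  invisible(x)
}

#' Tidy an allocation result
#'
#' Returns the allocation cube as a tibble, one row per
#' year-agent-tier-function cell with the amount in constant
#' international dollars and a flag for whether the cell counts towards
#' reproductive-health totals.
#'
#' @param x An `rhs_allocation`.
#' @param ... Unused.
#' @return A tibble `year, agent_id, tier, fn, amount, is_rh`.
#' @method tidy rhs_allocation
#' @export
tidy.rhs_allocation <- function(x, ...) {
  x$cube |>
    dplyr::mutate(is_rh = .data$fn != "OTHER_HEALTH") |>
    dplyr::arrange(.data$year, .data$agent_id, .data$tier, .data$fn)
}

#' One-row summary of an allocation result
#'
#' @param x An `rhs_allocation`.
#' @param ... Unused.
#' @return A one-row tibble: year range, entry and cell counts, total RH
#'   and overall expenditure, the worst conservation gap, and whether the
#'   audit passed.
#' @method glance rhs_allocation
#' @export
glance.rhs_allocation <- function(x, ...) {
  rh <- rh_totals(x)
  tibble::tibble(
    n_years = length(x$years),
    first_year = min(x$years),
    last_year = max(x$years),
    n_cells = nrow(x$cube),
    total_allocated = sum(x$cube$amount),
    rh_total = sum(rh$rh_total),
    max_conservation_gap = max(abs(x$audit$gap)),
    conserved = all(x$audit$ok))
}

#' Plot reproductive-health expenditure from an allocation
#'
#' Stacked bars of RH-attributable expenditure by year, filled either by
#' health function or by provider tier.
#'
#' @param object An `rhs_allocation`.
#' @param fill `"fn"` (default) or `"tier"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rhs_allocation
#' @export
autoplot.rhs_allocation <- function(object, fill = c("fn", "tier"), ...) {
  fill <- match.arg(fill)
  df <- object$cube |>
    dplyr::filter(.data$fn != "OTHER_HEALTH") |>
    dplyr::group_by(.data$year, .data[[fill]]) |>
    dplyr::summarise(amount = sum(.data$amount) / 1e3, .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$year), y = .data$amount,
                                   fill = .data[[fill]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Year", y = "RH expenditure (thousand Int$)",
                  fill = if (fill == "fn") "Function" else "Provider tier") +
    ggplot2::theme_minimal()
}

#' Plot a facility share matrix
#'
#' Bar chart of each facility tier's expenditure composition across
#' maternal health, family planning and other activities.
#'
#' @param share_matrix Tibble `year, tier, fn, share` from
#'   [compute_share_matrix()].
#' @return A ggplot object.
#' @export
plot_share_matrix <- function(share_matrix) {
  ggplot2::ggplot(share_matrix,
                  ggplot2::aes(x = .data$tier, y = 100 * .data$share,
                               fill = .data$fn)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(x = "Provider tier", y = "Share of expenditure (%)",
                  fill = "Function") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
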