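#' Compare two strategy outcomes: increments, ICER, NMB, dominance
#'
#' Computes reference-minus-comparator differences in discounted cost,
#' life-years and QALYs, the incremental cost-effectiveness ratios (per QALY
#' and per LY; undefined when the corresponding effect difference is zero),
#' net monetary benefit at the willingness-to-pay threshold
#' (`wtp * delta_qaly - delta_cost`), and a dominance verdict:
#' * `reference_dominant` - reference cheaper and more effective;
#' * `comparator_dominant` - reference dearer and less effective;
#' * `equivalent` - both differences zero;
#' * otherwise a trade-off, labelled `tradeoff_cost_effective` when the NMB
#'   is positive (equivalently ICER <= wtp for a QALY gain, or savings per
#'   QALY forgone >= wtp) and `tradeoff_not_cost_effective` when not.
#'
#' Negative ICERs in the dominant quadrants are reported numerically but are
#' never compared against the threshold; dominance drives the verdict.
#'
#' @param reference,comparator `"strategy_outcome"` objects from
#'   [accrue_outcomes()], produced under identical settings.
#' @param wtp Willingness-to-pay threshold (USD/QALY); defaults to the value
#'   in the outcomes' settings.
#' @return An object of class `"cea_comparison"`.
#' @export
compare_strategies <- function(reference, comparator, wtp = NULL) {
  stopifnot(inherits(reference, "strategy_outcome"),
            inherits(comparator, "strategy_outcome"))
  if (!identical(unclass(reference$settings), unclass(comparator$settings))) {
    rlang::abort("Outcomes were produced under different model settings.")
  }
  wtp <- wtp %||% reference$settings$wtp
  d_cost <- reference$total_cost - comparator$total_cost
  d_ly <- reference$life_years - comparator$life_years
  d_qaly <- reference$qalys - comparator$qalys
  icer_qaly <- if (d_qaly == 0) NA_real_ else d_cost / d_qaly
  icer_ly <- if (d_ly == 0) NA_real_ else d_cost / d_ly
  nmb <- wtp * d_qaly - d_cost
  dominance <- if (d_cost == 0 && d_qaly == 0) {
    "equivalent"
  } else if (d_cost < 0 && d_qaly > 0) {
    "reference_dominant"
  } else if (d_cost > 0 && d_qaly < 0) {
    "comparator_dominant"
  } else if (nmb > 0) {
    "tradeoff_cost_effective"
  } else {
    "tradeoff_not_cost_effective"
  }
  structure(
    list(
      reference_name = reference$name, comparator_name = comparator$name,
      delta_cost = d_cost, delta_ly = d_ly, delta_qaly = d_qaly,
      icer_per_qaly = icer_qaly, icer_per_ly = icer_ly,
      nmb_at_wtp = nmb, wtp = wtp, dominance = dominance
    ),
    class = "cea_comparison"
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<cea_comparison> %s vs %s\n", x$reference_name, x$comparator_name))
  cat(sprintf("  delta cost $%.2f | delta LY %.4f | delta QALY %.4f\n",
              x$delta_cost, x$delta_ly, x$delta_qaly))
  cat(sprintf("  ICER $%s/QALY | NMB at $%.2f: $%.2f | %s\n",
              ifelse(is.na(x$icer_per_qaly), "undefined",
                     sprintf("%.2f", x$icer_per_qaly)),
              x$wtp, x$nmb_at_wtp, x$dominance))
  invisible(x)
}

#' Tidy a strategy comparison into a one-row tibble
#'
#' @param x A `"cea_comparison"`.
#' @param ... Unused.
#' @method tidy cea_comparison
#' @export
tidy.cea_comparison <- function(x, ...) {
  tibble::tibble(
    reference = x$reference_name, comparator = x$comparator_name,
    delta_cost = x$delta_cost, delta_ly = x$delta_ly,
    delta_qaly = x$delta_qaly, icer_per_qaly = x$icer_per_qaly,
    icer_per_ly = x$icer_per_ly, nmb_at_wtp = x$nmb_at_wtp,
    wtp = x$wtp, dominance = x$dominance
  )
}

#' Run the full base-case analysis for a configuration
#'
#' Accrues discounted life-years, QALYs and costs for every strategy in the
#' configuration and compares the first strategy (the reference) against the
#' second at the configured willingness-to-pay threshold.
#'
#' @param config A [cea_config()], e.g. [mrcc_reference()] or the result of
#'   [load_config()].
#' @return An object of class `"cea_report"`: list with `outcomes` (named
#'   list of `"strategy_outcome"`), `comparison` (`"cea_comparison"`),
#'   `settings` and the `config` itself. `tidy()` gives the per-strategy
#'   table, `glance()` the one-row incremental summary.
#' @examples
#' report <- run_base_case(mrcc_reference())
#' tidy(report)
#' glance(report)
#' @export
run_base_case <- function(config) {
  stopifnot(inherits(config, "cea_config"))
  strategies <- build_strategies(config)
  outcomes <- purrr::map(strategies, accrue_outcomes,
                         settings = config$settings)
  comparison <- compare_strategies(outcomes[[1]], outcomes[[2]],
                                   wtp = config$settings$wtp)
  structure(
    list(outcomes = outcomes, comparison = comparison,
         settings = config$settings, config = config),
    class = "cea_report"
  )
}

#' @export
print.cea_report <- function(x, ...) {
  cat("Base-case cost-effectiveness analysis\n")
  df <- as.data.frame(tidy(x))
  df$life_years <- round(df$life_years, 3)
  df$qalys <- round(df$qalys, 3)
  df$total_cost <- round(df$total_cost, 2)
  df$dead_at_horizon <- round(df$dead_at_horizon, 4)
  print(df, row.names = FALSE)
  print(x$comparison)
  invisible(x)
}

#' Tidy a base-case report
#'
#' `tidy()` returns the per-strategy discounted outcomes; `glance()` the
#' one-row incremental comparison.
#'
#' @param x A `"cea_report"`.
#' @param ... Unused.
#' @method tidy cea_report
#' @export
tidy.cea_report <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$outcomes, tidy))
}

#' @rdname tidy.cea_report
#' @method glance cea_report
#' @export
glance.cea_report <- function(x, ...) {
  tidy(x$comparison)
}
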