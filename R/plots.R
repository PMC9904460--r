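#' Plot a cohort trace
#'
#' State-occupancy fractions over the model horizon.
#'
#' @param trace A trace tibble from [run_cohort()] (or a
#'   `"strategy_outcome"`, whose trace is used).
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  if (inherits(trace, "strategy_outcome")) trace <- trace$trace
  long <- tidyr::pivot_longer(trace, c("stable", "progressive", "dead"),
                              names_to = "state", values_to = "fraction")
  long$state <- factor(long$state, levels = c("stable", "progressive", "dead"))
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$fraction,
                                     colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Cycle (months)", y = "Cohort fraction",
                  colour = "State") +
    ggplot2::theme_minimal()
}

#' Tornado diagram for a one-way sensitivity analysis
#'
#' Horizontal bars spanning the outcome interval of each parameter, widest
#' at the top.
#'
#' @param owsa A `"cea_owsa"` tibble from [one_way_sensitivity()].
#' @param top Number of parameters to show (default 10).
#' @return A ggplot object.
#' @export
plot_tornado <- function(owsa, top = 10) {
  stopifnot(inherits(owsa, "cea_owsa"))
  metric <- attr(owsa, "metric")
  cols <- if (metric == "nmb") c("nmb_at_low", "nmb_at_high") else
    c("icer_at_low", "icer_at_high")
  base <- if (metric == "nmb") attr(owsa, "base_nmb") else attr(owsa, "base_icer")
  df <- utils::head(owsa, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  df$lo <- pmin(df[[cols[1]]], df[[cols[2]]])
  df$hi <- pmax(df[[cols[1]]], df[[cols[2]]])
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$lo, xend = .data$hi, yend = .data$parameter),
      linewidth = 5, colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(
      x = if (metric == "nmb") "Incremental net monetary benefit (USD)" else
        "ICER (USD/QALY)",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_tornado
#' @param object,... Passed to `plot_tornado()`.
#' @method autoplot cea_owsa
#' @export
autoplot.cea_owsa <- function(object, ...) plot_tornado(object, ...)

#' Incremental cost-effectiveness scatter of PSA draws
#'
#' One point per Monte Carlo draw on the incremental cost-effectiveness
#' plane, with the willingness-to-pay threshold as a reference line.
#'
#' @param psa A `"psa_result"` from [run_psa()].
#' @return A ggplot object.
#' @export
plot_psa_scatter <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  ggplot2::ggplot(psa$draws, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = psa$wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_psa_scatter
#' @param object,... Passed to `plot_psa_scatter()`.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, ...) plot_psa_scatter(object)

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `"cea_ceac"` tibble from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  stopifnot(inherits(curve, "cea_ceac"))
  ggplot2::ggplot(curve, ggplot2::aes(.data$wtp, .data$prob_cost_effective)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ceac
#' @param object,... Passed to `plot_ceac()`.
#' @method autoplot cea_ceac
#' @export
autoplot.cea_ceac <- function(object, ...) plot_ceac(object)
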