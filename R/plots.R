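#' Plot state occupancy over time
#'
#' Stacked-area view of the cohort trace: proportion of the cohort in the
#' independent, dependent and dead states at the end of each cycle.
#'
#' @param object A `stroke_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(run_cohort(default_parameters(), "mt", horizon = 10))
#' @method autoplot stroke_trace
#' @export
autoplot.stroke_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::transmute(tibble::as_tibble(object),
                     time = .data$start + .data$length,
                     independent = .data$end_indep, dependent = .data$end_dep,
                     dead = .data$end_dead),
    -"time", names_to = "state", values_to = "proportion")
  long$state <- factor(long$state, c("dead", "dependent", "independent"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$proportion,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Years since index stroke",
                  y = "Proportion of cohort",
                  title = paste("Cohort trace,", attr(object, "arm"), "arm")) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars from the ICER at each parameter's lower range limit to
#' the ICER at its upper limit, for the parameters with the largest
#' spread, with the base-case ICER as a reference line.
#'
#' @param dsa Output of [one_way_dsa()].
#' @param base_icer Base-case ICER for the reference line (CNY/QALY).
#' @param top Number of parameters to display (default 10).
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa, base_icer = NULL, top = 10) {
  shown <- utils::head(dplyr::arrange(dsa, dplyr::desc(.data$spread)), top)
  shown$label <- factor(shown$label, rev(shown$label))
  p <- ggplot2::ggplot(shown) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                   y = .data$label, yend = .data$label),
      linewidth = 5, colour = "steelblue") +
    ggplot2::labs(x = "ICER (CNY per QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
  if (!is.null(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer, linetype = 2)
  }
  p
}

#' Cost-effectiveness plane of a PSA
#'
#' Scatter of the incremental (QALY, cost) pairs across draws, with the
#' willingness-to-pay thresholds drawn as lines through the origin and the
#' deterministic base case marked.
#'
#' @param object A `stroke_psa` from [run_psa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stroke_psa
#' @export
autoplot.stroke_psa <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0, linetype = 1) +
    ggplot2::geom_abline(slope = object$wtp_low, intercept = 0, linetype = 2) +
    ggplot2::geom_point(data = glance(object$base_ce),
                        ggplot2::aes(.data$delta_qaly, .data$delta_cost),
                        colour = "red", size = 2, shape = 15) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (CNY)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_tbl Output of [ceac()].
#' @param wtp Optional threshold(s) to mark with vertical lines.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_tbl, wtp = NULL) {
  p <- ggplot2::ggplot(ceac_tbl,
                       ggplot2::aes(.data$wtp, .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (CNY per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp,
                                                  linetype = 2)
  p
}
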