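#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cost-effectiveness result
#'
#' One row per strategy with its discounted QALYs and costs.
#'
#' @param x A `stroke_ce` object from [icer()] or [run_cea()].
#' @param ... Unused.
#' @return A tibble with columns `strategy`, `qaly`, `cost`.
#' @method tidy stroke_ce
#' @export
tidy.stroke_ce <- function(x, ...) {
  tibble::tibble(
    strategy = c(x$arm_comparator, x$arm_intervention),
    qaly = c(x$qaly_comparator, x$qaly_intervention),
    cost = c(x$cost_comparator, x$cost_intervention)
  )
}

#' @rdname tidy.stroke_ce
#' @return `glance()`: a one-row tibble with `horizon`, `delta_qaly`,
#'   `delta_cost`, `icer`, `status`.
#' @method glance stroke_ce
#' @export
glance.stroke_ce <- function(x, ...) {
  tibble::tibble(horizon = x$horizon, delta_qaly = x$delta_qaly,
                 delta_cost = x$delta_cost, icer = x$icer, status = x$status)
}

#' Tidy a probabilistic sensitivity analysis
#'
#' `tidy()` returns the per-draw incremental pairs; `glance()` a one-row
#' summary with the mean increments and the probability of
#' cost-effectiveness at the two GDP-based thresholds.
#'
#' @param x A `stroke_psa` object from [run_psa()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stroke_psa
#' @export
tidy.stroke_psa <- function(x, ...) x$draws

#' @rdname tidy.stroke_psa
#' @method glance stroke_psa
#' @export
glance.stroke_psa <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws, seed = x$seed, horizon = x$horizon,
    mean_delta_qaly = mean(x$draws$delta_qaly),
    mean_delta_cost = mean(x$draws$delta_cost),
    prob_ce_wtp = probability_cost_effective(x, x$wtp),
    prob_ce_wtp_low = probability_cost_effective(x, x$wtp_low)
  )
}
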