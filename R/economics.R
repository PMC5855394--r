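#' Continuous discount factor
#'
#' `(1 + rate)^(-t)` with fractional years allowed, so sub-annual cycles
#' can be discounted at their midpoint.
#'
#' @param t Time in years (vectorised), >= 0.
#' @param rate Annual discount rate, >= 0.
#' @return Discount factor in (0, 1\].
#' @examples
#' discount_factor(1, 0.03)
#' @export
discount_factor <- function(t, rate) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  (1 + rate)^(-t)
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Implements the half-cycle correction in its cumulative form: the acute
#' cycle is valued trapezoidally from the dependent entry state to the
#' day-90 distribution (see [acute_qaly()]), and every later cycle is
#' valued at its end-of-cycle occupancy. Each cycle's rewards are
#' discounted at the cycle midpoint, costs and outcomes at their own
#' rates.
#'
#' Per post-acute cycle, QALYs are cycle length times the utility-weighted
#' end occupancy; surviving recurrers spend 30 days at the recurrent-stroke
#' utility instead of their destination-state utility. Costs are cycle
#' length times the annual post-hospitalisation cost of the end occupancy,
#' plus - when `recurrence_event_costs` is `TRUE` (the default) - the
#' one-time hospitalisation cost of the destination state for each
#' recurrence (fatal recurrences incur the mRS 6 cost). The acute-phase
#' decision-tree cost and QALY are added from [acute_cost()] and
#' [acute_qaly()].
#'
#' @param trace A `stroke_trace` from [run_cohort()].
#' @param params A [stroke_params] tibble; defaults to the set stored in
#'   the trace.
#' @param recurrence_event_costs Charge hospitalisation costs at recurrent
#'   strokes (default `TRUE`).
#' @return A one-row `stroke_arm_result` tibble: `arm`, `horizon`, `qaly`,
#'   `cost`, plus the acute-phase components `qaly_acute`, `cost_acute`.
#' @examples
#' accrue(run_cohort(default_parameters(), "tpa", horizon = 5))
#' @export
accrue <- function(trace, params = NULL, recurrence_event_costs = TRUE) {
  stopifnot(inherits(trace, "stroke_trace"))
  params <- params %||% attr(trace, "params")
  arm <- attr(trace, "arm")
  pv <- param_values(params)
  if (abs(sum(trace$length) - attr(trace, "horizon")) > 1e-9) {
    stop("trace does not span its stated horizon", call. = FALSE)
  }
  du <- pv[["discount_outcome"]]
  dc <- pv[["discount_cost"]]
  dist <- day90_distribution(params, arm)

  mid <- trace$start + trace$length / 2
  df_u <- discount_factor(mid, du)
  df_c <- discount_factor(mid, dc)

  q_acute <- acute_qaly(params, dist) * df_u[1]
  c_acute <- acute_cost(params, dist, arm) * df_c[1]

  post <- trace$cycle > 1
  q_cycle <- trace$length * (trace$end_indep * pv[["u_indep"]] +
                               trace$end_dep * pv[["u_dep"]]) +
    (trace$recur_surv_from_indep *
       ((pv[["u_recur_event"]] - pv[["u_indep"]]) / 2 +
          (pv[["u_recur_event"]] - pv[["u_dep"]]) / 2) +
       trace$recur_surv_from_dep * (pv[["u_recur_event"]] - pv[["u_dep"]])) *
    pv[["dur_recur_days"]] / 365.25
  c_cycle <- trace$length * (trace$end_indep * pv[["c_annual_indep"]] +
                               trace$end_dep * pv[["c_annual_dep"]])
  if (recurrence_event_costs) {
    c_cycle <- c_cycle + trace$recur_surv_from_indep *
      (pv[["c_hosp_indep"]] + pv[["c_hosp_dep"]]) / 2 +
      trace$recur_surv_from_dep * pv[["c_hosp_dep"]] +
      trace$recur_fatal * pv[["c_hosp_death"]]
  }
  qaly <- q_acute + sum(q_cycle[post] * df_u[post])
  cost <- c_acute + sum(c_cycle[post] * df_c[post])

  res <- tibble::tibble(arm = arm, horizon = attr(trace, "horizon"),
                        qaly = qaly, cost = cost,
                        qaly_acute = q_acute, cost_acute = c_acute)
  structure(res, trace = trace, class = c("stroke_arm_result", class(res)))
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' Computes incremental cost, incremental QALYs, and their ratio (ICER).
#' A strategy that is cheaper and more effective is flagged `"dominant"`
#' (no ratio reported); the reverse is `"dominated"`; the ICER is undefined
#' when the QALY difference is zero.
#'
#' @param comparator,intervention `stroke_arm_result` rows from [accrue()],
#'   computed at the same horizon.
#' @return A one-row `stroke_ce` tibble: per-arm QALYs and costs,
#'   `delta_qaly`, `delta_cost`, `icer` (NA under dominance) and `status`
#'   (`"icer"`, `"dominant"`, `"dominated"` or `"undefined"`).
#' @examples
#' p <- default_parameters()
#' icer(accrue(run_cohort(p, "tpa", 5)), accrue(run_cohort(p, "mt", 5)))
#' @export
icer <- function(comparator, intervention) {
  if (!isTRUE(all.equal(comparator$horizon, intervention$horizon))) {
    stop("arms were run at different horizons", call. = FALSE)
  }
  dq <- intervention$qaly - comparator$qaly
  dc <- intervention$cost - comparator$cost
  status <- if (dq > 0 && dc < 0) "dominant"
  else if (dq < 0 && dc > 0) "dominated"
  else if (dq == 0) "undefined"
  else "icer"
  res <- tibble::tibble(
    horizon = comparator$horizon,
    arm_comparator = comparator$arm, arm_intervention = intervention$arm,
    qaly_comparator = comparator$qaly, cost_comparator = comparator$cost,
    qaly_intervention = intervention$qaly, cost_intervention = intervention$cost,
    delta_qaly = dq, delta_cost = dc,
    icer = if (status == "icer") dc / dq else NA_real_,
    status = status
  )
  structure(res, class = c("stroke_ce", class(res)))
}

#' Run the full two-arm cost-effectiveness comparison
#'
#' Convenience wrapper: runs both arms through the decision tree and the
#' Markov engine, accrues discounted costs and QALYs, and returns the
#' incremental result.
#'
#' @param params A [stroke_params] tibble.
#' @param horizon Horizon in whole years; defaults to the `horizon` setting.
#' @param recurrence_event_costs Passed to [accrue()].
#' @return A one-row `stroke_ce` tibble (see [icer()]).
#' @examples
#' run_cea(default_parameters(), horizon = 5)
#' @export
run_cea <- function(params, horizon = NULL, recurrence_event_costs = TRUE) {
  a <- accrue(run_cohort(params, "tpa", horizon), params,
              recurrence_event_costs)
  b <- accrue(run_cohort(params, "mt", horizon), params,
              recurrence_event_costs)
  icer(a, b)
}

#' Is the intervention cost-effective at a willingness-to-pay threshold?
#'
#' `TRUE` when the intervention dominates, or gains QALYs at an ICER below
#' the threshold; equivalent to a positive incremental net benefit
#' `wtp * delta_qaly - delta_cost` for QALY-gaining strategies.
#'
#' @param ce A `stroke_ce` row from [icer()] or [run_cea()].
#' @param wtp Willingness-to-pay threshold in CNY per QALY.
#' @return Logical.
#' @examples
#' is_cost_effective(run_cea(default_parameters(), horizon = 6), 125700)
#' @export
is_cost_effective <- function(ce, wtp) {
  if (ce$status == "dominant") return(TRUE)
  if (ce$status %in% c("dominated", "undefined")) return(FALSE)
  ce$delta_qaly > 0 && ce$icer < wtp
}

#' @export
print.stroke_ce <- function(x, ...) {
  cat("<stroke_ce> ", x$arm_intervention, " vs ", x$arm_comparator,
      " over ", x$horizon, " years\n", sep = "")
  cat(sprintf("  dQALY %.3f, dCost %.0f CNY, %s\n", x$delta_qaly,
              x$delta_cost,
              if (x$status == "icer") sprintf("ICER %.0f CNY/QALY", x$icer)
              else x$status))
  invisible(x)
}

#' Base-case results table across horizons
#'
#' Mirrors the usual presentation of a cost-utility base case: one row per
#' horizon and strategy with discounted QALYs and costs, and the ICER on
#' the intervention rows.
#'
#' @param params A [stroke_params] tibble.
#' @param horizons Horizons in years (default 1, 5, 6 and 30).
#' @param recurrence_event_costs Passed to [accrue()].
#' @return A tibble with columns `horizon`, `strategy`, `qaly`, `cost`,
#'   `delta_qaly`, `delta_cost`, `icer` (NA on comparator rows).
#' @examples
#' base_case_table(default_parameters(), horizons = c(1, 5))
#' @export
base_case_table <- function(params, horizons = c(1, 5, 6, 30),
                            recurrence_event_costs = TRUE) {
  purrr::map_dfr(horizons, function(h) {
    ce <- run_cea(params, h, recurrence_event_costs)
    tibble::tibble(
      horizon = h,
      strategy = c("tpa", "mt"),
      qaly = c(ce$qaly_comparator, ce$qaly_intervention),
      cost = c(ce$cost_comparator, ce$cost_intervention),
      delta_qaly = c(NA_real_, ce$delta_qaly),
      delta_cost = c(NA_real_, ce$delta_cost),
      icer = c(NA_real_, ce$icer)
    )
  })
}
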