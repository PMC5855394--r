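#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full two-arm model with each ranged input set to its lower
#' and upper plausible value in turn, all other inputs at base. The result
#' is sorted by the ICER spread, the ordering of a tornado diagram.
#' Variations that eliminate the QALY gain are flagged rather than dropped
#' (their ICER is NA when undefined or dominated).
#'
#' @param params A [stroke_params] tibble.
#' @param horizon Horizon in whole years (default 30, the long-term case).
#' @param recurrence_event_costs Passed to [accrue()].
#' @return A tibble with one row per ranged parameter: `name`, `label`,
#'   `lo`, `hi`, `icer_low`, `icer_high`, `spread`, `flagged`.
#' @examples
#' \donttest{one_way_dsa(default_parameters())}
#' @export
one_way_dsa <- function(params, horizon = 30, recurrence_event_costs = TRUE) {
  stop_if_invalid(params)
  ranged <- params[params$lo < params$hi, ]
  rows <- purrr::pmap_dfr(
    list(ranged$name, ranged$label, ranged$lo, ranged$hi),
    function(name, label, lo, hi) {
      icer_at <- function(value) {
        ce <- run_cea(set_param(params, name, base = value), horizon,
                      recurrence_event_costs)
        list(icer = ce$icer, ok = ce$status == "icer" && ce$delta_qaly > 0)
      }
      low <- icer_at(lo)
      high <- icer_at(hi)
      tibble::tibble(
        name = name, label = label, lo = lo, hi = hi,
        icer_low = low$icer, icer_high = high$icer,
        spread = abs(high$icer - low$icer),
        flagged = !(low$ok && high$ok)
      )
    })
  dplyr::arrange(rows, dplyr::desc(.data$spread))
}

#' Hypothetical efficacy-by-price scenario grid
#'
#' Crosses worse-efficacy scenarios for the thrombectomy effect with price
#' scenarios for its add-on cost. The efficacy scenarios set the odds
#' ratio for independence to its published 95% CI lower limit
#' ("worse-unfavourable") and, when supplied, to its 90% CI lower limit
#' ("unfavourable"; this limit is not published, so the scenario is
#' skipped with a warning unless provided). Each efficacy scenario is
#' crossed with thrombectomy cost multipliers 1.10, 1.00, 0.90, 0.75 and
#' 0.50.
#'
#' @param params A [stroke_params] tibble.
#' @param or_mrs02_90ci_low Optional 90% CI lower limit of the
#'   independence odds ratio.
#' @param horizon Horizon in whole years (default 30).
#' @param recurrence_event_costs Passed to [accrue()].
#' @return A tibble with columns `or_scenario`, `or_mrs02`,
#'   `cost_multiplier`, `delta_qaly`, `delta_cost`, `icer`, `status`;
#'   15 rows with the 90% CI limit supplied, 10 without.
#' @examples
#' \donttest{scenario_grid(default_parameters())}
#' @export
scenario_grid <- function(params, or_mrs02_90ci_low = NULL, horizon = 30,
                          recurrence_event_costs = TRUE) {
  stop_if_invalid(params)
  i <- match("or_mrs02", params$name)
  ors <- tibble::tibble(
    or_scenario = c("base", "worse-unfavourable"),
    or_mrs02 = c(params$base[i], params$lo[i])
  )
  if (!is.null(or_mrs02_90ci_low)) {
    ors <- dplyr::bind_rows(
      ors[1, ],
      tibble::tibble(or_scenario = "unfavourable",
                     or_mrs02 = or_mrs02_90ci_low),
      ors[2, ])
  } else {
    warning("90% CI lower limit of or_mrs02 not supplied; ",
            "'unfavourable' scenario skipped", call. = FALSE)
  }
  mult <- c(1.10, 1.00, 0.90, 0.75, 0.50)
  c_mt <- param_value(params, "c_mt_addon")
  grid <- tidyr::expand_grid(ors, cost_multiplier = mult)
  purrr::pmap_dfr(grid, function(or_scenario, or_mrs02, cost_multiplier) {
    pp <- set_param(params, "or_mrs02", base = or_mrs02)
    pp <- set_param(pp, "c_mt_addon", base = c_mt * cost_multiplier)
    ce <- run_cea(pp, horizon, recurrence_event_costs)
    tibble::tibble(or_scenario = or_scenario, or_mrs02 = or_mrs02,
                   cost_multiplier = cost_multiplier,
                   delta_qaly = ce$delta_qaly, delta_cost = ce$delta_cost,
                   icer = ce$icer, status = ce$status)
  })
}
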