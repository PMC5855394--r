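#' Convert a baseline probability through an odds ratio
#'
#' Applies an odds ratio to a baseline event probability:
#' `p2 = OR * p1 / (1 + (OR - 1) * p1)`. This is how the pooled trial odds
#' ratios are turned into intervention-arm probabilities for the 90-day
#' decision tree. The map is strictly increasing in both arguments and
#' inverts exactly through `or_to_probability(p2, 1 / OR)`.
#'
#' @param p1 Baseline probability (vectorised), in \[0, 1\].
#' @param odds_ratio Odds ratio (vectorised), > 0.
#' @return The recalculated probability, in \[0, 1\].
#' @examples
#' or_to_probability(0.325, 2.046)
#' @export
or_to_probability <- function(p1, odds_ratio) {
  if (any(p1 < 0 | p1 > 1)) stop("p1 must be in [0, 1]", call. = FALSE)
  if (any(odds_ratio <= 0)) stop("odds_ratio must be > 0", call. = FALSE)
  odds_ratio * p1 / (1 + (odds_ratio - 1) * p1)
}

arm_label <- function(arm) {
  arm <- match.arg(arm, c("tpa", "mt"))
  arm
}

#' 90-day outcome distribution of a treatment arm
#'
#' The decision-tree stage of the model. The thrombolysis (`"tpa"`) arm
#' uses the observed 90-day proportions directly; the thrombectomy (`"mt"`)
#' arm converts each proportion through its pooled odds ratio with
#' [or_to_probability()]. The dependent proportion is the complement, so
#' the three states always sum to one.
#'
#' @param params A [stroke_params] tibble.
#' @param arm `"tpa"` (thrombolysis alone) or `"mt"` (thrombectomy + tPA).
#' @return A one-row tibble with columns `arm`, `p_indep`, `p_dep`,
#'   `p_dead`, `p_sich`.
#' @examples
#' day90_distribution(default_parameters(), "mt")
#' @export
day90_distribution <- function(params, arm) {
  arm <- arm_label(arm)
  pv <- param_values(params)
  if (arm == "tpa") {
    p_indep <- pv[["p_mrs02_tpa"]]
    p_dead <- pv[["p_death_tpa"]]
    p_sich <- pv[["p_sich_tpa"]]
  } else {
    p_indep <- or_to_probability(pv[["p_mrs02_tpa"]], pv[["or_mrs02"]])
    p_dead <- or_to_probability(pv[["p_death_tpa"]], pv[["or_death"]])
    p_sich <- or_to_probability(pv[["p_sich_tpa"]], pv[["or_sich"]])
  }
  p_dep <- 1 - p_indep - p_dead
  if (p_dep < 0) {
    stop("inconsistent 90-day inputs: p_indep + p_dead > 1 in arm ", arm,
         call. = FALSE)
  }
  tibble::tibble(arm = arm, p_indep = p_indep, p_dep = p_dep,
                 p_dead = p_dead, p_sich = p_sich)
}

#' Acute-phase (first 90 days) cost per patient
#'
#' One-time hospitalisation cost weighted by the day-90 state (deaths incur
#' the mRS 6 hospitalisation cost), plus the tPA add-on for the fraction
#' arriving within 4.5 h (both arms), the thrombectomy add-on for the
#' fraction actually treated (intervention arm only), and the sICH add-on
#' for the sICH fraction. Undiscounted; discounting is applied when the
#' acute phase enters [accrue()].
#'
#' @param params A [stroke_params] tibble.
#' @param dist A day-90 distribution from [day90_distribution()]; derived
#'   from `params` when omitted.
#' @param arm Treatment arm; taken from `dist` when omitted.
#' @return Cost per patient in 2013 CNY.
#' @examples
#' acute_cost(default_parameters(), arm = "tpa")
#' @export
acute_cost <- function(params, dist = NULL, arm = NULL) {
  if (is.null(dist)) dist <- day90_distribution(params, arm)
  arm <- arm_label(arm %||% dist$arm)
  pv <- param_values(params)
  cost <- dist$p_indep * pv[["c_hosp_indep"]] +
    dist$p_dep * pv[["c_hosp_dep"]] +
    dist$p_dead * pv[["c_hosp_death"]] +
    pv[["p_arrive_45h"]] * pv[["c_tpa_addon"]] +
    dist$p_sich * pv[["c_sich_addon"]]
  if (arm == "mt") cost <- cost + pv[["p_receive_mt"]] * pv[["c_mt_addon"]]
  unname(cost)
}

#' Acute-phase (first 90 days) QALY accrual per patient
#'
#' The first model cycle runs from the index stroke to day 90. All patients
#' enter hospitalised in the dependent state and reach their day-90 state
#' by the end of the cycle, so the cycle is valued trapezoidally: 0.25
#' years at the mean of the entry utility (dependent) and the day-90
#' utility (dead = 0). The sICH fraction additionally spends 14 days at its
#' state utility scaled by the sICH utility factor. Undiscounted;
#' [accrue()] discounts the acute phase at the cycle midpoint.
#'
#' @inheritParams acute_cost
#' @return QALYs per patient over the first 0.25 years.
#' @examples
#' acute_qaly(default_parameters(), arm = "tpa")
#' @export
acute_qaly <- function(params, dist = NULL, arm = NULL) {
  if (is.null(dist)) dist <- day90_distribution(params, arm)
  pv <- param_values(params)
  u_day90 <- dist$p_indep * pv[["u_indep"]] + dist$p_dep * pv[["u_dep"]]
  q <- 0.25 * (pv[["u_dep"]] + u_day90) / 2
  q <- q - dist$p_sich * u_day90 * (1 - pv[["u_sich_event"]]) *
    pv[["dur_sich_days"]] / 365.25
  unname(q)
}
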