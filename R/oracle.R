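#' Individual-level microsimulation of one treatment arm
#'
#' Simulates each patient's path through the same transition law as the
#' cohort engine - day-90 outcome, then per cycle recurrence, recurrence
#' case fatality, survivor reallocation and background mortality - and
#' accrues the same discounted costs and QALYs patient by patient. The
#' implementation is independent of the cohort code path (event sampling
#' rather than expectation propagation), so agreement between the two is
#' evidence of correctness rather than tautology: cohort totals should lie
#' within Monte Carlo error of the microsimulation means.
#'
#' @param params A [stroke_params] tibble.
#' @param arm `"tpa"` or `"mt"`.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed.
#' @param horizon Horizon in whole years; defaults to the `horizon` setting.
#' @param recurrence_event_costs Match the corresponding [accrue()] switch.
#' @return A one-row tibble: `arm`, `n`, `qaly`, `qaly_se`, `cost`,
#'   `cost_se` (means and Monte Carlo standard errors per patient).
#' @examples
#' microsimulate(default_parameters(), "tpa", 2000, seed = 1, horizon = 5)
#' @export
microsimulate <- function(params, arm, n_patients, seed, horizon = NULL,
                          recurrence_event_costs = TRUE) {
  arm <- arm_label(arm)
  stop_if_invalid(params)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  pv <- param_values(params)
  horizon <- horizon %||% pv[["horizon"]]
  sched <- cycle_schedule(horizon)
  d90 <- day90_distribution(params, arm)
  n <- as.integer(n_patients)
  du <- pv[["discount_outcome"]]
  dc <- pv[["discount_cost"]]
  u_state <- c(pv[["u_indep"]], pv[["u_dep"]], 0)        # 1 ind, 2 dep, 3 dead
  c_hosp <- c(pv[["c_hosp_indep"]], pv[["c_hosp_dep"]], pv[["c_hosp_death"]])
  c_ann <- c(pv[["c_annual_indep"]], pv[["c_annual_dep"]], 0)
  dur_rec <- pv[["dur_recur_days"]] / 365.25
  dur_sich <- pv[["dur_sich_days"]] / 365.25

  # acute phase: day-90 state and decision-tree events
  state <- sample.int(3L, n, replace = TRUE,
                      prob = c(d90$p_indep, d90$p_dep, d90$p_dead))
  sich <- stats::runif(n) < d90$p_sich
  tpa45 <- stats::runif(n) < pv[["p_arrive_45h"]]
  mt <- if (arm == "mt") stats::runif(n) < pv[["p_receive_mt"]] else
    rep(FALSE, n)
  df_u1 <- discount_factor(0.125, du)
  df_c1 <- discount_factor(0.125, dc)
  qaly <- (0.25 * (pv[["u_dep"]] + u_state[state]) / 2 -
             sich * u_state[state] * (1 - pv[["u_sich_event"]]) * dur_sich) *
    df_u1
  cost <- (c_hosp[state] + tpa45 * pv[["c_tpa_addon"]] +
             sich * pv[["c_sich_addon"]] + mt * pv[["c_mt_addon"]]) * df_c1

  rec_rate <- c(pv[["recur_rate_indep"]], pv[["recur_rate_dep"]], 0)
  for (i in seq_len(nrow(sched))[-1]) {
    t0 <- sched$start[i]
    len <- sched$length[i]
    alive <- state != 3L
    if (!any(alive)) break
    esc <- pv[["rr_recur_per_year"]]^(t0 - 0.25)
    pr <- pmin(rec_rate * esc * len, 1)
    age <- pv[["entry_age"]] + t0 + len / 2
    m_i <- annual_background_mortality(age, "independent", params)
    m_d <- annual_background_mortality(age, "dependent", params)
    pm <- c(1 - (1 - m_i)^len, 1 - (1 - m_d)^len, 0)

    recur <- alive & stats::runif(n) < pr[state]
    fatal <- recur & stats::runif(n) < pv[["p_death_given_recur"]]
    dest <- state
    moved <- recur & !fatal & state == 1L & stats::runif(n) < 0.5
    dest[moved] <- 2L
    # background mortality acts on every survivor, at the origin state's risk
    bg <- alive & !fatal & stats::runif(n) < pm[state]
    new_state <- dest
    new_state[fatal | bg] <- 3L

    df_uc <- discount_factor(t0 + len / 2, du)
    df_cc <- discount_factor(t0 + len / 2, dc)
    rec_alive <- recur & new_state != 3L
    qaly <- qaly + (len * u_state[new_state] +
                      rec_alive * (pv[["u_recur_event"]] - u_state[dest]) *
                      dur_rec) * df_uc
    ccyc <- len * c_ann[new_state]
    if (recurrence_event_costs) {
      ccyc <- ccyc + rec_alive * c_hosp[dest] + fatal * pv[["c_hosp_death"]]
    }
    cost <- cost + ccyc * df_cc
    state <- new_state
  }
  qaly_se <- stats::sd(qaly) / sqrt(n)
  cost_se <- stats::sd(cost) / sqrt(n)
  tibble::tibble(arm = arm, n = n, qaly = mean(qaly), qaly_se = qaly_se,
                 cost = mean(cost), cost_se = cost_se)
}

#' Random valid parameter set for property testing
#'
#' Perturbs every model input (run settings excluded) uniformly within
#' +/-30% of its base value, clips to the parameter's domain, rescales the
#' 90-day proportions if their sum exceeds one, collapses the ranges to
#' the perturbed value, and guarantees the result passes
#' [validate_parameters()].
#'
#' @param seed Integer seed.
#' @param spread Half-width of the relative perturbation (default 0.3).
#' @return A valid [stroke_params] tibble.
#' @examples
#' random_parameter_set(42)
#' @export
random_parameter_set <- function(seed, spread = 0.3) {
  set.seed(seed)
  params <- default_parameters()
  vary <- params$group != "settings"
  f <- stats::runif(sum(vary), 1 - spread, 1 + spread)
  base <- params$base
  base[vary] <- base[vary] * f
  unit <- params$type %in% c("probability", "utility")
  base[unit] <- pmin(pmax(base[unit], 0), 1)
  i1 <- match("p_mrs02_tpa", params$name)
  i2 <- match("p_death_tpa", params$name)
  s <- base[i1] + base[i2]
  if (s > 1) {
    base[i1] <- base[i1] / (s + 1e-9)
    base[i2] <- base[i2] / (s + 1e-9)
  }
  params$base <- base
  params$lo[vary] <- base[vary]
  params$hi[vary] <- base[vary]
  stop_if_invalid(params)
  params
}
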