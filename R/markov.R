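#' Cycle schedule of the Markov phase
#'
#' Cycles follow the model's clock: a 0.25-year acute cycle from the index
#' event to day 90, a 0.75-year cycle to the end of year one, then annual
#' cycles to the horizon.
#'
#' @param horizon Time horizon in whole years, >= 1.
#' @return A tibble with columns `cycle`, `start` (years since model
#'   entry) and `length` (years). Lengths sum to `horizon`.
#' @examples
#' cycle_schedule(30)
#' @export
cycle_schedule <- function(horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1 ||
      horizon != round(horizon)) {
    stop("horizon must be a whole number of years >= 1", call. = FALSE)
  }
  starts <- if (horizon == 1) c(0, 0.25) else c(0, 0.25, seq(1, horizon - 1))
  tibble::tibble(cycle = seq_along(starts), start = starts,
                 length = diff(c(starts, horizon)))
}

#' Annual background (non-stroke) mortality
#'
#' The published inputs anchor the annual non-stroke death probability at
#' two ages: entry (63 years, 0.0089) and 93 years (0.1653). Between and
#' beyond the anchors the probability is interpolated log-linearly (a
#' Gompertz-like geometric progression in age) and capped at 1. For the
#' dependent state the independent-state probability is multiplied by the
#' hazard ratio of non-stroke death for mRS 3-5 and capped at 1.
#'
#' @param age Age in years (vectorised), >= entry age.
#' @param state `"independent"` or `"dependent"`.
#' @param params A [stroke_params] tibble.
#' @return Annual death probability.
#' @examples
#' annual_background_mortality(63, "independent", default_parameters())
#' @export
annual_background_mortality <- function(age, state, params) {
  state <- match.arg(state, c("independent", "dependent"))
  pv <- param_values(params)
  if (any(age < pv[["entry_age"]])) {
    stop("age below model entry age", call. = FALSE)
  }
  a0 <- pv[["entry_age"]]
  a1 <- pv[["mortality_max_age"]]
  m0 <- pv[["mortality_anchor_entry"]]
  m1 <- pv[["mortality_anchor_max"]]
  m <- pmin(exp(log(m0) + (age - a0) / (a1 - a0) * (log(m1) - log(m0))), 1)
  if (state == "dependent") m <- pmin(pv[["hr_nonstroke_death_dep"]] * m, 1)
  m
}

#' Per-cycle stroke recurrence probability
#'
#' The annual recurrence rate of the state (events per patient-year) is
#' escalated by `rr_recur_per_year` for every year elapsed since day 90 and
#' treated as an annual probability scaled linearly to the cycle length,
#' capped at 1.
#'
#' @param state `"independent"` or `"dependent"`.
#' @param t Years since model entry at cycle start (vectorised), >= 0.25.
#' @param length Cycle length in years.
#' @param params A [stroke_params] tibble.
#' @return Probability of a recurrent stroke during the cycle.
#' @examples
#' cycle_recurrence_probability("dependent", 10.25, 1, default_parameters())
#' @export
cycle_recurrence_probability <- function(state, t, length, params) {
  state <- match.arg(state, c("independent", "dependent"))
  if (any(t < 0.25)) stop("recurrence applies from day 90 (t >= 0.25)",
                          call. = FALSE)
  if (any(length <= 0)) stop("cycle length must be > 0", call. = FALSE)
  pv <- param_values(params)
  rate <- if (state == "independent") pv[["recur_rate_indep"]] else
    pv[["recur_rate_dep"]]
  esc <- pv[["rr_recur_per_year"]]^(t - 0.25)
  pmin(rate * esc * length, 1)
}

# One Markov cycle on a cohort state vector. Hazards are sequential:
# recurrence (with its case fatality and survivor reallocation) is resolved
# first, then every survivor of the cycle - recurrent or not - faces the
# state's background mortality. Background mortality uses mid-cycle age.
# Returns end-of-cycle occupancy plus the event proportions accrual needs.
markov_cycle <- function(state, t, length, pv) {
  esc <- pv[["rr_recur_per_year"]]^(t - 0.25)
  pr_i <- min(pv[["recur_rate_indep"]] * esc * length, 1)
  pr_d <- min(pv[["recur_rate_dep"]] * esc * length, 1)
  age <- pv[["entry_age"]] + t + length / 2
  m_i <- min(exp(log(pv[["mortality_anchor_entry"]]) +
                   (age - pv[["entry_age"]]) /
                   (pv[["mortality_max_age"]] - pv[["entry_age"]]) *
                   (log(pv[["mortality_anchor_max"]]) -
                      log(pv[["mortality_anchor_entry"]]))), 1)
  m_d <- min(pv[["hr_nonstroke_death_dep"]] * m_i, 1)
  pm_i <- 1 - (1 - m_i)^length
  pm_d <- 1 - (1 - m_d)^length

  rec_i <- state[["indep"]] * pr_i
  rec_d <- state[["dep"]] * pr_d
  rec_i_fatal <- rec_i * pv[["p_death_given_recur"]]
  rec_d_fatal <- rec_d * pv[["p_death_given_recur"]]
  # recurrence survivors are still exposed to background mortality
  rec_i_surv <- (rec_i - rec_i_fatal) * (1 - pm_i)
  rec_d_surv <- (rec_d - rec_d_fatal) * (1 - pm_d)
  bg_i <- (state[["indep"]] - rec_i) * pm_i
  bg_d <- (state[["dep"]] - rec_d) * pm_d

  end_indep <- (state[["indep"]] - rec_i) * (1 - pm_i) + rec_i_surv / 2
  end_dep <- (state[["dep"]] - rec_d) * (1 - pm_d) + rec_i_surv / 2 +
    rec_d_surv
  end_dead <- state[["dead"]] + rec_i_fatal + rec_d_fatal + bg_i + bg_d +
    (rec_i - rec_i_fatal) * pm_i + (rec_d - rec_d_fatal) * pm_d

  list(end = c(indep = unname(end_indep), dep = unname(end_dep),
               dead = unname(end_dead)),
       recur_indep = unname(rec_i), recur_dep = unname(rec_d),
       recur_fatal = unname(rec_i_fatal + rec_d_fatal),
       recur_surv_from_indep = unname(rec_i_surv),
       recur_surv_from_dep = unname(rec_d_surv),
       bg_deaths = unname(bg_i + bg_d +
                            (rec_i - rec_i_fatal) * pm_i +
                            (rec_d - rec_d_fatal) * pm_d))
}

#' Propagate a treatment arm through the Markov model
#'
#' Initialises the cohort from the arm's 90-day distribution and propagates
#' it cycle by cycle to the horizon. Cycle 1 is the acute phase (all
#' patients enter dependent and end in their day-90 state); recurrence and
#' background mortality act from cycle 2 onwards. The run is fully
#' deterministic.
#'
#' @param params A [stroke_params] tibble.
#' @param arm `"tpa"` or `"mt"`.
#' @param horizon Horizon in whole years; defaults to the `horizon` setting.
#' @return A `stroke_trace` tibble with one row per cycle: `cycle`,
#'   `start`, `length`, `age`, start/end occupancy of the three states
#'   (`indep`, `dep`, `dead` / `end_*`), and event proportions
#'   (`recur_indep`, `recur_dep`, `recur_fatal`, `recur_surv_from_indep`,
#'   `recur_surv_from_dep`, `bg_deaths`). The treatment arm and parameters
#'   travel along as attributes.
#' @examples
#' run_cohort(default_parameters(), "tpa", horizon = 5)
#' @export
run_cohort <- function(params, arm, horizon = NULL) {
  arm <- arm_label(arm)
  stop_if_invalid(params)
  pv <- param_values(params)
  horizon <- horizon %||% pv[["horizon"]]
  sched <- cycle_schedule(horizon)
  d90 <- day90_distribution(params, arm)
  n <- nrow(sched)

  occ_start <- matrix(0, n, 3, dimnames = list(NULL, c("indep", "dep", "dead")))
  occ_end <- occ_start
  ev <- matrix(0, n, 6, dimnames = list(NULL, c(
    "recur_indep", "recur_dep", "recur_fatal",
    "recur_surv_from_indep", "recur_surv_from_dep", "bg_deaths")))

  # acute cycle: hospitalised (dependent) -> day-90 distribution
  occ_start[1, ] <- c(0, 1, 0)
  state <- c(indep = d90$p_indep, dep = d90$p_dep, dead = d90$p_dead)
  occ_end[1, ] <- state
  if (n > 1) for (i in 2:n) {
    occ_start[i, ] <- state
    cyc <- markov_cycle(state, sched$start[i], sched$length[i], pv)
    occ_end[i, ] <- cyc$end
    ev[i, ] <- c(cyc$recur_indep, cyc$recur_dep, cyc$recur_fatal,
                 cyc$recur_surv_from_indep, cyc$recur_surv_from_dep,
                 cyc$bg_deaths)
    state <- cyc$end
  }

  trace <- tibble::tibble(
    cycle = sched$cycle, start = sched$start, length = sched$length,
    age = pv[["entry_age"]] + sched$start,
    indep = occ_start[, "indep"], dep = occ_start[, "dep"],
    dead = occ_start[, "dead"],
    end_indep = occ_end[, "indep"], end_dep = occ_end[, "dep"],
    end_dead = occ_end[, "dead"],
    recur_indep = ev[, "recur_indep"], recur_dep = ev[, "recur_dep"],
    recur_fatal = ev[, "recur_fatal"],
    recur_surv_from_indep = ev[, "recur_surv_from_indep"],
    recur_surv_from_dep = ev[, "recur_surv_from_dep"],
    bg_deaths = ev[, "bg_deaths"]
  )
  structure(trace, arm = arm, horizon = horizon, params = params,
            class = c("stroke_trace", class(trace)))
}

#' @export
print.stroke_trace <- function(x, ...) {
  cat("<stroke_trace> arm = ", attr(x, "arm"),
      ", horizon = ", attr(x, "horizon"), " years\n", sep = "")
  NextMethod()
}
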