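test_that("cycle schedule is 0.25, 0.75, then annual, spanning the horizon", {
  s <- cycle_schedule(30)
  expect_equal(nrow(s), 31)
  expect_equal(s$length[1:3], c(0.25, 0.75, 1))
  expect_equal(sum(s$length), 30)
  # contiguity
  expect_equal(s$start[-1], (s$start + s$length)[-nrow(s)])

  s1 <- cycle_schedule(1)
  expect_equal(s1$length, c(0.25, 0.75))
  for (h in c(2, 7, 13)) expect_equal(sum(cycle_schedule(h)$length), h)
  expect_error(cycle_schedule(0), "horizon")
  expect_error(cycle_schedule(2.5), "horizon")
})

test_that("background mortality interpolates log-linearly between anchors", {
  p <- default_parameters()
  expect_equal(annual_background_mortality(63, "independent", p), 0.0089)
  expect_equal(annual_background_mortality(93, "independent", p), 0.1653)
  # probability-scale HR adjustment for the dependent state
  expect_equal(annual_background_mortality(63, "dependent", p),
               1.78 * 0.0089)
  # geometric (log-linear) midpoint at the midpoint age
  expect_equal(annual_background_mortality(78, "independent", p),
               sqrt(0.0089 * 0.1653), tolerance = 1e-12)
  # log-linear extrapolation beyond the upper anchor, capped at 1
  m94 <- annual_background_mortality(94, "independent", p)
  expect_gt(m94, 0.1653)
  expect_equal(annual_background_mortality(200, "independent", p), 1)
  expect_equal(annual_background_mortality(120, "dependent", p), 1)
  expect_error(annual_background_mortality(50, "independent", p), "entry age")
})

test_that("recurrence probability escalates per life-year from day 90", {
  p <- default_parameters()
  expect_equal(cycle_recurrence_probability("independent", 0.25, 1, p), 0.1026)
  expect_equal(cycle_recurrence_probability("dependent", 10.25, 1, p),
               0.1418 * 1.03^10, tolerance = 1e-12)
  # linear scaling to the 9-month cycle
  expect_equal(cycle_recurrence_probability("dependent", 0.25, 0.75, p),
               0.1418 * 0.75)
  pz <- set_param(p, "recur_rate_indep", base = 0, lo = 0, hi = 0)
  expect_equal(cycle_recurrence_probability("independent", 5.25, 1, pz), 0)
  # capped at 1
  pb <- set_param(p, "recur_rate_dep", base = 5, lo = 5, hi = 5)
  expect_equal(cycle_recurrence_probability("dependent", 0.25, 1, pb), 1)
  expect_error(cycle_recurrence_probability("independent", 0.1, 1, p),
               "day 90")
})

test_that("a Markov cycle matches exhaustive enumeration of the event tree", {
  p <- default_parameters()
  pv <- stats::setNames(p$base, p$name)
  start <- c(indep = 1, dep = 0, dead = 0)
  got <- strokecea:::markov_cycle(start, t = 0.25, length = 1, pv)

  # independent brute force: walk every path of the event tree for a
  # patient starting independent (recur? -> die of recurrence? -> move?
  # -> background death?), accumulating path probabilities
  pr <- 0.1026 * 1.03^0          # recurrence probability, cycle length 1
  pf <- 0.2101                   # case fatality of recurrence
  age <- 63 + 0.25 + 0.5
  m_i <- exp(log(0.0089) + (age - 63) / 30 * (log(0.1653) - log(0.0089)))
  end <- c(indep = 0, dep = 0, dead = 0)
  paths <- list(
    list(pr * pf, "dead"),                              # fatal recurrence
    list(pr * (1 - pf) * 0.5 * (1 - m_i), "indep"),     # recur, stay indep
    list(pr * (1 - pf) * 0.5 * (1 - m_i), "dep"),       # recur, move to dep
    list(pr * (1 - pf) * m_i, "dead"),                  # recur then bg death
    list((1 - pr) * (1 - m_i), "indep"),                # uneventful
    list((1 - pr) * m_i, "dead")                        # bg death
  )
  for (pa in paths) end[pa[[2]]] <- end[pa[[2]]] + pa[[1]]
  expect_equal(sum(end), 1, tolerance = 1e-14)
  expect_equal(got$end, end, tolerance = 1e-12)
  expect_equal(got$recur_indep, pr, tolerance = 1e-12)
  expect_equal(got$recur_fatal, pr * pf, tolerance = 1e-12)
})

test_that("the dead state is absorbing and zero hazards are the identity", {
  p <- default_parameters()
  pv <- stats::setNames(p$base, p$name)
  dead <- c(indep = 0, dep = 0, dead = 1)
  got <- strokecea:::markov_cycle(dead, t = 1, length = 1, pv)
  expect_equal(got$end, dead)
  expect_equal(got$recur_indep + got$recur_dep + got$bg_deaths, 0)

  pq <- quiet_params(p)
  pvq <- stats::setNames(pq$base, pq$name)
  start <- c(indep = 0.4, dep = 0.35, dead = 0.25)
  got <- strokecea:::markov_cycle(start, t = 2, length = 1, pvq)
  expect_equal(got$end, start, tolerance = 1e-9)
})

test_that("cohort traces conserve occupancy and absorb into death", {
  p <- default_parameters()
  for (arm in c("tpa", "mt")) {
    tr <- run_cohort(p, arm, horizon = 30)
    expect_equal(nrow(tr), 31)
    sums <- tr$end_indep + tr$end_dep + tr$end_dead
    expect_true(all(abs(sums - 1) <= 1e-12))
    expect_true(all(diff(tr$end_dead) >= 0))
    expect_gte(tr$end_dead[nrow(tr)], day90_distribution(p, arm)$p_dead)
    # end of cycle k is the start of cycle k + 1
    expect_equal(tr$indep[-1], tr$end_indep[-nrow(tr)])
    expect_equal(tr$dep[-1], tr$end_dep[-nrow(tr)])
    # no inflow to the independent state after day 90
    expect_true(all(diff(tr$end_indep[-1]) <= 1e-12))
  }
})

test_that("without post-acute hazards occupancy is frozen at day 90", {
  tr <- run_cohort(quiet_params(), "tpa", horizon = 10)
  d90 <- day90_distribution(default_parameters(), "tpa")
  expect_equal(tr$end_indep, rep(d90$p_indep, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$end_dead, rep(d90$p_dead, nrow(tr)), tolerance = 1e-9)
})

test_that("a higher dependent-state mortality hazard costs life-years", {
  p <- default_parameters()
  ly <- function(params) {
    tr <- run_cohort(params, "tpa", horizon = 30)
    sum(tr$length * (tr$end_indep + tr$end_dep))
  }
  p_hi <- set_param(p, "hr_nonstroke_death_dep", base = 2.14)
  expect_lt(ly(p_hi), ly(p))
})
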