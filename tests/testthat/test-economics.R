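test_that("discount factors are continuous in fractional years", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(0.625, 0.03), 1.03^(-0.625))
  expect_equal(discount_factor(2, 0), 1)
  expect_error(discount_factor(-1, 0.03), "t")
})

test_that("undiscounted single-state accrual has its closed form", {
  # whole cohort dependent at day 90, no further transitions, no discounting:
  # the cumulative half-cycle correction accrues exactly horizon * utility
  p <- set_discounts(quiet_params(all_dependent_params()), 0)
  arm <- accrue(run_cohort(p, "tpa", horizon = 30))
  expect_equal(arm$qaly, 30 * 0.21, tolerance = 1e-9)
  # costs: acute tree plus 29.75 years of dependent maintenance cost
  expect_equal(arm$cost, 13729 + 11179 + 29.75 * 11350, tolerance = 1e-6)
})

test_that("positive discounting strictly lowers both totals", {
  p0 <- set_discounts(default_parameters(), 0)
  p3 <- default_parameters()
  a0 <- accrue(run_cohort(p0, "mt", 30))
  a3 <- accrue(run_cohort(p3, "mt", 30))
  expect_lt(a3$qaly, a0$qaly)
  expect_lt(a3$cost, a0$cost)
  # QALYs never exceed undiscounted life-years
  tr <- run_cohort(p0, "mt", 30)
  expect_lte(a0$qaly, sum(tr$length * (tr$end_indep + tr$end_dep)) + 0.25)
})

test_that("accrue agrees with a direct recomputation from the trace", {
  p <- default_parameters()
  tr <- run_cohort(p, "tpa", 30)
  res <- accrue(tr)
  # independent accumulation over trace rows with plain vector arithmetic
  pv <- stats::setNames(p$base, p$name)
  mid <- tr$start + tr$length / 2
  post <- tr$cycle > 1
  q <- tr$length * (tr$end_indep * 0.76 + tr$end_dep * 0.21) +
    (tr$recur_surv_from_indep * ((0.34 - 0.76) + (0.34 - 0.21)) / 2 +
       tr$recur_surv_from_dep * (0.34 - 0.21)) * 30 / 365.25
  qaly <- acute_qaly(p, arm = "tpa") * 1.03^(-0.125) +
    sum((q * 1.03^(-mid))[post])
  expect_equal(res$qaly, qaly, tolerance = 1e-12)
  c_post <- tr$length * (tr$end_indep * 7385 + tr$end_dep * 11350) +
    tr$recur_surv_from_indep * (10055 + 13729) / 2 +
    tr$recur_surv_from_dep * 13729 + tr$recur_fatal * 11121
  cost <- acute_cost(p, arm = "tpa") * 1.03^(-0.125) +
    sum((c_post * 1.03^(-mid))[post])
  expect_equal(res$cost, cost, tolerance = 1e-9)
})

test_that("recurrence event costs can be switched off", {
  p <- default_parameters()
  tr <- run_cohort(p, "tpa", 30)
  with_ev <- accrue(tr, recurrence_event_costs = TRUE)
  without <- accrue(tr, recurrence_event_costs = FALSE)
  expect_lt(without$cost, with_ev$cost)
  expect_equal(without$qaly, with_ev$qaly)
})

test_that("incremental ratios reproduce the published identities", {
  mk <- function(arm, horizon, qaly, cost) {
    structure(tibble::tibble(arm = arm, horizon = horizon, qaly = qaly,
                             cost = cost),
              class = c("stroke_arm_result", class(tibble::tibble())))
  }
  # thirty-year and one-year published per-arm totals
  ce30 <- icer(mk("tpa", 30, 2.979, 117940), mk("mt", 30, 3.773, 167970))
  expect_equal(ce30$delta_qaly, 0.794)
  expect_equal(ce30$delta_cost, 50030)
  expect_equal(round(ce30$icer), 63010)
  ce1 <- icer(mk("tpa", 1, 0.326, 27220), mk("mt", 1, 0.405, 77700))
  expect_equal(round(ce1$icer), 638987)

  dom <- icer(mk("tpa", 1, 1.0, 100), mk("mt", 1, 2.0, 50))
  expect_equal(dom$status, "dominant")
  expect_true(is.na(dom$icer))
  dtd <- icer(mk("tpa", 1, 2.0, 50), mk("mt", 1, 1.0, 100))
  expect_equal(dtd$status, "dominated")
  und <- icer(mk("tpa", 1, 1.0, 50), mk("mt", 1, 1.0, 100))
  expect_equal(und$status, "undefined")
  expect_error(icer(mk("tpa", 1, 1, 1), mk("mt", 5, 1, 1)), "horizon")
})

test_that("cost-effectiveness calls agree with incremental net benefit", {
  mk <- function(arm, qaly, cost) {
    structure(tibble::tibble(arm = arm, horizon = 30, qaly = qaly,
                             cost = cost),
              class = c("stroke_arm_result", class(tibble::tibble())))
  }
  set.seed(5)
  for (i in 1:25) {
    q <- runif(2, 0, 5)
    cst <- runif(2, 0, 2e5)
    wtp <- runif(1, 1e4, 3e5)
    ce <- icer(mk("tpa", q[1], cst[1]), mk("mt", q[2], cst[2]))
    inb <- wtp * ce$delta_qaly - ce$delta_cost
    if (ce$delta_qaly > 0) {
      expect_equal(is_cost_effective(ce, wtp), inb > 0)
    } else {
      expect_false(is_cost_effective(ce, wtp))
    }
  }
  ce <- icer(mk("tpa", 2.979, 117940), mk("mt", 3.773, 167970))
  expect_true(is_cost_effective(ce, 125700))
  ce1 <- icer(mk("tpa", 0.326, 27220), mk("mt", 0.405, 77700))
  expect_false(is_cost_effective(ce1, 125700))
})

test_that("the base-case table mirrors the two-arm layout per horizon", {
  tbl <- base_case_table(default_parameters(), horizons = c(1, 5))
  expect_equal(nrow(tbl), 4)
  expect_equal(tbl$strategy, rep(c("tpa", "mt"), 2))
  expect_true(all(is.na(tbl$icer[tbl$strategy == "tpa"])))
  expect_true(all(tbl$icer[tbl$strategy == "mt"] > 0))
  ce <- run_cea(default_parameters(), 5)
  expect_equal(tbl$icer[4], ce$icer)
})

test_that("tidiers expose per-strategy rows and one-row summaries", {
  ce <- run_cea(default_parameters(), horizon = 1)
  td <- tidy(ce)
  expect_equal(td$strategy, c("tpa", "mt"))
  expect_equal(td$qaly[2] - td$qaly[1], ce$delta_qaly)
  gl <- glance(ce)
  expect_equal(gl$icer, ce$icer)
})
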