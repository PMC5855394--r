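# strokecea

Cost-utility modelling of endovascular mechanical thrombectomy (MT) added
to intravenous tPA thrombolysis, versus tPA alone, for acute ischaemic
stroke with proximal anterior circulation occlusion, in the Chinese
healthcare setting (2013 CNY, payer perspective).

The package is aimed at health-economics analysts who want a fully
scripted, testable version of this class of model: a 90-day decision tree
feeding a three-state Markov cohort (independent mRS 0-2, dependent
mRS 3-5, dead), with deterministic, one-way, scenario and probabilistic
sensitivity analyses, and an individual-level microsimulation oracle for
validating the cohort engine.

## The model in brief

* **Decision tree (day 0-90).** The tPA arm's 90-day outcome proportions
  are inputs; the MT arm's are derived through pooled trial odds ratios
  via p2 = OR·p1 / (1 + (OR−1)·p1). Acute costs: one-time
  hospitalisation by state, tPA and MT add-ons, sICH add-on.
* **Markov cohort (day 90 onward).** Cycles of 0.75 y then 1 y to a
  30-year horizon. Per cycle: recurrent stroke (state-specific annual
  rate, escalating 1.03-fold per year since day 90; case fatality
  0.2101; surviving independents split 50/50 between independent and
  dependent), then background non-stroke mortality (log-linear in age
  between anchors 0.0089 at 63 and 0.1653 at 93; ×1.78 for the dependent
  state). Utilities 0.76 / 0.21 / 0, with temporary states for recurrence
  (30 d at 0.34) and sICH (14 d at a 0.84 multiplicative factor).
* **Economics.** Half-cycle-corrected accrual, 3%/year discounting at
  cycle midpoints, ICER = ΔCost/ΔQALY, cost-effectiveness thresholds
  125 700 and 41 900 CNY per QALY (3× and 1× 2013 GDP per capita).

## Worked example

```r
library(strokecea)

params <- default_parameters()
base_case_table(params, horizons = c(1, 6, 30))
#> # A tibble: 6 × 7
#>   horizon strategy  qaly    cost delta_qaly delta_cost    icer
#>     <dbl> <chr>    <dbl>   <dbl>      <dbl>      <dbl>   <dbl>
#> 1       1 tpa      0.320  28522.    NA             NA      NA
#> 2       1 mt       0.400  79747.     0.0806     51225. 635270.
#> 3       6 tpa      1.60   66047.    NA             NA      NA
#> 4       6 mt       2.02  115957.     0.422      49910. 118240.
#> 5      30 tpa      3.03  117660.    NA             NA      NA
#> 6      30 mt       3.81  168812.     0.786      51152.  65097.
```

Read: at one year MT buys 0.081 QALYs for an extra 51 225 CNY — an ICER
of about 635 000 CNY/QALY, far above the 125 700 threshold, so MT is not
cost-effective that early. By year 6 the ICER (118 240) drops below the
threshold, and over 30 years MT gains 0.786 QALYs at 51 152 CNY extra,
about 65 000 CNY per QALY.

```r
ce <- run_cea(params, horizon = 30)
is_cost_effective(ce, param_value(params, "wtp"))
#> [1] TRUE

psa <- run_psa(params, n_draws = 10000, seed = 1)
probability_cost_effective(psa, 125700)
#> [1] 0.9991
```

At 10 000 probabilistic draws, 99.9% of simulations are cost-effective at
the 125 700 CNY/QALY threshold. `ceac(psa)` returns the full
acceptability curve; `autoplot(psa)` draws the cost-effectiveness plane;
`one_way_dsa(params)` and `plot_tornado()` give the tornado analysis;
`scenario_grid(params)` crosses worse-efficacy scenarios with MT price
changes; `microsimulate()` cross-checks the cohort engine patient by
patient.

Parameters are a plain tibble: inspect them with `default_parameters()`,
override with `set_param()`, or load a (partial) YAML configuration with
`read_parameters()` — the packaged default file is at
`inst/extdata/default_inputs.yaml`.

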