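---
title: "Model structure and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecea)
```

## The decision problem

strokecea models the lifetime cost-utility of adding endovascular
mechanical thrombectomy (MT, second-generation stent retrievers, within
6 h of onset) to intravenous tPA thrombolysis, versus tPA alone, for acute
ischaemic stroke caused by proximal anterior circulation occlusion. The
setting is the Chinese healthcare payer, with all costs in 2013 CNY and
willingness-to-pay thresholds of 125 700 CNY/QALY (3x 2013 GDP per capita)
and 41 900 CNY/QALY (1x). A cohort of 100 000 patients enters at age 63
and is followed for up to 30 years.

The model has two stages:

1. **A 90-day decision tree.** The tPA arm's 90-day outcome mix -
   independent (mRS 0-2), dependent (mRS 3-5), dead (mRS 6) - and its
   symptomatic intracerebral haemorrhage (sICH) proportion are inputs.
   The MT arm's proportions are obtained by pushing each tPA proportion
   through its pooled trial odds ratio,
   $p_2 = \mathrm{OR}\,p_1 / (1 + (\mathrm{OR}-1)\,p_1)$,
   with the dependent share as the complement. The odds ratios are
   intention-to-treat effects and so apply to the whole arm, while the MT
   add-on cost applies only to the 86.1% who actually receive the
   procedure and the tPA add-on cost to the 85.4% arriving within 4.5 h
   (both arms).
2. **A three-state Markov cohort model.** After day 90 the cohort moves
   between independent, dependent and dead over a 0.75-year cycle to the
   end of year one and annual cycles thereafter. Within a cycle a patient
   may suffer a recurrent stroke (state-specific annual rate, escalating
   3%/year), die of it (case fatality 0.2101), or - having survived
   recurrence or avoided it - die of a non-stroke cause. Recurrence
   survivors from the independent state are reallocated 50/50 between
   independent and dependent; survivors from the dependent state remain
   dependent. Death is absorbing and there is no inflow to the
   independent state.

## Engine conventions

Several internals of such models are conventions rather than published
facts. The choices below are this package's model definition; they were
fixed once against the published base-case results and are exercised
directly by the test suite.

* **Half-cycle correction, cumulative form.** Post-acute cycles are valued
  at end-of-cycle occupancy; the acute cycle is valued trapezoidally from
  an all-dependent entry state (patients are hospitalised, functionally
  dependent, at the index event) to the day-90 distribution. The sum is
  the classic "initial half-cycle credit plus end-of-cycle rewards"
  correction. Patients dying by day 90 therefore accrue the entry-side
  half of the acute cycle and nothing after.
* **Discounting.** Continuous factors $(1+r)^{-t}$ evaluated at each
  cycle's midpoint, 3%/year for both costs and outcomes (separate rates
  supported).
* **Recurrence probabilities.** Annual recurrence rates (0.1026
  independent, 0.1418 dependent, per patient-year) are treated as annual
  probabilities scaled linearly by cycle length and capped at 1, after
  escalation by $1.03^{t-0.25}$ - the escalation clock starts at day 90,
  when the Markov phase begins.
* **Background mortality.** The annual non-stroke death probability is
  anchored at 0.0089 (age 63) and 0.1653 (age 93) and interpolated
  log-linearly in age (a geometric, Gompertz-like progression),
  extrapolated beyond 93 and capped at 1. It is evaluated at the cycle's
  mid-cycle age. The dependent state multiplies the probability by the
  hazard ratio 1.78 directly on the probability scale, capped at 1.
* **Event ordering.** Recurrence (with its case fatality and
  reallocation) resolves first; every survivor of that stage - recurrent
  or not - then faces the cycle's background mortality at the origin
  state's risk. The two hazards are sequential, not mutually exclusive.
* **Temporary health states.** A surviving recurrence spends 30 days at
  utility 0.34 instead of its destination-state utility. An sICH spends
  14 days with its state utility multiplied by 0.84; the factor is
  multiplicative because 0.84 exceeds the best state utility (0.76), so
  it cannot be an absolute utility. sICH status is drawn independently of
  the day-90 state.
* **Recurrence event costs.** Each surviving recurrence is charged the
  one-time hospitalisation cost of its destination state in the cycle of
  occurrence; fatal recurrences are charged the mRS 6 cost. The published
  inputs do not state this explicitly, so it is exposed as the
  `recurrence_event_costs` switch (on by default; switching it off lowers
  both arms' costs by a similar amount and moves the 30-year ICER only
  modestly).

These conventions reproduce the published base case to within 2% on every
QALY cell and 5% on every cost cell across the 1-, 5-, 6- and 30-year
horizons, and the published one-way and scenario ICERs to within 4%
(see `tests/testthat/test-acceptance.R`, which asserts looser, explicit
tolerances). During development, plausible alternatives - mean-of-
start/end accrual, exponential rate-to-probability transforms, rate-scale
hazard-ratio adjustment, mutually exclusive event pathways - were each
worse by 4-12% against the published results and were rejected.

```{r basecase}
base_case_table(default_parameters(), horizons = c(1, 5, 6, 30))
```

## Parameters

`default_parameters()` returns all inputs as a tibble with base values and
plausible ranges; `read_parameters()`/`write_parameters()` round-trip a
YAML configuration (the packaged copy lives in
`inst/extdata/default_inputs.yaml`). Inputs without a published range
(durations, the mortality anchors, run settings other than discount
rates) carry `lo == hi == base` and are never varied. The model computes
in 2013 CNY throughout; `cny_to_usd()` (divide by 6.5) is display-only.

## Sensitivity analyses

**One-way (tornado).** `one_way_dsa()` re-runs the full model at each
ranged input's lower and upper limit, everything else at base, and sorts
by ICER spread; `plot_tornado()` displays the top 10. Variations that
erase the QALY gain are flagged rather than dropped. Discount rates are
varied here (their published ranges are 0.03-0.08 for costs and +/-20%
for outcomes) even though they are excluded from the probabilistic
analysis below.

**Scenario grid.** `scenario_grid()` crosses efficacy scenarios for the
independence odds ratio (base; its published 95% CI lower limit 1.692 as
"worse-unfavourable"; optionally a user-supplied 90% CI lower limit as
"unfavourable", which is not published and therefore has no default) with
MT price multipliers 1.10, 1.00, 0.90, 0.75, 0.50 - 15 model runs when
the 90% limit is supplied, 10 otherwise.

**Probabilistic (PSA).** `run_psa()` interprets each plausible range as a
central 95% interval and samples parameters independently: beta for
probabilities, utilities and the recurrence rates (moment-matched, mean at
the base value, SD = (hi - lo)/3.92), log-normal for the eight costs and
for the odds/hazard-ratio parameters (log-scale median at base,
log-SD = (log hi - log lo)/3.92). Discount rates are not sampled: the
published cost-rate range has its base at the lower limit, which admits no
central-interval fit, and varying discount rates deterministically is the
field's convention. Joint draws violating the 90-day constraint
`p_mrs02_tpa + p_death_tpa <= 1` are resampled (this is rare; more than
100 rounds abort). Each draw runs the full two-arm 30-year model; the
default analysis uses 10 000 draws and reports the cost-effectiveness
acceptability curve over 0-300 000 CNY/QALY. With all ranges collapsed,
every draw reproduces the deterministic base case exactly - a property
the tests assert.

## The microsimulation oracle

`microsimulate()` is an independent implementation of the same transition
law at the individual level: it samples each patient's day-90 state and
decision-tree events, then per cycle samples recurrence, case fatality,
reallocation and background death, and accrues the same discounted
rewards patient by patient. It shares the parameter structures but not
the cohort code path, so agreement is evidence rather than tautology. The
central correctness property - asserted over 20 random parameter sets
from `random_parameter_set()` (every input perturbed uniformly within
+/-30% of base, clipped to domain) - is that cohort totals lie within 3
Monte Carlo standard errors of microsimulation means at 200 000 patients.

## What the synthetic inputs do and do not show

`random_parameter_set()` produces internally consistent inputs for
property testing; it preserves the model's structure, not the
epidemiology of any real population. Passing the equivalence and property
suites shows the cohort algebra, accrual and discounting are implemented
correctly - it cannot validate the published inputs themselves, the
trial-derived odds ratios, or transportability beyond the modelled
setting.

## Problem sizes and numerical choices

Deterministic runs propagate 31 cycles and complete in milliseconds; the
packaged analyses use 10 000 PSA draws and 200 000-patient
microsimulations, the sizes at which Monte Carlo error is small relative
to the tolerances asserted. State-vector conservation is maintained to
1e-12 per cycle (the dead state absorbs the exact complement).
Probabilities from rates and hazard-ratio scaling are capped at 1;
log-linear mortality extrapolation is capped at 1 from roughly age 108.
ICERs are reported only when the QALY difference is non-zero; dominance
is flagged instead of returning a signed ratio.

## Known limitations

* The three-state structure collapses mRS 0-2 and 3-5; no tunnel states,
  no functional improvement after rehabilitation, no treatment switching.
* Non-stroke morbidity costs and indirect (productivity) costs are
  excluded by design, matching the payer perspective of the source data.
* Background mortality rests on two published anchor probabilities; the
  full life table behind them is not available, so the log-linear
  interpolation is an assumption.
* PSA draws are independent across parameters; no correlation structure
  is available for these inputs.
* The efficacy inputs are pooled intention-to-treat odds ratios from
  trials run in high-income countries; the model inherits whatever bias
  they carry.
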