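# shared fixtures built in code

# parameter set with no stochastic events after day 90: no recurrence,
# (numerically) no background mortality
quiet_params <- function(params = default_parameters()) {
  params <- set_param(params, "recur_rate_indep", base = 0, lo = 0, hi = 0)
  params <- set_param(params, "recur_rate_dep", base = 0, lo = 0, hi = 0)
  params <- set_param(params, "mortality_anchor_entry",
                      base = 1e-12, lo = 1e-12, hi = 1e-12)
  params <- set_param(params, "mortality_anchor_max",
                      base = 1e-12, lo = 1e-12, hi = 1e-12)
  params
}

# everyone dependent at day 90, no sICH, deterministic tPA receipt
all_dependent_params <- function(params = default_parameters()) {
  params <- set_param(params, "p_mrs02_tpa", base = 0, lo = 0, hi = 0)
  params <- set_param(params, "p_death_tpa", base = 0, lo = 0, hi = 0)
  params <- set_param(params, "p_sich_tpa", base = 0, lo = 0, hi = 0)
  params <- set_param(params, "p_arrive_45h", base = 1, lo = 1, hi = 1)
  params
}

# collapse every plausible range onto the base value
degenerate_params <- function(params = default_parameters()) {
  params$lo <- params$base
  params$hi <- params$base
  params
}

set_discounts <- function(params, rate) {
  params <- set_param(params, "discount_cost", base = rate, lo = rate, hi = rate)
  set_param(params, "discount_outcome", base = rate, lo = rate, hi = rate)
}
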