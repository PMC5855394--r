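outcomes:
  p_mrs02_tpa:
    base: 0.325
    lo: 0.258
    hi: 0.392
  p_death_tpa:
    base: 0.168
    lo: 0.131
    hi: 0.205
  p_sich_tpa:
    base: 0.058
    lo: 0.035
    hi: 0.095
  or_mrs02:
    base: 2.046
    lo: 1.692
    hi: 2.474
  or_death:
    base: 0.871
    lo: 0.684
    hi: 1.109
  or_sich:
    base: 0.965
    lo: 0.665
    hi: 1.399
transitions:
  p_receive_mt:
    base: 0.861
    lo: 0.839
    hi: 0.883
  p_arrive_45h:
    base: 0.854
    lo: 0.839
    hi: 0.869
  recur_rate_indep:
    base: 0.1026
    lo: 0.0961
    hi: 0.1093
  recur_rate_dep:
    base: 0.1418
    lo: 0.1303
    hi: 0.1534
  rr_recur_per_year:
    base: 1.03
    lo: 1.02
    hi: 1.04
  p_death_given_recur:
    base: 0.2101
    lo: 0.1887
    hi: 0.2316
  mortality_anchor_entry:
    base: 0.0089
    lo: 0.0089
    hi: 0.0089
  mortality_anchor_max:
    base: 0.1653
    lo: 0.1653
    hi: 0.1653
  hr_nonstroke_death_dep:
    base: 1.78
    lo: 1.43
    hi: 2.14
costs:
  c_mt_addon:
    base: 60821.0
    lo: 52314.0
    hi: 70311.0
  c_tpa_addon:
    base: 11179.0
    lo: 10555.0
    hi: 11829.0
  c_sich_addon:
    base: 2374.0
    lo: 2249.0
    hi: 2504.0
  c_hosp_indep:
    base: 10055.0
    lo: 9907.0
    hi: 10205.0
  c_hosp_dep:
    base: 13729.0
    lo: 13428.0
    hi: 14035.0
  c_hosp_death:
    base: 11121.0
    lo: 10219.0
    hi: 12081.0
  c_annual_indep:
    base: 7385.0
    lo: 7156.0
    hi: 7619.0
  c_annual_dep:
    base: 11350.0
    lo: 10730.0
    hi: 11996.0
utilities:
  u_indep:
    base: 0.76
    lo: 0.69
    hi: 0.82
  u_dep:
    base: 0.21
    lo: 0.17
    hi: 0.26
  u_death:
    base: 0.0
    lo: 0.0
    hi: 0.0
  u_recur_event:
    base: 0.34
    lo: 0.32
    hi: 0.36
  u_sich_event:
    base: 0.84
    lo: 0.72
    hi: 1.0
  dur_recur_days:
    base: 30.0
    lo: 30.0
    hi: 30.0
  dur_sich_days:
    base: 14.0
    lo: 14.0
    hi: 14.0
settings:
  cohort_size:
    base: 100000.0
    lo: 100000.0
    hi: 100000.0
  entry_age:
    base: 63.0
    lo: 63.0
    hi: 63.0
  mortality_max_age:
    base: 93.0
    lo: 93.0
    hi: 93.0
  horizon:
    base: 30.0
    lo: 30.0
    hi: 30.0
  discount_cost:
    base: 0.03
    lo: 0.03
    hi: 0.08
  discount_outcome:
    base: 0.03
    lo: 0.024
    hi: 0.036
  wtp:
    base: 125700.0
    lo: 125700.0
    hi: 125700.0
  wtp_low:
    base: 41900.0
    lo: 41900.0
    hi: 41900.0
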