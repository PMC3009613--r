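# Base-case model configuration: four-state quarterly Markov model of
# chronic low back pain, usual care vs usual-care-plus-acupuncture
# (collaborative) treatment. All monetary values are 2009 KRW.
model:
  n_cycles: 20            # 3-month cycles, 5-year horizon
  cycle_length_years: 0.25
  annual_discount_rate: 0.05
  cohort_size: 10000      # 60-year-old women entering in acute LBP

# Accounting conventions (see the methods vignette). cycle_discounting: false
# is the accumulation convention under which the model reproduces the
# published base-case cost/QALY table; setting it true applies
# (1 + rate)^(-cycle/4) to every per-cycle reward.
conventions:
  reward_timing: start    # start | end
  half_cycle: false
  cycle_discounting: false
  rr_scale: probability   # probability | rate

transitions:
  tATC: {value: 0.24, dist: beta, a: 29, b: 91}       # acute -> chronic
  tWTC: {value: 0.16, dist: beta, a: 26, b: 137}      # well -> chronic (6-month recurrence rescaled to 3 months)
  tCTW: {value: 0.35, dist: beta, a: 135, b: 252}     # chronic -> well, usual care
  tRR:  {value: 1.40, dist: lognormal, a: 0.34, b: 0.05}  # pooled recovery risk ratio

# All-cause mortality of the cohort. The constant stand-in approximates a
# 60-year-old Korean woman (~0.4%/year -> 0.001/quarter); alternatives:
#   type: life_table  with base_annual, growth_per_year, start_age
#   type: vector      with values: [...] (one probability per cycle)
mortality:
  type: constant
  per_cycle: 0.001

utilities:
  uALBP:     {value: 0.85, dist: beta, a: 3.97, b: 0.70}
  uCLBPUC:   {value: 0.62, dist: beta, a: 13.99, b: 8.57}
  uCLBPACUC: {value: 0.65, dist: beta, a: 14.14, b: 7.61}
  uWell:     {value: 0.96, dist: beta, a: 22.08, b: 0.92}

# Chronic-state costs per 3-month cycle. Direct medical costs are the
# per-visit-type totals times frequency; the itemised fee lines behind each
# total (first examination, diagnostics, pharmacy, drugs, physical therapy,
# and for the collaborative arm oriental-medicine examinations and
# general/special spine acupuncture) are folded into the per-visit totals.
costs:
  usual_care:
    visits:
      - {label: first visit, unit_cost: 53983, frequency: 1}
      - {label: regular visit (diagnosis and treatment), unit_cost: 31685, frequency: 6}
      - {label: simple regular visit, unit_cost: 10549, frequency: 3}
    direct_nonmedical: 232036
    chronic_cycle_dist: {dist: gamma, a: 24.69, b: 20566.20}   # mean ~507,776
  collaborative:
    visits:
      - {label: first visit, unit_cost: 57463, frequency: 1}
      - {label: regular visit (diagnosis and treatment), unit_cost: 50223, frequency: 6}
      - {label: simple regular visit, unit_cost: 24877, frequency: 3}
    direct_nonmedical: 296897
    chronic_cycle_dist: {dist: gamma, a: 19.54, b: 37372.18}   # mean ~730,329
  indirect_nonmedical: 239142   # per cycle, equal in both strategies
  include_indirect: false       # base case; univariate sensitivity toggles on

psa:
  n_draws: 10000
  seed: 20100101
  lambda_grid: {from: 0, to: 20000000, by: 20000}

voi:
  annual_incidence: 57400
  horizon_years: 5
  discount_rate: 0.05
  cohort_timing: start
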