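---
title: "Methods: a Markov cohort cost-effectiveness model of acupuncture collaborative care for chronic low back pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model of acupuncture collaborative care for chronic low back pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbpcea)
```

## The decision problem

South Korean patients with chronic low back pain (LBP) can be treated by
usual care alone (NSAIDs, heat therapy, electrotherapy, lumbar traction) or
by usual care plus acupuncture delivered collaboratively by medical and
Oriental-medicine doctors in the same facility. Collaboration improves the
chance of recovering from the chronic state and the quality of life while
chronically ill, but at a higher per-cycle cost. `lbpcea` implements the
decision-analytic model that weighs these against each other from a
societal perspective: a four-state Markov cohort model, incremental
cost-effectiveness analysis, probabilistic sensitivity analysis (PSA) with
cost-effectiveness acceptability curves (CEAC), and value-of-information
analysis, plus the random-effects meta-analysis machinery that produces the
treatment-effect parameter.

## Model structure

A cohort of 60-year-old women enters in the **acute LBP** state and moves
between four states in 3-month cycles over a 5-year horizon (20 cycles):

* **acute LBP** — a one-cycle entry state: after one cycle the patient has
  either chronified (probability `tATC = 0.24`) or recovered
  (`tATW = 0.76`). Acute care is identical across strategies, so the state
  carries no cost and the strategies share its dynamics.
* **chronic LBP** — the only cost-accruing state. Per cycle a chronic
  patient recovers with probability `tCTW = 0.35` under usual care; the
  collaborative strategy multiplies this by the pooled risk ratio
  `tRR = 1.40` (on the probability scale, capped at 1 — see below).
* **well** — recovered; relapse back to chronic LBP with `tWTC = 0.16` per
  cycle (a 6-month recurrence figure rescaled to 3 months through the
  constant-hazard conversion `p = 1 - exp(-rt)` implemented in
  `rate_to_prob()` / `prob_to_rate()`).
* **dead** — absorbing; every alive state dies with the cycle's all-cause
  mortality probability `mr`, applied before the clinical transitions
  (each remaining transition is scaled by `1 - mr`).

```{r matrix}
params <- transition_parameters()
build_transition_matrix(USUAL_CARE, params)
```

Rows are exactly stochastic by construction for every admissible parameter
draw, which the test suite asserts at 1e-12, and the cohort trace conserves
mass at 1e-10.

## Rewards: utilities and costs

Each cycle of state occupancy contributes `utility x 0.25` QALYs, with
utilities 0.85 (acute), 0.62 (chronic, usual care), 0.65 (chronic,
collaborative) and 0.96 (well); death contributes zero. Costs accrue only
in the chronic state: per 3-month cycle 507,776 KRW (usual care) and
730,329 KRW (collaborative) in the base case, composed from visit-schedule
arithmetic (one first visit, six regular visits, three simple visits at
per-visit totals of 53,983/31,685/10,549 and 57,463/50,223/24,877 KRW) plus
direct non-medical costs of 232,036 and 296,897 KRW. An indirect
productivity-loss component of 239,142 KRW per cycle — daily wage x
proportion economically active x employment rate, `indirect_cost()` — is
equal across strategies and excluded from the base case; the univariate
sensitivity analysis toggles it on. Because it is equal, it changes the
incremental cost only through the difference in chronic person-cycles
between strategies, which the tests assert.

One source discrepancy is resolved in the configuration: the collaborative
direct medical cost is printed once as 433,434 KRW, but the per-visit
component sum and the cost-composition table both give 433,432 KRW, which
the package uses.

## Accounting conventions

Three conventions are configuration-exposed because the source material
does not determine them:

* `reward_timing` (default `"start"`): rewards use the occupancy at the
  start of each cycle `c = 0..19`, so the initial all-acute cycle is
  rewarded. `"end"` uses post-transition occupancy (`c = 1..20`).
* `half_cycle` (default off): trapezoid correction averaging start- and
  end-of-cycle occupancy, discounted mid-cycle. Spreadsheet-era cohort
  models typically omit it, and the published results are matched without
  it.
* `cycle_discounting` (default off). The configured 5% annual rate drives
  `discount_factor()` (`1.05^(-0.25c)`) and the population EVPI
  multiplier. Applied per cycle to rewards, however, it produces
  accumulated QALYs around 3.79/3.90 per person — about 8% below the
  published 4.11/4.24 — whereas the *undiscounted* accumulation reproduces
  all five published base-case figures within about 3% simultaneously
  (4.238/4.369 QALYs, 2,923,397/3,374,836 KRW, ICER 3,439,780 vs 3,421,394
  KRW/QALY). We therefore treat "no per-cycle reward discounting" as the
  accounting convention of the original analysis, make it the shipped
  default so that the default configuration reproduces the published
  table, and keep true per-cycle discounting one flag away.

```{r conventions}
run_base_case(load_config())
```

## Mortality

The original mortality inputs are age- and sex-specific life-table values
that are not available here. The package accepts any per-cycle probability
vector; the shipped default is a constant 0.001 per quarterly cycle
(roughly a 0.4% annual risk, plausible for a 60-year-old Korean woman),
and `generate_life_table()` provides a clearly-synthetic Gompertz-like
alternative (default 0.4%/year at age 60 growing 8%/year, converted
annual-to-quarterly through the rate transforms rather than by division).
This stand-in is the main fidelity caveat: the published final-cycle
chronic occupancy is 29.71% and the model's is 30.75%, and the published
mean of 2,982 chronic cases per 10,000 is reproduced as 2,879 (-3.5%).
Both live inside the tolerance the calibration checks use (±2 percentage
points; ±5%).

## Treatment effect: meta-analysis and its application

The risk ratio multiplying the chronic-to-well probability is a
DerSimonian–Laird random-effects pooled estimate across trials of
acupuncture added to usual care. `log_rr_and_se()` computes per-study log
risk ratios with the large-sample standard error and a 0.5 continuity
correction applied to all cells of a study with a zero cell;
`dersimonian_laird_pool()` implements the moment estimator
(`tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`), reducing
exactly to the fixed-effect estimate when `tau2 = 0`. The pooled
`lognormal(0.34, 0.05)` — point value `exp(0.34) = 1.40` — parameterises
the PSA distribution via `pooled_to_lognormal()`.

The per-study 2x2 counts behind the original pooled estimate live in
external trial reports, so the default pipeline uses the pooled lognormal
directly, and `generate_meta_studies()` supplies seed-reproducible
synthetic evidence bases for exercising the pooling stage (the tests
recover a planted `logRR = 0.34` within 3 pooled standard errors from 50
synthetic studies, and cross-check the estimator against
`metafor::rma(method = "DL")`).

The risk ratio applies on the probability scale, `min(tRR x tCTW, 1)`,
matching the multiplicative structure of the transition-matrix definition;
a hazard-scale application (`rr_scale: rate`) is available but off by
default. Clamped products are warned about, never dropped.

## Probabilistic sensitivity analysis

Every uncertain parameter is drawn simultaneously, 10,000 times: Beta for
probabilities and utilities, Gamma (shape, scale) for the two chronic-state
cycle costs, lognormal for the risk ratio. The published parameter table's
"Probabilistic"/"Standard error" columns are internally inconsistent
(standard errors like 28.773 for a probability), so the alpha/beta columns
are interpreted as Beta/Gamma parameters — a reading
`check_distribution_consistency()` verifies by matching every analytic
distribution mean to its point value within 2% (e.g. Beta(135, 252) has
mean 0.3488 vs the 0.35 point value; Gamma(24.69, 20566.20) has mean
507,780 vs 507,776 KRW). The transition pairs (`tATC`,`tATW`) and
(`tWTC`,`tWTW`) are one Beta draw plus its complement, never two
independent draws. Draw order within an iteration is fixed (transitions,
utilities, costs, risk ratio) so seeds are portable across machines.

Per draw both strategies are evaluated with shared transition and utility
draws; only the risk ratio, chronic utility and chronic cycle cost are
strategy-specific. The CEAC uses the pairwise definition: the probability
that collaboration is cost-effective at threshold `lambda` is the fraction
of draws with `lambda x dQALY - dCost > 0`, ties counted toward usual
care, so the two acceptance probabilities sum to one exactly. The original
figure reports 72.3% and 26.3% at 20,000,000 KRW/QALY — summing to 98.6%,
which the pairwise definition cannot produce — so 72.3% is matched
approximately (the model gives 70–72% across seeds) and no attempt is made
to force agreement. The 50% crossing of the curve sits near the
deterministic ICER (published: 3,260,000 KRW/QALY; the package reports the
first grid threshold reaching 50% plus a linear interpolation).

Because the Beta and lognormal inputs are skewed, the PSA mean of the
incremental QALY sits about 10% below the deterministic point-value
evaluation (≈0.118 vs 0.1312). This is a property of the model, not a
sampling defect; the tests therefore check the law of large numbers across
independent seeds and only a coarse centring band against the
deterministic delta.

## Value of information

`evpi_at_threshold()` computes per-person EVPI as
`mean(max per-draw NMB) - max(mean NMB)`, non-negative by construction and
zero under degenerate distributions. `population_evpi()` scales it by
annual incident cohorts (57,400 cases/year) over a 5-year decision horizon
at 5%, cohorts arriving at the start of each year (year 0 undiscounted;
`cohort_timing: end` discounts every cohort one extra year), giving a
discounted population multiplier of about 260,938 persons. The resulting
curve shows the canonical two-strategy shape: a local per-person maximum
near the threshold region where the adoption decision flips (around
3.4–4M KRW/QALY), which is checked qualitatively only.

## Numerical choices and degenerate inputs

* ICERs are computed from full-precision cost and QALY differences;
  rounding to presentation precision happens only at output.
* Dominance labelling: equal outcomes are `"equivalent"`; cheaper-and-not-
  worse comparators are `"dominant"`; costlier-and-not-better are
  `"dominated"`, with an infinite ICER when the QALY difference is exactly
  zero — never an error.
* CEAC ties (`NMB` difference exactly zero) count toward the reference
  strategy; a curve that never reaches the requested level returns a
  sentinel rather than extrapolating.
* Degenerate (point-mass) distributions collapse the PSA to the
  deterministic base case exactly and the CEAC to a step function at the
  ICER; both are tested.
* All generators and the PSA are reproducible from a single integer seed;
  identical seeds give byte-identical CSV exports.

## Scope and limitations

* Two strategies only, as in the decision problem; the incremental
  analysis does not implement n-strategy extended-dominance pruning.
* Cohort-level simulation only: no tunnel states for chronicity duration,
  no patient-level memory (the Markov assumption).
* The mortality schedule and the meta-analytic evidence base are
  synthetic stand-ins with the right statistical structure, not the
  original sources; passing tests show the machinery reproduces the
  published analysis under those stand-ins, not that the stand-ins match
  Korean vital statistics or the six source trials.
* Costs are 2009 KRW throughout; no inflation adjustment. The 1,181.50
  KRW/USD rate is display-only.
* Problem sizes: the acceptance checks run the full 10,000-draw PSA
  (a few seconds); unit and property tests use 150–2,000 draws, and the
  brute-force path-enumeration oracle verifies the cohort engine up to 4
  cycles, where exhaustive enumeration is exact.
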