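---
title: "A decision-tree cost-of-illness model of deployment travelers' diarrhea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree cost-of-illness model of deployment travelers' diarrhea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcea)
```

## The model and its assumptions

`tdcea` models the burden of travelers' diarrhea (TD) over one
deployment-year of a military cohort as a static expected-value decision
tree. The core assumptions are:

* **Episodes are independent draws.** There is no transmission dynamic and
  no within-deployment time structure; the annual episode count is simply
  `deployment_size * duration_months * monthly_incidence`. With the default
  cohort (50,000 persons, 3.5 months, 28.9%/person-month) that is 50,575
  episodes.
* **Eight mutually exclusive terminal pathways.** Four medical dispositions
  partition every episode — outpatient treatment by a military healthcare
  (MH) provider, no MH treatment, hospitalization, medevac — and the first
  two branch into three conditional outcomes each (suboptimal care, optimal
  care, bed rest; run its course, self-treatment success, self-treatment
  failure). Hospitalization and medevac are top-level dispositions, not
  nested under care-seeking: the four disposition probabilities themselves
  sum to 100%.
* **Costs and effectiveness are attached to leaves, not to time.** Each leaf
  carries a per-episode cost to the military health system (USD) and a
  per-episode effectiveness loss in duty days lost (DDL). Run-its-course and
  self-treatment success generate no system cost. Self-treatment failure is
  a *terminal* costed outcome ($27, 0.48 DDL) rather than a cascade into an
  outpatient re-treatment subtree; this choice reproduces the reference
  annual-DDL totals exactly and the cost totals within 0.2% (see
  *Limitations*).
* **No discounting, no QALYs, no sequelae.** The horizon is one
  deployment-year and the effectiveness unit is the duty day; long-term
  post-infectious gastrointestinal disorders are out of scope.

The DDL unit values encode a duration-to-DDL chain (0.25 DDL per diarrheal
day of latrine and gear time, 1.5 days mean pre-treatment delay, and
endpoint-specific post-treatment durations); the package takes the resulting
per-leaf DDL values as parameters rather than recomputing the chain.

## Parameters

`td_parameters()` returns the full parameter table: 3 cohort constants, 10
branch probabilities in three sibling groups, 6 unit costs and 8 unit DDL
values, each with point estimate, low/high bounds and a distribution kind.
Cost bounds are ±20% of the point estimate; probability and DDL bounds come
from the underlying systematic review and expert elicitation. Everything is
stored in natural units — probabilities as fractions in [0, 1], costs in
USD, durations in days — with percentage conversion confined to display.

```{r params}
td_parameters()
```

Validation (`validate_parameters()`) enforces bound ordering, role-specific
ranges, and the three group-sum invariants at tolerance `1e-6`:
disposition `0.6907 + 0.30 + 0.009 + 0.0003 = 1`, outpatient
`0.278 + 0.351 + 0.371 = 1`, self-care `0.60 + 0.32 + 0.08 = 1`.

## Scenario transformations

Scenarios modify the base parameter set and nothing else; cohort constants,
hospitalization/medevac and the self-care group are never touched.

* **HCSB** (increased health-care-seeking) sets `p_mh_treatment` to its
  implementation level (40/55/70%) and removes the same mass from
  `p_no_mh`, conserving the disposition group sum. Because care is sought
  within ~8 hours rather than after 1.5 days, optimal-care DDL drops
  0.37 → 0.31 and bed-rest DDL 1.60 → 1.41.
* **OPB** (optimized provider prescribing) re-splits the outpatient
  *therapeutic pool* (everything except bed rest, 0.629 at baseline) so a
  target fraction (65/75/85%) receives single-dose antibiotic plus
  loperamide. The optimal share is `level * pool` rounded half-up to three
  decimals — the convention that makes the split agree with one-decimal
  percentage reporting (85% → 53.5%/9.4%) — and the suboptimal share takes
  the remainder, so the pool is conserved exactly. Optimal care is re-costed
  at $30 (a 65%/35% blend of $3 medic-level care and facility care), its
  DDL drops to 0.33 (15 h time-to-last-unformed-stool), and bed rest is
  halved to 12 h (0.88 DDL).
* **Combination** applies both probability shifts with further-compounded
  durations: optimal-care DDL 0.11 (8 h pre-treatment + 15 h TLUS) and
  bed-rest DDL 0.69.

On the scenario DDL overrides the available summaries disagree internally
(one tabulation prints 0.25/1.38 for HCSB and 0.08/0.66 for the
combination). We use the values consistent with the narrative derivation
and — decisively — the only ones that reproduce all ten reference annual
DDL totals exactly: HCSB 0.31/1.41, OPB 0.33/0.88, combination 0.11/0.69.
The combination bed-rest value 0.69 is itself derived: the OPB 12-hour bed
rest (0.88) minus the 0.19-day pre-treatment reduction that HCSB applies to
bed rest (1.60 − 1.41); all three combination DDL totals confirm it.

Outcomes are `ddl_averted = base − scenario` total DDL (negative values are
DDL-*gained*) and `cer = cost_difference / |ddl_averted|`, which keeps the
cost difference's sign: net-harm scenarios report positive $/DDL-gained,
cost-saving averting scenarios report negative $/DDL-averted.

## Sensitivity analyses

**Tornado (one-way).** Each parameter alone is set to its low and then high
estimate and the base-case cost ratio (USD/DDL) recomputed. Sibling
probabilities are deliberately *not* renormalized — branch mass may
transiently differ from one — matching the behavior of spreadsheet one-way
sensitivity tools; with renormalization the hospitalization sweep would not
reproduce its reference endpoints ($82/$190). Group-sum validation is
suspended for the sweep only. Cohort parameters scale numerator and
denominator equally and so show zero swing on the ratio.

**Probabilistic sensitivity analysis.** Per iteration one joint draw of all
parameters is taken and evaluated under the base case and under each
scenario; outcomes are summarized by median and interquartile range over
3,000 iterations (the default). Conventions, each of which the underlying
sources leave open:

* *Distributions.* "Triangular" rows sample a triangular(low, mode, high)
  via inverse CDF. "Normal" rows sample a normal with mean at the point
  estimate and `sd = (high − low)/3.92`, i.e. the printed range is read as
  a 95% confidence interval — the reading that matches the incidence
  estimate, which is explicitly a 95% CI. Normal draws are truncated by
  rejection (at most 100 rounds) to [0, 1] for probabilities and [0, ∞) for
  costs and durations, since negative values are meaningless; `low == high`
  collapses to a point mass.
* *Normalization.* After sampling, each sibling probability group is
  rescaled proportionally to sum to one (percentages "normalized to 100%").
* *Common random numbers.* Base and scenario are evaluated on the *same*
  draw, the standard variance-reduction choice and the one consistent with
  differencing against the base case; it also makes each scenario's summary
  independent of which other scenarios are in the grid.
* *Overrides are not sampled.* Scenario override values ($30 optimal cost,
  the scenario DDL values, the implementation levels) are applied as point
  values after sampling; no ranges exist for them.
* *Cohort sampling.* Cohort constants carry distributions, so they are
  sampled by default; `run_psa(..., sample_cohort = FALSE)` holds them at
  their point estimates for a tree-parameters-only analysis.
* *Quantiles.* Linear interpolation between order statistics
  (`stats::quantile()` type 7), so IQRs are bit-reproducible given a seed,
  which is recorded in the result. Iterations with exactly zero DDL-averted
  stay in the DDL summaries but are excluded from CER summaries
  (`n_cer_excluded`).

## The microsimulator as oracle

`simulate_cohort()` draws individual episodes from the categorical leaf
distribution and accrues each leaf's unit cost and DDL; costs and DDL are
deterministic given the pathway because the model carries no within-pathway
variance (an episode-level jitter would change nothing the model reports,
so none is offered). `summarize_cohort()` aggregates to the same shape as
`evaluate_model()`, and the test suite requires the two routes to agree
within four standard errors at two million episodes for dozens of random
parameter sets from `random_parameter_set()` (uniform-simplex probability
groups, log-uniform costs in [1, 20000], uniform DDL in [0, 10]).

What this does and does not establish: passing shows the expectation
arithmetic, the tree wiring, and the samplers are mutually consistent over
the whole valid parameter space — not that real deployments behave like the
model. The generator emulates the model's own stochastic structure
(categorical pathways, independent episodes); it does not emulate features
real surveillance data would have, such as overdispersion across units,
seasonality, regional pathogen and resistance mix, or correlated
care-seeking.

## Numerical choices

* Internal arithmetic is never rounded; reported integers use half-up
  (away-from-zero) rounding at the final step only (`round_half_up()`,
  since R's `round()` rounds half to even). The base cost ratio is 114.71
  unrounded: displays that round the ratio give $115, displays that
  truncate intermediate dollars can show $114 — reports here carry the
  unrounded value.
* The OPB split rounds the optimal share to three decimals (half-up) before
  taking the complement, as described above; the same rule is applied to
  sampled pools in the PSA, where its sub-0.0005 effect is negligible.
* Scenario overrides and proportional renormalization may place a value
  outside its original elicitation bounds (e.g. HCSB 70% sets `p_no_mh`
  to 0.2907, far below its elicited low of 0.68); the transformed set's
  bounds are widened to include the new point estimate so the set remains
  self-consistent.
* JSON parameter configs are written with 17 significant digits, enough for
  bit-exact round trips of doubles.
* Degenerate inputs: a model with zero total DDL has no cost ratio and
  errors; comparing a scenario with itself leaves the CER undefined (`NA`
  with a warning); an all-point-mass parameter set degenerates the PSA to
  the deterministic values with zero IQR width.

## Problem sizes in the test suite

The suite checks sampler moments at 10^5 draws, pathway frequencies by
chi-square at 10^5 episodes, oracle-vs-expectation agreement at 2×10^6
episodes per parameter set, and PSA behavior at 300–30,000 iterations; the
full suite runs in well under a minute on a single core.

## Known limitations

* **Cost accounting gap.** The reconstructed base-case total cost is
  $2,973,006 against a reference value of $2,974,311 (+0.04%), with similar
  ≤0.2% gaps in every scenario cost row and consequently up to $1–2 in
  rounded CERs ($192 vs $193, −$73 vs −$74, $117 vs $118). The reference
  model's exact cost accounting for the self-treatment arm is not
  recoverable from its published description; we do not force agreement,
  and the tests assert the 0.2%/±$2 bands instead.
* **PSA medians are convention-dependent.** With triangular distributions
  on the published asymmetric ranges, the normalized disposition draws have
  mean treated-fraction ≈ 0.27 (below the 0.30 mode) and the episode count
  has mean ≈ 87,000 (the deployment-duration triangular(1, 3.5, 12) has
  mean 5.5 months), so sampled HCSB outcomes skew toward *more* DDL-gained
  than the deterministic value, while the reference medians skew the other
  way — evidence of a different, unstated sampling convention in the
  original spreadsheet implementation. Reference interquartile ranges are
  therefore treated as interval-level stochastic checks only, and under
  this package's conventions the HCSB 40% (and, with sampled cohort, HCSB
  55%) medians fall outside them; the OPB and combination medians fall
  inside under both cohort modes.
* The model is a global average: regional pathogen prevalence and
  antibiotic resistance are expressible only by editing the parameter
  config, and nothing links the management scenarios to hospitalization
  rates, which the tornado analysis shows to be the dominant uncertainty.
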