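---
title: "Modelling methods: MR-HIFU versus radiotherapy for painful bone metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling methods: MR-HIFU versus radiotherapy for painful bone metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifucea)
```

## The decision problem

Painful bone metastases from breast, prostate or lung cancer are usually
palliated with external-beam radiotherapy (EBRT): mostly multi-fraction
(20 Gy in 5 fractions), single-fraction (8 Gy) in about 10% of German
practice, with re-irradiation an option when pain persists. Magnetic
Resonance guided High Intensity Focused Ultrasound (MR-HIFU) is a
non-invasive thermal ablation alternative with similar overall response
rates but faster pain relief (about one week versus about four weeks).
`hifucea` evaluates, from the German statutory-health-insurance
perspective, whether a treatment strategy that uses MR-HIFU — as first-line
treatment for 60% of patients, and as retreatment after failed EBRT for the
rest (strategy A) — is cost-effective against EBRT with re-irradiation
(strategy B).

## Model structure

The model is a discrete-time state-transition process with a one-month
cycle. A patient is described by

* primary cancer (breast / prostate / lung, 1/3 each by default),
* pain state: complete relief, partial relief, or persistent pain,
* first-line modality, whether the single permitted retreatment has been
  used, and whether a pathological fracture has occurred.

Each month the following happen, in this order: cancer-specific death
(monthly probability by year since diagnosis), pain relapse, retreatment
uptake among eligible patients, pathological fracture, and accrual of that
month's utility, costs and pain-response time. The event order is a
modelling choice (the underlying evidence fixes only the rates); it is
documented here and locked by tests.

Two engines share these mechanics:

* **Cohort engine** (`expected_outcomes()`): propagates the full joint
  state distribution. Because death hits every alive state with the same
  cancer-specific probability, survival factorizes out of the state chain;
  one 36-state transition kernel per strategy serves all three cancers.
  This gives exact expectations in milliseconds and is the default inner
  evaluator for PSA and value-of-information analysis.
* **Microsimulation** (`microsim_arm()`): the identical model simulated
  patient by patient with counter-based substreams and common random
  numbers across strategies. Its means converge to the cohort engine's
  expectations — the package tests this on randomized parameter sets — and
  it supplies Monte-Carlo standard errors.

## Parameters and units

All inputs live in a single `bm_parameters()` object: monthly event
probabilities (response triplets per modality, retreatment uptake, fracture,
relapse), monthly utilities, unit costs in EUR (price year 2021/22), the
cancer-specific monthly mortality schedules, strategy settings, and a table
of standard deviations for everything varied in sensitivity analyses.
Retreatment rates quoted per year in the literature are converted by
compounding (`annual_to_monthly()`), which reproduces the printed monthly
values (20%/year to 0.018/month; 8%/year to 0.007/month). Costs and QALYs
are discounted at 3% per year, applied as `1.03^(-month/12)`.

Key strategy mechanics, each an explicit setting:

* **Response onset.** MR-HIFU palliates within about a week: responders
  accrue response utility and pain-response time for 23/30 of the treatment
  month. EBRT palliates within about four weeks: responders accrue nothing
  in the treatment month and respond fully from the next. The same rule
  applies to retreatments.
* **Retreatment** (`max_retreatments = 1`, no MR-HIFU after MR-HIFU).
  In strategy A, EBRT-first patients are retreated with MR-HIFU (first-line
  MR-HIFU effectiveness — they are thermal-ablation naive) when in
  persistent pain or with only partial relief; MR-HIFU-first patients are
  retreated with EBRT (90/10 multi-/single-fraction mix, first-line
  effectiveness since they are radiation naive) when in persistent pain,
  mirroring the persistent-pain-only rule the comparator strategy uses for
  re-irradiation (`retreat_eligibility_A = "by_modality"`). Strategy B
  re-irradiates persistent pain with the same modality; re-irradiation is
  less effective (42% no-response, the remainder split between complete and
  partial in the first-line ratio). Strategy A uptake uses the MR-HIFU
  retreatment rate 0.018/month for all its retreats
  (`retreat_uptake_A = "strategy_rate"`); per-first-line-modality uptake is
  available as an option.
* **Relapse** (`relapse_structure = "cascade"`): pain recurrence is
  progression-driven, so complete relief decays to partial relief and
  partial relief to persistent pain, both at 0.022/month. The alternative
  (`"to_persistent"`), in which any response collapses straight to
  persistent pain, is kept as a setting; the cascade matches the published
  strategy-B pain-response months (9.35 vs 9.41 printed; the direct
  collapse gives 8.34).
* **Fracture**: at most once per patient, cost and disutility in the event
  month only, hazard given by the most recent treatment modality.

## Two structural choices that deserve scrutiny

Re-deriving a model from a published description always leaves degrees of
freedom; two of ours were fixed by requiring consistency with the published
results rather than by the text alone, and both remain user-switchable.

**Accrual horizon (`horizon_months = 60`).** The mortality evidence behind
the model stops at five years after bone-metastasis diagnosis. With the
year-5 hazards extrapolated to a 50-year lifetime horizon, every absolute
outcome of the comparator strategy overshoots the published values by
8–12% (costs 9,010 vs 8,115 EUR; QALYs 0.99 vs 0.94); accruing over the
60 months actually covered by the survival data reproduces them within
about 2%. The default therefore accrues over the evidence span;
`horizon_months` accepts any value from 12 up (year-5 hazards are held
constant beyond year 5) for users who prefer explicit extrapolation.

**Valuation of response months (`response_gain_mode = "pooled"`).** The
input table lists distinct monthly utility gains for complete (+0.019) and
partial (+0.008) pain relief. The published incremental results, however,
satisfy `dQALY = 0.019 x dPainMonths + d(entry disutility)` essentially
exactly in the mixed cohort and all three cancer subgroups, and the
absolute QALYs match only when every response month is valued at the
complete-relief gain. The default therefore values any
complete-or-partial response month at +0.019/month ("pooled"); the
category-specific valuation is available as
`response_gain_mode = "by_category"`. Note the pain-state split still
matters under the pooled valuation: complete relief stops opioid costs,
partial relief does not.

## Sensitivity analyses

**One-way DSA** (`one_way_dsa()`): every parameter with a standard
deviation (all inputs except the mortality schedules) is varied one at a
time over mean ± 1 SD, clipped to its domain; response triplets are varied
one component at a time with the complement renormalized on the simplex.
The tornado is ranked by the spread of incremental net monetary benefit at
a reference willingness-to-pay of EUR 20,000/QALY (ranking on the ICER
itself is unstable where the incremental effect can change sign); ICERs at
both bounds are reported alongside. The published analysis reports which
variables mattered most but not the ranges it used, so tornado *order* is
only loosely comparable; in ours the MR-HIFU fracture rate (whose SD is
larger than its mean) and the MR-HIFU procedure cost dominate, consistent
with the published value-of-information ranking.

**Structural scenarios** (`run_scenario()`): strategy-A retreatment uptake
at 8%/year (0.007/month) and 32%/year (1 − 0.68^(1/12)/month), MR-HIFU
first-line for everyone, a cost-covering lump sum (EUR 5,147, replacing the
DRG reimbursement of EUR 3,430; the pre-treatment MRI logic is unchanged,
since the lump sum covers the procedure itself), 100% single-fraction EBRT,
and 100% out-patient EBRT. The lump-sum low/high values (4,092–5,876) are
kept as scenario variants, not DSA bounds.

## Probabilistic sensitivity analysis

The published analysis states the mean and SD of every varied parameter but
not its distribution family. The package's assignment (configurable):

* event probabilities and proportions: beta, moment matched;
* response triplets: Dirichlet, concentration matched to the SD of the
  complete-response component (triplets are normalized first — the printed
  MR-HIFU triplet sums to 0.99);
* costs: gamma, moment matched; the five fracture cost components are
  scaled with the sampled total so their audit sum stays exact;
* utility gains and decrements: sign-preserving and moment matched, via a
  truncated normal where that family can reach the target SD, otherwise a
  scaled beta on the sign-preserving domain (a 0-bounded truncated normal
  cannot have an SD much above its distance from the bound, and several
  disutilities have SDs two to five times their means). A clipped normal
  remains as a warned last resort.
* cancer-specific mortality is held fixed, mirroring its exclusion from
  the DSA.

Inputs the published table varies without printing an SD (out-patient MRI,
single-fraction EBRT cost, single-fraction proportion) get the 20%-of-mean
rule its footnote applies to assumed SDs.

The default inner evaluator is the deterministic cohort engine: 10,000
iterations take a few minutes on one core and the value-of-information
regressions see no inner Monte-Carlo noise. This is a deliberate deviation
from the original patient-level PSA, whose per-iteration outcomes carry
simulation noise of unknown size (the trial count was not reported); some
of the published decision uncertainty (e.g. the 10% of iterations in which
strategy A was less effective; we obtain 7-8% from parameter
uncertainty alone) plausibly reflects that inner noise. CEAC probabilities
should be compared with this in mind.

## Value of information

`evpi()` implements the per-person EVPI as the mean over iterations of the
best-strategy net monetary benefit minus the net monetary benefit of the
on-average-best strategy, at a reference willingness-to-pay of EUR
20,000/QALY by default (the published report does not state the WTP behind
its per-person figure); `evpi_curve()` always reports the full WTP-indexed
curve. `evppi()` is the regression estimator: each strategy's net monetary
benefit is smoothed on the parameter subset — a penalized spline for one
parameter, an isotropic Gaussian-process smooth (`mgcv`, `bs = "gp"`) on
standardized inputs for sets — and the EVPI formula is applied to the
fitted conditional means; standard errors come from a nonparametric
bootstrap over iterations. `population_evpi()` multiplies the per-person
value into user-supplied annual affected-population counts with annual
discounting (the registry counts behind the published population figure are
not printed, so they are an input, not a default).

Estimator validation uses synthetic tables with analytic ground truth
(`sim_gaussian_nb()`, `sim_linear_nb()`): Gaussian incremental net benefit
with closed-form EVPI, and linear-in-parameters net benefit whose subset
EVPPIs follow the same closed form with Pythagorean variances.

## What the synthetic fixtures do and do not show

`perturb_parameters()` draws valid random parameter sets from the PSA
machinery for property tests (mass conservation, microsim-vs-cohort
agreement); the linear/Gaussian net-benefit tables exercise the VOI
estimators against known truths. These fixtures emulate the *statistical
shape* of the analysis — they do not emulate real patient heterogeneity,
within-patient correlation of events, or any structure outside the model
(e.g. repeat MR-HIFU, bone-targeting agents, transportation costs, all of
which the underlying study also excluded). Green tests certify internal
consistency and faithful mechanics, not clinical validity.

## Numerical choices and degenerate inputs

* Probability-mass leaks above 1e-9 per cycle raise an internal error.
* ICERs are computed from unrounded deltas; incremental effects below 1e-12
  report an `"undefined"` ratio rather than infinity, and dominance labels
  replace ratios when the cost and effect deltas disagree in sign.
* CEAC ties (net-benefit difference exactly zero) count 1/2.
* Degenerate response triplets (e.g. all mass on one category) and zero
  SDs are supported throughout; a zero SD simply pins the parameter.
* The microsimulation draws per-(event, cycle) uniforms for all patient
  slots from seeds derived arithmetically from the master seed, so results
  are reproducible, early patients are invariant to the cohort size, and
  common random numbers pair the shared event streams across strategies
  (response-category draws are strategy-specific by design).
* Problem sizes used by the test-suite: microsim oracle sweeps use 1,200 to
  3,000 patients per arm (Monte-Carlo SEs make the 3.5-SE criterion
  scale-free); the acceptance analyses use the full 10,000 PSA iterations.

## Known limitations

* The subgroup ICER gradient across cancers is flatter than published, and
  the all-MR-HIFU-first-line scenario moves the ICER down rather than up.
  Both trace to the same tension: the published base case is a 60/40
  mixture of MR-HIFU-first and EBRT-first sub-arms, and mixture arithmetic
  on the published numbers forces the EBRT-first sub-arm to gain about
  0.016 QALYs at *negative* incremental cost from roughly 0.1 retreatments
  per patient — unreachable for a pathway that adds a paid retreatment to
  the comparator's. The package keeps the mixture-consistent mechanics
  (subgroups mix exactly to the base case, a tested invariant) and reports
  its own scenario values.
* Cancer-specific mortality SDs are printed only partially and mortality is
  never varied, so all uncertainty statements condition on the survival
  schedules.
* EVPPI standard errors come from a modest default bootstrap (30
  replicates); raise `n_boot` for publication-grade intervals.
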