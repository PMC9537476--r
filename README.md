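# hifucea

Early health-economic evaluation of **MR-HIFU** (Magnetic Resonance guided
High Intensity Focused Ultrasound) as a treatment option for painful bone
metastases, compared against external-beam radiotherapy (EBRT) from the
perspective of the German statutory health insurance.

Patients with painful bone metastases from breast, prostate or lung cancer
are palliated with EBRT (mostly 20 Gy in 5 fractions, 10% single-fraction
8 Gy), with re-irradiation an option for persistent pain. MR-HIFU achieves
similar response rates but palliates within about a week instead of four.
The package asks: is a strategy that offers MR-HIFU — first-line for 60% of
patients, or as retreatment after failed EBRT (strategy **A**) — worth its
extra cost against EBRT with re-irradiation (strategy **B**)?

## The model

A monthly-cycle state-transition model over
(pain state: complete / partial / persistent) × (first-line modality) ×
(retreatment used) × (fracture occurred), with cancer-specific monthly
mortality, run to the 60-month span of the survival evidence and discounted
at 3%/year. Monthly event order: death → pain relapse → retreatment →
pathological fracture → accrual. Outcomes per strategy are mean discounted
cost (EUR), QALYs, and months spent in complete-or-partial pain response;
strategies are compared by

* **ICER** = Δcost / Δeffect (EUR per QALY, and EUR per pain-response month),
* **NMB** at a willingness-to-pay λ: `NMB = λ·QALY − cost`.

Two interchangeable engines implement the identical mechanics: an exact
deterministic cohort-expectation engine (milliseconds per evaluation; the
inner loop for probabilistic analyses) and a patient-level microsimulation
with common random numbers (Monte-Carlo SEs; tested to agree with the
cohort engine within simulation error).

On top sit one-way deterministic sensitivity analysis with a tornado
ranking, the six structural scenarios of the underlying study,
probabilistic sensitivity analysis (moment-matched beta / Dirichlet /
gamma / sign-preserving utility distributions) with cost-effectiveness
acceptability curves, and value-of-information analysis: per-person EVPI
and regression-based EVPPI (spline / Gaussian-process smoothers with
bootstrap SEs).

## Worked example

```r
library(hifucea)

fit <- bm_cea(bm_parameters())   # cohort engine, embedded base case
fit
#> Cost-effectiveness of MR-HIFU-based strategy (A) vs EBRT alone (B)
#>   strategy B: cost     8161 EUR,  0.920 QALY,   9.35 pain-response months
#>   strategy A: cost     8498 EUR,  0.940 QALY,  10.30 pain-response months
#>   incremental cost:   336.89 EUR   incremental QALY: 0.0196   incremental pain months: 0.953
#>   ICER: 17207 EUR/QALY; 353 EUR per pain-response month
```

Strategy A costs 337 EUR more per patient and yields 0.020 additional
QALYs and 0.95 additional months of pain response, i.e. about 17,200 EUR
per QALY — cost-effective for any willingness-to-pay above that, a range
usually considered acceptable in European settings.

```r
subgroup_cea("lung")$incremental$icer_qaly   # per-cancer subgroup ICERs
scenario_table()                             # six structural scenarios
plot(one_way_dsa(), n_top = 10)              # tornado

psa <- run_psa(bm_parameters(), n_iter = 10000, seed = 1)
summary(psa, wtp = 20000)
#> PSA with 10000 iterations (cohort engine)
#>   CE-plane quadrants: NE 50.9%, SE 41.8%, NW 4.2%, SW 3.1%
#>   P(A cost-effective at WTP 20000): 60.7%; per-person EVPI: 402 EUR
plot(psa, type = "ceac")

evppi(psa, "costs.c_hifu_inpatient", wtp = 20000)  # what knowledge is worth
population_evpi(evpi(psa, 20000), annual_affected = rep(82000, 5))
```

Parameters are a single typed object; any input can be overridden by its
flat dotted name (`bm_parameters("strategy.share_sf_ebrt" = 1)`), edited in
a YAML config (`write_parameters()` / `read_parameters()`, a ready-made one
ships in `inst/extdata/basecase.yaml`), or exported as a table
(`parameter_table()`). A thin command-line wrapper over the same functions
is in `inst/cli/run-model.R`.

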