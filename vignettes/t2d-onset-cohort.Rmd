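---
title: "Identifying incident type 2 diabetes and dating its onset from EMR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying incident type 2 diabetes and dating its onset from EMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dcohort)
```

## The problem

Type 2 diabetes develops gradually: a long pre-diabetic phase of rising
insulin resistance precedes clinical recognition, and many patients carry
the disease for years before a diagnosis is coded. Administrative data
therefore record when diabetes was *recognized*, not when it *began*,
which frustrates any analysis that needs a clean time axis around disease
onset — for example, studying whether cancer risk differs before and
after diabetes develops. `t2dcohort` implements a computable phenotype
that combines ICD-9 diagnostic codes with glycemic laboratory results to
(i) classify patients as incident type 2 diabetes cases or non-diabetic
controls, (ii) assign each case a clinically meaningful **onset date**,
and (iii) construct a frequency-matched non-diabetic comparison cohort in
which every control receives a **reference date** drawn from the case
onset distribution of its own matching stratum, so that observation-time
opportunity is comparable between arms (guarding against immortal-time
artifacts).

Because the source EMR such a study would run on is proprietary, the
package ships a synthetic longitudinal EMR generator with known ground
truth, so every stage of the pipeline is testable end to end.

## The case definition

A patient is an incident type 2 diabetes case when all of the following
hold (each is checked in a fixed order and every failed criterion is
recorded in the decision log):

1. **Eligibility.** At least `min_age_years` (30) completed years of age
   by the end of the accrual window (1995-01-01 to 2009-12-31), and no
   diabetes-related diagnosis code or antidiabetic medication before the
   window opens.
2. **Coding.** At least one type 2 code (`250.X0`/`250.X2`; `X` is a
   single-digit wildcard and the dot is ignored) inside the window.
   Patients with no such code are evaluated against the control
   definition instead.
3. **Type 1 precedence.** No type 1 code (`250.X1`/`250.X3`) dated up to
   `type1_precedence` (365) days after the first type 2 code.
4. **No remote hyperglycemia.** No abnormal glycemic lab more than
   `onset_window` (1095) days before the first type 2 code — such
   patients have long-standing, undated disease.
5. **Two abnormal labs.** At least two abnormal results on distinct
   dates (HbA1c ≥ 6.5%, fasting glucose ≥ 126 mg/dL, or random glucose ≥
   200 mg/dL; thresholds are inclusive), with the chronologically second
   no more than `onset_window` days before the first code. Same-day
   duplicates count once — they are not independent evidence.
6. **A recent normal.** At least one normal result inside the
   `onset_window` before the first code, which brackets onset inside the
   three-year window.
7. **Onset.** The onset date is the *earlier* of the first type 2 code
   and the second abnormal lab.
8. **Treatment check.** No antidiabetic medication started more than
   `med_exclusion_lead` (30) days before the onset date.

Controls must be age-eligible, carry no diabetes-related code through the
study end, have at least one normal glycemic lab, and no antidiabetic
medication. Glucose thresholds are in mg/dL throughout (the conventional
units of the ADA criteria).

### Design choices worth knowing about

* **The second abnormal lab may postdate the first code.** Only its
  earliest permissible date is constrained; a confirmatory lab drawn
  after coding plainly supports the same diagnosis, and the onset date
  (the minimum of the two anchors) is unaffected.
* **The medication exclusion is anchored at onset** (config
  `med_anchor = "code"` switches to the first code date). Onset is the
  study's reference event; a patient started on metformin well before
  the assigned onset was evidently recognized earlier than the data can
  date.
* **Controls are not excluded for abnormal labs** under the base
  definition — the letter of the control rule asks only for a normal
  test and the absence of codes and treatment. The config flag
  `exclude_probable_undiagnosed` removes controls with two or more
  abnormal results on distinct dates, as a sensitivity analysis.
* **Statuses.** Every patient receives exactly one of `case`, `control`,
  `excluded`, `ineligible`. Patients failing the eligibility gate, and
  patients with no diagnosis, lab, or medication data at all, are
  `ineligible`; patients with data who fail case or control criteria are
  `excluded`, with all failed criteria listed.
* **Date arithmetic** is in whole days with fixed constants: one year =
  365 d, three years = 1095 d, six months = 183 d. Ages are completed
  years.

## Cohort construction

Cases whose onset falls inside the accrual window then pass three
filters, and matched controls pass the same three at their assigned
reference date:

* **Engagement.** At least one non-diabetes diagnosis or well-visit code
  in one of the three calendar years strictly before the reference year
  (the reference year itself is excluded under the default literal
  reading; a config flag includes it). This keeps only patients actually
  receiving care in the system around time zero.
* **Gap censoring.** Four or more consecutive calendar years with no
  encounter constitute an EMR gap. The observation window runs from
  January 1 after the last gap ending before the reference year (or the
  first encounter) to December 31 before the first gap starting after
  the reference year (or the administrative follow-up end, 2011-12-31).
  A year counts as covered if it has at least one encounter. Re-censoring
  at the censored follow-up end is a fixed point.
* **Minimum observation.** At least 60 days between the reference date
  and the censored follow-up end. The post-reference reading of the
  60-day rule is used.

Matching strata cross five birth-year categories (quintiles of the case
birth-year distribution by default, frozen into the run manifest; fixed
cut points can be configured), ever-smoking, ever-residency in the
clinic's epidemiologic study area, and the reference period (1995–1999,
2000–2004, 2005–2009). Controls are sampled 5:1 without replacement
within strata; each selected control then receives the onset date of a
case drawn uniformly *with replacement* from its stratum (small strata
make without-replacement assignment impossible at 5:1). Controls that
fail the engagement, censoring, or 60-day filters at their assigned date
are dropped and not replaced, so the achieved ratio can fall below the
5:1 target. Every stage's count lands in the attrition log.

Covariates and outcomes are ascertained strictly inside each member's
censored window: cancer (breast/prostate/colon) by the two-code rule
with the first code's date as the diagnosis date; seven comorbidities by
the same two-code rule, summarized by a modified Charlson score using
the original 1987 weights (MI, coronary, peripheral vascular,
cerebrovascular, chronic pulmonary, rheumatic each 1; renal 2) with the
diabetes and malignancy components removed; visit counts in half-open
two-year windows around the reference date (an encounter on the
reference date is "after"), binned 0–5 / 6–10 / 11–20 / >20; BMI as the
measurement nearest the reference date within ±365 days; and per-class
antidiabetic exposure as the union of medication intervals clipped to
the window. "Cardiovascular disease" is mapped to the cerebrovascular
ICD-9 range (430–438) — the Charlson category — and, like every code
set, is configurable; none of the condition or cancer code sets is
canonical, so they are all exposed in `inst/extdata/code_sets.yaml`.

## Validation statistics

`confusion_stats()` computes the 2×2 table against review (or ground
truth) labels and PPV, NPV, sensitivity and specificity, each with a
Clopper–Pearson interval on its own numerator and denominator: the lower
bound is `qbeta(alpha/2, s, n - s + 1)`, the upper
`qbeta(1 - alpha/2, s + 1, n - s)`, with the conventions 0 at `s = 0`
and 1 at `s = n`. The exact method is the package default because it is
the standard choice for the small denominators of chart-review samples;
Wilson intervals are available by flag. A statistic with an empty
denominator is reported as undefined rather than an error.
`sample_for_review()` draws proportional stratified samples
(largest-remainder allocation) for manual validation.

## The synthetic EMR

`simulate_population()` generates the world the phenotype assumes:

* A latent HbA1c trajectory per patient: baseline ~ N(5.3, 0.35)%,
  rising linearly at 0.3 %/yr before onset and 1.0 %/yr after, where
  **true onset** is the day the trajectory crosses 6.5% (the crossing of
  the fasting criterion can be chosen instead via `onset_definition`).
  True onsets are uniform over the accrual window.
* A homogeneous Poisson visit process per arm — 4 visits/yr for
  diabetics, 2.5/yr otherwise, reflecting the heavier healthcare contact
  of diabetic patients — from EMR entry (uniform 1985–1995) to the end
  of follow-up.
* Labs at 50% of visits (HbA1c : fasting : random = 5 : 3 : 2). Observed
  HbA1c adds N(0, 0.15) assay noise and rounds to one decimal. Fasting
  glucose is a linear transform of latent HbA1c whose intercept is
  calibrated so 126 mg/dL is crossed when HbA1c crosses 6.5% — the two
  criteria are designed to flag the same dysglycemic state. Random
  glucose sits 45 mg/dL above fasting with much larger noise (s.d. 30):
  it is a deliberately late, noisy indicator, which is why its
  diagnostic threshold is conservative.
* **Confirmatory retesting and surveillance.** An abnormal result
  triggers a repeat test 14–42 days later with probability 0.8 (the ADA
  criteria require confirmation), and once any abnormal result exists
  the patient's subsequent visits carry a lab with probability 0.9
  rather than 0.5 — an unexplained abnormal puts the patient under
  glycemic monitoring. These two mechanisms matter: the algorithm's
  onset-dating accuracy in real practice rests on the fact that
  clinicians chase abnormal glycemia promptly.
* The first type 2 code falls at the first encounter after true onset
  plus an exponential coding lag (mean 180 days); later encounters
  repeat the code sporadically. A small miscoding probability (0.005)
  flips the fifth digit, turning type 2 codes into type 1 codes and vice
  versa (type 1 distractor patients carry `250.X1`/`250.X3` and
  insulin). Medications begin 60 days after coding, never before.
* Benign diagnosis codes and well-visits drive the engagement filter;
  comorbidity and cancer code pairs, and BMI measurements (higher in the
  diabetic arm), exercise the covariate module.

All randomness flows from a single seed through named substreams
(demographics, visits, labs, retests, coding, comorbidities,
medications, bmi), so a fixed seed reproduces the dataset byte for byte
and stages can be re-drawn independently.

**What the simulator does not emulate:** real ICD-9 coding breadth,
assay recalibration over calendar time, care fragmentation across
providers, treatment feedback on the glycemic trajectory (no HbA1c
decline after medication start), gestational or secondary diabetes, and
any attempt to match a particular clinic population's demographics.
Passing tests on this generator therefore demonstrate the *logic* of the
pipeline — criteria, windows, matching, censoring arithmetic — and the
qualitative behavior of onset dating under visit-driven testing; they do
not certify performance on any real EMR.

Two generator properties are stated for the noise-free limit and tested
there: with dense visits, universal testing and vanishing assay noise,
essentially every case accrued with room for the coding lag is detected
and the assigned onset converges on the true onset; and detection
sensitivity is non-decreasing in the testing probability. With realistic
noise those statements weaken — more testing also surfaces more false
early abnormals, which the three-year look-back rule then converts into
exclusions — and that trade-off is intrinsic to the phenotype, not a
bug.

## Problem sizes and numerical conventions

The default simulated population is 10,000 patients with 2,000 true
type 2 cases; the onset-agreement check in the test suite and the
acceptance script run at exactly that size, and the remaining unit and
property tests use populations of 300–1,500 patients and 1,500–10,000
randomly generated small patients for oracle-equivalence checks — sizes
chosen so the whole suite exercises every stage at meaningful scale
while remaining quick to run. Ties in onset assignment return the shared
date; strata are processed in sorted key order and matched controls are
drawn `sort()`-stably, so no result depends on hash or input order;
reference-period boundaries are calendar-year based; all half-open
window conventions place the reference date on the "after" side.

## Worked example

```{r example, eval = FALSE}
library(t2dcohort)

sim <- simulate_population(simulation_params(n_patients = 2000), seed = 11)
decisions <- evaluate_population(sim$dataset)
table(decisions$status)

build <- build_cohort(sim$dataset, decisions, run_config(seed = 11))
build

covs <- compute_covariates(sim$dataset, build$cohort, run_config())
descriptive_summary(build$cohort, covs, sim$dataset)

onset_error_distribution(decisions, sim$truth)
```

## Known limitations

* The phenotype is rule-based by design; no probabilistic smoothing of
  borderline labs is attempted, so patients hovering at a threshold can
  flip status with a single result.
* The engagement and censoring rules are calendar-year constructs; a
  patient seen every January and December of alternating years has the
  same "coverage" as one seen monthly.
* The exclusion set for "diabetes-related" diagnoses defaults to a
  published five-pattern list (`250.X0, 250.X2, 357.2, 362.0X, 583.81`)
  that notably does not contain the type 1 codes; add them via the
  code-set YAML if your source codes type 1 diabetes without any type 2
  or complication codes.
* Printed upper confidence bounds from small validation samples are
  method-sensitive; this package reports Clopper–Pearson (or Wilson)
  bounds and makes no attempt to reproduce intervals whose method is
  unknown.
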