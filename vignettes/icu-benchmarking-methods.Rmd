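---
title: "Methods: federated ICU benchmarking with APACHE II on OMOP CDM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated ICU benchmarking with APACHE II on OMOP CDM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Critical-care quality registries compare ICUs through case-mix-adjusted
outcomes. The workhorse quantity is the standardized mortality ratio
(SMR): observed deaths divided by expected deaths over a period, where
the expected count comes from a per-patient severity model. An SMR of 1
means mortality is as predicted by case mix; the informative question is
whether a unit lies outside the range compatible with 1 given its size.

When several registries standardize their databases to the OMOP Common
Data Model, one shared analysis script plus per-source configuration can
benchmark them *federatedly*: the code travels to each source, and only
registry-level aggregates — never person-level rows — cross the source
boundary. `icubench` implements that pipeline end to end, together with
a synthetic OMOP data generator with known ground truth, because real
registry extracts are access-controlled.

## Severity model

Risk adjustment uses APACHE II: twelve worst-in-first-24-hours
physiologic components scored 0–4 points each (Glasgow coma score
contributes `15 − GCS`), age points (0–6), and 2 or 5 chronic-health
points, for a total score in [0, 71]. Predicted ICU mortality is

$$\operatorname{logit}(R) = -3.517 + 0.146 \cdot \text{score} +
0.603 \cdot 1\{\text{emergency surgery}\} + w_{\text{category}},$$

with a diagnostic-category weight $w$. The scoring bands, age bands,
chronic-health rule, category weights, and logistic constants are
transcribed into `inst/extdata/apache2_scoring.yaml` — a data file, not
code — so the transcription is auditable and swappable. The test suite
contains a *second, independent* transcription (explicit threshold
chains) plus three hand-scored patient vignettes; engine and oracle must
agree on dense grids over every component's domain.

Numerical conventions the published sheet leaves open:

* **Band edges.** Printed bands are inclusive ranges with small gaps
  (e.g. 38.4 | 38.5). A value falling in a gap takes the adjacent band
  with the *higher* point value: edge cases resolve deterministically
  toward severity. Bands printed as strict inequalities ("< 200") keep
  their strict boundary.
* **Worst value.** Both stored extrema are scored and the larger point
  value wins, reproducing "most deranged in 24 h" from highest/lowest
  pairs.
* **Oxygenation.** FiO2 ≥ 0.5 scores the alveolar–arterial gradient,
  otherwise arterial PaO2; a missing FiO2 is read as < 0.5 (the usual
  unventilated case).
* **Serum bicarbonate** may substitute for an absent arterial pH only
  when `use_bicarbonate_fallback = TRUE`; the default is off, since both
  emulated registries record blood gases.
* **Acute renal failure** (doubling creatinine points) and the severe
  chronic organ insufficiency flag are extracted as presence variables.

## Extraction

The cohort rules are applied in a fixed, reported order: admission date
inside the window (2019-07-01 to 2022-12-31 by default) → age ≥ 17
(OMOP stores year of birth only, so age is admission year minus birth
year, and a computed age of exactly 17 is eligible) → no burns
diagnosis → a recorded reason for admission → first ICU stay per
hospital visit (ties on start time keep the lowest `visit_detail_id`).
The attrition report counts each step so any re-ordering would be
visible.

Worst values scan only events matching the configured concept set and
table, linked to the ICU stay, with timestamps in the half-open window
`[admit, admit + 24 h)` — half-open so a measurement at exactly +24 h is
not double-counted. Events carrying an unexpected non-absent unit are
dropped with a warning, never converted: silent unit conversion is a
known source of cross-registry error. Per-source differences in
vocabulary (e.g. automated- vs manual-count leukocyte concepts) and
table placement (comorbidities as conditions vs observations) live
entirely in the configuration file; the extraction code is shared.

ICU death is a death record timestamped inside `[admit, discharge]`
(closed); a death after ICU discharge is a hospital death and does not
count. The registry label is the source; the ICU label is
`visit_detail.care_site_id`.

## Missing data: two strategies

**Normal-range fill** (sources where clinicians leave presumed-normal
values unmeasured): an absent component resolves to 0 points. The fill
acts on points, so filling and scoring commute, and it can only leave
the observed-components score unchanged.

**PMM multiple imputation** (sources where missingness tracks resource
constraints): chained equations over the incomplete component columns in
fixed column order. Each update fits a linear model on the observed
rows, draws coefficients from the standard noninformative posterior
(proper imputation needs parameter uncertainty), predicts observed rows
under the posterior mean and missing rows under the draw, matches each
missing row to its `donors_k = 5` nearest observed predicted means (the
conventional PMM default), and donates one of their observed values
uniformly — so every imputed value lies on the variable's support.
Predictors are the quality registry (indicator-coded when several
sources are pooled), ICU survival status, ICU length of stay, and the
component variables. Defaults are 30 imputations × 100 cycles. The
structurally conditional oxygenation columns are not imputed by default:
a missing A–a gradient encodes ventilation status, not a data gap.

Registry-level inference pools per-imputation expected deaths with
Rubin's rules (`T = W + (1 + 1/m) B`, t reference with
`ν = (m−1)(1 + W/((1+1/m)B))²`). The within-imputation variance of
expected deaths is `Σ R_i (1 − R_i)`, treating risks as independent
Bernoulli means — a documented, swappable choice. Per-patient reported
risk under MI is the mean of the per-imputation risks.

## Benchmarking

Expected deaths are the sum of predicted risks (identically mean risk ×
n). Registry SMR is the ratio of summed observed to summed expected over
the registry's ICUs, not a mean of ICU SMRs. Funnel control limits use
*exact* Poisson tail quantiles with continuity interpolation (the
piecewise-linear inverse CDF), rather than a normal approximation:
exact limits behave correctly at small expected counts, and an
independent brute-force CDF scan pins the implementation in the tests.
No overdispersion adjustment is applied by default. Report rounding is
half-up to one decimal, matching registry-report convention.

## The synthetic data generator

Each patient draws a latent severity `z ~ N(0, 1)`. Every component's
worst value is a monotone map of `z` plus independent noise: a
derangement fraction `u = Φ(0.6 z + 0.8 ε)^(3·s_v)` (per-variable shape
`s_v`) interpolates between the variable's normal centre and a far
extreme, on a randomly chosen derangement side; the opposite extremum is
a benign value inside the normal band. The shapes were calibrated once
so that scores span roughly 0–60 with a median near the low teens and
overall ICU mortality near 20% — plausible for a mixed adult ICU
population — and are not revisited. Deaths are Bernoulli with
probability `min(1, multiplier × R)` where `R` is the APACHE II risk of
the generated values computed by the package's own engine and the
per-ICU multiplier is the true SMR, making SMR recovery a well-posed
parameter-recovery experiment.

Admissions get 2–5 timestamped measurement events per variable whose
within-window extrema equal the truth exactly, plus occasional
more-deranged distractor events after the 24 h window that extraction
must ignore. Configurable fractions of admissions exercise each
exclusion rule (minors, burns, missing reason, readmissions, admissions
outside the window) and the hospital-death edge case. Two dialects
emulate the registries' structural differences: leukocyte concept
3000905 vs 3003282, comorbidities in `condition_occurrence` vs
`observation`, an APACHE-IV-like vs a SNOMED-like (two-stage)
reason-for-admission vocabulary, and the CDM v5.3 vs v5.4 column-name
dialect. The shipped reason-mapping tables are synthetic stand-ins.

Missingness: MCAR deletes a patient's whole per-variable event block
with the configured probability; MAR deletes with probability
`plogis(a + 1.2 z)`, the intercept solved so the marginal rate matches —
sicker patients' laboratories go missing more often. Default study
conditions: source A (older population, male fraction 0.62) with 5%
MCAR on laboratories and normal-range fill; source B (younger, male
fraction 0.56) with 25% MAR on laboratories and PMM imputation.

What the generator does **not** emulate: realistic longitudinal
trajectories, treatment effects, inter-variable clinical couplings
beyond the shared latent severity, drug exposures, or pediatric
populations. Tests passing on synthetic data therefore demonstrate that
the pipeline's logic and statistics are correct under the stated
generative model — not that APACHE II is well calibrated for any real
registry.

## Problem sizes and verification

The test suite checks, among others: engine–oracle scoring equivalence
on ~450-point grids per component; funnel null coverage with 200
simulated on-target ICUs of 500 admissions each (within 3 Monte-Carlo
standard errors of 95%); SMR recovery at true multipliers 0.7 / 1.0 /
1.5 with 3000 admissions each (within `3·√O/E`); and imputation
recovery over 50 replicates of 5000 admissions with 30% MAR laboratory
missingness, 10 imputations × 20 cycles, requiring ≥ 90% coverage of
the complete-data expected deaths — sizes chosen to keep Monte-Carlo
error well below the tolerances being asserted.

## Known limitations

* Within-imputation variance of expected deaths ignores risk-model
  parameter uncertainty (the severity model is treated as fixed, as is
  conventional in SMR benchmarking).
* The capped death probability `min(1, m·R)` slightly attenuates
  realized SMRs for multipliers well above 1 in the sickest tail.
* Unit mismatches are dropped, not converted; a source mixing unit
  systems within one variable needs a pre-harmonization step.
* `validate_store()` checks referential integrity and typed invariants,
  not clinical plausibility; domain checks happen at scoring time.
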