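---
title: "Methods: EMR phenotyping rules, validation metrics, and association model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMR phenotyping rules, validation metrics, and association model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htcpamd)
```

## The phenotyping rules

The classifier operates on three kinds of dated EMR facts: diagnosis
codes (ICD-9 decimal strings), procedure codes (CPT and HCPCS Level II
J-codes, kept in one namespace since they participate in the same
same-date joins), and medication orders (free-text drug names matched
case-insensitively against a configurable synonym list:
ranibizumab/Lucentis, bevacizumab/Avastin, aflibercept/Eylea).

Under the refined rules (**V2**, the default):

* **Case**: at least 2 *distinct calendar dates* carrying a qualifying
  AMD diagnosis (362.50, 362.51, 362.52, 362.16, 362.57) entered by an
  ophthalmologist, with age ≥ 60 completed years at the first such date.
  Distinct dates, not code rows, are counted because EMRs routinely
  duplicate a code within an encounter; distinct dates are the closest
  observable proxy for distinct visits.
* **Wet**: among established cases, some date carries both treatment
  evidence (an anti-VEGF injection J-code — J2778, J9035, J3490, J3590 —
  or a medication order for an anti-VEGF agent) and a diagnosis matching
  the 362.5 prefix on that same date. Cases without this are dry.
* **Control**: at least one ophthalmology-attributed event in the
  half-open window `(index_date − 2 years, index_date]`, age ≥ 60 at
  that event, and no disqualifying diagnosis at any time.

**V1** is the pilot rule set: one qualifying diagnosis suffices, there is
no age gate, and any treatment event makes a case wet regardless of date.
V2 criteria are strictly stronger, so V2 cases are a subset of V1 cases —
a property the test suite checks on noisy synthetic cohorts.

Patients meeting neither case nor control criteria are `UNCLASSIFIED`;
case criteria are evaluated first, so treatment codes alone never produce
`WET_AMD`.

### Design choices that were genuinely open

* **The control lookback anchor.** "Within the last two years" needs a
  reference date; we require an explicit `index_date` in the
  configuration rather than defaulting to the wall clock, because a
  classifier whose output depends on when it is run is not reproducible.
  The window is half-open, `(index − 2y, index]`.
* **The control exclusion set.** The disqualifying "AMD or
  AMD-associated diagnosis" list is not fully enumerable from first
  principles. The default is conservative: the five qualifying AMD codes
  plus the whole 362.5x family. The non-specific codes bare `362` and
  `377.21` are deliberately *not* disqualifying — they are whitelisted —
  and the set is user-extensible for locally defined AMD-associated
  codes. An alternative reading (treating those two codes as themselves
  disqualifying) is expressible by passing a different
  `control_exclusion_codes`.
* **Age convention.** Completed whole years (floor), the standard
  clinical convention; the day before the 60th birthday is 59. Leap-day
  births anniversary on Mar 1 in non-leap years. Boundary behaviour is
  pinned by tests.
* **Specialty attribution.** EMRs do not carry a standard
  "entered by an ophthalmologist" bit; we model it as a
  `provider_specialty` field on each event
  (`OPHTHALMOLOGY`/`OTHER`/`UNKNOWN`), with the requirement toggleable
  via `require_ophthalmologist_dx`.

All rule evaluation is set-based and order-independent; there is no
randomness anywhere in the classifier.

## Validation metrics

From algorithm-vs-expert pairs, the 3×3 confusion matrix (algorithm:
dry/wet/control × expert: dry/wet/not-AMD) is collapsed to 2×2 per task:

* **overall AMD**: positive = {dry, wet} on both axes;
* **dry** (and analogously **wet**): positive = that subtype only, so
  the other subtype *and* controls are test-negative. This is the only
  collapse under which the published subtype NPV and FNR are
  reproducible, and it is the clinically meaningful one (calling a wet
  patient dry is a subtype failure, not a case-detection failure).

PPV = TP/(TP+FP), NPV = TN/(TN+FN), FNR = FN/(FN+TP). Zero denominators
yield an explicit undefined marker (`NA` plus a flag), never a silent 0
or 1, because silent defaults corrupt aggregate reports. Overall accuracy
is the AMD-versus-control agreement (subtype confusions among true AMD
count as correct); the stricter 3-class agreement is reported separately
as subtype accuracy.

The packaged 100-chart review is a *reconstruction*: the published
account gives the bin sizes (30 dry, 30 wet, 40 control), the overall
2×2 counts, and the subtype metrics, and exactly one 3×3 assignment is
consistent with all of them simultaneously (dry bin 22/4/4, wet bin
3/26/1, control bin 0/1/39, with the polypoidal-choroidal-vasculopathy
control counted as wet pathology). `chart_review_100()` reproduces every
published cell at once, which is what makes it usable as a fixture. The
20-chart pilot fixture is determined only down to its 9/20 accuracy;
its per-subtype detail is synthetic and documented as such.

## The synthetic EMR generator

`simulate_cohort()` emulates the population such an algorithm would
screen: an all-ages biorepository enriched for ophthalmology care. Per
patient it draws a latent class — true dry AMD (2.0%), true wet AMD
(1.5%), mimicker retinal disease (3.0%), healthy (93.5%) — an age from a
truncated normal (mean 70, SD 12, range 40–95 years at the index date),
routine ophthalmology visits (Poisson, 1.5/year over a 10-year history
window), and class-specific coded events. True AMD ages are re-truncated
to ≥ 62 so that every planted case is old enough to satisfy the age
gate; this mirrors the strong case-control age gradient typical of AMD
cohorts (cases average roughly a decade older than clinic controls) and
makes "noise-free ⇒ zero false negatives" a meaningful claim rather
than an artifact of planting ineligible cases. Mimicker types and their
ICD-9 codes are the documented confusion modes for this phenotype:
diabetic retinopathy (362.02), pattern dystrophy (362.76), central
serous chorioretinopathy (362.41), polypoidal choroidal vasculopathy
(362.43), macular scar (363.32).

Coding noise is controlled by four probabilities, each a distinct
failure mode observed in practice:

| parameter | default | failure mode |
|---|---|---|
| `p_miscode_amd` | 0.05 | a mimicker also receives AMD codes (PCV additionally receives wet-like injection coding) |
| `p_missed_second_visit` | 0.10 | a true case has only one coded diagnosis date |
| `p_injection_coded_same_date` | 0.90 | complement = injection lacks its same-date 362.5x partner |
| `p_specialty_other` | 0.05 | diagnosis attributed to a non-ophthalmologist |

Each patient consumes an independent RNG stream keyed by
`(seed, patient index)` (Mersenne–Twister seeded per patient from a
32-bit mix). Consequences, all tested: identical seeds give
byte-identical cohorts; growing `n` extends a cohort without reshuffling
existing patients; and raising `p_miscode_amd` with a fixed seed grows
the miscoded set monotonically, so the PPV-erosion property can be
tested with common random numbers instead of large-sample statistics.

The generator also emits, per patient, the label the reference V2 rules
*should* produce for the realized (noise-included) record, derived by
direct arithmetic inside the generator, independent of the classifier
implementation. The suite asserts classifier-vs-generator agreement on
noisy and noise-free cohorts — a much stronger oracle than aggregate
counts.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: longitudinal disease progression
(dry→wet conversion), per-eye laterality, free-text clinical notes,
provider-level coding idiosyncrasies, correlated comorbidity structure,
and informative missingness of visits. Validation metrics on synthetic
cohorts certify the *implementation* of the rules, not the clinical
performance of the rules themselves; the latter is what the packaged
chart-review fixtures record.

## The association model

For each SNP, case/control status is regressed on risk-allele dosage
`g ∈ [0, 2]` (hard calls as integers, imputed expected dosages as
continuous values — never rounded) under the additive model, adjusted by
default for age (years), sex (0 = female reference), BMI (kg/m²) and
ever-smoking (0/1). Missing covariates drop the sample for that model
(complete-case), with per-SNP sample counts reported.

Numerical choices:

* **Fitting** is Newton/IRLS written against the explicit score and
  information: convergence when the largest absolute score component
  < 1e-8 or the relative log-likelihood change < 1e-10, capped at 50
  iterations. The fit is cross-checked against `stats::glm()` in the
  test suite to 1e-6 on coefficients; `glm` is the oracle, not the
  implementation, so the package controls its own convergence and
  failure semantics.
* **Separation** is diagnosed, not silently diverged: complete
  separation on the dosage axis is detected up front, and any iteration
  whose linear predictor exceeds ±30 aborts with a separation error
  (quasi-complete and multivariate separation end up there). Constant or
  collinear predictors raise a rank-deficiency error.
* **Inference** is Wald — `exp(β ± z·SE)`, two-sided normal P — matching
  the reporting convention of the standard GWAS tools for this model
  class. The Bonferroni threshold is `alpha/m` with `m` the configured
  test count (11 for the reference candidate panel).
* **Allelic 2×2 path**: the pooled allele-count odds ratio
  (cross-product ratio) with Woolf's log-scale CI and a 1-df Pearson
  chi-squared without continuity correction; a 0.5 continuity correction
  is added to the OR/CI only when a cell is zero. Published "final
  allelic OR" analyses are ambiguous between this and pooled-sample
  regression, so both are implemented; regression is the default and
  `method = "allelic"` selects the count path. On hard-call data the two
  estimate the same quantity, which the suite checks.
* **Pooling** imputed and directly genotyped samples requires disjoint
  sample sets; a SNP absent from one source is analyzed on the samples
  that have it, with a warning, and per-SNP missing dosages reduce that
  SNP's n only. The European-ancestry filter is an upstream boolean
  (`ancestry_european`) applied before analysis with case/control
  exclusion counts reported; imputation quality filtering (info ≥ 0.75)
  is likewise accepted as a pre-applied upstream flag, not recomputed.

### The genotype simulator

`simulate_case_control_genotypes()` draws genotypes Hardy–Weinberg at
the population risk-allele frequency, assigns disease by the additive
logistic model with the intercept solved (by `uniroot` on the exact
three-point genotype mixture, or by Monte Carlo when covariates are
present) to hit a target population prevalence of 5%, then samples
retrospectively to the requested case/control counts — exactly, via the
conditional genotype distributions `P(g | case) ∝ P(g)·P(case | g)`,
when no covariate model is given. Requested sizes that the prevalence
cannot support raise an error rather than silently under-filling.

## Problem sizes and calibration checks

The test suite works at cohort sizes of 80–5,000 patients and the
calibration checks use 500 replicates at the reference study geometry
(57 cases, 142 controls, population RAF 0.363, planted per-allele OR
2.43): 95% CI coverage is required to land in [0.92, 0.98] and the
0.05-level null rejection rate within three binomial standard errors of
0.05. Parameter recovery is additionally checked across a planted-OR
grid {1, 1.5, 2, 2.76} at 2,000/2,000. These sizes make the full suite
run in well under a minute while leaving the binomial error bands tight
enough to detect calibration bugs.

## Known limitations

* The classifier is per-patient, not per-eye; ICD-9/CPT codes are not
  eye-linked, so treatment-response and laterality phenotypes are out of
  scope.
* ICD-10, HL7/FHIR ingestion and free-text NLP are out of scope; the
  input contract is the documented CSV extract.
* The published per-SNP odds ratios and P values from the original
  cohort are not reproducible from first principles because the
  underlying individual-level data are not published; the association
  machinery is therefore certified by parameter-recovery and calibration
  properties on simulated data, plus the closed-form and `glm` oracles.
* The 3×3 chart-review fixture is the unique assignment consistent with
  the published summary numbers, but the underlying charts themselves
  are of course not available; fixture chart IDs are synthetic.
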