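---
title: "Validating stroke diagnostic codes against chart review: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating stroke diagnostic codes against chart review: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoval)
```

## The problem

A diagnosis code in an electronic medical record is not a diagnosis. Codes
are entered for billing, for ordering tests, to carry a history forward, or
to document a suspicion being ruled out, so a study that counts stroke codes
as strokes can overestimate the outcome several-fold. Before EMR codes are
used as a research outcome, the code-based case definition (the
*phenotyping algorithm*) has to be validated: sample flagged records, review
the charts, and estimate the positive predictive value (PPV) — the fraction
of flagged records that truly are the disease.

`phenoval` implements this validation workflow for stroke ICD-10 codes in a
hospital-based cancer registry, together with a synthetic EMR generator that
plays the role of the hospital database and the human chart reviewer, so the
whole pipeline is testable end to end without access to protected data.

## Pipeline

1. **Registry cleaning** (`clean_registry()`): drop repeated patient
   registrations (the earliest registration survives; ties resolve to file
   order) and rows whose death date precedes their birth date. Every
   excluded row is logged under exactly one reason, so
   retained + excluded = input always holds. A row that is both a
   non-surviving duplicate and date-impossible is logged as a duplicate;
   this precedence keeps the two exclusion counts disjoint.
2. **Code extraction** (`code_set()`, `extract_codes()`): the stroke set is
   the I60, I61 and I63 categories plus the exact codes G458 and G459 —
   deliberately *not* the whole G45 category, which would sweep in other
   transient syndromes. Covariate sets (hypertension I10–I15, diabetes
   E10–E14, dyslipidemia E78, atrial fibrillation I48, brain metastases
   C793) use inclusive category ranges: a range matches any code whose
   first three characters fall inside it. Codes are normalized to the
   dot-free uppercase form on load.
3. **Same-day deduplication** (`dedup_diagnoses()`): different departments
   may register the identical code for the same patient on the same day;
   counting each registration would overstate the code burden. Within a
   (patient, code, day) group the survivor is the record with the highest
   position rank (primary > secondary > other), ties broken by record
   order; definite and suspected registrations deduplicate independently.
4. **Arm classification** (`classify_arms()`): five overlapping algorithm
   arms — definite code alone; definite + any brain imaging (CT or MRI)
   for the patient; definite + imaging within 30 days of the code date;
   definite + imaging within 1 day; suspected + any imaging. Imaging
   linkage is patient-level, with the day window applied to the imaging
   order nearest the code date.
5. **Review sampling and estimation** (`draw_review_sample()`,
   `estimate_ppv()`, `pooled_ppv()`, `tally_nondisease()`): each arm is
   sampled independently and uniformly without replacement (default 100
   records, seeded), labels are attached from a reviewer worksheet or from
   the synthetic truth table, and the PPV is estimated overall and within
   the primary / secondary-or-others code-position strata.

## Numerical and design choices

**Day-resolution windows.** All dates are calendar days; "within *W* days"
means an absolute signed offset of at most *W*. "Within 1 day" therefore
admits same-day, previous-day and next-day imaging — day-resolution data
cannot express a 24-hour window. The window is two-sided by default
(pre-code imaging that prompted the diagnosis and post-code confirmatory
imaging are both clinically plausible); `arm_spec(direction =)` switches to
after-only or before-only linkage.

**Nearest-offset tie break.** When a past and a future imaging order are
equidistant from the code date, the non-negative offset is reported. This
only affects the reported offset, never window membership, because windows
are symmetric by default.

**Exact binomial intervals.** PPVs near 0.9 at n = 100 sit where the normal
approximation is poor, so `ppv_estimate()` uses the Clopper–Pearson
interval computed from the closed-form beta quantiles; it is conservative
by construction (coverage at least the nominal level). A Wilson score
option is available via `method = "wilson"`.

**Rounding.** Reported percentages round to the nearest integer with ties
away from zero (`47/93` prints as 51%), which is how such validation
tables are conventionally printed; `round()`'s round-half-to-even would
disagree on exact halves.

**Pooling.** `pooled_ppv()` sums numerators and denominators over disjoint
position strata, so the pooled PPV is exactly the sample-size-weighted
mean of the stratum PPVs before any rounding.

## The synthetic EMR generator

`generate_cohort()` emits a full registry (optionally with pre-cleaning
duplicate and impossible-date rows), diagnosis registrations and imaging
orders, plus a latent truth table covering every stroke-code record. Each
stroke code traces to exactly one mechanism:

| mechanism | certainty | truth | imaging behaviour |
|---|---|---|---|
| true event | definite | positive | at the event: 95% within a day |
| history of stroke | definite | negative | absent (81%) or far from the code date |
| stroke mimic | definite | negative | present for 37%, mostly distant |
| test-only coding | definite | negative | often present but unrelated in time |
| rule-out work-up | suspected | rarely positive (7%) | essentially always, near the code date |

The default per-patient rates (0.0078 / 0.0145 / 0.0078 / 0.0053 / 0.0088)
and the offset models were derived arithmetically from the arm-size and
PPV profile the pipeline is designed to exhibit — roughly 910 deduplicated
definite records of which ~22% are true, rising to ~50% with any imaging,
~84% within 30 days and ~90% within 1 day, with a suspected arm near 7% —
rather than tuned by simulation. Same-day re-registration is geometric per
record (definite p = 0.54, suspected p = 0.66, so the expected extra
copies per event are p/(1−p)), reproducing the roughly 2.2:1 and 2.9:1
total-to-distinct ratios of the two certainty streams. Background brain
imaging unconnected to stroke coding is concentrated in brain-tumour
patients (surveillance imaging) plus a 2% random fraction, which
reconciles a cohort-wide imaging volume of several thousand orders with an
any-imaging arm of only ~48% of definite records.

One global seed drives ordered sub-streams per table and per mechanism, so
raising one mechanism's rate leaves every other mechanism's draws — and
hence the arms they populate — untouched. This is what makes the
monotonicity test meaningful: increasing the test-only coding rate dilutes
the definite arm's PPV while leaving the within-1-day arm essentially
unchanged.

`generate_fixture()` is the deterministic counterpart: it realizes exact
counts (registry rows, duplicates, impossible dates, distinct and total
code records, nested imaging-linkage arm sizes) by construction — each
definite event lives on its own patient so patient-level linkage cannot
bleed between events — and is the basis of the package's worked example:
27,932 registry rows → 25,827 retained; 1,991/663 definite/suspected
records → 912/228 after same-day deduplication; definite arms
438 / 239 / 212.

### What the generator does and does not emulate

It reproduces the marginal structure that the pipeline consumes:
demographics (49.5% female, age 61.6 ± 15.7 at registration, a
comprehensive-cancer-centre case mix with sex-consistent prostate/uterus
assignment), registration dates uniform over 2007–2015, covariate code
prevalences (20.3% hypertension, 17.5% diabetes, 12.7% dyslipidemia, 3.3%
atrial fibrillation, 1.8% brain metastases), and the mechanism-driven
joint distribution of codes, truth and imaging offsets. It does **not**
emulate free-text clinical narratives, within-patient correlation of
comorbidities, care episodes spanning multiple codes, seasonal coding
drift, or mortality dynamics. Passing tests therefore demonstrate that the
pipeline measures what the generator encodes — they do not certify PPVs in
any particular real EMR, which is precisely why the validation machinery
exists as a reusable tool.

## Test problem sizes

The test suite checks the estimator's statistical guarantees at sizes
chosen to make the assertions sharp while keeping the suite quick:
Clopper–Pearson coverage is verified over 20,000 simulated reviews at
n = 100 for each true prevalence in {0.07, 0.22, 0.51, 0.84, 0.90} (the
exact method's true coverage at p = 0.90 is ≈ 0.956, so a small simulation
would be too noisy to separate from 0.95); parameter recovery runs 500
replicate cohorts of 2,500 patients with mechanism rates scaled eightfold
so every arm holds comfortably more than the 100-record review sample.
Review sampling is without replacement from a finite arm, which makes the
binomial interval conservative for the realized arm fraction — the
recovery criterion (truth fraction inside the 95% CI in at least 95% of
replicates) inherits that conservatism.

## Known limitations

- Duplicate patients are detected by repeated `patient_id` only; true
  re-registrations of the same person under different ids require
  probabilistic record linkage, which is out of scope.
- Imaging records are treated as performed studies; if a source system
  records cancelled orders, they should be filtered before loading.
- Sensitivity, specificity and NPV are out of scope: chart review of
  code-negative records would be required, and the sampling design here
  conditions on the code being present.
- The three-level code position is preserved in data but collapsed to
  primary vs secondary-or-others for reporting; the primary stratum of a
  100-record sample is typically small (~7 records), so its interval is
  wide.
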