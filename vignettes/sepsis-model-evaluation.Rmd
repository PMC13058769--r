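---
title: "Evaluating streaming sepsis risk scores against computable sepsis definitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating streaming sepsis risk scores against computable sepsis definitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepseval)
```

## Scope and model of the data

`sepseval` evaluates a streaming in-hospital sepsis risk score — a number
in 0–100 emitted every 15 minutes for every adult encounter — against
three electronically computable sepsis definitions. The model that
produces the scores is *not* part of the package: scores are an input, as
they are in a silent deployment, where predictions are stored but hidden
from clinicians. The package's inputs are three tidy tables:

- **events**: one row per timestamped observation or action
  (`encounter_id, patient_id, time, kind, concept, value,
  antibiotic_name`), with a fixed concept vocabulary
  (`concept_registry()`);
- **encounters**: admission episodes with type, demographics, unit
  intervals, and in-hospital death;
- **predictions**: `(encounter_id, time, score)` at a fixed cadence.

Timestamps are timezone-naive, minute-resolution POSIXct (UTC). Lead
times and windows are reported in hours, so sub-minute precision carries
no information. Events up to a configurable lookback before arrival are
accepted on read, but by default only events at or after arrival
participate in criteria (`pre_arrival_lookback_hours = 0`): pre-arrival
handling differs between sites, and the conservative default is easy to
relax. Encounters with stays under one hour are excluded by
`apply_inclusion_filters()` before any evaluation.

## The three definitions and their time zeros

Each definition is implemented as a pure function of one encounter's
event stream returning case status, a time zero, and the component
criterion times that justify the label (auditable provenance). Time zero
is always the *earliest qualifying time point* under the definition's own
rule, which makes it stable under stream extension: appending later events
can never move an established time zero.

**Sepsis-3.** Suspected infection is a culture–antibiotic pair: an IV
antibiotic within 72 h after a blood culture, or a culture within 24 h
after an antibiotic; the suspicion time is the earlier of the pair. The
encounter is a case if some pair shows a SOFA rise ≥ 2 in (−48 h, +24 h)
around suspicion, computed as the window maximum minus the pre-window
baseline (the minimum SOFA in the 48 h before suspicion, 0 if
unmeasured — the convention for patients presenting without prior
measurements). Each SOFA subscore is the worst qualifying value in a 24-h
lookback; unmeasured organs score 0. Vasopressor administration scores
cardiovascular 3: dose information, which distinguishes 3 from 4, is not
in the event model. Some deployments compute a reduced SOFA; this package
implements the full six-organ score, with every threshold overridable via
`criteria_config()`.

**SEP-1 (severe-sepsis logic).** ≥ 2 SIRS criteria concurrent with ≥ 1
organ dysfunction criterion. Concurrency is a rolling 6-h window — no
standard concurrency rule exists for computable implementations, so 6 h is
exposed as a default, not a claim. The conjunction is scanned at event
times; time zero
is the first time it holds, i.e. the latest of the completing component
times. SIRS and SEP-1 thresholds are strict (`>`/`<`), following the
measure's wording; urine output is omitted from organ dysfunction by
default because it is rarely computable from typical event extracts.

**ASE.** Blood culture, qualifying antibiotic days, and organ dysfunction
within ± 2 *calendar* days of the culture. QADs are counted on calendar
days (midnight boundaries), not 24-h blocks: a new antibiotic (no same
agent in the prior 2 days) starting within the culture window must run
≥ 4 consecutive days, bridging single-day gaps, or until in-hospital
death. Ratio criteria (creatinine ×2, bilirubin ×2, platelet halving) use
the best encounter value *before* the window as baseline and cannot fire
without one; the ASE lactate threshold is inclusive (≥ 2.0), unlike
SEP-1's strict > 2.0. The phrase "earliest qualifying time point" is
ambiguous for a three-component definition; the default takes the minimum
over culture, QAD start and first organ dysfunction
(`ase_time_zero = "component_min"`), with a culture-anchored variant
available, because the component minimum is the only reading that makes
ASE time zero comparable to the other definitions' earliest-evidence
semantics.

A spreadsheet of the exact thresholds in force is the `thresholds` element
of `criteria_config()`; sites can override any number without touching
code.

## Evaluation framework

**Encounter level.** One instance per encounter, scored by the maximum
prediction *strictly before* min(time zero, discharge). "Strictly before"
is applied at every boundary (time zero, discharge, censoring actions):
a score generated at the moment of recognition is not advance warning.
Encounters with no eligible prediction are flagged and excluded from
metrics with a logged count, so instance counts plus flagged counts always
equal the cohort size.

**Prediction level.** Every prediction becomes an instance labeled
positive iff time zero falls within the horizon (8 h and 24 h by default)
after it. For case encounters, predictions at/after time zero are excluded
by default rather than labeled positive — the early-warning reading; the
alternative (keep them, labeled positive) is available via
`include_post_t0 = TRUE`, since published evaluations rarely state which
convention they use. Unit at prediction time is resolved by
half-open interval containment `[start, end)`.

**Pre-treatment censoring.** `censor_before_actions()` keeps predictions
strictly before the earliest lactate order, blood culture order, or IV
antibiotic administration, per encounter; encounters without such actions
keep all predictions. This isolates performance before clinicians had
acted on a sepsis suspicion.

**Lead time.** For a threshold, the lead is time zero minus the first
crossing, for cases crossing before time zero; late detections (first
crossing at/after time zero) and never-crossers are tallied separately.
Raising the threshold can only delay or remove crossings, which the tests
assert as a monotonicity property.

## Metric conventions

- **AUROC** is the Mann–Whitney probability of concordance with ties ½.
  Tests compare it to an exhaustive pairwise oracle on all small inputs
  and to an independent library implementation.
- **AUPRC** is average precision — the step integral of precision over
  recall at distinct score cuts. Linear PR interpolation is optimistic and
  deliberately avoided; cross-checks must use the same convention.
- **ECE** bins *normalized* scores (score/100) into equal-count deciles of
  the empirical score distribution and averages |observed − predicted|
  with bin-count weights. Equal-count (not equal-width) binning follows
  the decile phrasing of the classic calibration plot; with a score that
  is not a risk (a score of 60 is not a 60 % risk), the ECE is precisely
  the diagnostic of that mismatch.
- **Decision curves** use NB(pt) = TPR·π − FPR·(1−π)·pt/(1−pt) and
  sNB = NB/π, with treat-all and treat-none references. Two closed forms
  anchor the tests exactly: a perfect classifier has sNB ≡ 1, and treat-all
  has NB = 0 at pt = π.
- **Operating points**: sweeps run over integer thresholds 0–100, matching
  the printed score scale. NNE = 1/precision (so NNE·precision = 1
  identically); displayed values are rounded half-up to one decimal, the
  convention used for all reported percentages. "Youden top left" is read
  as the ROC point closest to (0, 1); because the phrase is sometimes used
  for the J statistic, both are implemented (`style = "youden_j"`), with
  top-left the default. Predefined points are high recall (≥ 0.8), high
  precision (≥ 0.15), and the top-left point, each absent with a warning
  when unattainable.

## Uncertainty

Confidence intervals resample *patients* with replacement, each sampled
patient contributing all its encounters — the standard cluster bootstrap
reading of "resampling at the encounter level, accounting for clustering
at the patient level". Intervals are percentile rather than BCa:
percentile is reproducible and assumption-light, and the `method` field
leaves room for extensions. `n_boot` defaults to 1000 and a seed is
mandatory.
Replicates on which the statistic is undefined (e.g. single-class
resamples) are dropped; estimates with > 20 % failures are flagged rather
than silently reported. Weekly drift groups encounter instances by ISO
week of arrival, reporting single-class weeks as `NA`.

## The synthetic generator: what it emulates and what it does not

`generate_cohort()` stands in for the kind of large health-system cohort
on which a silent deployment is evaluated but which is never deposited.
Its defaults describe a realistic acute-care mix: encounter types 68.1 %
ED-only / 21.8 % ED-to-admission / 4.9 % post-operative (the remainder
split between direct and obstetric admissions), per-definition sepsis
incidences 2.9 % / 1.2 % / 2.0 %, arrival-to-time-zero lognormals with
median [IQR] 4.1 [1.2–25.2] h, 5.8 [1.8–31.3] h and 1.7 [0.7–11.6] h for
Sepsis-3, SEP-1 and ASE respectively, case mortalities 14.2 % / 21.9 % /
18.7 %, a 15-minute score cadence, a sub-hour-stay fraction of
8995/207489, and 10 % of patients carrying 2–3 encounters. A lognormal is
matched to a reported median m and quartiles (q1, q3) by meanlog = log m,
sdlog = log(q3/q1)/(2·z₀.₇₅).

**Constructive planting.** Case status is assigned mutually exclusively
across definitions (the joint distribution of the three definitions is
not published, and exclusive planting is what makes an exact oracle
possible), and only within admitted encounter types, mirroring the
near-zero ED-only sepsis rates of such cohorts. Each case receives an
event bundle satisfying exactly its own definition at known times — e.g.
the Sepsis-3 bundle's antibiotics stop after one day so the ASE
antibiotic-day rule cannot fire, and the ASE bundle's lactate is not a
SOFA component so Sepsis-3 cannot. Background vitals and labs are clamped
inside ranges from which no criterion of any definition can fire.
Phenotype recovery on planted cohorts is therefore expected to be *exact*
(sensitivity = specificity = 1, time zeros equal), and the tests assert
exactly that. The price is realism: no noisy near-miss encounters, no
multi-definition cases, no disease progression beyond what the criteria
require. Passing planted-truth tests shows the definitions are computed
correctly, not that they would agree with chart review on real data.

**Scores.** A latent binormal model drives discrimination: non-cases draw
z ~ N(0, 1), cases z ~ N(μ, 1) with μ = √2·Φ⁻¹(AUROC*), so the intended
AUROC against the any-definition case indicator is exact in expectation.
The encounter's *peak* score is 100·P(case | z) under that mixture —
perfectly calibrated by construction — and the stream is shaped so the
encounter maximum equals the peak: non-case streams jitter below the peak
with the peak placed at one random in-stay prediction; case streams sit at
a baseline fraction of the peak and step up to it ahead of time zero. A
logit-scale slope/intercept map (`calibration_slope`,
`calibration_intercept`) injects miscalibration when wanted. When several
definitions are planted together, each definition's encounter-level AUROC
is necessarily below the any-case target, because the other definitions'
cases are high-scoring negatives; recovery tests therefore use
single-definition configurations.

**Lead-time semantics.** The default ramp is a step starting
(lead + cadence/2) before time zero. With prediction times on a 15-minute
grid whose offset to time zero is effectively uniform, the first crossing
lags the ramp start by U(0, cadence), so the half-cadence head start makes
the *median* recovered lead equal the nominal lead exactly — a design
choice that turns lead-time recovery into a sharp test rather than one
with a known discretization bias. A logistic ramp shape is available
(`ramp_shape = "logistic"`) for smoother streams; its crossing times
depend on the peak, so the step form remains the default for exact
semantics.

## Numerical choices and degenerate inputs

- Reported percentages round half-up to one decimal (`round_half_up()`),
  matching printed-table conventions; base R's banker's rounding does not.
- Single-class inputs raise "undefined metric" errors rather than
  returning a number; stratified tables and drift tables convert these to
  `NA` entries, mirroring how clinical tables print "NA" for empty strata.
- Ties in the top-left selection break toward the higher threshold (fewer
  alerts at equal geometry); simultaneous time-zero component times are
  ordered culture < antibiotic < organ dysfunction for display only.
- Equal-count binning with heavy score ties may split a tied value across
  bins; bin sizes differ by at most one.

## Problem sizes

The test suite phenotypes a 5,000-encounter cohort for exact planted-truth
recovery, uses 20,000 encounters for discrimination/calibration recovery
(tolerances 0.02), ~5,000 cases for lead-time recovery against a
Monte-Carlo band, and 100 repetitions of a 2,000-encounter cohort with 500
bootstrap replicates for interval coverage. These sizes put Monte-Carlo
noise comfortably below the asserted tolerances while keeping a full run
in minutes on one CPU; the acceptance script uses the same sizes.

## Limitations

- The generator's event streams are schedule-driven (vitals every 4 h,
  labs on arrival), without missingness patterns, unit-dependent sampling,
  or physiologic trajectories; results on it bound implementation
  correctness, not clinical performance.
- Computable implementations of these definitions differ between health
  systems in their exact thresholds and windows; the defaults here come
  from the primary published definitions and are fully configurable, which
  is also the recommended path for site calibration.
- Encounter types are taken as ground truth; transfers out of ED-only
  encounters are not reconciled.
- The SEP-1 implementation is the severe-sepsis logic only, not the CMS
  bundle-compliance measure.
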