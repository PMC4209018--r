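---
title: "Modelling metabolic-syndrome progression with a 7-state annual Markov chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metabolic-syndrome progression with a 7-state annual Markov chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmarkov)
```

## The model

Metabolic syndrome (MS) is a clustering of four metabolic risk components
— overweight/obesity, hypertension, dyslipidemia and hyperglycemia — and
is diagnosed, under the Chinese Diabetes Society (CDS) criteria used
throughout this package, when at least three of the four are present at
the same time. Rather than tracking all 16 component profiles (and their
256 transitions), the package works with a reduced 7-state space that is
mutually exclusive and collectively exhaustive:

1. no component,
2. isolated overweight/obesity,
3. isolated hypertension,
4. isolated dyslipidemia,
5. isolated hyperglycemia,
6. any 2 components,
7. MS (3 or 4 components).

Progression is modelled as a reversible discrete-time Markov chain with a
cycle length of one year: any state may persist or move to any other state
at each annual check-up. Two assumptions carry the whole projection
machinery: the next state depends only on the current state (first-order
Markov property), and the annual transition matrix is constant over the
projection horizon (time homogeneity). Neither is innocuous — component
remission and onset rates drift with age and with secular trends in
treatment — which is why matrices are estimated separately within 8
strata (two sexes by age groups 18–40, 40–49, 50–59, ≥60) and projections
never migrate a cohort between strata.

### Classification

A check-up record carries BMI (kg/m²), systolic/diastolic blood pressure
(mmHg), fasting triglyceride, HDL cholesterol and fasting glucose
(mmol/L), an optional 2-h post-meal glucose, and prior-diagnosis flags.
The CDS component rules are threshold rules with `>=` semantics on every
cut except HDL, which is dyslipidemic strictly *below* 0.9 mmol/L; a
prior diagnosis of hypertension or hyperglycemia is sufficient alone for
its component. Thresholds are configurable (`cds_thresholds()`) but the
defaults are the CDS values and are logged with every pipeline run.

Age groups partition `[18, Inf)` as `[18,40), [40,50), [50,60), [60,Inf)`.
The published group labels overlap at 40; the half-open convention gives a
single-valued mapping and is consistent with the "≥60" phrasing of the
oldest group. Subjects with a history of coronary heart disease, type-1
diabetes or familial hyperlipidemia, with incomplete mandatory
measurements at any visit, or aged under 18 are excluded entirely (all
visits), the conservative reading of cohort-level exclusion; per-reason
counts are logged.

### Estimation

Transition probabilities are estimated in two steps. For each pair of
consecutive calendar years (y, y+1) and each stratum, an annual
incidence-rate matrix is formed: `rate(i,j) = 100 * n(i->j) / n(i)`,
conditioning on the row's starting state. Rows with no observations are
marked *unobserved*, never zero-filled — zero-filling would bias
persistence downward. The stratum's annual transition matrix is then the
cell-wise **unweighted mean** of the year-pair matrices (over the
year-pairs in which the row was observed), renormalized row-wise to 100.
The unweighted mean is the primary estimator because each year-pair
contributes one rate estimate regardless of its denominator; count-weighted
pooling is available (`averaging = "pooled"`) as a sensitivity analysis
and coincides with the mean exactly when denominators are equal across
year-pairs (an algebraic identity the test suite exercises).

Two conventions were genuinely open and are exposed as switches:

* **Gaps.** Only visits in adjacent calendar years form an event; a
  2007→2009 pair contributes nothing. The alternative — annualizing over
  the gap — would require an interpolation model the data cannot support.
* **Stratum timing.** By default an event is assigned to the stratum of
  the subject's age in the *first* year of the pair (`per_pair`), so a
  subject crossing 40 mid-follow-up contributes to both age groups in
  turn; `baseline` freezes the stratum at enrolment instead.

### Projection and validation

An occupancy vector π over the 7 states is propagated by
π_{t+1} = π_t P with P the annual matrix (entries percent/100), for a
default horizon of 10 cycles from each starting state. Printed tables are
used **verbatim** for one-cycle read-outs (so a unit start reproduces a
table row exactly, including its rounding), and **renormalized** (rows
rescaled to sum to exactly 100) for multi-cycle propagation, which keeps
total occupancy conserved to 1e-9 over the horizon. Projection refuses to
push probability mass into an unobserved row rather than guessing.

Because every packaged matrix is irreducible and aperiodic (self-loops
everywhere, and every state reaches every other via the 2-component
state), trajectories from all 7 starting states contract toward a common
stationary distribution; by cycle 10 the spread in MS occupancy across
starting states is a small fraction of its cycle-1 value. Validation is
descriptive: the baseline occupancy of each stratum is projected 5 cycles
and compared with the observed MS prevalence among subjects actually seen
at that follow-up year; no pass/fail threshold is imposed.

As an independent cross-check on the propagation algebra, a
microsimulation oracle (`microsimulation_oracle()`) steps 100,000
individual chains through the same matrix and compares empirical
occupancies with the matrix-power result; the two agree within binomial
Monte-Carlo error on every packaged matrix.

## The synthetic cohort generator

No check-up cohort is distributed with the package, so the generator is a
first-class module rather than a test fixture: it produces cohorts whose
*latent* state dynamics follow a known per-stratum matrix, which makes
the entire pipeline testable and supports parameter-recovery experiments
(simulate from a printed matrix, re-estimate, compare).

Its defaults encode the study conditions the package targets:

* **Matrices.** The 8 packaged stratum matrices (`fixture_matrices()`).
  Five are published tables stored verbatim in percent; the three strata
  whose tables were only published in supplementary material not
  redistributable here (women 50–59, men and women ≥60) ship as
  hand-constructed stand-ins flagged `synthetic` in both filename and
  provenance. They follow the qualitative elderly pattern — more traffic
  into hypertension and the 2-component state — but are not estimates of
  any real cohort, and no numerical claim in the tests rests on their
  specific values.
* **Visits.** Up to 6 annual visits starting in 2006, matching a six-year
  follow-up window.
* **Dropout.** Independent Bernoulli with probability 0.30 before each
  visit after the second, chosen so the mean number of visits is ≈3.7,
  matching the source cohort's mean follow-up of 3.74 years; every subject
  keeps at least two visits ("at least two check-ups" is an inclusion
  criterion, not an outcome). The real visit-count distribution is
  unknown, so this is the simplest mechanism consistent with the reported
  mean, and dropout is independent of state (missing completely at
  random) — real attrition is plausibly state-dependent, which the
  generator does not emulate.
* **Initial distribution.** (0.40, 0.12, 0.10, 0.10, 0.04, 0.14, 0.10)
  over the 7 states, spread so that every matrix row is well populated in
  recovery experiments; the published cohort reports only per-component
  baseline prevalences, not a 7-state baseline distribution.
* **Ages.** Uniform within the stratum's age interval at baseline
  (60–75 for the open-ended group), advancing one year per visit. Under
  `per_pair` stratum assignment a subject can age out of their generating
  stratum; since age is independent of state here, this thins the sample
  without biasing the stratum's estimate.

Measurements are rendered by drawing each value uniformly from a range
lying entirely on the correct side of its threshold (e.g. BMI from
25.0–32.0 when overweight is present, 19.0–24.8 when absent), with the
alternative trigger routes — diagnosis flags, low HDL versus high TG,
2-h glucose — selected with fixed probabilities. A renderer whose ranges
straddle a threshold is rejected at construction: that validation is
precisely what guarantees `classify(render(state)) == state`, which the
tests check exactly on tens of thousands of records. Composite states
pick their component combination uniformly (6 pairs; 4 triples plus the
quadruple) — downstream classification only uses the count, so the choice
is immaterial. The renderer guarantees threshold consistency *only*: the
joint distribution of biomarkers is not physiological (no correlation
between BMI and blood pressure within a state, uniform margins), so
passing tests demonstrate correctness of the pipeline's logic, not
realism of the synthetic data.

## Numerical choices

* Printed matrices are stored in percent exactly as published; rows sum
  to 100 within ±0.01 and are renormalized on load wherever exact
  stochasticity matters. Estimated matrices are renormalized after
  averaging as a guard against exclusion-induced drift, although the mean
  of fully-observed normalized rows already sums to 100.
* Occupancy conservation is asserted at 1e-9; the initial distribution
  simplex at 1e-8; verbatim fixture rows at a 0.5 tolerance that admits
  printed rounding but rejects transcription errors.
* Duplicate subject-year rows abort estimation with the subject named —
  they would silently double-count transitions.
* All randomness flows from one integer seed per model/run; simulation,
  rendering and microsimulation consume a single stream, so a seed pins
  every byte of the cohort CSV.

## Problem sizes used by the test suite

Parameter-recovery checks simulate 200,000 subjects per stratum (the
size at which the targeted cells are stable to well under ±0.5
percentage points); law-of-large-numbers checks on raw trajectories use
200,000 subjects with a uniform initial distribution; the
microsimulation cross-check uses 100,000 chains over 10 cycles per
matrix; routine structural tests run on a few hundred subjects. These
sizes are the package's own accuracy choices for each property.

## Limitations

* The three synthetic stand-in matrices are illustrative, not empirical.
* Time homogeneity and the absence of mortality mean long-horizon
  projections describe the model, not demography; the source setting
  omitted mortality deliberately and this package follows it.
* The estimator treats visit gaps as uninformative and dropout as
  ignorable; both are simplifications of real attendance behaviour.
* No confidence intervals are attached to transition probabilities; the
  averaging estimator's sampling error is visible only through the
  simulation experiments.
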