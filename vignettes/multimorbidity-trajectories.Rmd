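---
title: "Modelling multimorbidity trajectories with ltctraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multimorbidity trajectories with ltctraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal primary-care records register, for each patient, dated onsets
of chronic long-term conditions (LTCs), dated resolutions for the subset of
conditions where remission is coded, and dates of death. `ltctraj` analyses
how multimorbidity — the concurrent presence of two or more LTCs — develops,
resolves and ends in death over follow-up, and how that differs between
demographic and clinical subgroups. Four complementary views are provided:

1. **Five-state histories and trajectory classes.** A patient's record is
   collapsed to a piecewise-constant path over states indexed by the capped
   number of active conditions, {0, 1, 2, 3+}, plus an absorbing death
   state. Comparing uncapped start and end counts classifies each patient
   as *Stable*, *Progressed* (more conditions, or died) or *Remitted*
   (fewer conditions).
2. **A continuous-time multistate Markov model** over those five states,
   with log-linear covariate effects on every transition intensity.
3. **Mean cumulative function (MCF) curves** of condition acquisition,
   treating death as censoring and ignoring resolution.
4. **First-order Markov chains of disease sequences**: which condition
   tends to be acquired after which.

Because real primary-care extracts cannot be shared, the package includes a
first-class synthetic cohort generator with known ground truth; every
statistical claim the package makes is tested by parameter recovery against
that truth.

## The multistate model

Let $q_{rs}(x) \ge 0$ be the transition intensity from state $r$ to state
$s$ for a patient with covariate vector $x$. The allowed transitions are
the single-step moves $0 \leftrightarrow 1 \leftrightarrow 2
\leftrightarrow 3+$ plus $r \to \text{Death}$ from every living state —
ten in all; death is absorbing. Intensities are modelled log-linearly,

$$ q_{rs}(x) = q^{0}_{rs}\, \exp(\beta_{rs}^\top x), $$

so $\exp(\beta)$ is a hazard ratio (HR) multiplying the baseline intensity
$q^0_{rs}$ of the reference pattern. Each fitted model adjusts for age
group at entry (18–39 reference, 40–59, 60–79, 80+) plus one exposure at a
time (sex, ethnicity, IMD quintile, a risk factor with never/ever/resolved
levels, or the derived "any risk factor" indicator); this mirrors the
common epidemiological strategy of separate similarly-structured models per
exposure.

### Likelihoods

EHR condition events carry dates, so the primary observation scheme treats
transition times as **exactly observed**: a sojourn of length $d$ in state
$r$ contributes $q_{rr} d$ (with $q_{rr} = -\sum_{s \ne r} q_{rs}$) to the
log-likelihood and each observed jump $r \to s$ contributes $\log q_{rs}$;
a censored final sojourn contributes only its survival term. Under this
scheme, with time-constant covariates, the likelihood factorises over
transitions into independent Poisson-type kernels in (event count, time at
risk in the origin state). `msm_fit(mode = "exact")` exploits this: each
transition is maximised separately by quasi-Newton iteration from the
crude-rate initialiser (events ÷ person-years at risk), polished by Newton
steps with the analytic Hessian, which also supplies the Wald covariance.

A **panel** scheme is provided for sensitivity analysis
(`mode = "panel"`): states are taken as observed only at the recorded
times and intervals contribute $\log [\exp(\Delta t\, Q)]_{s_i, s_{i+1}}$,
with death exactly timed (the interval ending in death contributes
$\sum_r P_{s,r}(\Delta t)\, q_{r,\text{Death}}$). Two facts about the
relationship between the schemes matter for interpretation and are
asserted in the tests:

* On intervals without living-state jumps, and for death transitions, the
  panel log-likelihood converges absolutely to the exact one as the
  observation grid becomes dense. A living-state jump contributes a
  probability mass $\approx q\,\Delta t$ in the panel scheme versus a
  density $q$ in the exact scheme, so the two differ by $\log \Delta t$
  per jump — an additive constant that does not affect maximisation.
* Using *only* the transition times as panel observation times is
  informative sampling and biases panel estimates upward. The
  `panel_grid_dt` argument densifies the observation grid; with a dense
  grid the panel estimates agree with the exact ones to within a few
  percent, which is what the agreement test asserts.

### Derived quantities

* `transition_probability(Q, t)` computes $P(t) = e^{tQ}$ by degree-13
  Padé approximation with scaling and squaring — stable without assuming
  $Q$ diagonalisable. Rows must sum to 1 within $10^{-8}$; a larger
  deviation raises an error rather than being silently renormalised.
* `sojourn_times(Q)` returns $-1/q_{rr}$, the mean time per visit to each
  living state (infinite when a state has no exit rate).
* `one_year_report()` emits, for a covariate pattern (default age 40–59),
  the one-year matrix, the headline sums $P(S0\to S1) + P(S0\to D)$ and
  $P(S2 \to S3{+}) + P(S2 \to D)$, and their "1 in N" renderings with
  $N = \mathrm{round}(1/p)$ (shown as "1" when the rounded odds reach 1
  and "-" for zero).
* Transitions with zero observed events in a stratum are reported `NA`
  (their fitted intensity is zero) rather than regularised; a covariate
  category with no events on a transition gets an `NA` coefficient there
  and its exposure time is excluded from that transition's kernel so the
  remaining estimates are unbiased.

## The MCF estimator

`estimate_mcf()` is the recurrent-event Nelson–Aalen-type estimator: at
each distinct onset time $u$ (measured in years since each subject's own
follow-up start) the curve increments by the number of onsets at $u$
divided by the number of subjects still under follow-up at $u$. Subjects
leave the risk set at follow-up end or death; ties between an event and a
risk-set exit process the event first. Resolutions never decrement the
curve, and onsets dated before follow-up start are baseline conditions,
not accumulation. With no censoring the estimator reduces exactly to the
mean per-subject count curve, which the tests assert. Death is treated
purely as censoring; no competing-risk correction is applied, so in
populations where death intensity rises with morbidity the curves can be
biased slightly upward — a documented limitation of the estimand, not a
property the tests can sign.

## Disease sequences

`build_sequences()` orders each patient's *first* onsets by date (same-day
ties broken alphabetically by condition code, making the result invariant
to input row order) and appends a Death token for deceased patients. "One
time step" of the chain means the next acquisition event, not a calendar
interval. `estimate_chain()` pools adjacent pairs over patients — the
maximum-likelihood estimator of a first-order chain — giving a
row-stochastic matrix over 32 conditions plus Death whose diagonal is
structurally zero. `select_top()` returns the top-k (default 3)
consequents per row and antecedents per column, keeping all ties at the
k-th value and dropping zero probabilities, so lists may be longer or
shorter than k. Pre-follow-up onsets are included by default (their dates
are recorded); `include_prior = FALSE` restricts to in-follow-up onsets —
the original analytic choice is not documented in the field's reports, so
both modes are provided and neither is claimed canonical.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of an urban, young,
multi-ethnic primary-care population. Its defaults are fixed study
conditions, not tuning knobs:

* **Initial states** 76/15/5/4% for 0/1/2/3+ conditions.
* **Follow-up**: entry is a mixture (36% of patients present at the study
  window start, the rest uniform over the window); durations are lognormal
  with spread set from the target IQR (1.8–8.4 y) and the meanlog
  calibrated by `uniroot` so that the *observed*, window-censored median
  equals the target 4.2 years. Durations are additionally truncated by
  death. The 15.1-year window of 2005-04-01 to 2020-05-02 is the default.
* **Covariates**: sex, age group, ethnicity (including an explicit Missing
  category), IMD quintile and six never/ever/resolved risk factors, with
  prevalences chosen to resemble a deprived inner-city denominator.
  "Resolved" is a sub-category of ever-exposed by construction.
* **Ground truth intensities** (`default_truth_model()`): acquisition
  accelerates with the number of conditions, resolution is slower than
  acquisition, death is rare from health and rises steeply with age and
  morbidity; female sex increases movement up and down but lowers death;
  resolved smoking carries a larger acquisition hazard than current
  smoking (matching the monitoring-intensity pattern seen in routine
  records).
* **Condition identities**: a newly acquired condition is drawn from the
  cluster (A mental health, B cardiovascular, C pain, D liver, E
  dependence, F unclustered) of the patient's most recent active onset
  with probability `p_same = 0.7`, otherwise from global weights. The
  stickiness applies to all six clusters — including F — so the chain
  module has recoverable structure for every condition. A patient entering
  in state 3+ receives exactly three prior-onset conditions, which keeps
  the latent active count equal to the capped state and makes downward
  moves from 3+ well-defined.
* **Resolvability guarantee**: a downward move must resolve an active
  resolvable condition. If a downward move would find none, the most
  recent active onset is re-drawn as a resolvable condition (same cluster
  where possible) before the move is rendered; the move/event bijection is
  therefore exact and the round-trip test (events → history → path)
  recovers every simulated path.

What the generator does **not** emulate: coding-system artefacts
(Read/SNOMED), under-recording, list-cleansing deregistrations,
time-varying intensities, or correlation between covariates beyond what
the truth model induces. Passing recovery tests therefore demonstrates
estimator correctness under the stated model, not robustness to these
real-data features.

## Numerical choices

* Dates are parsed as calendar dates and converted to fractional years at
  365.25 days/year throughout; rendered output is at day resolution.
* Same-day events are sequenced deterministically (resolutions first, then
  alphabetically by condition code) and separated by `epsilon` (default
  one day in years) so the single-step property holds exactly whatever
  the input row order.
* Optimisation is unconstrained on the (log-rate, raw coefficient) scale.
  Confidence intervals are Wald with z = 1.96 on the log scale; profile
  intervals are out of scope.
* The acceptance checks run at sizes chosen to keep the full suite
  comfortably reproducible on a laptop: 50 replicates of 5,000 patients
  for recovery/coverage, 20,000 patients for cluster-sequence recovery,
  50,000 draws for sojourn and absorption checks, 1,000 random matrices
  for the exponential contract, and a 2,000-patient demo pipeline run
  twice for byte-identical determinism.
* The recovery study deliberately uses a flatter initial-state
  distribution (40/30/20/10%) and somewhat higher death intensities than
  the cohort-emulation defaults, so that every one of the ten transitions
  accrues enough events (roughly 100–1,300 per replicate) for the mean
  relative bias of each baseline intensity to be measured against a
  Monte-Carlo standard error well below the 5% bound being asserted.
  Recovery tests measure estimator correctness; cohort realism is the
  default configuration's job.

## Known limitations

* Intensities are time-homogeneous given covariates; age enters as age at
  entry only, never as a time-varying covariate, and there are no frailty
  terms.
* Missing ethnicity/IMD are retained as an explicit "Missing" category;
  no imputation is performed.
* The MCF carries no variance bands and no competing-risk correction.
* Low-number suppression (cells ≤ 10 rendered "≤10") is an opt-in output
  filter on rendered tables; numeric results are never altered by it.
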