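---
title: "Methods: dose-response modelling of self-managed digital therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response modelling of self-managed digital therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosefreq)
```

## The scientific problem

Self-managed digital therapy apps for post-stroke speech, language and
cognitive rehabilitation let patients choose their own practice schedule.
That naturally occurring variation in *dosage frequency* — the number of
days per week with at least one practice session — makes retrospective
dose-response analysis possible: do patients who practice more days per
week improve faster over a fixed treatment period?

`dosefreq` implements the full analysis chain for this question: a
session-level performance score built from each domain's task progression
order, cohort preparation (inclusion rule, 10-week analysis window,
dosage binning), a linear mixed-effects inference layer (slope contrasts,
estimated marginal means, Tukey adjustment, standardized effect sizes),
and a synthetic-cohort simulator so that every stage is testable without
proprietary app data.

## The domain score

Each skill domain exposes an ordered inventory of `L` task levels ranked
from least to most difficult. Within a session a task is *passed* at
accuracy ≥ 90%, *failed* below 40%, and *working* in between. The session
score summarizes the difficulty level the patient operated at:

1. find `hi`, the highest task passed or working, and `lo`, the lowest
   task working or failed;
2. reduce an endpoint by one rank when its own status is working or
   failed (the highest level actually *passed* at that point is the
   previous task in the progression order), with a floor at 0;
3. average the two adjusted endpoints and divide by `L`.

The score is therefore a fraction of the domain's ladder, comparable
across domains, and weekly scores are session means within 7-day bins
anchored at the patient's first active day.

Decisions the score definition leaves open, and how this package takes
them (each is a deliberate design choice, exercised in the tests):

* **One-sided sessions.** If every task was passed, both endpoints are
  the highest passed rank, unadjusted; if none was passed or working,
  both endpoints are the lowest failed rank, adjusted. This keeps the
  score defined and continuous with the two-sided rule.
* **Repeated ranks** are pooled by mean accuracy before classification —
  the rule classifies tasks, not attempts.
* **Session boundaries.** A session is everything one patient did in one
  domain on one calendar day; app logs do not delimit sittings.
* **Per-endpoint adjustment.** A working task serving as `hi` is
  adjusted even though it is the highest — the adjustment is a statement
  about that task, not about its position.

## Cohort preparation

A patient enters the cohort when at least 10 of their first 15
patient-relative calendar weeks contain activity. The analysis window is
the first 10 *active* weeks among those 15, re-indexed 0..9; taking
active weeks (rather than truncating at calendar week 10) guarantees a
week-0 baseline score exists for every included unit. Week 0 doubles as
the baseline-severity covariate and stays in the outcome series; the
model formula requires both.

Dosage frequency is the median number of active days per week over the
10 window weeks, with inactive window weeks counting 0. Half-integer
medians round up (2.5 → 3) and medians of five or more fall in the open
"5+" bin. The default assignment unit is the patient × domain (activity
in the scored domain), because a patient's domains can be practiced on
different schedules; a per-patient mode (activity in any domain) is a
switch away.

## The mixed model and its inference layer

The pooled model, fitted by `lme4::lmer` with REML, is

```
score ~ week * (group + total_hours) + baseline + age + sex + chronicity
        + (1 + week | patient) + (1 + week | domain)
```

with reference levels group "1 day/week", sex female, chronicity chronic
(> 6 months post-stroke). The crossed patient and domain random
intercept/slope terms are fitted directly — lme4 handles crossed grouping
factors natively. Per-domain analyses drop the domain term. ML replaces
REML whenever models with different fixed effects are compared by
likelihood-ratio test (`compare_models`, which also reports AIC/BIC
deltas).

Group `g`'s improvement rate is `beta_week + beta_week:group_g`, so a
pairwise slope contrast is a difference of two interaction coefficients;
estimated marginal means at week `w` average the linear predictor over a
reference grid (equal weights over sex and chronicity levels, continuous
covariates at their sample means). Because contrasts are linear in the
coefficients, group differences are invariant to the continuous grid
values. All pairwise tests use asymptotic (z) inference and the Tukey
studentized-range adjustment for a family of five estimates:
`p = P(Q_{k,df} > |t|·sqrt(2))`, evaluated with R's `ptukey` (numerically
integrated; cross-checked in the test suite against an independent
integration of the range distribution, and against `emmeans` on fitted
models). At `k = 2` the adjustment reduces to the two-sided normal
p-value.

The standardized pre/post effect size per group is
`d_g = (EMM_g(9) − EMM_g(0)) / σ`. The standardizer is a required choice
that reported analyses in this field rarely spell out; the package
defaults to the residual SD and offers a "total" mode
(`sqrt` of the summed variance components) — both are exposed, neither is
claimed to be the only defensible choice.

## The synthetic cohort

Two generators cover the two testing needs.

**Mechanistic simulator** (`simulate_patient`, `simulate_cohort`):
emulates adaptive-difficulty practice. Expected accuracy follows a
two-parameter logistic item-response curve `plogis(kappa * (theta −
delta_rank))` with binomial sampling over `n_items = 20` items (the
simplest form with the right monotonicity; `n_items = Inf` gives the
noise-free mode used by exact tests). A patient advances one rank after
two sessions at ≥ 90% accuracy, and drops one (floor 1) on a session
below 40% or after three consecutive sessions without an accuracy
increase — the "not improving" window is not specified by the scoring
rule and is configurable. Demoted work *replaces* the working rank
(sessions track a single current rank); practicing old and new ranks in
parallel is not represented. Ability rises by a per-session learning
rate, ~Gamma(2, 0.015) difficulty units across patients, which over a
10-week course moves a median patient a few percent up a 20-level
ladder — the order of magnitude the weekly score slopes imply. Active
days are placed uniformly at random within each week; five groups target
1, 2, 3, 4 and 5-7 days/week. Ages are N(63, 14) truncated at 18, sex
56/43/1% female-reference mix, months post-stroke log-normal with ~59%
acute (≤ 6 months) — the demographic mix of a large real-world
post-stroke app cohort. Every patient × domain stream derives its RNG
seed from the root seed, so cohorts are bit-for-bit reproducible.

**Direct LMM generator** (`generate_lmm_dataset`): draws weekly scores
straight from the fitted-model family — fixed effects
`reference_fixef()`, bivariate-normal random intercept/slope pairs and
Gaussian residuals `reference_varcomps()` — so that estimator recovery
can be checked against known truth. With all variance components zero
the outcome equals the linear predictor exactly (no clipping by
default, keeping the generative model exactly linear-Gaussian; clipping
to [0, 1] is available but off).

What the simulators do **not** emulate: task-inventory heterogeneity
within a domain, practice-time/accuracy dependence, dropout and
re-engagement patterns, concurrent in-person therapy, or self-selection
of dosage by severity. Passing tests therefore demonstrate that the
pipeline is correct and the estimator calibrated under the stated
generative assumptions — not that those assumptions describe any
particular real cohort.

## Numerical choices and problem sizes

* Studentized-range tail probabilities: `ptukey`, whose quadrature is
  accurate well below the 1e-6 absolute tolerance the tests assert.
* lme4 fits use the default nonlinear optimizer at its standard relative
  convergence tolerance; singular-fit warnings are suppressed in favour
  of an explicit `converged` flag, and non-convergence warns rather than
  silently returning.
* Rank-deficient fixed-effect designs error up front, naming the
  collinear columns, instead of letting the backend drop columns.
* Median rounding in dosage binning is half-*up* (base R rounds half to
  even), implemented in `round_half_up()`.
* Recovery experiments in the test suite use 40 patients/group × 3
  domains × 10 weeks × 50 replicates, and the LRT calibration null uses
  40 clusters × 6 observations × 500 replicates — sizes chosen to give
  stable Monte-Carlo estimates while keeping a full test run in minutes
  on one core.

## Known limitations

* With only 3 simulated domains the domain-level variance components are
  weakly identified; fixed-effect inference is unaffected but domain
  variance estimates are noisy.
* At the recovery-experiment scale the adjacent dosage groups' true
  slope differences are comparable to their estimation SE, so the
  *strict ordering* of all estimated group slopes is not a reliable
  event at that size, even though each interaction's confidence interval
  is well calibrated. Distinguishing adjacent dosage groups reliably
  needs cohorts of thousands of patients, which is exactly why the
  real-world analyses this package mirrors used them.
* The effect-size standardizer is a modelling choice; `d` values are
  comparable within one choice only.
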