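---
title: "Modelling basic ADL impairment and death in Alzheimer's disease as an illness-death process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling basic ADL impairment and death in Alzheimer's disease as an illness-death process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlsurv)
```

## The scientific problem

Patients with Alzheimer's disease differ in whether they pass through a
stage of cognitively driven impairment in *basic* activities of daily
living (feeding, dressing, grooming, ambulation, bathing, continence)
before death. If developing such impairment carries a mortality risk of
its own, beyond what global disease severity explains, then the
*transition* into the impaired state is prognostic information that a
baseline-only survival model throws away.

`adlsurv` models an AD cohort as a three-state illness-death process:

* state 1 — intact basic ADL,
* state 2 — impaired basic ADL (absorbing short of death),
* state 3 — death,

with three transition intensities on the common clock of years since the
initial clinic visit:

$$h_I(t)\;(1\to 2), \qquad h_{D1}(t)\;(1\to 3), \qquad h_{D2}(t)\;(2\to 3),$$

each a Cox proportional-hazards model
$h_k(t \mid z) = h_{0k}(t)\, e^{\beta_k' z}$ on the same eight baseline
covariates: age, sex, race, education, baseline MMSE, symptom duration,
marital status and CVDE (a cardiovascular disease equivalent composite,
see `derive_cvde()`). Using the forward clock for $h_{D2}$ (a Markov
assumption) lets patients enter the post-impairment risk set at their
onset time through left truncation, which is how the delayed entry is
handled in the partial likelihood.

## Impairment state from PSMS scores

Basic ADL is measured by the Physical Self-Maintenance Scale (PSMS): six
items scored 1 (no impairment) to 5 (severe), total 6–30, with 6 meaning
fully intact. Two complementary definitions of *developing* impairment
are supported (`adl_onset()`):

* **absolute** (`psms_ge7`): a total score above 6 at a post-baseline
  visit; a baseline score above 6 means the patient is impaired from
  entry;
* **relative** (`delta_ge2`): an increase of at least 2 points over the
  patient's own baseline, which remains meaningful for patients who
  already score above 6 at entry.

Onset is dated at the first qualifying visit. Clinic cohorts are
reassessed roughly annually, so this is the finest dating the data
support; a midpoint convention (`convention = "midpoint"`) is available
for sensitivity analysis. A patient who dies with no qualifying visit
beforehand is treated as never impaired — no impairment is imputed
between the last intact assessment and death. The consequences of this
choice are quantified below.

## Estimation machinery

All three transitions, the fixed-covariate death model, and the
time-dependent-impairment death model are fitted by one engine,
`fit_cox()`: Newton–Raphson maximisation of the weighted Cox partial
likelihood on counting-process `(start, stop]` rows. Numerical choices:

* **Risk sets**: a row is at risk at event time $t$ iff
  $\text{start} < t \le \text{stop}$; at tied times, events precede
  censorings. Risk-set sums are suffix sums over time-sorted rows, which
  avoids the catastrophic cancellation a total-minus-prefix evaluation
  suffers in small late risk sets.
* **Ties**: Breslow by default, consistent with the Breslow baseline
  used for prediction; Efron by option. With jittered continuous visit
  and death times, ties are rare.
* **Convergence**: absolute change in partial log-likelihood below
  `1e-9`, at most 50 iterations, with up to 10 step-halvings per
  iteration on any likelihood decrease.
* **Degenerate inputs**: zero events, a covariate constant within every
  risk set, and a monotone likelihood (separation; detected as a
  coefficient exceeding 15 on the centred-covariate SD scale, far beyond
  any plausible hazard ratio and below the level where the likelihood
  plateaus numerically) raise typed errors naming the covariate.
* **Weights** enter score, information and baseline hazard alike; the
  reported variance is the inverse information, matching the plain
  confidence intervals clinical papers print. An infinitesimal-jackknife
  sandwich variance (grouped by patient) is available with
  `robust = TRUE` and is the conservative choice under IPCW weights.

The cumulative baseline hazard is the Breslow estimator
$\hat H_{0k}(t) = \sum_{t_j \le t} \frac{\sum_i w_i\, dN_i(t_j)}{\sum_{l \in R(t_j)} w_l e^{\hat\beta_k' z_l}},$
referenced to covariates all zero; at $\hat\beta = 0$ and unit weights it
reduces exactly to Nelson–Aalen, which the test suite asserts.
Proportional hazards is checked by `schoenfeld_ph_test()`: the residual
at each event is the event's covariate minus the risk-set weighted mean,
and the per-covariate and global chi-square statistics test a linear
trend of the residuals in the rank of event time. Its size under the
null is verified by simulation in the test suite.

## Loss to follow-up and IPCW

Patients unreachable at follow-up are *lost*, and loss is plausibly
related to covariates that also predict death. The correction used here
is a single logistic regression of being lost on the nine baseline
covariates (the eight above plus baseline PSMS), giving each patient the
fixed subject-level weight $w_i = 1/(1 - \hat p_i^{\text{lost}})$
(`cohort_ipcw()`). Weights are capped at the 99th percentile by default
(configurable, and recorded in the run log) to guard against
near-separation blow-ups. This subject-level form — not the time-varying
product-limit form of IPCW — is a deliberate, documented simplification:
it matches the single-logistic description of the source analysis, and
the time-varying variant is out of scope. When loss depends only on
covariates already in the Cox model, the unweighted fit is already
consistent and weighting mainly costs a little efficiency; the weights
earn their keep when the analysis model omits a covariate that drives
both loss and death, which is the situation the test suite's
bias-reduction experiment constructs.

## Prediction

For a covariate profile $z$ (the "average patient" helper
`adl_profile()` uses age 75.1, education 13.6, baseline MMSE 19 — a
memory-clinic AD cohort average — and a policy for the rest: modal
category and mean symptom duration from the analysed cohort, or
reference categories when no cohort is supplied; the policy is recorded
on every prediction), the conditional probability of death within $t$
years for a patient in state $k$ at the start of observation is

$$F_k(t \mid z) = 1 - \exp\{-e^{\hat\beta_k' z}\, \hat H_{0k}(t)\},$$

with $k = D1$ for intact and $k = D2$ for impaired patients
(`predict()` on an `illness_death` fit). These are state-conditional
curves — "what if this patient is impaired now?" — not path-integrated
occupation probabilities; Aalen–Johansen-type predictors that integrate
over future onset times are an explicit non-goal.

## What the synthetic cohorts emulate

`simulate_cohort()` draws cohorts with the statistical structure the
estimator assumes, plus the observation scheme that makes real cohorts
hard:

* baseline covariates with memory-clinic marginals (age
  $\mathcal N(75.1, 8.3^2)$ truncated to [39, 97], education
  $\mathcal N(13.6, 3.6^2)$ truncated at 0, MMSE
  $\mathcal N(19, 7^2)$ truncated to [0, 30] and rounded, symptom
  duration Gamma with mean 3.9 and SD 2.3, 31.2% male, 9.1% nonwhite,
  39.2% not married, 62.2% CVDE);
* baseline PSMS as a mixture: fully intact (score 6) with probability
  0.445, otherwise $7 + \text{Poisson}(3.5)$ capped at 30, so about
  55% start impaired under the absolute definition;
* latent transition times from Weibull proportional-hazards intensities
  (`study_scenario()` uses constant intensities 0.12/yr for onset,
  0.045/yr for intact death and 0.13/yr for post-impairment death at the
  average profile, giving a post-impairment median survival near 5.3
  years and an overall death fraction near one half);
* annual visits with Gaussian jitter (SD 0.15 yr, realistic clinic
  scheduling); PSMS trajectories are built backwards from the latent
  onset so the score first satisfies *both* definitions at the first
  visit at or after the latent onset (a floor of 6 makes
  "$\Delta \ge 2$ while staying $\le 6$" impossible, so the definitions
  can only diverge through baseline-impaired patients, whose scores stay
  flat by default);
* covariate-dependent loss to follow-up via a logistic law on centred
  covariates, with the loss time uniform over the patient's
  administrative follow-up, and staggered administrative censoring
  (uniform between 1.5 and 14 years in the study preset, emulating a
  clinic that enrolled over two decades);
* per-patient random streams keyed by (seed, patient index), so cohorts
  are reproducible and a patient's draws do not depend on cohort size.

Death times are exact (vital status in such cohorts comes from registry
linkage); impairment is only observed at visits. MMSE decline over
follow-up is *not* emulated — only baseline MMSE enters any model.

The study preset's true log-hazard-ratios are in the range clinic
cohorts report: a strong male effect on both death transitions (0.60 and
0.65), protective education and MMSE, a modest age effect, and small
effects elsewhere. The continuous-covariate death effects are shared
between the two death transitions by design: as shown next, annual
observation unavoidably mixes a slice of early post-onset deaths into
the pre-impairment death model, so transition *contrasts* in those
coefficients are partly an artefact of the observation scheme, and
keeping them equal makes the recovery diagnostics interpretable as
estimator error.

## What annual observation does to the estimates

Two selection mechanisms are built into any annually assessed
illness-death cohort, and the simulator reproduces both:

1. **Onset is observed only if the patient survives to the next
   visit.** Profiles with a high death hazard (male sex, low MMSE) are
   selectively removed between their latent onset and the visit that
   would have confirmed it, so the impairment model's coefficients for
   death-driving covariates are biased toward "protective".
2. **Deaths inside the latent-onset-to-next-visit window count as
   pre-impairment deaths** (the no-imputation rule). These decedents are
   onset-selected — enriched for low MMSE — so the intact-death model's
   MMSE coefficient is pulled toward the impairment model's.

At the replication scale the test suite runs (100 cohorts of n = 2000),
the measured biases are small in absolute terms — the largest is about
−0.066 on the log scale for sex in the impairment model, with MMSE
biases under 0.01 — and every bias is below 0.7 of a single fit's
standard error, so Wald interval coverage stays in the nominal band
(the suite asserts pooled coverage in [0.92, 0.97]). But they are real,
systematic, and detectable at Monte-Carlo resolution: the strict
"every coefficient within 3 Monte-Carlo standard errors" recovery check
in `test-acceptance.R` fails for exactly the three coefficients named
above, and is expected to. The post-impairment death model shows no
detectable bias: entering its risk set at the *observed* onset is valid
conditioning, which is the quiet strength of the left-truncated design.
Practically: treat small transition contrasts in continuous covariates
between the two death models with caution in annually assessed cohorts;
the impairment-model coefficients of strong mortality predictors are
conservative.

## Problem sizes and other choices

Simulation-based checks in the package run at the sizes that make their
conclusions meaningful rather than as large as possible: exact
identities and oracle comparisons on fixtures of up to 10 subjects;
size/calibration checks at 150–800 subjects and 200 replicates;
recovery at n = 2000 and 100 replicates; the analytic-CDF comparison at
n = 5000. The two-group descriptive table (`describe_groups()`) uses
Welch's t (computed directly when a group is constant, as baseline PSMS
is in the intact group), chi-square without continuity correction, and
the log-rank test for median survival, mirroring the layout such papers
print as their Table 1.

Open design points were resolved as follows. The time-dependent death
model keeps all patients, with baseline-impaired patients coded impaired
from entry (restricting to the baseline-intact subset is a flag). Under
the relative definition everyone starts intact, including
baseline-impaired patients, who remain able to transition. An onset
recorded at the very end of follow-up yields an impairment event but no
post-impairment exposure; a death at that same instant counts as
pre-impairment (events precede the state change). Whether the multistate
models should carry the IPCW weights is not settled by the source
description, so `illness_death()` takes `weights` optionally and the
pipeline emits weighted runs by default with the setting in its log.

## Known limitations

* The subject-level IPCW form corrects confounded *occurrence* of loss,
  not its timing; informative censoring whose timing depends on
  post-baseline history is outside the model.
* The Markov (clock-forward) assumption for $h_{D2}$ means time since
  onset affects the post-impairment hazard only through total time; a
  clock-reset (semi-Markov) variant exists for sensitivity analysis
  only.
* Passing the synthetic-data checks shows the machinery is correct under
  the stated generating process; real cohorts add measurement error in
  PSMS ratings, non-annual visit patterns, and covariate drift that the
  generator deliberately does not emulate.
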