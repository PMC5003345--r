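# adlsurv

Illness-death survival modelling of basic ADL impairment in Alzheimer's
disease.

## The problem

Alzheimer's disease patients differ in whether they develop cognitively
driven impairment in *basic* activities of daily living (basic ADL:
feeding, dressing, grooming, ambulation, bathing, continence) before
death. For clinicians and health-economic planners the operative
question is prognostic: given a patient's covariates and current
functional state, what is their probability of dying within the next few
years — and how much does *becoming* impaired change it?

`adlsurv` answers this with a three-state illness-death model on the
clock of years since the initial clinic visit:

```
  intact basic ADL ──h_I(t)──▶ impaired basic ADL
        │                            │
      h_D1(t)                      h_D2(t)
        ▼                            ▼
      death                        death
```

Each transition intensity is a Cox proportional-hazards model
`h_k(t | z) = h_0k(t) exp(β_k' z)` on eight baseline covariates (age,
sex, race, education, baseline MMSE, symptom duration, marital status,
CVDE). Deaths after impairment are fitted with a left-truncated partial
likelihood — patients enter that risk set at their impairment onset.
Impairment status comes from serial Physical Self-Maintenance Scale
(PSMS) totals under two complementary definitions: a score above 6 at a
post-baseline visit (`psms_ge7`), or a gain of ≥ 2 points over the
patient's own baseline (`delta_ge2`). Loss to follow-up is corrected by
inverse-probability-of-censoring weights from a logistic model of being
lost on the baseline covariates. The conditional probability of death
within `t` years for a profile `z` in state `k` is
`F_k(t | z) = 1 − exp{−exp(β_k' z) · H_0k(t)}` with `H_0k` the Breslow
cumulative baseline hazard.

The Cox engine (`fit_cox()`) is implemented in the package — weighted
Newton–Raphson partial likelihood on `(start, stop]` counting-process
rows with delayed entry, Breslow/Efron ties, Breslow baseline, and
Schoenfeld-residual proportional-hazards diagnostics — and is verified
in the test suite against brute-force likelihood maximisation and
against an independent implementation.

## Worked example

Simulate a study-scale cohort (1029 patients, memory-clinic covariate
marginals, annual visits, informative dropout), estimate IPCW weights,
and fit the three-state model under the absolute impairment definition:

```r
library(adlsurv)
sim <- simulate_cohort(study_scenario(n = 1029), seed = 1)
sim$cohort
#> <adl_cohort> 1029 patients, 4198 follow-up visits
#>   outcomes: 494 dead, 375 administratively censored, 160 lost

w  <- cohort_ipcw(sim$cohort)
ms <- illness_death(sim$cohort, "psms_ge7", weights = w)
ms
#> Illness-death model for basic ADL impairment (definition: psms_ge7, IPCW-weighted)
#>   1029 patients; events: 171 impairment onsets, 102 deaths while intact,
#>   392 deaths after impairment
#> ...
#> -- death_impaired (hazard ratios):
#>          covariate   hr lower upper    p
#> 1              age 1.05  1.03  1.06 0.00
#> 2              sex 1.84  1.51  2.23 0.00
#> 5            mmse0 0.95  0.93  0.96 0.00
#> ...
```

The three blocks read like the hazard-ratio table of a multistate
analysis: in this simulated cohort, male sex roughly doubles the death
hazard in both states (HR 2.00 intact, 1.84 impaired), each MMSE point
lowers both the impairment and death hazards by 5–9%, and age acts on
death but barely on impairment onset. Event counts are conserved by
construction: 102 + 392 deaths across the two states equal the cohort's
494 deaths.

Prediction for an average male patient (age 75.1, education 13.6,
MMSE 19, remaining covariates set by the cohort-modal policy):

```r
pr <- adl_profile("male", cohort = sim$cohort)
round(predict(ms, pr, state = "impaired", times = c(2, 4, 6)), 3)
#> [1] 0.317 0.501 0.669
round(predict(ms, pr, state = "intact",   times = c(2, 4, 6)), 3)
#> [1] 0.157 0.296 0.376
```

An impaired 75-year-old man has a 67% predicted probability of dying
within 6 years, against 38% had he remained intact — the impairment
state itself carries most of that difference. `plot(ms)` draws the four
sex × state curves; `run_pipeline(run_config(...))` emits the full set
of analysis artifacts (descriptive table, fixed and time-dependent Cox
models, both multistate fits, prediction curves) as CSVs with a config
hash on every file.

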