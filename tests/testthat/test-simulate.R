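test_that("the generator is deterministic and order-independent", {
  sc <- study_scenario(n = 120)
  a <- simulate_cohort(sc, seed = 42)
  b <- simulate_cohort(sc, seed = 42)
  expect_identical(a$cohort$baseline, b$cohort$baseline)
  expect_identical(a$cohort$visits, b$cohort$visits)
  expect_identical(a$cohort$outcomes, b$cohort$outcomes)
  expect_identical(a$truth$patients, b$truth$patients)
  ## per-patient streams: the first patients do not depend on n
  sc2 <- study_scenario(n = 60)
  c_ <- simulate_cohort(sc2, seed = 42)
  expect_identical(c_$cohort$baseline,
                   a$cohort$baseline[1:60, ])
  ## different seeds differ
  expect_false(identical(simulate_cohort(sc2, seed = 43)$cohort$baseline,
                         c_$cohort$baseline))
})

test_that("generated cohorts always satisfy the structural invariants", {
  for (seed in 1:5) {
    sim <- simulate_cohort(study_scenario(n = 150), seed = seed)
    expect_equal(nrow(validate_cohort(sim$cohort)), 0)
  }
  sim2 <- simulate_cohort(
    sim_scenario(n = 100, dropout = c(`(Intercept)` = 0.5, age = 0.05),
                 admin_censor = 8), seed = 3)
  expect_equal(nrow(validate_cohort(sim2$cohort)), 0)
})

test_that("null-effect exponential scenario matches analytic death fraction", {
  ## both death transitions at rate 0.1/yr: the marginal death time is
  ## exponential(0.1) whatever the illness path; P(death by 10) = 1 - e^-1
  n <- 2000
  sc <- sim_scenario(n = n,
                     impairment = list(shape = 1, scale = 1 / 0.12),
                     death_intact = list(shape = 1, scale = 10),
                     death_impaired = list(shape = 1, scale = 10),
                     admin_censor = 10)
  sim <- simulate_cohort(sc, seed = 17)
  frac <- mean(sim$cohort$outcomes$status == "dead")
  p <- 1 - exp(-1)
  band <- 2.576 * sqrt(p * (1 - p) / n)
  expect_gt(frac, p - band)
  expect_lt(frac, p + band)
  ## no dropout model, no lost outcomes
  expect_equal(sum(sim$cohort$outcomes$status == "lost"), 0)
})

test_that("latent death times follow the scenario's Weibull law", {
  ## same Weibull on both death transitions: marginal death time is that
  ## Weibull exactly; compare the empirical curve of the latent times
  sc <- sim_scenario(n = 10000,
                     impairment = list(shape = 1, scale = 9),
                     death_intact = list(shape = 1.4, scale = 8),
                     death_impaired = list(shape = 1.4, scale = 8),
                     admin_censor = 50)
  sim <- simulate_cohort(sc, seed = 29)
  td <- sim$truth$patients$latent_death
  grid <- seq(0.2, 20, by = 0.2)
  emp <- vapply(grid, function(t) mean(td > t), numeric(1))
  expect_lt(max(abs(emp - exp(-(grid / 8)^1.4))), 0.02)
})

test_that("PSMS trajectories reveal onset at the first qualifying visit", {
  sim <- simulate_cohort(study_scenario(n = 400), seed = 23)
  tp <- sim$truth$patients
  on1 <- cohort_onsets(sim$cohort, "psms_ge7")
  on2 <- cohort_onsets(sim$cohort, "delta_ge2")
  v <- sim$cohort$visits
  for (i in which(!tp$baseline_impaired & !is.na(tp$latent_onset))) {
    pid <- tp$patient_id[i]
    vt <- v$visit_time[v$patient_id == pid]
    expected <- vt[vt >= tp$latent_onset[i]][1]   # NA when unobserved
    got1 <- on1$onset_time[on1$patient_id == pid]
    got2 <- on2$onset_time[on2$patient_id == pid]
    expect_equal(got1, expected)
    expect_equal(got2, expected)                  # both definitions coincide
  }
  ## baseline-impaired keep a flat score by default: no relative onset
  flat <- tp$patient_id[tp$baseline_impaired]
  expect_true(all(is.na(on2$onset_time[on2$patient_id %in% flat])))
})

test_that("the study-like preset reproduces the clinic cohort marginals", {
  sc <- study_scenario()          # n = 1029
  sim <- simulate_cohort(sc, seed = 31)
  b <- sim$cohort$baseline
  expect_lt(abs(mean(b$age) - 75.1), 3 * 8.3 / sqrt(1029))
  p_imp <- 1 - sc$covariate_laws$psms0_intact_p
  band <- 2.576 * sqrt(p_imp * (1 - p_imp) / 1029)
  expect_lt(abs(mean(b$psms0 >= 7) - p_imp), band)
  frac_dead <- mean(sim$cohort$outcomes$status == "dead")
  expect_gt(frac_dead, 0.3)
  expect_lt(frac_dead, 0.6)
  expect_lt(abs(mean(b$education) - 13.6), 3 * 3.6 / sqrt(1029))
  expect_lt(abs(mean(b$sex == "male") - 0.312), 2.576 * sqrt(0.312 * 0.688 / 1029))
})
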