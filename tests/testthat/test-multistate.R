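# minimal illness_death skeleton with prescribed baselines, for
# closed-form prediction checks
fake_ms <- function(beta_d1, base_d1, beta_d2, base_d2, covs = names(beta_d1)) {
  mk <- function(beta, base) structure(
    list(coefficients = beta, covariates = names(beta),
         means = setNames(rep(0, length(beta)), names(beta)),
         baseline = base), class = "coxfit")
  structure(list(
    fits = list(impairment = mk(beta_d1, base_d1),
                death_intact = mk(beta_d1, base_d1),
                death_impaired = mk(beta_d2, base_d2)),
    covariates = covs, definition = "psms_ge7", weighted = FALSE,
    events = c(impairment = 1, death_intact = 1, death_impaired = 1), n = 1
  ), class = "illness_death")
}

test_that("conditional death probability matches the closed form", {
  ## H0(t) = 0.1 t as a fine step function
  grid <- seq(0.01, 10, by = 0.01)
  lin <- data.frame(time = grid, hazard = rep(0.001, length(grid)))
  steps <- data.frame(time = c(1, 2), hazard = c(0.05, 0.07))
  ms <- fake_ms(c(z = 0), lin, c(z = 0), steps)
  ## linear predictor 0 at t = 6: 1 - exp(-0.6)
  expect_equal(predict(ms, c(z = 0), "intact", times = 6),
               1 - exp(-0.6), tolerance = 1e-12)
  ## linear predictor log 2 doubles the cumulative hazard
  ms2 <- fake_ms(c(z = log(2)), lin, c(z = 0), steps)
  expect_equal(predict(ms2, c(z = 1), "intact", times = 6),
               1 - exp(-1.2), tolerance = 1e-12)
  ## step baseline evaluated between jumps
  expect_equal(predict(ms, c(z = 0), "impaired", times = 1.5),
               1 - exp(-0.05), tolerance = 1e-12)
  expect_equal(predict(ms, c(z = 0), "impaired", times = c(0, 2.5)),
               c(0, 1 - exp(-0.12)), tolerance = 1e-12)
  ## a missing profile covariate is named
  expect_error(predict(ms, c(w = 1), "intact"), "z",
               class = "adlsurv_schema_error")
})

test_that("transition risk sets conserve events exactly", {
  for (seed in c(2, 13, 27)) {
    sim <- simulate_cohort(study_scenario(n = 350), seed = seed)
    deaths <- sum(sim$cohort$outcomes$status == "dead")
    for (def in adl_definitions()) {
      ms <- illness_death(sim$cohort, def)
      expect_identical(ms$events[["death_intact"]] + ms$events[["death_impaired"]],
                       as.numeric(deaths))
      on <- cohort_onsets(sim$cohort, def)
      n_onsets <- sum(!on$baseline_impaired & !is.na(on$onset_time) &
                        on$onset_time > 0)
      expect_identical(ms$events[["impairment"]], as.numeric(n_onsets))
    }
  }
})

test_that("a cohort where nobody becomes impaired degrades gracefully", {
  sc <- sim_scenario(n = 300,
                     impairment = list(shape = 1, scale = 1e9),
                     death_intact = list(shape = 1, scale = 8),
                     death_impaired = list(shape = 1, scale = 8),
                     covariate_laws = modifyList(
                       study_scenario()$covariate_laws,
                       list(psms0_intact_p = 1)),
                     admin_censor = 10)
  sim <- simulate_cohort(sc, seed = 9)
  ms <- illness_death(sim$cohort, "psms_ge7")
  expect_s3_class(ms$fits$impairment, "condition")
  expect_match(conditionMessage(ms$fits$impairment), "empty")
  expect_s3_class(ms$fits$death_impaired, "condition")
  expect_error(predict(ms, adl_profile("male"), "impaired"),
               class = "adlsurv_estimation_error")
  ## with no impairment, the intact-state death model is the plain
  ## whole-cohort survival model
  plain <- fit_cox(survival_rows(sim$cohort, covariates = adl_covariates()))
  expect_equal(coef(ms$fits$death_intact), coef(plain), tolerance = 1e-10)
})

test_that("transition effects are recovered on one large synthetic cohort", {
  sc <- study_scenario(n = 2000)
  sim <- simulate_cohort(sc, seed = 101)
  w <- cohort_ipcw(sim$cohort)
  ms <- illness_death(sim$cohort, "psms_ge7", weights = w)
  truth <- rbind(impairment = sc$beta_I, death_intact = sc$beta_D1,
                 death_impaired = sc$beta_D2)
  for (tr in rownames(truth)) {
    f <- ms$fits[[tr]]
    se <- sqrt(diag(vcov(f)))
    ## single replicate: allow the usual 3-SE sampling slack per coefficient
    expect_true(all(abs(coef(f) - truth[tr, names(coef(f))]) < 3.5 * se),
                label = tr)
  }
})

test_that("predicted curves are probability curves with the right ordering", {
  sim <- simulate_cohort(study_scenario(n = 800), seed = 55)
  ms <- illness_death(sim$cohort, "psms_ge7", weights = cohort_ipcw(sim$cohort))
  cv <- death_probability_curves(ms, horizon = 6, cohort = sim$cohort)
  expect_true(all(cv$prob >= 0 & cv$prob <= 1))
  expect_true(all(cv$prob[cv$time == 0] == 0))
  for (g in split(cv, interaction(cv$sex, cv$state)))
    expect_true(all(diff(g$prob[order(g$time)]) >= -1e-12))
  ## the study-like scenario has a dominating post-impairment hazard
  grid_t <- sort(unique(cv$time))
  for (sx in c("male", "female")) {
    imp <- cv$prob[cv$sex == sx & cv$state == "impaired"][order(grid_t)]
    int <- cv$prob[cv$sex == sx & cv$state == "intact"][order(grid_t)]
    expect_true(all(imp >= int - 1e-9))
  }
})

test_that("null covariate effects give profile-independent predictions", {
  sc <- sim_scenario(n = 1500,
                     impairment = list(shape = 1, scale = 8),
                     death_intact = list(shape = 1, scale = 12),
                     death_impaired = list(shape = 1, scale = 7),
                     admin_censor = 10)
  sim <- simulate_cohort(sc, seed = 77)
  ms <- illness_death(sim$cohort, "psms_ge7")
  pr1 <- adl_profile("male")
  pr2 <- adl_profile("female", age = 60, education = 8, mmse0 = 28)
  fit <- ms$fits$death_impaired
  lp1 <- sum(coef(fit) * pr1[names(coef(fit))])
  lp2 <- sum(coef(fit) * pr2[names(coef(fit))])
  ## true effects are all zero, so the two linear predictors differ only
  ## through estimation noise; bound the gap by its own standard error
  dz <- pr1[names(coef(fit))] - pr2[names(coef(fit))]
  se_gap <- sqrt(drop(t(dz) %*% vcov(fit) %*% dz))
  expect_lt(abs(lp1 - lp2), 3 * se_gap)
})

test_that("schoenfeld residuals are available per transition", {
  sim <- simulate_cohort(study_scenario(n = 400), seed = 12)
  ms <- illness_death(sim$cohort, "psms_ge7")
  r <- residuals(ms, "death_impaired")
  expect_equal(ncol(r), length(adl_covariates()))
  expect_lt(max(abs(colSums(r))), 1e-6)
})
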