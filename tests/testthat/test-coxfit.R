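test_that("Newton-Raphson estimate matches the brute-force maximizer", {
  for (nm in names(cox_fixtures())) {
    d <- cox_fixtures()[[nm]]
    cov <- fixture_covariates(d)
    fit <- fit_cox(d, cov)
    bf <- brute_force_beta(d, cov)
    expect_lt(max(abs(coef(fit) - bf)), 1e-4, label = nm)
    ## both routes evaluate to the same partial likelihood at the optimum
    expect_equal(fit$loglik[2], naive_cox_loglik(coef(fit), d, cov),
                 tolerance = 1e-10)
  }
})

test_that("engine agrees with an independent Cox implementation", {
  skip_if_not_installed("survival")
  sim <- simulate_cohort(study_scenario(n = 400), seed = 21)
  rows <- counting_process(sim$cohort, "psms_ge7")
  f1 <- fit_cox(rows, c("age", "sex", "mmse0", "impaired"))
  f2 <- survival::coxph(
    survival::Surv(start, stop, event) ~ age + sex + mmse0 + impaired,
    data = rows, ties = "breslow")
  cf <- coef(f2)[names(coef(f1))]
  expect_equal(unname(coef(f1)), unname(cf), tolerance = 1e-6)
  se1 <- sqrt(diag(vcov(f1)))[names(cf)]
  se2 <- sqrt(diag(vcov(f2)))[names(cf)]
  expect_equal(unname(se1), unname(se2), tolerance = 1e-6)
  bh <- survival::basehaz(f2, centered = FALSE)
  expect_equal(cumhaz_at(f1$baseline, bh$time), bh$hazard, tolerance = 1e-6)
  ## Efron ties on genuinely tied data
  tied <- data.frame(start = 0, stop = rep(1:4, each = 3),
                     event = rep(c(1, 1, 0), 4),
                     z = c(1, 0, 1, 0, 1, 0, 0, 1, 1, 1, 0, 0))
  fe <- fit_cox(tied, "z", ties = "efron")
  ge <- survival::coxph(survival::Surv(start, stop, event) ~ z, data = tied,
                        ties = "efron")
  expect_equal(unname(coef(fe)), unname(coef(ge)), tolerance = 1e-6)
})

test_that("degenerate inputs raise the named estimation errors", {
  d <- cox_fixtures()$toy6
  d0 <- d; d0$event <- 0
  expect_error(fit_cox(d0, "z"), class = "adlsurv_estimation_error")
  dc <- d; dc$z <- 1
  expect_error(fit_cox(dc, "z"), "z", class = "adlsurv_singularity_error")
  ## perfectly ordered covariate: the likelihood is monotone in beta
  dm <- data.frame(start = 0, stop = 1:6, event = 1, z = 6:1)
  expect_error(fit_cox(dm, "z"), class = "adlsurv_monotone_likelihood_error")
})

test_that("Breslow baseline at beta = 0 is the Nelson-Aalen estimator", {
  null_fit <- structure(list(coefficients = c(z = 0), covariates = "z",
                             means = c(z = 0)), class = "coxfit")
  d3 <- data.frame(start = 0, stop = c(1, 2, 3), event = c(1, 1, 0), z = c(1, 0, 1))
  bb <- breslow_baseline(null_fit, d3)
  expect_equal(bb$hazard, c(1 / 3, 1 / 2))
  for (d in cox_fixtures()) {
    d$z <- if ("z" %in% names(d)) d$z else d$z1
    bb <- breslow_baseline(null_fit, d)
    na <- naive_nelson_aalen(d)
    expect_equal(bb$time, na$time)
    expect_equal(bb$hazard, na$hazard)
  }
})

test_that("baseline hazard is invariant to rescaling all weights", {
  d <- cox_fixtures()$weighted5
  fit <- fit_cox(d, "z")
  d2 <- d; d2$weight <- d$weight * 2
  fit2 <- fit_cox(d2, "z")
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-8)
  expect_equal(fit$baseline$hazard, fit2$baseline$hazard, tolerance = 1e-8)
})

test_that("weighted Breslow increments match the direct formula", {
  d <- cox_fixtures()$weighted5
  fit <- fit_cox(d, "z")
  beta <- coef(fit)
  manual <- vapply(fit$baseline$time, function(t) {
    at <- d$start < t & d$stop >= t
    sum(d$weight[d$event == 1 & d$stop == t]) /
      sum(d$weight[at] * exp(beta * d$z[at]))
  }, numeric(1))
  expect_equal(fit$baseline$hazard, unname(manual), tolerance = 1e-10)
})

test_that("integer weights are equivalent to row replication", {
  d <- cox_fixtures()$toy6
  d$weight <- c(2, 1, 3, 1, 2, 1)
  rep_rows <- d[rep(seq_len(nrow(d)), d$weight), ]
  rep_rows$weight <- 1
  f1 <- fit_cox(d, "z")
  f2 <- fit_cox(rep_rows, "z")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$baseline$hazard, f2$baseline$hazard, tolerance = 1e-8)
})

test_that("delayed entry changes risk sets exactly as it should", {
  d <- cox_fixtures()$toy6
  ## explicit zero truncation is a no-op
  d0 <- d; d0$start <- 0
  expect_equal(coef(fit_cox(d0, "z")), coef(fit_cox(d, "z")))
  ## entering everyone else after the first event leaves that event alone
  ## in its risk set; its likelihood term becomes constant, so the fit
  ## equals the fit on the remaining subjects
  d8 <- cox_fixtures()$two_cov8
  dt <- d8; dt$start[-1] <- 0.7          # between the 1st and 2nd event times
  f_trunc <- fit_cox(dt, c("z1", "z2"))
  f_drop <- fit_cox(d8[-1, ], c("z1", "z2"))
  expect_equal(coef(f_trunc), coef(f_drop), tolerance = 1e-6)
})

test_that("true effects are recovered with nominal interval coverage", {
  ## exponential baseline, two covariates with log-HRs (0.7, -0.3)
  truth <- c(0.7, -0.3)
  reps <- 200; n <- 500
  est <- se <- matrix(NA_real_, reps, 2)
  set.seed(90)
  for (r in seq_len(reps)) {
    z1 <- rbinom(n, 1, 0.5); z2 <- rnorm(n)
    t_ev <- rexp(n, rate = 0.1 * exp(truth[1] * z1 + truth[2] * z2))
    cens <- runif(n, 0, 20)
    d <- data.frame(start = 0, stop = pmin(t_ev, cens),
                    event = as.integer(t_ev <= cens), z1 = z1, z2 = z2)
    f <- fit_cox(d, c("z1", "z2"))
    est[r, ] <- coef(f); se[r, ] <- sqrt(diag(vcov(f)))
  }
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - truth[1]), 3 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - truth[2]), 3 * mc_se[2])
  cover <- (est - 1.96 * se <= rep(truth, each = reps)) &
    (est + 1.96 * se >= rep(truth, each = reps))
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.97)
})
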