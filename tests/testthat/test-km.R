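test_that("product-limit estimator and median behave on hand cases", {
  ## single subject, event at 5
  expect_equal(km_median(km_curve(5, 1)), 5)
  ## four subjects, all events: S = 3/4, 1/2, 1/4, 0
  cv <- km_curve(1:4, rep(1, 4))
  expect_equal(cv$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km_at(cv, 2), 0.5)
  expect_equal(km_median(cv), 2)
  ## right-continuity and S(0) = 1
  expect_equal(km_at(cv, c(0, 0.99, 1)), c(1, 1, 0.75))
  ## censoring shrinks the risk set but not the curve support
  cv2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(cv2$surv, c(2 / 3, 2 / 3 * 0))
  ## curve that never reaches 0.5 has no median
  expect_true(is.na(km_median(km_curve(c(1, 2, 3), c(1, 0, 0)))))
})

test_that("weighted curve matches replication and survfit", {
  skip_if_not_installed("survival")
  t <- c(1, 2, 2, 3, 4, 6); e <- c(1, 1, 0, 1, 0, 1); w <- c(2, 1, 1, 3, 1, 2)
  cv <- km_curve(t, e, w)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1, weights = w)
  expect_equal(cv$surv, sf$surv[sf$n.event > 0], tolerance = 1e-10)
  cvr <- km_curve(rep(t, w), rep(e, w))
  expect_equal(cv$surv, cvr$surv, tolerance = 1e-10)
})

test_that("log-rank statistic matches the direct O-E tabulation", {
  expect_error(logrank_test(1:3, c(1, 1, 0), rep("a", 3)),
               class = "adlsurv_schema_error")
  ## identical groups: observed equals expected
  t <- c(1, 2, 3, 4); e <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0)
  ## 4 vs 4 with no ties, risk sets tabulated by hand:
  ## events at 1(a; Y=8, Ya=4), 2(b; 7, 3), 4(a; 6, 3), 5(b; 5, 2), 7(a; 4, 2)
  ta <- c(1, 4, 7, 9); tb <- c(2, 5, 8, 10)
  ea <- c(1, 1, 1, 0); eb <- c(1, 1, 0, 0)
  lr <- logrank_test(c(ta, tb), c(ea, eb), rep(c("a", "b"), each = 4))
  e_a <- 4 / 8 + 3 / 7 + 3 / 6 + 2 / 5 + 2 / 4
  v <- (4 / 8) * (4 / 8) + (3 / 7) * (4 / 7) + (3 / 6) * (3 / 6) +
    (2 / 5) * (3 / 5) + (2 / 4) * (2 / 4)
  expect_equal(lr$observed[1], 3)
  expect_equal(lr$expected[1], e_a)
  expect_equal(lr$chisq, (3 - e_a)^2 / v)
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(c(ta, tb), c(ea, eb)) ~
                             rep(c("a", "b"), each = 4))
  expect_equal(lr$chisq, unname(sd$chisq), tolerance = 1e-10)
})

test_that("descriptive table flags true group differences and no false ones", {
  ## two identical halves except the grouping score: every test is null
  n <- 60
  base <- data.frame(
    patient_id = sprintf("x%02d", 1:n),
    age = rep(c(70, 80), n / 2), sex = rep(c("female", "male"), n / 2),
    race = "white", education = 12,
    marital = rep(c("married", "not_married"), n / 2), cvde = FALSE,
    symptom_duration = 3, mmse0 = rep(c(18, 22), n / 2),
    psms0 = rep(c(6, 8), each = n / 2), stringsAsFactors = FALSE)
  visits <- data.frame(patient_id = base$patient_id, visit_time = 1,
                       psms = base$psms0, stringsAsFactors = FALSE)
  outc <- data.frame(patient_id = base$patient_id,
                     followup_end = rep(c(2, 5), n / 2),
                     status = rep(c("dead", "censored_admin"), n / 2),
                     stringsAsFactors = FALSE)
  ch <- adl_cohort(base, visits, outc)
  tab <- describe_groups(ch)
  num_rows <- c("Age at baseline", "Formal education", "Symptom duration",
                "MMSE score at baseline")
  expect_true(all(abs(tab$statistic[tab$characteristic %in% num_rows]) < 1e-8))
  expect_lt(abs(tab$statistic[tab$characteristic == "Female, n (%)"]), 1e-8)

  ## injected mean age difference is reported at its true size
  sc <- study_scenario(n = 1200)
  sim <- simulate_cohort(sc, seed = 33)
  ch2 <- sim$cohort
  shift <- 4.4
  imp <- ch2$baseline$psms0 >= 7
  ch2$baseline$age <- ifelse(imp, ch2$baseline$age + shift / 2,
                             ch2$baseline$age - shift / 2)
  z <- covariate_matrix(ch2)
  diff_hat <- mean(z[imp, "age"]) - mean(z[!imp, "age"])
  mc <- sqrt(var(z[imp, "age"]) / sum(imp) + var(z[!imp, "age"]) / sum(!imp))
  expect_lt(abs(diff_hat - shift), 3 * mc)
  tab2 <- describe_groups(ch2)
  expect_lt(tab2$p[tab2$characteristic == "Age at baseline"], 0.001)
})

test_that("death-count contrast of the study's size is overwhelming", {
  ## groups with 165/458 vs 312/571 deaths: chi-square p far below 1e-4
  n1 <- 458; n2 <- 571
  base <- data.frame(
    patient_id = sprintf("p%04d", 1:(n1 + n2)),
    age = 75, sex = "female", race = "white", education = 12,
    marital = "married", cvde = FALSE, symptom_duration = 3, mmse0 = 20,
    psms0 = rep(c(6, 8), c(n1, n2)), stringsAsFactors = FALSE)
  dead <- c(rep(c(TRUE, FALSE), c(165, n1 - 165)),
            rep(c(TRUE, FALSE), c(312, n2 - 312)))
  outc <- data.frame(patient_id = base$patient_id,
                     followup_end = ifelse(dead, 4, 8),
                     status = ifelse(dead, "dead", "censored_admin"),
                     stringsAsFactors = FALSE)
  visits <- data.frame(patient_id = base$patient_id, visit_time = 1,
                       psms = base$psms0, stringsAsFactors = FALSE)
  ch <- adl_cohort(base, visits, outc)
  tab <- describe_groups(ch)
  expect_lt(tab$p[tab$characteristic == "Death, n (%)"], 1e-4)
  expect_lt(tab$p[tab$characteristic ==
                    "Median survival from initial visit (years)"], 1e-4)
})
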