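# Independent oracles, written naively on purpose: direct loops over event
# times and risk-set membership, never sharing code with the package's
# sorted/cumulative-sum engine.

# Breslow weighted partial log-likelihood by brute-force risk-set loops
naive_cox_loglik <- function(beta, data, covariates) {
  z <- as.matrix(data[covariates])
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  eta <- drop(z %*% beta)
  ll <- 0
  for (t in sort(unique(data$stop[data$event == 1]))) {
    at_risk <- data$start < t & data$stop >= t
    evs <- which(data$event == 1 & data$stop == t)
    ll <- ll + sum(w[evs] * eta[evs]) -
      sum(w[evs]) * log(sum(w[at_risk] * exp(eta[at_risk])))
  }
  ll
}

# grid + golden-section / Nelder-Mead maximiser of the naive likelihood
brute_force_beta <- function(data, covariates) {
  p <- length(covariates)
  if (p == 1) {
    opt <- stats::optimize(function(b) naive_cox_loglik(b, data, covariates),
                           interval = c(-5, 5), maximum = TRUE, tol = 1e-9)
    setNames(opt$maximum, covariates)
  } else {
    grid <- as.matrix(expand.grid(rep(list(seq(-3, 3, by = 0.5)), p)))
    lls <- apply(grid, 1, naive_cox_loglik, data = data, covariates = covariates)
    start <- grid[which.max(lls), ]
    opt <- stats::optim(start, function(b) -naive_cox_loglik(b, data, covariates),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    setNames(opt$par, covariates)
  }
}

# Nelson-Aalen estimator by direct counting (unit hazard increments d/n)
naive_nelson_aalen <- function(data) {
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  et <- sort(unique(data$stop[data$event == 1]))
  inc <- vapply(et, function(t) {
    sum(w[data$event == 1 & data$stop == t]) /
      sum(w[data$start < t & data$stop >= t])
  }, numeric(1))
  data.frame(time = et, hazard = inc)
}

# small counting-process fixtures (<= 10 subjects each)
cox_fixtures <- function() {
  list(
    toy6 = data.frame(start = 0, stop = 1:6, event = c(1, 1, 0, 1, 0, 1),
                      z = c(1, 0, 1, 0, 1, 0)),
    weighted5 = data.frame(start = 0, stop = c(1, 2, 3, 4, 5),
                           event = c(1, 0, 1, 1, 0),
                           z = c(0.5, -1, 2, 0, 1),
                           weight = c(1, 2, 1.5, 1, 3)),
    delayed7 = data.frame(start = c(0, 0, 0.5, 1, 1.5, 0, 2),
                          stop = c(1, 2, 2.5, 3, 4, 5, 6),
                          event = c(1, 0, 1, 1, 0, 1, 1),
                          z = c(1, 1, 0, 0, 1, 0, 1)),
    two_cov8 = data.frame(start = 0,
                          stop = c(0.5, 1, 1.5, 2, 3, 4, 5, 6),
                          event = c(1, 1, 0, 1, 1, 0, 1, 0),
                          z1 = c(1, 0, 1, 0, 1, 0, 1, 0),
                          z2 = c(0.2, -0.5, 1, 0.7, -1, 0.3, 0, 1.2))
  )
}

fixture_covariates <- function(d) setdiff(names(d), c("start", "stop", "event", "weight"))

# three-patient cohort used across the I/O and validation tests
tiny_cohort <- function() {
  adl_cohort(
    baseline = data.frame(
      patient_id = c("A", "B", "C"),
      age = c(70.5, 80, 75), sex = c("female", "male", "female"),
      race = c("white", "white", "nonwhite"),
      education = c(12, 16, 10.5),
      marital = c("married", "not_married", "married"),
      cvde = c(TRUE, FALSE, TRUE),
      symptom_duration = c(3, 5.25, 2),
      mmse0 = c(22, 15, 19), psms0 = c(6, 9, 6),
      stringsAsFactors = FALSE),
    visits = data.frame(
      patient_id = c("A", "A", "B", "C", "C"),
      visit_time = c(1, 2.1, 1.05, 0.9, 2),
      psms = c(6, 8, 10, 6, 6),
      mmse = c(20, 18, NA, 19, 17),
      stringsAsFactors = FALSE),
    outcomes = data.frame(
      patient_id = c("A", "B", "C"),
      followup_end = c(3.5, 1.5, 2),
      status = c("dead", "lost", "censored_admin"),
      stringsAsFactors = FALSE)
  )
}
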