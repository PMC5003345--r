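## Cohort simulator with proportional-hazards illness-death transitions,
## annual-visit observation of PSMS and covariate-dependent dropout.
##
## Latent event times are drawn from Weibull proportional-hazards
## intensities on the years-since-baseline clock (post-onset death uses the
## same forward clock, matching the Markov assumption of the estimator).
## PSMS trajectories are constructed so that a patient's score first meets
## both impairment definitions at the first visit at or after the latent
## onset; deaths before that visit therefore leave the onset unobserved,
## exactly as in an annually assessed clinic cohort.

#' Specify a simulation scenario
#'
#' All parameters of the data-generating process: covariate laws with
#' memory-clinic AD marginals, Weibull baselines and true log-hazard-ratio
#' vectors for the three transitions, the annual visit schedule, the
#' loss-to-follow-up model and administrative censoring. Transition
#' intensities are \eqn{h_k(t) = h_{0k}(t) \exp\{\beta_k'(z - z_{ref})\}}
#' with \eqn{h_{0k}} Weibull (`shape`, `scale`; shape 1 = constant) and
#' \eqn{z_{ref}} the covariate means, so the baselines are those of the
#' average patient. Dropout is a Bernoulli draw per patient on the logistic
#' scale (coefficients on centred covariates); a lost patient's loss time
#' is uniform over their administrative follow-up.
#'
#' @param n number of patients.
#' @param beta_I,beta_D1,beta_D2 named true log-hazard-ratio vectors
#'   (any subset of `age, sex, race, education, mmse0, symptom_duration,
#'   marital, cvde`; unnamed covariates have effect 0).
#' @param impairment,death_intact,death_impaired lists `list(shape, scale)`
#'   for the Weibull transition baselines.
#' @param covariate_laws list of marginal parameters; see defaults.
#' @param visit_interval,visit_jitter_sd annual reassessment schedule
#'   (years); jitter is a per-visit normal perturbation.
#' @param dropout named logistic coefficients, first element the intercept,
#'   the rest on centred covariates; `NULL` or intercept `-Inf` disables
#'   dropout.
#' @param admin_censor administrative censoring: a scalar time or a
#'   `c(lo, hi)` range for per-patient uniform entry staggering.
#' @param psms_drift annual PSMS increase for baseline-impaired patients
#'   (default 0: their score stays at its baseline value).
#' @return object of class `sim_scenario`.
#' @seealso [study_scenario()], [simulate_cohort()]
#' @export
sim_scenario <- function(n = 1000,
                         beta_I = c(age = 0), beta_D1 = c(age = 0),
                         beta_D2 = c(age = 0),
                         impairment = list(shape = 1, scale = 1 / 0.12),
                         death_intact = list(shape = 1, scale = 1 / 0.045),
                         death_impaired = list(shape = 1, scale = 1 / 0.13),
                         covariate_laws = list(
                           age_mean = 75.1, age_sd = 8.3, age_range = c(39, 97),
                           educ_mean = 13.6, educ_sd = 3.6,
                           mmse_mean = 19.0, mmse_sd = 7.0,
                           sympdur_mean = 3.9, sympdur_sd = 2.3,
                           sex_male_p = 0.312, race_nonwhite_p = 0.091,
                           marital_notmar_p = 0.392, cvde_p = 0.622,
                           psms0_intact_p = 0.445, psms0_pois_lambda = 3.5),
                         visit_interval = 1, visit_jitter_sd = 0.15,
                         dropout = NULL, admin_censor = c(2, 16),
                         psms_drift = 0) {
  full <- function(b) {
    out <- stats::setNames(rep(0, length(.adl_covariates)), .adl_covariates)
    bad <- setdiff(names(b), .adl_covariates)
    if (length(bad))
      stop_adl("adlsurv_schema_error", "unknown covariate(s) in beta: %s",
               paste(sQuote(bad), collapse = ", "))
    out[names(b)] <- b
    out
  }
  for (tr in list(impairment, death_intact, death_impaired))
    if (tr$shape <= 0 || tr$scale <= 0)
      stop_adl("adlsurv_schema_error", "Weibull shape and scale must be > 0")
  if (length(admin_censor) == 1) admin_censor <- rep(admin_censor, 2)
  structure(list(
    n = n, beta_I = full(beta_I), beta_D1 = full(beta_D1),
    beta_D2 = full(beta_D2),
    impairment = impairment, death_intact = death_intact,
    death_impaired = death_impaired,
    covariate_laws = covariate_laws,
    visit_interval = visit_interval, visit_jitter_sd = visit_jitter_sd,
    dropout = dropout, admin_censor = admin_censor,
    psms_drift = psms_drift
  ), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> n = %d, admin censor U(%g, %g), dropout %s\n",
              x$n, x$admin_censor[1], x$admin_censor[2],
              if (is.null(x$dropout)) "off" else "on"))
  invisible(x)
}

#' Reference covariate profile (means) of a scenario
#' @param scenario a [sim_scenario()].
#' @return named numeric vector on the model coding.
#' @export
scenario_reference <- function(scenario) {
  cl <- scenario$covariate_laws
  ## mean baseline PSMS is not a model covariate; reference uses the laws'
  ## location parameters (truncation shifts them only slightly)
  c(age = cl$age_mean, sex = cl$sex_male_p, race = cl$race_nonwhite_p,
    education = cl$educ_mean, mmse0 = cl$mmse_mean,
    symptom_duration = cl$sympdur_mean, marital = cl$marital_notmar_p,
    cvde = cl$cvde_p)
}

#' Study-like scenario
#'
#' Preset scenario emulating a memory-clinic AD cohort: covariate marginals
#' of a 1029-patient clinic population (age 75.1 +/- 8.3, education
#' 13.6 +/- 3.6, baseline MMSE 19.0 +/- 7.0, symptom duration 3.9 +/- 2.3,
#' 31% male, 9% nonwhite, 39% not married, 62% CVDE, 44.5% intact at
#' baseline), exponential transition baselines giving a post-impairment
#' median survival near 5 years and an overall death fraction near one
#' half under staggered administrative censoring, mild covariate-dependent
#' loss to follow-up, and true transition log-hazard-ratios in the range
#' such cohorts report (strong male effect on death, protective MMSE and
#' education, modest age effects). Continuous-covariate effects are shared
#' between the two death transitions; see the package vignette for why.
#'
#' @param n number of patients (default 1029).
#' @return a [sim_scenario()].
#' @export
study_scenario <- function(n = 1029) {
  sim_scenario(
    n = n,
    beta_I  = c(age = 0.012, education = 0.015, mmse0 = -0.06,
                race = 0.05, cvde = 0.07, marital = -0.05),
    beta_D1 = c(age = 0.03, sex = 0.60, race = 0.10, education = -0.03,
                mmse0 = -0.055, symptom_duration = 0.01, marital = -0.05,
                cvde = 0.10),
    beta_D2 = c(age = 0.03, sex = 0.65, race = 0.10, education = -0.03,
                mmse0 = -0.055, symptom_duration = 0.01, marital = 0.15,
                cvde = 0.10),
    impairment     = list(shape = 1, scale = 1 / 0.12),
    death_intact   = list(shape = 1, scale = 1 / 0.045),
    death_impaired = list(shape = 1, scale = 1 / 0.13),
    dropout = c(`(Intercept)` = -1.45, age = 0.03),
    admin_censor = c(1.5, 14)
  )
}

## inverse cumulative hazard of Weibull PH given H(T) = u (u = E * e^-lp)
.weib_inv <- function(u, shape, scale) scale * u^(1 / shape)
.weib_H <- function(t, shape, scale) (t / scale)^shape

## deterministic per-patient seed below 2^31, keyed by (seed, patient index)
.patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 8191 + 1) %% 2147483647)
}

.rtrunc_norm <- function(mean, sd, lo = -Inf, hi = Inf) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Simulate a cohort with ground truth
#'
#' Draws one patient at a time from an independent random stream keyed by
#' `(seed, patient index)`, so the same seed always yields the identical
#' cohort and per-patient draws do not depend on order or on `n`. Returns
#' the observed cohort (what the clinic would record: baseline covariates,
#' annual PSMS visits, one outcome row) together with the latent ground
#' truth (true onset and death times, transition of death, true
#' parameters) for validating estimators.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer master seed.
#' @return list with elements `cohort` (an [adl_cohort()]) and `truth`
#'   (list: `patients` data frame with latent times, `scenario`,
#'   `warnings`).
#' @examples
#' sim <- simulate_cohort(study_scenario(n = 200), seed = 42)
#' sim$cohort
#' @export
simulate_cohort <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  cl <- scenario$covariate_laws
  ref <- scenario_reference(scenario)
  n <- scenario$n
  adm <- scenario$admin_censor

  ## preallocated columns (per-patient data.frame construction is far too
  ## slow for repeated-simulation studies)
  pid_all <- sprintf("P%05d", seq_len(n))
  num <- function() numeric(n)
  B <- list(age = num(), education = num(), mmse0 = num(), sympdur = num(),
            sex = character(n), race = character(n), marital = character(n),
            cvde = logical(n), psms0 = integer(n))
  O <- list(end = num(), status = character(n))
  TR <- list(bimp = logical(n), latent_onset = num(), latent_death = num(),
             cause = character(n), p_lost = num(), admin = num(),
             lost = logical(n))
  vis_pid <- vector("list", n); vis_t <- vector("list", n)
  vis_psms <- vector("list", n)

  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)

  for (i in seq_len(n)) {
    set.seed(.patient_seed(seed, i))
    pid <- pid_all[i]

    age <- .rtrunc_norm(cl$age_mean, cl$age_sd, cl$age_range[1], cl$age_range[2])
    education <- .rtrunc_norm(cl$educ_mean, cl$educ_sd, 0, Inf)
    mmse0 <- round(.rtrunc_norm(cl$mmse_mean, cl$mmse_sd, 0, 30))
    sympdur <- stats::rgamma(1, shape = (cl$sympdur_mean / cl$sympdur_sd)^2,
                             rate = cl$sympdur_mean / cl$sympdur_sd^2)
    sex <- if (stats::runif(1) < cl$sex_male_p) "male" else "female"
    race <- if (stats::runif(1) < cl$race_nonwhite_p) "nonwhite" else "white"
    marital <- if (stats::runif(1) < cl$marital_notmar_p) "not_married" else "married"
    cvde <- stats::runif(1) < cl$cvde_p
    psms0 <- if (stats::runif(1) < cl$psms0_intact_p) 6L
             else min(7L + stats::rpois(1, cl$psms0_pois_lambda), 30L)

    z <- c(age = age, sex = as.numeric(sex == "male"),
           race = as.numeric(race == "nonwhite"), education = education,
           mmse0 = mmse0, symptom_duration = sympdur,
           marital = as.numeric(marital == "not_married"),
           cvde = as.numeric(cvde))
    zc <- z - ref
    bimp <- psms0 >= 7

    lp_I <- sum(scenario$beta_I * zc)
    lp_D1 <- sum(scenario$beta_D1 * zc)
    lp_D2 <- sum(scenario$beta_D2 * zc)

    if (bimp) {
      T_onset <- 0
      T_death <- .weib_inv(stats::rexp(1) * exp(-lp_D2),
                           scenario$death_impaired$shape,
                           scenario$death_impaired$scale)
      cause <- "impaired"
    } else {
      T_I <- .weib_inv(stats::rexp(1) * exp(-lp_I),
                       scenario$impairment$shape, scenario$impairment$scale)
      T_D1 <- .weib_inv(stats::rexp(1) * exp(-lp_D1),
                        scenario$death_intact$shape, scenario$death_intact$scale)
      if (T_D1 <= T_I) {
        T_onset <- NA_real_
        T_death <- T_D1
        cause <- "intact"
      } else {
        T_onset <- T_I
        sh <- scenario$death_impaired$shape; sc <- scenario$death_impaired$scale
        ## forward-clock post-onset death, conditional on survival to T_I
        T_death <- sc * (.weib_H(T_I, sh, sc) +
                           stats::rexp(1) * exp(-lp_D2))^(1 / sh)
        cause <- "impaired"
      }
    }

    A <- stats::runif(1, adm[1], adm[2])
    p_lost <- 0
    L <- Inf
    if (!is.null(scenario$dropout)) {
      p_lost <- stats::plogis(scenario$dropout[1] +
                                sum(scenario$dropout[-1] * zc[names(scenario$dropout)[-1]]))
      if (stats::runif(1) < p_lost) L <- stats::runif(1, 0, A)
    }
    end <- min(T_death, L, A)
    status <- if (T_death <= end) "dead" else if (L <= A) "lost" else "censored_admin"
    end <- min(T_death, L, A)

    ## annual visits with jitter, strictly increasing, while under observation
    vt <- numeric(0)
    tprev <- 0
    j <- 1L
    repeat {
      tj <- j * scenario$visit_interval +
        stats::rnorm(1, 0, scenario$visit_jitter_sd)
      tj <- max(tj, tprev + 0.02)
      if (tj >= end) break
      vt <- c(vt, tj)
      tprev <- tj
      j <- j + 1L
      if (j > 1000L) break
    }

    if (length(vt)) {
      if (bimp) {
        psms <- pmin(psms0 + floor(scenario$psms_drift * vt), 30)
      } else if (!is.na(T_onset)) {
        ## first visit at/after the latent onset reveals impairment: the
        ## score meets both definitions there (>= 7 and >= baseline + 2)
        post <- vt >= T_onset
        psms <- ifelse(post, pmin(max(psms0 + 2, 7) + pmax(cumsum(post) - 1, 0), 30),
                       psms0)
      } else {
        psms <- rep(psms0, length(vt))
      }
      vis_pid[[i]] <- rep(pid, length(vt))
      vis_t[[i]] <- vt
      vis_psms[[i]] <- as.integer(round(psms))
    }

    B$age[i] <- age; B$education[i] <- education; B$mmse0[i] <- mmse0
    B$sympdur[i] <- sympdur; B$sex[i] <- sex; B$race[i] <- race
    B$marital[i] <- marital; B$cvde[i] <- cvde; B$psms0[i] <- psms0
    O$end[i] <- end; O$status[i] <- status
    TR$bimp[i] <- bimp
    TR$latent_onset[i] <- if (bimp) 0 else T_onset
    TR$latent_death[i] <- T_death; TR$cause[i] <- cause
    TR$p_lost[i] <- p_lost; TR$admin[i] <- A; TR$lost[i] <- is.finite(L)
  }

  baseline <- data.frame(
    patient_id = pid_all, age = B$age, sex = B$sex, race = B$race,
    education = B$education, marital = B$marital, cvde = B$cvde,
    symptom_duration = B$sympdur, mmse0 = B$mmse0, psms0 = B$psms0,
    stringsAsFactors = FALSE)
  vp <- unlist(vis_pid) %||% character(0)
  visits <- data.frame(
    patient_id = vp,
    visit_time = unlist(vis_t) %||% numeric(0),
    psms = unlist(vis_psms) %||% integer(0),
    mmse = rep(NA_real_, length(vp)), stringsAsFactors = FALSE)
  outcomes <- data.frame(patient_id = pid_all, followup_end = O$end,
                         status = O$status, stringsAsFactors = FALSE)
  cohort <- adl_cohort(baseline, visits, outcomes, validate = FALSE)

  truth_patients <- data.frame(
    patient_id = pid_all, baseline_impaired = TR$bimp,
    latent_onset = TR$latent_onset, latent_death = TR$latent_death,
    death_transition = TR$cause, p_lost = TR$p_lost, admin_time = TR$admin,
    lost = TR$lost, stringsAsFactors = FALSE)
  truth <- list(patients = truth_patients, scenario = scenario,
                seed = seed, warnings = character(0))
  if (!any(outcomes$status == "dead"))
    truth$warnings <- "scenario produced zero deaths at this n"
  list(cohort = cohort, truth = truth)
}

## save/restore the global RNG state so simulation does not disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
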