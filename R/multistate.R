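## Three-state illness-death model for basic ADL impairment and death.
##
##      intact basic ADL --- h_I(t) ---> impaired basic ADL
##             |                                |
##          h_D1(t)                          h_D2(t)
##             v                                v
##           death                            death
##
## All three transition intensities are Cox proportional-hazards models on
## the same baseline covariates and on the same clock (years since the
## initial visit; Markov assumption). The impairment and pre-impairment
## death models share the intact risk set: onset censors h_D1 and death
## censors h_I. Patients enter the post-impairment death model's risk set
## only at their onset (delayed entry / left truncation); patients already
## impaired at baseline (absolute PSMS definition) enter it at time 0.

.build_transition_rows <- function(cohort, definition, covariates, weights,
                                   convention) {
  on <- cohort_onsets(cohort, definition, convention)
  b <- cohort$baseline; o <- cohort$outcomes
  m <- match(b$patient_id, o$patient_id)
  end <- o$followup_end[m]
  dead <- o$status[m] == "dead"
  z <- covariate_matrix(cohort, covariates)
  w <- if (is.null(weights)) stats::setNames(rep(1, nrow(b)), b$patient_id)
       else weights
  onset <- on$onset_time
  bimp <- on$baseline_impaired
  ## a qualifying visit at the very end of follow-up gives an impairment
  ## event but no post-impairment exposure; deaths at that instant count as
  ## pre-impairment (events precede the state change on ties)
  has_onset <- !bimp & !is.na(onset) & onset > 0
  texit <- ifelse(has_onset, pmin(onset, end), end)

  intact <- !bimp & end > 0
  mkrows <- function(keep, start, stop, event) {
    data.frame(patient_id = b$patient_id[keep],
               start = start[keep], stop = stop[keep],
               event = as.integer(event[keep]),
               z[keep, , drop = FALSE],
               weight = as.numeric(w[b$patient_id[keep]]),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  rows_I  <- mkrows(intact, rep(0, nrow(b)), texit, has_onset)
  rows_D1 <- mkrows(intact, rep(0, nrow(b)), texit,
                    dead & !(has_onset & onset < end))
  keep2 <- (bimp & end > 0) | (has_onset & onset < end)
  start2 <- ifelse(bimp, 0, onset)
  rows_D2 <- mkrows(keep2, start2, end, dead)
  list(impairment = rows_I, death_intact = rows_D1, death_impaired = rows_D2,
       onsets = on)
}

#' Fit the three-state illness-death model
#'
#' Fits the three transition-specific Cox models of the illness-death
#' process for basic ADL impairment: time to impairment (`impairment`,
#' deaths censor), time to death while still intact (`death_intact`,
#' impairment censors), and time to death after impairment
#' (`death_impaired`, with delayed entry at the onset; patients impaired at
#' baseline under the absolute definition enter at time 0). All models
#' share the baseline covariates and the years-since-baseline clock and are
#' fitted by [fit_cox()]; optional IPCW weights apply to all three.
#'
#' When a transition cannot be estimated (e.g. nobody becomes impaired, so
#' the impairment and post-impairment models have no events), the fit is
#' partial: the failing transitions hold the error condition instead of a
#' `coxfit`, and methods that need them say so.
#'
#' @param cohort an [adl_cohort()].
#' @param definition `"psms_ge7"` (PSMS > 6 at a post-baseline visit;
#'   baseline scores > 6 are impaired from entry) or `"delta_ge2"`
#'   (an increase of >= 2 points over the patient's own baseline).
#' @param weights optional named per-patient weights, e.g. from
#'   [cohort_ipcw()].
#' @param covariates baseline covariates (default the study's eight:
#'   age, sex, race, education, baseline MMSE, symptom duration, marital
#'   status, CVDE).
#' @param ties,tol,max_iter passed to [fit_cox()].
#' @param convention onset dating convention, see [adl_onset()].
#' @return object of class `illness_death`: list with `fits` (the three
#'   `coxfit`s or error conditions), `rows` (the three counting-process
#'   row sets), `events` (per-transition event counts), `onsets`,
#'   `definition`, `covariates`, `weighted`, `n`.
#' @examples
#' sim <- simulate_cohort(study_scenario(n = 300), seed = 1)
#' ms <- illness_death(sim$cohort, "psms_ge7")
#' ms
#' @export
illness_death <- function(cohort, definition = c("psms_ge7", "delta_ge2"),
                          weights = NULL, covariates = .adl_covariates,
                          ties = c("breslow", "efron"), tol = 1e-9,
                          max_iter = 50L, convention = c("visit", "midpoint")) {
  definition <- match.arg(definition)
  ties <- match.arg(ties)
  convention <- match.arg(convention)
  parts <- .build_transition_rows(cohort, definition, covariates, weights,
                                  convention)
  fit_one <- function(nm) {
    rows <- parts[[nm]]
    if (!nrow(rows) || sum(rows$event) == 0)
      return(structure(
        class = c("adlsurv_estimation_error", "adlsurv_error", "error", "condition"),
        list(message = sprintf("transition '%s' is empty: no %s observed", nm,
                               if (nm == "impairment") "impairment onsets" else "deaths"),
             call = NULL)))
    tryCatch(fit_cox(rows, covariates, ties = ties, tol = tol,
                     max_iter = max_iter),
             error = function(e) e)
  }
  fits <- list(impairment = fit_one("impairment"),
               death_intact = fit_one("death_intact"),
               death_impaired = fit_one("death_impaired"))
  events <- vapply(c("impairment", "death_intact", "death_impaired"),
                   function(nm) sum(parts[[nm]]$event), numeric(1))
  structure(list(
    fits = fits,
    rows = parts[c("impairment", "death_intact", "death_impaired")],
    events = events, onsets = parts$onsets,
    definition = definition, covariates = covariates,
    weighted = !is.null(weights), ties = ties, convention = convention,
    n = nrow(cohort$baseline), call = match.call()
  ), class = "illness_death")
}

.transition_fit <- function(object, transition) {
  f <- object$fits[[transition]]
  if (inherits(f, "condition"))
    stop_adl("adlsurv_estimation_error",
             "transition '%s' was not estimated: %s", transition,
             conditionMessage(f))
  f
}

#' @export
print.illness_death <- function(x, digits = 3, ...) {
  cat(sprintf("Illness-death model for basic ADL impairment (definition: %s%s)\n",
              x$definition, if (x$weighted) ", IPCW-weighted" else ""))
  cat(sprintf("  %d patients; events: %d impairment onsets, %d deaths while intact, %d deaths after impairment\n",
              x$n, x$events[["impairment"]], x$events[["death_intact"]],
              x$events[["death_impaired"]]))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    if (inherits(f, "condition")) {
      cat(sprintf("\n-- %s: NOT estimated (%s)\n", nm, conditionMessage(f)))
    } else {
      cat(sprintf("\n-- %s (hazard ratios):\n", nm))
      hr <- hazard_ratios(f)
      hr[-1] <- lapply(hr[-1], round, digits)
      print(hr)
    }
  }
  invisible(x)
}

#' @export
summary.illness_death <- function(object, ...) {
  out <- list(definition = object$definition, events = object$events,
              n = object$n, weighted = object$weighted,
              tables = lapply(object$fits, function(f)
                if (inherits(f, "condition")) conditionMessage(f)
                else hazard_ratios(f)))
  class(out) <- "summary.illness_death"
  out
}

#' @export
print.summary.illness_death <- function(x, digits = 3, ...) {
  cat(sprintf("Illness-death model (%s)%s: n = %d\n", x$definition,
              if (x$weighted) " [IPCW]" else "", x$n))
  for (nm in names(x$tables)) {
    cat(sprintf("\n-- %s:\n", nm))
    tb <- x$tables[[nm]]
    if (is.character(tb)) cat("  ", tb, "\n") else {
      tb[-1] <- lapply(tb[-1], round, digits)
      print(tb)
    }
  }
  invisible(x)
}

#' @export
coef.illness_death <- function(object, ...) {
  p <- length(object$covariates)
  out <- matrix(NA_real_, 3, p,
                dimnames = list(names(object$fits), object$covariates))
  for (nm in names(object$fits))
    if (!inherits(object$fits[[nm]], "condition"))
      out[nm, ] <- object$fits[[nm]]$coefficients
  out
}

#' Covariate profile for prediction
#'
#' Builds the "average patient" covariate profile used for predicted
#' death-probability curves: age 75.1 years, 13.6 years of education and a
#' baseline MMSE of 19 by default (a memory-clinic AD cohort average), with
#' the remaining covariates set by a policy — modal category for the binary
#' ones and the mean for symptom duration, taken from a cohort when one is
#' supplied, otherwise reference categories (white, married, no CVDE) and
#' 3.9 years of symptoms. Any value can be overridden.
#'
#' @param sex `"male"` or `"female"`.
#' @param cohort optional [adl_cohort()] from which to take the policy
#'   values.
#' @param age,education,mmse0,symptom_duration,race,marital,cvde numeric
#'   covariate values on the model coding (race: 1 = nonwhite; marital:
#'   1 = not married; cvde: 1 = yes).
#' @return named numeric vector with attribute `policy` describing how the
#'   unstated covariates were set.
#' @export
adl_profile <- function(sex = c("female", "male"), cohort = NULL,
                        age = 75.1, education = 13.6, mmse0 = 19.0,
                        symptom_duration = NULL, race = NULL, marital = NULL,
                        cvde = NULL) {
  sex <- match.arg(sex)
  pol <- if (is.null(cohort)) "reference" else "cohort_modal_mean"
  mode01 <- function(x) as.numeric(mean(x) > 0.5)
  if (!is.null(cohort)) {
    z <- covariate_matrix(cohort)
    race <- race %||% mode01(z[, "race"])
    marital <- marital %||% mode01(z[, "marital"])
    cvde <- cvde %||% mode01(z[, "cvde"])
    symptom_duration <- symptom_duration %||% mean(z[, "symptom_duration"])
  } else {
    race <- race %||% 0; marital <- marital %||% 0; cvde <- cvde %||% 0
    symptom_duration <- symptom_duration %||% 3.9
  }
  out <- c(age = age, sex = as.numeric(sex == "male"), race = race,
           education = education, mmse0 = mmse0,
           symptom_duration = symptom_duration, marital = marital, cvde = cvde)
  attr(out, "policy") <- pol
  out
}

#' Conditional probability of death for a covariate profile
#'
#' For a profile in a given state at the start of observation, returns
#' \eqn{F(t) = 1 - \exp\{-e^{\beta_k' z} H_{0k}(t)\}} on the requested time
#' grid, where k is the pre-impairment death transition for the intact
#' state and the post-impairment one for the impaired state, and
#' \eqn{H_{0k}} is that transition's Breslow cumulative baseline hazard.
#' The curve is non-decreasing, 0 at t = 0 and bounded by 1.
#'
#' @param object an [illness_death()] fit.
#' @param profile named covariate vector, e.g. from [adl_profile()].
#' @param state `"intact"` or `"impaired"` basic ADL at observation start.
#' @param times time grid (years since observation start).
#' @param ... unused.
#' @return numeric vector of death probabilities at `times`.
#' @export
predict.illness_death <- function(object, profile,
                                  state = c("intact", "impaired"),
                                  times = seq(0, 6, by = 0.1), ...) {
  state <- match.arg(state)
  fit <- .transition_fit(object,
                         if (state == "intact") "death_intact" else "death_impaired")
  miss <- setdiff(object$covariates, names(profile))
  if (length(miss))
    stop_adl("adlsurv_schema_error",
             "profile is missing covariate(s) %s",
             paste(sQuote(miss), collapse = ", "))
  lp <- sum(fit$coefficients * as.numeric(profile[object$covariates]))
  1 - exp(-exp(lp) * cumhaz_at(fit$baseline, times))
}

#' Predicted death-probability curves by sex and impairment state
#'
#' The four average-patient curves (sex x intact/impaired) over a horizon,
#' in long format suitable for CSV export or plotting.
#'
#' @param object an [illness_death()] fit.
#' @param horizon years (default 6).
#' @param by grid step in years.
#' @param cohort optional cohort for the profile policy (see
#'   [adl_profile()]).
#' @return data frame `sex`, `state`, `time`, `prob`, with attributes
#'   `definition` and `profile_policy`.
#' @export
death_probability_curves <- function(object, horizon = 6, by = 0.1,
                                     cohort = NULL) {
  times <- seq(0, horizon, by = by)
  grid <- expand.grid(sex = c("female", "male"),
                      state = c("intact", "impaired"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    pr <- adl_profile(grid$sex[i], cohort = cohort)
    data.frame(sex = grid$sex[i], state = grid$state[i], time = times,
               prob = predict(object, pr, state = grid$state[i], times = times),
               stringsAsFactors = FALSE)
  }))
  attr(out, "definition") <- object$definition
  attr(out, "profile_policy") <- if (is.null(cohort)) "reference" else "cohort_modal_mean"
  out
}

#' Plot predicted conditional death probabilities
#'
#' Draws the four average-patient curves: solid for intact, dashed for
#' impaired basic ADL at observation start; men in blue, women in red.
#'
#' @param x an [illness_death()] fit.
#' @param horizon,by,cohort passed to [death_probability_curves()].
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.illness_death <- function(x, horizon = 6, by = 0.1, cohort = NULL, ...) {
  cv <- death_probability_curves(x, horizon, by, cohort)
  graphics::plot(NULL, xlim = c(0, horizon), ylim = c(0, 1),
                 xlab = "Years of observation",
                 ylab = "Conditional probability of death",
                 main = sprintf("Illness-death prediction (%s)", x$definition),
                 ...)
  cols <- c(male = "blue", female = "red")
  ltys <- c(intact = 1, impaired = 2)
  for (sx in names(cols)) for (st in names(ltys)) {
    d <- cv[cv$sex == sx & cv$state == st, ]
    graphics::lines(d$time, d$prob, col = cols[[sx]], lty = ltys[[st]], lwd = 2)
  }
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = rep(cols, each = 2), lty = rep(ltys, 2),
                   legend = c("male intact", "male impaired",
                              "female intact", "female impaired"))
  invisible(cv)
}

#' Schoenfeld residuals for one transition of an illness-death fit
#' @param object an [illness_death()] fit.
#' @param transition one of `"impairment"`, `"death_intact"`,
#'   `"death_impaired"`.
#' @param ... unused.
#' @export
residuals.illness_death <- function(object,
                                    transition = c("impairment", "death_intact",
                                                   "death_impaired"), ...) {
  transition <- match.arg(transition)
  fit <- .transition_fit(object, transition)
  schoenfeld_ph_test(fit, object$rows[[transition]])$residuals
}
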