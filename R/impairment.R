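## Basic-ADL impairment detection from serial PSMS scores.
##
## Two complementary definitions of developing basic ADL impairment:
##   "psms_ge7"  -- a PSMS total score > 6 at a post-baseline visit
##                  (absolute definition; a baseline score > 6 means the
##                  patient is already impaired at entry),
##   "delta_ge2" -- an increase of >= 2 PSMS points relative to the
##                  patient's own baseline (relative definition; nobody is
##                  baseline-impaired by construction).

#' @export
adl_definitions <- function() c("psms_ge7", "delta_ge2")

match_definition <- function(definition) {
  match.arg(definition, adl_definitions())
}

#' Detect basic-ADL impairment onset from a PSMS trajectory
#'
#' Scans a patient's post-baseline PSMS scores for the first visit meeting
#' the chosen impairment definition. Under `"psms_ge7"` the patient is
#' baseline-impaired when `psms0 >= 7` and the onset time is then 0; under
#' `"delta_ge2"` impairment is always relative to the patient's own
#' baseline, so nobody is impaired at entry. By default onset is dated at
#' the first qualifying visit itself; `convention = "midpoint"` dates it at
#' the midpoint between that visit and the previous assessment, for
#' sensitivity analysis.
#'
#' @param visit_time,psms numeric vectors (sorted by time) of a patient's
#'   post-baseline visit times (years) and PSMS totals. May be empty (e.g.
#'   a patient who died before the first reassessment); onset is then
#'   unobserved and `NA`.
#' @param psms0 baseline PSMS total (6-30).
#' @param definition `"psms_ge7"` or `"delta_ge2"`.
#' @param convention `"visit"` (default) or `"midpoint"`.
#' @return list with `baseline_impaired` (logical) and `onset_time`
#'   (years, `NA` if impairment never observed).
#' @examples
#' adl_onset(c(1, 2), c(6, 8), psms0 = 6, definition = "psms_ge7")$onset_time  # 2
#' adl_onset(c(1, 2.1), c(7, 7), psms0 = 6, definition = "delta_ge2")$onset_time  # NA
#' @export
adl_onset <- function(visit_time, psms, psms0,
                      definition = c("psms_ge7", "delta_ge2"),
                      convention = c("visit", "midpoint")) {
  definition <- match.arg(definition)
  convention <- match.arg(convention)
  if (length(visit_time) != length(psms))
    stop_adl("adlsurv_schema_error", "visit_time and psms differ in length")
  if (is.unsorted(visit_time, strictly = TRUE))
    stop_adl("adlsurv_integrity_error", "visits must be sorted, strictly increasing")
  if (definition == "psms_ge7") {
    baseline_impaired <- psms0 >= 7
    hit <- which(psms >= 7)
  } else {
    baseline_impaired <- FALSE
    hit <- which(psms - psms0 >= 2)
  }
  if (definition == "psms_ge7" && baseline_impaired)
    return(list(baseline_impaired = TRUE, onset_time = 0))
  if (!length(hit))
    return(list(baseline_impaired = baseline_impaired, onset_time = NA_real_))
  k <- hit[1]
  onset <- if (convention == "visit") visit_time[k]
           else (visit_time[k] + if (k == 1) 0 else visit_time[k - 1]) / 2
  list(baseline_impaired = baseline_impaired, onset_time = onset)
}

#' Impairment onset for every patient in a cohort
#'
#' @param cohort an [adl_cohort()].
#' @inheritParams adl_onset
#' @return data frame with `patient_id`, `baseline_impaired`, `onset_time`
#'   (`NA` when impairment was never observed).
#' @export
cohort_onsets <- function(cohort, definition = c("psms_ge7", "delta_ge2"),
                          convention = c("visit", "midpoint")) {
  definition <- match.arg(definition)
  convention <- match.arg(convention)
  b <- cohort$baseline
  v <- split(cohort$visits, factor(cohort$visits$patient_id, levels = b$patient_id))
  res <- lapply(seq_len(nrow(b)), function(i) {
    vi <- v[[i]]
    adl_onset(vi$visit_time, vi$psms, b$psms0[i], definition, convention)
  })
  data.frame(
    patient_id = b$patient_id,
    baseline_impaired = vapply(res, `[[`, logical(1), "baseline_impaired"),
    onset_time = vapply(res, `[[`, numeric(1), "onset_time"),
    stringsAsFactors = FALSE
  )
}

#' Expand a patient into counting-process intervals
#'
#' Splits follow-up at the impairment onset so that impairment enters the
#' Cox model as a time-dependent covariate on (start, stop] intervals.
#' A patient with no observed onset contributes one interval
#' `(0, followup_end]` with `impaired` equal to the baseline state; a
#' patient with onset at `t*` strictly inside follow-up contributes
#' `(0, t*]` unimpaired (no event) and `(t*, followup_end]` impaired; a
#' baseline-impaired patient contributes a single impaired interval from 0.
#' Deaths with no qualifying visit beforehand are treated as never impaired
#' (no imputation between the last intact visit and death).
#'
#' @param patient_id id string.
#' @param followup_end end of follow-up in years.
#' @param dead logical, `TRUE` if follow-up ended in death.
#' @param baseline_impaired,onset_time as returned by [adl_onset()].
#' @return data frame with columns `patient_id`, `start`, `stop`, `event`,
#'   `impaired`.
#' @export
split_episodes <- function(patient_id, followup_end, dead,
                           baseline_impaired, onset_time) {
  if (!is.na(onset_time) && onset_time > followup_end + 1e-9)
    stop_adl("adlsurv_integrity_error",
             "onset after end of follow-up for patient %s", patient_id)
  if (followup_end <= 0)
    stop_adl("adlsurv_integrity_error",
             "non-positive follow-up for patient %s", patient_id)
  ev <- as.integer(dead)
  if (baseline_impaired || (!is.na(onset_time) && onset_time <= 0)) {
    out <- data.frame(patient_id = patient_id, start = 0,
                      stop = followup_end, event = ev, impaired = 1L)
  } else if (is.na(onset_time) || onset_time >= followup_end) {
    ## onset at the very end of follow-up leaves no impaired exposure time
    out <- data.frame(patient_id = patient_id, start = 0,
                      stop = followup_end, event = ev, impaired = 0L)
  } else {
    out <- data.frame(patient_id = rep(patient_id, 2),
                      start = c(0, onset_time),
                      stop = c(onset_time, followup_end),
                      event = c(0L, ev),
                      impaired = c(0L, 1L))
  }
  out$patient_id <- as.character(out$patient_id)
  out
}

#' Counting-process data for the time-dependent impairment Cox model
#'
#' Builds the full (start, stop] data set for a weighted Cox model of death
#' with the development of basic ADL impairment as a time-dependent
#' covariate, alongside the fixed baseline covariates. By default all
#' patients are retained and baseline-impaired patients (absolute
#' definition) are coded impaired from entry; `baseline_intact_only = TRUE`
#' restricts to patients intact at baseline instead.
#'
#' @param cohort an [adl_cohort()].
#' @inheritParams adl_onset
#' @param covariates baseline covariates to carry (see
#'   [covariate_matrix()]).
#' @param weights optional named vector of per-patient weights (e.g. from
#'   [ipcw_weights()]); default all 1.
#' @param baseline_intact_only drop patients impaired at baseline.
#' @param convention onset dating convention, see [adl_onset()].
#' @return data frame of counting-process rows: `patient_id`, `start`,
#'   `stop`, `event`, `impaired`, `weight`, one column per covariate.
#' @export
counting_process <- function(cohort, definition = c("psms_ge7", "delta_ge2"),
                             covariates = .adl_covariates, weights = NULL,
                             baseline_intact_only = FALSE,
                             convention = c("visit", "midpoint")) {
  definition <- match.arg(definition)
  on <- cohort_onsets(cohort, definition, convention)
  b <- cohort$baseline; o <- cohort$outcomes
  m <- match(b$patient_id, o$patient_id)
  keep <- if (baseline_intact_only) !on$baseline_impaired else rep(TRUE, nrow(b))
  rows <- lapply(which(keep), function(i) {
    split_episodes(b$patient_id[i], o$followup_end[m[i]],
                   o$status[m[i]] == "dead",
                   on$baseline_impaired[i], on$onset_time[i])
  })
  rows <- do.call(rbind, rows)
  z <- covariate_matrix(cohort, covariates)
  rows <- cbind(rows, z[rows$patient_id, , drop = FALSE])
  w <- if (is.null(weights)) rep(1, nrow(rows)) else {
    wi <- weights[rows$patient_id]
    if (anyNA(wi))
      stop_adl("adlsurv_schema_error", "weights missing for some patients")
    as.numeric(wi)
  }
  rows$weight <- w
  rownames(rows) <- NULL
  rows
}
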