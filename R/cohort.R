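#' @importFrom stats setNames
NULL

## Condition helpers -------------------------------------------------------

stop_adl <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "adlsurv_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Constructor -------------------------------------------------------------

#' Assemble a longitudinal AD cohort
#'
#' Bundles the three tables of a longitudinal Alzheimer's disease cohort —
#' baseline covariates, serial PSMS/MMSE visits, and one outcome row per
#' patient — into a validated `adl_cohort` object. Time is measured in years
#' since each patient's initial (baseline) visit, so `visit_time = 0` is the
#' baseline assessment and `followup_end` is years from baseline to death,
#' loss to follow-up, or administrative censoring.
#'
#' @param baseline data frame with columns `patient_id`, `age` (years),
#'   `sex` (`"male"`/`"female"`), `race` (`"white"`/`"nonwhite"`),
#'   `education` (years), `marital` (`"married"`/`"not_married"`),
#'   `cvde` (logical: cardiovascular disease equivalent), `symptom_duration`
#'   (years of cognitive symptoms before baseline), `mmse0` (baseline MMSE,
#'   0-30) and `psms0` (baseline PSMS total, 6-30).
#' @param visits data frame with `patient_id`, `visit_time` (years since
#'   baseline, > 0), `psms` (6-30) and optionally `mmse`.
#' @param outcomes data frame with `patient_id`, `followup_end` (years) and
#'   `status` (`"dead"`, `"censored_admin"` or `"lost"`).
#' @param validate raise an integrity error if the cohort violates any
#'   invariant (default `TRUE`); see [validate_cohort()].
#' @return An object of class `adl_cohort`: a list with elements `baseline`,
#'   `visits` (sorted by patient and time) and `outcomes`.
#' @seealso [read_cohort()], [validate_cohort()], [simulate_cohort()]
#' @export
adl_cohort <- function(baseline, visits, outcomes, validate = TRUE) {
  req <- list(
    baseline = c("patient_id", "age", "sex", "race", "education", "marital",
                 "cvde", "symptom_duration", "mmse0", "psms0"),
    visits   = c("patient_id", "visit_time", "psms"),
    outcomes = c("patient_id", "followup_end", "status")
  )
  tabs <- list(baseline = baseline, visits = visits, outcomes = outcomes)
  for (nm in names(req)) {
    missing_cols <- setdiff(req[[nm]], names(tabs[[nm]]))
    if (length(missing_cols))
      stop_adl("adlsurv_schema_error",
               "schema error: %s table is missing column(s) %s",
               nm, paste(sQuote(missing_cols), collapse = ", "))
  }
  baseline$patient_id <- as.character(baseline$patient_id)
  visits$patient_id   <- as.character(visits$patient_id)
  outcomes$patient_id <- as.character(outcomes$patient_id)
  baseline$cvde <- as.logical(baseline$cvde)
  if (!"mmse" %in% names(visits)) visits$mmse <- NA_real_
  ## canonical order so that input row order never affects results
  baseline <- baseline[order(baseline$patient_id), , drop = FALSE]
  visits   <- visits[order(visits$patient_id, visits$visit_time), , drop = FALSE]
  outcomes <- outcomes[order(outcomes$patient_id), , drop = FALSE]
  rownames(baseline) <- rownames(visits) <- rownames(outcomes) <- NULL
  dup <- duplicated(visits[c("patient_id", "visit_time")])
  if (any(dup))
    stop_adl("adlsurv_integrity_error",
             "integrity error: duplicate (patient_id, visit_time) for %s",
             paste(unique(visits$patient_id[dup]), collapse = ", "))
  x <- structure(list(baseline = baseline, visits = visits, outcomes = outcomes),
                 class = "adl_cohort")
  if (validate) {
    v <- validate_cohort(x)
    if (nrow(v))
      stop_adl("adlsurv_integrity_error",
               "integrity error: cohort violates %d invariant(s); first: [%s] %s",
               nrow(v), v$rule[1], v$message[1])
  }
  x
}

#' @export
print.adl_cohort <- function(x, ...) {
  n <- nrow(x$baseline)
  st <- table(factor(x$outcomes$status,
                     levels = c("dead", "censored_admin", "lost")))
  cat(sprintf("<adl_cohort> %d patients, %d follow-up visits\n",
              n, nrow(x$visits)))
  cat(sprintf("  outcomes: %d dead, %d administratively censored, %d lost\n",
              st[["dead"]], st[["censored_admin"]], st[["lost"]]))
  invisible(x)
}

## Validation --------------------------------------------------------------

#' Check a cohort against its structural invariants
#'
#' Reports (never raises) one row per violated rule so that pipelines can
#' quarantine offending patients. Rules cover score ranges (PSMS 6-30, MMSE
#' 0-30), non-negative age/education/symptom duration, strictly positive and
#' strictly increasing visit times, follow-up end at or after the last
#' visit, exactly one outcome per patient, referential integrity of patient
#' ids, and (optionally) the inclusion rule that every patient has at least
#' one follow-up visit or died/was lost before the first one.
#'
#' @param cohort an [adl_cohort()].
#' @param inclusion also check the at-least-one-follow-up inclusion rule.
#' @return data frame with columns `patient_id`, `rule`, `message`;
#'   zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort, inclusion = TRUE) {
  b <- cohort$baseline; v <- cohort$visits; o <- cohort$outcomes
  out <- list()
  bad <- function(id, rule, msg)
    data.frame(patient_id = as.character(id), rule = rule, message = msg,
               stringsAsFactors = FALSE)

  rng <- function(tab, col, lo, hi, rule, where) {
    x <- tab[[col]]
    i <- which(!is.na(x) & (x < lo | x > hi))
    if (length(i)) bad(tab$patient_id[i], rule,
                       sprintf("%s %s = %g outside [%g, %g]", where, col, x[i], lo, hi))
  }
  out$psms0 <- rng(b, "psms0", 6, 30, "psms_range", "baseline")
  out$mmse0 <- rng(b, "mmse0", 0, 30, "mmse_range", "baseline")
  out$psms  <- rng(v, "psms", 6, 30, "psms_range", "visit")
  out$mmse  <- rng(v, "mmse", 0, 30, "mmse_range", "visit")
  for (col in c("age", "education", "symptom_duration")) {
    i <- which(b[[col]] < 0)
    if (length(i)) out[[paste0("neg_", col)]] <-
      bad(b$patient_id[i], "nonnegative", sprintf("baseline %s < 0", col))
  }
  lev <- list(sex = c("male", "female"), race = c("white", "nonwhite"),
              marital = c("married", "not_married"))
  for (col in names(lev)) {
    i <- which(!b[[col]] %in% lev[[col]])
    if (length(i)) out[[paste0("lev_", col)]] <-
      bad(b$patient_id[i], "category",
          sprintf("baseline %s not one of {%s}", col, paste(lev[[col]], collapse = ", ")))
  }
  i <- which(v$visit_time <= 0)
  if (length(i)) out$vt <- bad(v$patient_id[i], "visit_time_positive",
                               "visit_time must be > 0 (years since baseline)")
  ## strictly increasing within patient (table is sorted by patient, time)
  if (nrow(v) > 1) {
    same <- v$patient_id[-1] == v$patient_id[-nrow(v)]
    nondec <- v$visit_time[-1] <= v$visit_time[-nrow(v)]
    i <- which(same & nondec)
    if (length(i)) out$inc <- bad(v$patient_id[i + 1], "visit_time_increasing",
                                  "visit times not strictly increasing")
  }
  ## referential integrity
  for (tab in c("visits", "outcomes")) {
    orphan <- setdiff(unique(cohort[[tab]]$patient_id), b$patient_id)
    if (length(orphan)) out[[paste0("ref_", tab)]] <-
      bad(orphan, "missing_baseline", sprintf("%s row without baseline row", tab))
  }
  dupo <- o$patient_id[duplicated(o$patient_id)]
  if (length(dupo)) out$dupo <- bad(unique(dupo), "one_outcome",
                                    "more than one outcome row")
  noout <- setdiff(b$patient_id, o$patient_id)
  if (length(noout)) out$noout <- bad(noout, "one_outcome", "no outcome row")
  i <- which(!o$status %in% c("dead", "censored_admin", "lost"))
  if (length(i)) out$st <- bad(o$patient_id[i], "status",
                               "status not one of dead/censored_admin/lost")
  ## follow-up end covers the last visit
  if (nrow(v)) {
    last <- tapply(v$visit_time, v$patient_id, max)
    m <- match(names(last), o$patient_id)
    i <- which(!is.na(m) & o$followup_end[m] < as.numeric(last) - 1e-9)
    if (length(i)) out$fe <- bad(names(last)[i], "followup_covers_visits",
                                 "followup_end before last visit_time")
  }
  if (inclusion) {
    has_visit <- b$patient_id %in% v$patient_id
    m <- match(b$patient_id, o$patient_id)
    ok <- has_visit | (!is.na(m) & o$status[m] %in% c("dead", "lost"))
    i <- which(!ok)
    if (length(i)) out$incl <- bad(b$patient_id[i], "inclusion",
                                   "no follow-up visit and not dead/lost")
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(patient_id = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## CVDE --------------------------------------------------------------------

#' Cardiovascular disease equivalent (CVDE)
#'
#' Composite comorbidity indicator following NCEP-ATP III: true for a
#' history of myocardial infarction, congestive heart failure, stent
#' placement or diabetes mellitus, or for high coronary risk defined as any
#' two of hypertension, hyperlipidemia and current cigarette smoking.
#' All arguments are logical and vectorised.
#'
#' @param mi,chf,stent,dm,htn,lipid,smoking comorbidity history flags.
#' @return logical vector.
#' @examples
#' derive_cvde(mi = TRUE)                      # TRUE
#' derive_cvde(htn = TRUE)                     # FALSE: only one of the trio
#' derive_cvde(htn = TRUE, smoking = TRUE)     # TRUE: two of the trio
#' @export
derive_cvde <- function(mi = FALSE, chf = FALSE, stent = FALSE, dm = FALSE,
                        htn = FALSE, lipid = FALSE, smoking = FALSE) {
  flags <- list(mi, chf, stent, dm, htn, lipid, smoking)
  if (!all(vapply(flags, is.logical, logical(1))))
    stop_adl("adlsurv_schema_error", "CVDE flags must be logical")
  mi | chf | stent | dm | ((htn + lipid + smoking) >= 2)
}

## I/O ---------------------------------------------------------------------

.cohort_cols <- c("record", "patient_id", "age", "sex", "race", "education",
                  "marital", "cvde", "symptom_duration", "mmse0", "psms0",
                  "visit_time", "psms", "mmse", "followup_end", "status")

#' Read a cohort from a long CSV file
#'
#' The canonical on-disk dialect is a single UTF-8 CSV with a `record`
#' column taking values `baseline`, `visit` and `outcome`; each record type
#' uses its own subset of the remaining columns (see [adl_cohort()]), with
#' the others left empty. Files exported from other layouts (for example a
#' spreadsheet with per-visit PSMS rows under different headers) are read by
#' supplying `col_map`, a named character vector mapping canonical column
#' names to the file's column names.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector, e.g.
#'   `c(patient_id = "ID", psms = "PSMS_TOTAL")`.
#' @param validate raise an integrity error on invariant violations
#'   (default `TRUE`).
#' @return an [adl_cohort()].
#' @export
read_cohort <- function(path, col_map = NULL, validate = TRUE) {
  if (!file.exists(path))
    stop_adl("adlsurv_schema_error", "file does not exist: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(col_map)) {
    m <- match(unname(col_map), names(d))
    if (anyNA(m))
      stop_adl("adlsurv_schema_error",
               "schema error: mapped column(s) %s not in file",
               paste(sQuote(col_map[is.na(m)]), collapse = ", "))
    names(d)[m] <- names(col_map)
  }
  if (!"record" %in% names(d))
    stop_adl("adlsurv_schema_error", "schema error: missing column 'record'")
  pick <- function(rec, cols) {
    missing_cols <- setdiff(cols, names(d))
    if (length(missing_cols))
      stop_adl("adlsurv_schema_error",
               "schema error: missing column(s) %s",
               paste(sQuote(missing_cols), collapse = ", "))
    d[d$record == rec, cols, drop = FALSE]
  }
  baseline <- pick("baseline", c("patient_id", "age", "sex", "race", "education",
                                 "marital", "cvde", "symptom_duration",
                                 "mmse0", "psms0"))
  vis_cols <- c("patient_id", "visit_time", "psms",
                if ("mmse" %in% names(d)) "mmse")
  visits   <- pick("visit", vis_cols)
  outcomes <- pick("outcome", c("patient_id", "followup_end", "status"))
  adl_cohort(baseline, visits, outcomes, validate = validate)
}

#' Write a cohort to the long CSV dialect
#'
#' Numeric fields are written with full (17 significant digit) precision so
#' that a read/write round trip is lossless.
#'
#' @param cohort an [adl_cohort()].
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(e)
        if (is.na(e)) "" else sprintf("%.17g", e), character(1))
      ## keep integers clean
      ifelse(!is.na(x) & x == round(x), ifelse(is.na(x), "", sprintf("%.0f", x)), out)
    } else if (is.logical(x)) ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
    else as.character(x)
  }
  blank <- setNames(rep("", length(.cohort_cols)), .cohort_cols)
  expand <- function(tab, rec) {
    if (!nrow(tab)) return(NULL)
    m <- as.data.frame(matrix(blank, nrow(tab), length(.cohort_cols), byrow = TRUE,
                              dimnames = list(NULL, .cohort_cols)),
                       stringsAsFactors = FALSE)
    m$record <- rec
    for (col in names(tab)) m[[col]] <- fmt(tab[[col]])
    m
  }
  out <- rbind(expand(cohort$baseline, "baseline"),
               expand(cohort$visits, "visit"),
               expand(cohort$outcomes, "outcome"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

## Covariate coding --------------------------------------------------------

## model covariates; reference coding matches the study's tables (male vs
## female, nonwhite vs white, not married vs married)
.adl_covariates <- c("age", "sex", "race", "education", "mmse0",
                     "symptom_duration", "marital", "cvde")

#' The default model covariates
#'
#' The eight baseline covariates used by every transition model: age, sex,
#' race, education, baseline MMSE, symptom duration, marital status and
#' CVDE. Baseline PSMS additionally enters the fixed-covariate death model.
#'
#' @return character vector of covariate names.
#' @export
adl_covariates <- function() .adl_covariates

#' Numeric design matrix for the baseline covariates
#'
#' Codes sex as male = 1 (reference female), race as nonwhite = 1 (reference
#' white), marital as not married = 1 (reference married), CVDE as 1 = yes.
#'
#' @param cohort an [adl_cohort()].
#' @param covariates character vector of covariate names; any of
#'   `age, sex, race, education, mmse0, symptom_duration, marital, cvde,
#'   psms0`.
#' @return numeric matrix with one row per patient (rownames = patient_id).
#' @export
covariate_matrix <- function(cohort, covariates = .adl_covariates) {
  b <- cohort$baseline
  col <- function(nm) switch(nm,
    sex     = as.numeric(b$sex == "male"),
    race    = as.numeric(b$race == "nonwhite"),
    marital = as.numeric(b$marital == "not_married"),
    cvde    = as.numeric(b$cvde),
    {
      if (!nm %in% names(b))
        stop_adl("adlsurv_schema_error", "unknown covariate '%s'", nm)
      as.numeric(b[[nm]])
    })
  z <- vapply(covariates, col, numeric(nrow(b)))
  z <- matrix(z, nrow = nrow(b), dimnames = list(b$patient_id, covariates))
  z
}
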