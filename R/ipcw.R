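## Inverse probability of censoring weighting for loss to follow-up.
##
## The dropout model is a single logistic regression of "lost to follow-up"
## on the baseline covariates; each patient then receives the fixed
## subject-level weight 1 / (1 - p_lost). This is the simple subject-level
## form of IPCW (not the time-varying product form, which is out of scope
## here); see the package vignette for the implied assumptions.

#' Fit the loss-to-follow-up logistic model
#'
#' Maximum-likelihood logistic regression of being lost to follow-up
#' (`status == "lost"`) on baseline covariates: by default age, sex, race,
#' marital status, education, baseline PSMS and MMSE, symptom duration and
#' CVDE. An empty covariate set fits the intercept-only model (everyone's
#' fitted probability is then the lost fraction).
#'
#' @param cohort an [adl_cohort()].
#' @param covariates baseline covariates (see [covariate_matrix()]); may be
#'   `character(0)` for intercept-only.
#' @return object of class `dropout_model`: list with `coefficients`,
#'   `fitted` (named per-patient probabilities of being lost), `vcov`,
#'   `n_lost`, `n`, and the underlying `glm`.
#' @export
fit_dropout_model <- function(cohort,
                              covariates = c("age", "sex", "race", "marital",
                                             "education", "psms0", "mmse0",
                                             "symptom_duration", "cvde")) {
  o <- cohort$outcomes
  m <- match(cohort$baseline$patient_id, o$patient_id)
  lost <- as.integer(o$status[m] == "lost")
  if (all(lost == 1) || all(lost == 0))
    stop_adl("adlsurv_estimation_error",
             "degenerate dropout model: need at least one lost and one not-lost patient")
  if (length(covariates)) {
    z <- covariate_matrix(cohort, covariates)
    df <- data.frame(lost = lost, z)
    form <- stats::as.formula(paste("lost ~", paste(covariates, collapse = " + ")))
  } else {
    df <- data.frame(lost = lost)
    form <- lost ~ 1
  }
  sep_warn <- FALSE
  g <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep_warn || !g$converged || any(abs(stats::coef(g)[-1]) > 15)) {
    cf <- stats::coef(g)[-1]
    culprit <- if (length(cf)) names(cf)[which.max(abs(cf))] else "(intercept)"
    stop_adl("adlsurv_separation_error",
             "complete or quasi-complete separation in the dropout model (covariate %s)",
             sQuote(culprit))
  }
  p <- stats::fitted(g)
  names(p) <- cohort$baseline$patient_id
  structure(list(coefficients = stats::coef(g), fitted = p,
                 vcov = stats::vcov(g), n_lost = sum(lost), n = length(lost),
                 covariates = covariates, glm = g),
            class = "dropout_model")
}

#' @export
print.dropout_model <- function(x, digits = 4, ...) {
  cat(sprintf("Loss-to-follow-up logistic model: %d lost of %d patients\n",
              x$n_lost, x$n))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Inverse-probability-of-censoring weights
#'
#' Computes the fixed subject-level weight `1 / (1 - p_lost)` from a fitted
#' dropout model and caps the weights at a configurable quantile (default
#' the 99th percentile) to guard against near-separation blow-ups. With no
#' patient lost, every weight is exactly 1.
#'
#' @param model a [fit_dropout_model()] object.
#' @param cap_quantile cap weights at this quantile of the weight
#'   distribution (`NULL` or 1 disables capping).
#' @return named numeric vector of weights (>= 1), one per patient, with
#'   attributes `cap` (the applied cap, or `Inf`) and `cap_quantile`.
#' @export
ipcw_weights <- function(model, cap_quantile = 0.99) {
  p <- model$fitted
  if (any(p >= 1))
    stop_adl("adlsurv_estimation_error",
             "fitted loss probability >= 1: weights undefined")
  w <- 1 / (1 - p)
  cap <- Inf
  if (!is.null(cap_quantile) && cap_quantile < 1) {
    cap <- stats::quantile(w, cap_quantile, names = FALSE)
    w <- pmin(w, cap)
  }
  attr(w, "cap") <- cap
  attr(w, "cap_quantile") <- cap_quantile %||% 1
  w
}

#' IPCW weights for a cohort in one step
#'
#' Convenience wrapper: returns unit weights for every patient when nobody
#' was lost to follow-up (no censoring model is needed or identifiable),
#' otherwise fits the dropout model and computes capped weights.
#'
#' @inheritParams fit_dropout_model
#' @inheritParams ipcw_weights
#' @return named weight vector as in [ipcw_weights()].
#' @export
cohort_ipcw <- function(cohort,
                        covariates = c("age", "sex", "race", "marital",
                                       "education", "psms0", "mmse0",
                                       "symptom_duration", "cvde"),
                        cap_quantile = 0.99) {
  o <- cohort$outcomes
  if (!any(o$status == "lost")) {
    w <- rep(1, nrow(cohort$baseline))
    names(w) <- cohort$baseline$patient_id
    attr(w, "cap") <- Inf
    attr(w, "cap_quantile") <- cap_quantile %||% 1
    return(w)
  }
  ipcw_weights(fit_dropout_model(cohort, covariates), cap_quantile)
}

#' Write per-patient weights as a two-column CSV
#' @param weights named weight vector from [ipcw_weights()].
#' @param path output file.
#' @export
write_weights <- function(weights, path) {
  utils::write.csv(data.frame(patient_id = names(weights),
                              weight = as.numeric(weights)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
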