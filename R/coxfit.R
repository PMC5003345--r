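## Weighted Cox partial likelihood on counting-process data.
##
## The estimator works directly on (start, stop] intervals, so delayed
## entry (left truncation) and time-dependent covariates are handled by the
## risk-set convention: a row is at risk at event time t iff start < t <= stop.
## Risk-set sums are computed by sorting + cumulative sums (O(n log n) per
## Newton iteration), which keeps repeated simulation fits cheap.

## indices of cumulative sums: number of values strictly below each t
.count_below <- function(t, sorted_x) findInterval(t, sorted_x, left.open = TRUE)

## column-wise cumsum with a leading zero row, as a matrix
.cumsum0 <- function(m) {
  m <- as.matrix(m)
  rbind(0, apply(m, 2, cumsum))
}

## column-wise suffix sums (row k = sum over rows k..n) with a trailing
## zero row; summing from the tail avoids the catastrophic cancellation a
## total-minus-prefix evaluation suffers in small late risk sets
.suffix0 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n == 0) return(matrix(0, 1, ncol(m)))
  s <- apply(m[n:1, , drop = FALSE], 2, cumsum)
  s <- matrix(s, nrow = n)
  rbind(s[n:1, , drop = FALSE], 0)
}

#' Fit a weighted Cox proportional-hazards model with delayed entry
#'
#' Newton-Raphson maximisation of the weighted Cox partial likelihood over
#' counting-process rows, with step-halving on any likelihood decrease.
#' Weights enter the score, the information and the baseline hazard alike
#' (the variance reported is the inverse information; a robust sandwich
#' variance is available via `robust = TRUE`). Ties are handled by the
#' Breslow approximation by default (consistent with the Breslow baseline
#' hazard used throughout), or Efron's by option. The cumulative baseline
#' hazard (Breslow estimator, referenced to covariates all zero) is
#' attached to the fit.
#'
#' @param data data frame of counting-process rows with columns `start`,
#'   `stop`, `event` (0/1) and optionally `weight`; all remaining numeric
#'   columns are treated as covariates unless `covariates` is given.
#'   Rows with `start = 0` for everyone reduce to ordinary right-censored
#'   data.
#' @param covariates character vector naming the covariate columns.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol convergence tolerance on the change in partial log-likelihood.
#' @param max_iter maximum Newton iterations.
#' @param robust also compute an infinitesimal-jackknife (sandwich)
#'   variance, grouped by `patient_id` when present.
#' @param init optional starting coefficient vector.
#' @return An object of class `coxfit`: list with `coefficients`, `var`
#'   (inverse information), `loglik` (initial and final partial
#'   log-likelihood), `score_norm`, `n`, `nevent`, `iter`, `converged`,
#'   `ties`, `means`, `baseline` (data frame `time`, `hazard` of Breslow
#'   increments) and, if requested, `var_robust`.
#' @examples
#' d <- data.frame(start = 0, stop = 1:6, event = c(1, 1, 0, 1, 0, 1),
#'                 z = c(1, 0, 1, 0, 1, 0))
#' fit <- fit_cox(d)
#' coef(fit)
#' @export
fit_cox <- function(data, covariates = NULL,
                    ties = c("breslow", "efron"),
                    tol = 1e-9, max_iter = 50L, robust = FALSE, init = NULL) {
  ties <- match.arg(ties)
  reserved <- c("patient_id", "start", "stop", "event", "weight")
  for (col in c("start", "stop", "event"))
    if (!col %in% names(data))
      stop_adl("adlsurv_schema_error", "data must have column '%s'", col)
  if (is.null(covariates))
    covariates <- setdiff(names(data), reserved)
  if (!length(covariates))
    stop_adl("adlsurv_schema_error", "no covariates to fit")
  Z <- as.matrix(data[covariates])
  storage.mode(Z) <- "double"
  start <- as.numeric(data$start); stop_ <- as.numeric(data$stop)
  event <- as.integer(data$event)
  w <- if ("weight" %in% names(data)) as.numeric(data$weight) else rep(1, nrow(data))
  if (any(w <= 0)) stop_adl("adlsurv_schema_error", "weights must be positive")
  if (any(start >= stop_))
    stop_adl("adlsurv_integrity_error", "intervals must satisfy start < stop")

  n <- nrow(Z); p <- ncol(Z)
  nevent <- sum(event)
  if (nevent == 0)
    stop_adl("adlsurv_estimation_error", "no events: cannot fit a Cox model")

  ## precomputable structure -------------------------------------------
  et <- sort(unique(stop_[event == 1L]))
  D <- length(et)
  ev <- which(event == 1L)
  grp <- match(stop_[ev], et)                       # event's tie group
  ord_stop <- order(stop_); ord_start <- order(start)
  k_stop <- .count_below(et, stop_[ord_stop]) + 1L   # index into cumsum0
  k_start <- .count_below(et, start[ord_start]) + 1L
  dW <- as.numeric(rowsum(w[ev], grp))               # weighted events per time
  dN <- as.numeric(rowsum(rep(1, length(ev)), grp))  # tied event counts
  any_ties <- any(dN > 1)

  ## centre covariates for numerical stability (beta is unchanged)
  zbar <- colSums(w * Z) / sum(w)
  Zc <- sweep(Z, 2, zbar)
  zw_events <- colSums(w[ev] * Zc[ev, , drop = FALSE])

  ## identifiability screen: a covariate constant within every risk set
  ## carries no information; catch the global-constant case up front
  const <- apply(Z, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    stop_adl("adlsurv_singularity_error",
             "covariate(s) %s constant across all rows: not identifiable",
             paste(sQuote(covariates[const]), collapse = ", "))

  pp <- p * (p + 1L) / 2L
  pair_i <- rep(seq_len(p), times = seq_len(p))
  pair_j <- unlist(lapply(seq_len(p), seq_len))
  unpack_sym <- function(v) {                        # length-pp -> p x p
    m <- matrix(0, p, p)
    m[cbind(pair_i, pair_j)] <- v
    m[cbind(pair_j, pair_i)] <- v
    m
  }

  risk_sums <- function(r) {
    rz <- r * Zc
    rzz <- rz[, pair_i, drop = FALSE] * Zc[, pair_j, drop = FALSE]
    s0s <- .suffix0(r[ord_stop]);      s0a <- .suffix0(r[ord_start])
    s1s <- .suffix0(rz[ord_stop, , drop = FALSE])
    s1a <- .suffix0(rz[ord_start, , drop = FALSE])
    s2s <- .suffix0(rzz[ord_stop, , drop = FALSE])
    s2a <- .suffix0(rzz[ord_start, , drop = FALSE])
    list(S0 = s0s[k_stop, 1] - s0a[k_start, 1],
         S1 = s1s[k_stop, , drop = FALSE] - s1a[k_start, , drop = FALSE],
         S2 = s2s[k_stop, , drop = FALSE] - s2a[k_start, , drop = FALSE])
  }

  ## partial log-likelihood, score and information at beta
  evaluate <- function(beta, need_deriv = TRUE) {
    eta <- drop(Zc %*% beta)
    r <- w * exp(eta)
    rs <- risk_sums(r)
    S0 <- rs$S0; S1 <- rs$S1; S2 <- rs$S2
    if (any(S0 <= 0)) return(NULL)                  # numerically broken step
    if (ties == "breslow" || !any_ties) {
      ll <- sum(w[ev] * eta[ev]) - sum(dW * log(S0))
      if (!need_deriv) return(list(ll = ll))
      Ebar <- S1 / S0
      U <- zw_events - colSums(dW * Ebar)
      Ipp <- colSums(dW * (S2 / S0 - Ebar[, pair_i, drop = FALSE] *
                             Ebar[, pair_j, drop = FALSE]))
      list(ll = ll, U = U, I = unpack_sym(Ipp))
    } else {
      ## Efron: downweight tied events' own contribution to the risk sums
      E0 <- as.numeric(rowsum(r[ev], grp))
      E1 <- rowsum((r * Zc)[ev, , drop = FALSE], grp)
      E2 <- rowsum((r * Zc[, pair_i, drop = FALSE] *
                      Zc[, pair_j, drop = FALSE])[ev, , drop = FALSE], grp)
      ll <- sum(w[ev] * eta[ev])
      U <- zw_events
      Imat <- matrix(0, p, p)
      for (t in seq_len(D)) {
        d <- dN[t]; wt <- dW[t] / d
        for (j in seq_len(d) - 1L) {
          s0 <- S0[t] - (j / d) * E0[t]
          s1 <- S1[t, ] - (j / d) * E1[t, ]
          s2 <- S2[t, ] - (j / d) * E2[t, ]
          ll <- ll - wt * log(s0)
          eb <- s1 / s0
          U <- U - wt * eb
          Imat <- Imat + wt * (unpack_sym(s2) / s0 - tcrossprod(eb))
        }
      }
      list(ll = ll, U = U, I = Imat)
    }
  }

  zsd <- apply(Zc, 2, stats::sd)
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  cur <- evaluate(beta)
  if (is.null(cur))
    stop_adl("adlsurv_estimation_error", "partial likelihood undefined at start")
  ll0 <- cur$ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) NULL)
    if (is.null(step)) {
      culprit <- covariates[which.min(diag(cur$I))]
      stop_adl("adlsurv_singularity_error",
               "information matrix is singular (covariate %s carries no information within risk sets)",
               sQuote(culprit))
    }
    halving <- 0L
    repeat {
      cand <- beta + step
      nxt <- evaluate(cand)
      if (!is.null(nxt) && nxt$ll >= cur$ll - 1e-12) break
      halving <- halving + 1L
      if (halving > 10L) break
      step <- step / 2
    }
    if (halving > 10L) break                         # cannot improve further
    ## a coefficient running away on a centred covariate scale means the
    ## partial likelihood is monotone (separation); it plateaus numerically
    ## around |beta| ~ 20 under the default tolerance, so the guard sits
    ## well below that and still far beyond any plausible hazard ratio
    if (any(abs(cand) * zsd > 15))
      stop_adl("adlsurv_monotone_likelihood_error",
               "coefficient diverging: monotone partial likelihood for covariate %s",
               sQuote(covariates[which.max(abs(cand) * zsd)]))
    delta <- nxt$ll - cur$ll
    beta <- cand; cur <- nxt
    if (abs(delta) < tol) { converged <- TRUE; break }
  }

  var <- solve(cur$I)
  dimnames(var) <- list(covariates, covariates)
  names(beta) <- covariates

  ## Breslow cumulative baseline hazard at covariates = 0
  r <- w * exp(drop(Zc %*% beta))
  S0 <- risk_sums(r)$S0
  inc <- dW / S0 * exp(-sum(beta * zbar))
  baseline <- data.frame(time = et, hazard = inc)

  fit <- structure(list(
    coefficients = beta, var = var,
    loglik = c(ll0, cur$ll), score_norm = sqrt(sum(cur$U^2)),
    n = n, nevent = nevent, iter = iter, converged = converged,
    ties = ties, means = zbar, covariates = covariates,
    baseline = baseline, call = match.call()
  ), class = "coxfit")

  if (robust) fit$var_robust <- .cox_robust_var(fit, data, covariates)
  fit
}

## Infinitesimal-jackknife (sandwich) variance, grouping score residuals
## by patient when ids are available.
.cox_robust_var <- function(fit, data, covariates) {
  sc <- .cox_score_residuals(fit, data, covariates)
  id <- if ("patient_id" %in% names(data)) data$patient_id else seq_len(nrow(data))
  L <- rowsum(sc, id) %*% fit$var
  crossprod(L)
}

## per-row score residuals (weighted), via the martingale decomposition
.cox_score_residuals <- function(fit, data, covariates) {
  Z <- as.matrix(data[covariates])
  start <- as.numeric(data$start); stop_ <- as.numeric(data$stop)
  event <- as.integer(data$event)
  w <- if ("weight" %in% names(data)) as.numeric(data$weight) else rep(1, nrow(data))
  beta <- fit$coefficients
  Zc <- sweep(Z, 2, fit$means)
  r <- w * exp(drop(Zc %*% beta))
  et <- fit$baseline$time
  ## risk sums at the event grid
  ord_stop <- order(stop_); ord_start <- order(start)
  k_stop <- .count_below(et, stop_[ord_stop]) + 1L
  k_start <- .count_below(et, start[ord_start]) + 1L
  s0s <- .suffix0(r[ord_stop]); s0a <- .suffix0(r[ord_start])
  s1s <- .suffix0((r * Zc)[ord_stop, , drop = FALSE])
  s1a <- .suffix0((r * Zc)[ord_start, , drop = FALSE])
  S0 <- s0s[k_stop, 1] - s0a[k_start, 1]
  Ebar <- (s1s[k_stop, , drop = FALSE] - s1a[k_start, , drop = FALSE]) / S0
  ev <- which(event == 1L)
  grp <- match(stop_[ev], et)
  dW <- as.numeric(rowsum(w[ev], grp))
  dL <- dW / S0                                      # centred Breslow increments
  p <- ncol(Zc)
  out <- matrix(0, nrow(Zc), p)
  ## event part
  out[ev, ] <- w[ev] * (Zc[ev, , drop = FALSE] - Ebar[grp, , drop = FALSE])
  ## compensator part: - integral over (start, stop] of r_i (z_i - Ebar) dL
  cums_dL <- c(0, cumsum(dL)); cums_EdL <- .cumsum0(Ebar * dL)
  ## number of event times <= t (right-continuous integral bound)
  upto <- function(t) findInterval(t, et) + 1L
  a <- upto(stop_); b <- upto(start)
  intL <- cums_dL[a] - cums_dL[b]
  intE <- cums_EdL[a, , drop = FALSE] - cums_EdL[b, , drop = FALSE]
  out - r * (Zc * intL - intE)
}

#' @export
print.coxfit <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted Cox model (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$nevent))
  print(round(summary(x)$coefficients, digits))
  cat(sprintf("Partial log-likelihood: %.4f (null %.4f); %sconverged in %d iterations\n",
              x$loglik[2], x$loglik[1], if (x$converged) "" else "NOT ", x$iter))
  invisible(x)
}

#' @export
summary.coxfit <- function(object, conf_level = 0.95, ...) {
  beta <- object$coefficients
  se <- sqrt(diag(object$var))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- cbind(coef = beta, `exp(coef)` = exp(beta), se = se,
               z = beta / se, p = 2 * stats::pnorm(-abs(beta / se)),
               lower = exp(beta - zq * se), upper = exp(beta + zq * se))
  out <- list(coefficients = tab, loglik = object$loglik, n = object$n,
              nevent = object$nevent, ties = object$ties,
              converged = object$converged)
  class(out) <- "summary.coxfit"
  out
}

#' @export
print.summary.coxfit <- function(x, digits = 4, ...) {
  cat(sprintf("n = %d, events = %d, ties = %s\n", x$n, x$nevent, x$ties))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.coxfit <- function(object, ...) object$coefficients

#' @export
vcov.coxfit <- function(object, ...) object$var

#' @export
logLik.coxfit <- function(object, ...) {
  structure(object$loglik[2], df = length(object$coefficients), class = "logLik")
}

#' Hazard-ratio table of a Cox fit
#'
#' @param fit a [fit_cox()] object.
#' @param conf_level confidence level for the Wald interval.
#' @return data frame `covariate`, `hr`, `lower`, `upper`, `p`.
#' @export
hazard_ratios <- function(fit, conf_level = 0.95) {
  s <- summary(fit, conf_level)$coefficients
  data.frame(covariate = rownames(s), hr = s[, "exp(coef)"],
             lower = s[, "lower"], upper = s[, "upper"], p = s[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}

## Step function helpers ---------------------------------------------------

#' Evaluate a cumulative-hazard step function
#'
#' Right-continuous evaluation of a non-decreasing step function given as
#' jump times and non-negative increments; the value at and before time 0
#' is 0.
#'
#' @param sf data frame with columns `time` and `hazard` (increments), as
#'   in `fit$baseline`.
#' @param t times at which to evaluate.
#' @return cumulative values at `t`.
#' @export
cumhaz_at <- function(sf, t) {
  cums <- c(0, cumsum(sf$hazard))
  cums[findInterval(t, sf$time) + 1L]
}

#' Breslow cumulative baseline hazard of a fitted Cox model
#'
#' Recomputes the Breslow estimator
#' \eqn{dH_0(t) = \sum_i w_i dN_i(t) / \sum_{j \in R(t)} w_j e^{\beta' z_j}}
#' on a data set at the fitted coefficients, referenced to covariates all
#' zero. (The same estimator is attached to every fit as `fit$baseline`.)
#'
#' @param fit a [fit_cox()] object.
#' @param data counting-process rows (same layout as in [fit_cox()]).
#' @return data frame with `time` (distinct event times) and `hazard`
#'   (increments); pass to [cumhaz_at()] to evaluate.
#' @export
breslow_baseline <- function(fit, data) {
  covariates <- fit$covariates
  Z <- as.matrix(data[covariates])
  start <- as.numeric(data$start); stop_ <- as.numeric(data$stop)
  event <- as.integer(data$event)
  w <- if ("weight" %in% names(data)) as.numeric(data$weight) else rep(1, nrow(data))
  eta <- drop(Z %*% fit$coefficients)
  r <- w * exp(eta)
  et <- sort(unique(stop_[event == 1L]))
  ord_stop <- order(stop_); ord_start <- order(start)
  s0s <- .suffix0(r[ord_stop]); s0a <- .suffix0(r[ord_start])
  S0 <- s0s[.count_below(et, stop_[ord_stop]) + 1L, 1] -
    s0a[.count_below(et, start[ord_start]) + 1L, 1]
  ev <- which(event == 1L)
  dW <- as.numeric(rowsum(w[ev], match(stop_[ev], et)))
  data.frame(time = et, hazard = dW / S0)
}

## Schoenfeld diagnostics --------------------------------------------------

#' Schoenfeld-residual test of proportional hazards
#'
#' Computes the (weighted) Schoenfeld residual at each event — the event's
#' covariate value minus the risk-set weighted mean at the fitted
#' coefficients — and tests, per covariate and globally, whether the
#' residuals drift with the rank of the event time (a linear trend in
#' scaled time indicates a time-varying coefficient).
#'
#' @param fit a [fit_cox()] object.
#' @param data the counting-process rows the model was fitted to.
#' @return list of class `ph_test` with `table` (per covariate:
#'   `correlation` of residual with event-time rank, `chisq`, `p`),
#'   `global_chisq`, `df`, `global_p`, and the residual matrix
#'   `residuals` (one row per event, ordered by event time).
#' @export
schoenfeld_ph_test <- function(fit, data) {
  covariates <- fit$covariates
  Z <- as.matrix(data[covariates])
  start <- as.numeric(data$start); stop_ <- as.numeric(data$stop)
  event <- as.integer(data$event)
  w <- if ("weight" %in% names(data)) as.numeric(data$weight) else rep(1, nrow(data))
  if (sum(event) < 3)
    stop_adl("adlsurv_estimation_error",
             "fewer than 3 events: proportional-hazards test undefined")
  Zc <- sweep(Z, 2, fit$means)
  r <- w * exp(drop(Zc %*% fit$coefficients))
  et <- sort(unique(stop_[event == 1L]))
  ord_stop <- order(stop_); ord_start <- order(start)
  k_stop <- .count_below(et, stop_[ord_stop]) + 1L
  k_start <- .count_below(et, start[ord_start]) + 1L
  s0s <- .suffix0(r[ord_stop]); s0a <- .suffix0(r[ord_start])
  s1s <- .suffix0((r * Zc)[ord_stop, , drop = FALSE])
  s1a <- .suffix0((r * Zc)[ord_start, , drop = FALSE])
  S0 <- s0s[k_stop, 1] - s0a[k_start, 1]
  Ebar <- (s1s[k_stop, , drop = FALSE] - s1a[k_start, , drop = FALSE]) / S0

  ev <- which(event == 1L)
  ev <- ev[order(stop_[ev])]
  grp <- match(stop_[ev], et)
  res <- w[ev] * (Zc[ev, , drop = FALSE] - Ebar[grp, , drop = FALSE])
  colnames(res) <- covariates
  d <- length(ev)
  g <- rank(stop_[ev], ties.method = "average")
  gc <- g - mean(g)
  Vbar <- .cox_information(fit, data) / d
  num <- drop(crossprod(gc, res))                    # per-covariate trend
  den <- sum(gc^2)
  chisq <- num^2 / (den * diag(Vbar))
  global <- drop(t(num) %*% solve(Vbar * den, num))
  structure(list(
    table = data.frame(covariate = covariates,
                       correlation = apply(res, 2, function(s) stats::cor(g, s)),
                       chisq = chisq,
                       p = stats::pchisq(chisq, 1, lower.tail = FALSE),
                       row.names = NULL, stringsAsFactors = FALSE),
    global_chisq = global, df = length(covariates),
    global_p = stats::pchisq(global, length(covariates), lower.tail = FALSE),
    residuals = res, time = stop_[ev]
  ), class = "ph_test")
}

#' @export
print.ph_test <- function(x, digits = 4, ...) {
  cat("Proportional-hazards test (Schoenfeld residuals vs event-time rank)\n")
  tab <- x$table; tab[-1] <- lapply(tab[-1], round, digits)
  print(tab)
  cat(sprintf("GLOBAL chisq = %.3f on %d df, p = %.4g\n",
              x$global_chisq, x$df, x$global_p))
  invisible(x)
}

## observed information at the fitted beta (for diagnostics)
.cox_information <- function(fit, data) {
  covariates <- fit$covariates
  Z <- as.matrix(data[covariates])
  start <- as.numeric(data$start); stop_ <- as.numeric(data$stop)
  event <- as.integer(data$event)
  w <- if ("weight" %in% names(data)) as.numeric(data$weight) else rep(1, nrow(data))
  Zc <- sweep(Z, 2, fit$means)
  r <- w * exp(drop(Zc %*% fit$coefficients))
  p <- ncol(Zc)
  pair_i <- rep(seq_len(p), times = seq_len(p))
  pair_j <- unlist(lapply(seq_len(p), seq_len))
  et <- sort(unique(stop_[event == 1L]))
  ord_stop <- order(stop_); ord_start <- order(start)
  k_stop <- .count_below(et, stop_[ord_stop]) + 1L
  k_start <- .count_below(et, start[ord_start]) + 1L
  rz <- r * Zc
  rzz <- rz[, pair_i, drop = FALSE] * Zc[, pair_j, drop = FALSE]
  s0s <- .suffix0(r[ord_stop]); s0a <- .suffix0(r[ord_start])
  s1s <- .suffix0(rz[ord_stop, , drop = FALSE]); s1a <- .suffix0(rz[ord_start, , drop = FALSE])
  s2s <- .suffix0(rzz[ord_stop, , drop = FALSE]); s2a <- .suffix0(rzz[ord_start, , drop = FALSE])
  S0 <- s0s[k_stop, 1] - s0a[k_start, 1]
  S1 <- s1s[k_stop, , drop = FALSE] - s1a[k_start, , drop = FALSE]
  S2 <- s2s[k_stop, , drop = FALSE] - s2a[k_start, , drop = FALSE]
  Ebar <- S1 / S0
  ev <- which(event == 1L)
  dW <- as.numeric(rowsum(w[ev], match(stop_[ev], et)))
  Ipp <- colSums(dW * (S2 / S0 - Ebar[, pair_i, drop = FALSE] *
                         Ebar[, pair_j, drop = FALSE]))
  m <- matrix(0, p, p)
  m[cbind(pair_i, pair_j)] <- Ipp
  m[cbind(pair_j, pair_i)] <- Ipp
  dimnames(m) <- list(covariates, covariates)
  m
}

#' Schoenfeld residuals of a Cox fit
#' @param object a [fit_cox()] object.
#' @param data the rows the model was fitted to.
#' @param type only `"schoenfeld"` is supported.
#' @param ... unused.
#' @export
residuals.coxfit <- function(object, data, type = "schoenfeld", ...) {
  type <- match.arg(type)
  schoenfeld_ph_test(object, data)$residuals
}
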