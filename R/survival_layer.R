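#' Endpoint definitions with study-specific censoring
#'
#' Two endpoints are supported. Under `all_cause_death` the event is death
#' and a CRT-D upgrade, LVAD implantation, or heart transplantation censors
#' the patient at its time. Under the sensitivity `composite` endpoint,
#' death, LVAD, and transplantation all count as events and only an upgrade
#' censors.
#'
#' @param name `"all_cause_death"` or `"composite"`.
#' @return An `endpoint_spec` with the censor reasons it applies.
#' @export
endpoint_spec <- function(name = c("all_cause_death", "composite")) {
  name <- match.arg(name)
  censoring <- if (name == "all_cause_death") {
    c("crtd_upgrade", "lvad", "htx")
  } else {
    "crtd_upgrade"
  }
  structure(list(name = name, censor_reasons_applied = censoring),
            class = "endpoint_spec")
}

#' Apply an endpoint to survival records
#'
#' @param records Data frame with `time_years`, `event` (death flag) and
#'   `censor_reason` in `none`, `admin`, `crtd_upgrade`, `lvad`, `htx`.
#' @param spec An [endpoint_spec()].
#' @return A list with numeric `time` and logical `event`.
#' @export
apply_endpoint <- function(records, spec = endpoint_spec("all_cause_death")) {
  known <- c("none", "admin", "crtd_upgrade", "lvad", "htx")
  bad <- setdiff(unique(records$censor_reason), known)
  if (length(bad)) {
    stop(sprintf("unknown censor_reason: %s", paste(bad, collapse = ", ")))
  }
  event <- records$event
  if (spec$name == "composite") {
    event <- event | records$censor_reason %in% c("lvad", "htx")
  }
  list(time = records$time_years, event = as.logical(event))
}

#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit survival estimate with the Greenwood variance and a 95%
#' log-transformed confidence interval clipped to `[0, 1]`.
#'
#' @param time Positive follow-up times.
#' @param event Logical (or 0/1) event indicators.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `km_curve`: `time` (sorted unique times),
#'   `n_risk`, `n_event`, `surv`, `greenwood_var`, `ci_lo`, `ci_hi`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) >= 1, all(time > 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "log", conf.int = conf_level)
  s <- fit$surv
  # survfit's std.err is the SE of log S; Greenwood variance of S itself
  gvar <- (s * fit$std.err)^2
  gvar[!is.finite(gvar)] <- 0
  structure(
    list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         surv = s, greenwood_var = gvar,
         ci_lo = pmax(0, ifelse(is.na(fit$lower), s, fit$lower)),
         ci_hi = pmin(1, ifelse(is.na(fit$upper), s, fit$upper)),
         n = fit$n),
    class = "km_curve"
  )
}

#' Evaluate a Kaplan-Meier step function
#'
#' The survival (or Greenwood variance) at `t` is the value at the last
#' estimate time `<= t`; before the first time the survival is 1 and the
#' variance 0.
#'
#' @param curve A `km_curve`.
#' @param t Time points.
#' @param what `"surv"`, `"var"`, `"ci_lo"` or `"ci_hi"`.
#' @return Numeric vector; `NA` where `t` exceeds the curve's support (last
#'   follow-up time).
#' @export
km_at <- function(curve, t, what = c("surv", "var", "ci_lo", "ci_hi")) {
  what <- match.arg(what)
  col <- switch(what, surv = curve$surv, var = curve$greenwood_var,
                ci_lo = curve$ci_lo, ci_hi = curve$ci_hi)
  idx <- findInterval(t, curve$time)
  out <- ifelse(idx == 0, if (what == "var") 0 else 1, col[pmax(idx, 1)])
  out[t > max(curve$time)] <- NA_real_
  out
}

#' Reverse Kaplan-Meier follow-up duration
#'
#' Swaps the event and censoring roles so the "event" is end of follow-up;
#' the median and interquartile range of that curve estimate the follow-up
#' distribution. A quantile the curve never reaches is returned as `NA` and
#' flagged.
#'
#' @inheritParams km_estimate
#' @return A list with `median`, `q25`, `q75` (years) and `undefined`
#'   (character vector naming unreachable quantiles).
#' @export
reverse_km <- function(time, event) {
  stopifnot(length(time) >= 1)
  fit <- survival::survfit(
    survival::Surv(time, 1L - as.integer(event)) ~ 1
  )
  q <- stats::quantile(fit, probs = c(0.25, 0.5, 0.75))$quantile
  res <- list(median = unname(q[2]), q25 = unname(q[1]), q75 = unname(q[3]))
  res$undefined <- c("q25", "median", "q75")[is.na(q)]
  res
}

#' Yearly absolute risk reduction between two arms
#'
#' At each horizon `t`, `arr(t)` is the difference in cumulative mortality
#' `1 - S(t)` between the comparator (CRT-P) and treatment (CRT-D) curves,
#' in percentage points. The variance is the sum of the two Greenwood
#' variances; the 95% CI is the normal interval, and the reduction is
#' flagged significant exactly when 0 falls outside the CI.
#'
#' @param curve_comparator `km_curve` of the comparator arm (CRT-P).
#' @param curve_treatment `km_curve` of the treatment arm (CRT-D).
#' @param horizons Numeric horizons in years.
#' @return A data frame with `horizon`, `arr`, `ci_lo`, `ci_hi`,
#'   `significant`, `available`. Horizons beyond either curve's support are
#'   flagged unavailable with `NA` values.
#' @export
arr_table <- function(curve_comparator, curve_treatment, horizons) {
  sA <- km_at(curve_comparator, horizons, "surv")
  sB <- km_at(curve_treatment, horizons, "surv")
  vA <- km_at(curve_comparator, horizons, "var")
  vB <- km_at(curve_treatment, horizons, "var")
  arr <- ((1 - sA) - (1 - sB)) * 100
  se <- sqrt(vA + vB) * 100
  z <- stats::qnorm(0.975)
  lo <- arr - z * se
  hi <- arr + z * se
  avail <- !is.na(arr)
  data.frame(
    horizon = horizons, arr = arr, ci_lo = lo, ci_hi = hi,
    significant = ifelse(avail, lo > 0 | hi < 0, NA),
    available = avail
  )
}

#' Two-group log-rank test
#'
#' @param time_a,event_a Times and event flags of arm A.
#' @param time_b,event_b Times and event flags of arm B.
#' @return A list with `statistic` (chi-square, 1 df) and `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) >= 1, length(time_b) >= 1)
  time <- c(time_a, time_b)
  event <- as.integer(c(event_a, event_b))
  arm <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm)
  stat <- sd$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron tie correction; Wald 95%
#' confidence intervals and p-values. Covariates that are constant are
#' dropped with a note and do not disturb the remaining estimates.
#' Non-convergence or separation (divergent coefficients) raises an error
#' with diagnostics.
#'
#' @param time Positive follow-up times.
#' @param event Event flags.
#' @param covariates Data frame of numeric covariates (no missing values).
#' @return An object of class `cox_result`: a data frame `coefficients`
#'   with `term`, `coef`, `hr`, `ci_lo`, `ci_hi`, `se`, `p`; plus `loglik`,
#'   `n`, `events`, `dropped` (constant covariates) and `converged`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates)) {
    stop("cox_fit requires complete covariates; only fully observed features enter the models")
  }
  keep <- vapply(covariates, function(x) length(unique(x)) > 1, logical(1))
  dropped <- names(covariates)[!keep]
  covariates <- covariates[keep]
  if (ncol(covariates) == 0) stop("no non-constant covariates to fit")
  dat <- cbind(data.frame(.time = time, .event = as.integer(event)),
               covariates)
  f <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")
  ))
  fit <- survival::coxph(f, data = dat, ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(abs(beta) > 15)) {
    stop(sprintf(
      "cox_fit did not converge (possible separation); coefficients: %s",
      paste(sprintf("%s=%.3g", names(beta), beta), collapse = ", ")
    ))
  }
  z <- stats::qnorm(0.975)
  structure(
    list(
      coefficients = data.frame(
        term = names(beta), coef = unname(beta), hr = exp(unname(beta)),
        ci_lo = exp(unname(beta) - z * se), ci_hi = exp(unname(beta) + z * se),
        se = unname(se),
        p = 2 * stats::pnorm(-abs(unname(beta) / se)),
        stringsAsFactors = FALSE
      ),
      loglik = fit$loglik[length(fit$loglik)],
      n = fit$n, events = fit$nevent,
      dropped = dropped,
      converged = TRUE
    ),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d\n", x$n, x$events))
  print(x$coefficients, row.names = FALSE, digits = 3)
  if (length(x$dropped)) {
    cat("dropped constant covariates:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Device-effect Cox models for one patient set
#'
#' Fits the univariable (device only) and multivariable device-effect
#' models. Two adjustment sets are supported: `"af"` adjusts for age, sex,
#' atrial-fibrillation history, and ventricular-arrhythmia history (the
#' default), `"etiology"` swaps atrial fibrillation for ischemic etiology.
#'
#' @param records Survival records carrying `device` plus covariate columns
#'   `age`, `sex`, `af`, `va`, and `ischemic` as generated by
#'   [generate_cohort()].
#' @param spec An [endpoint_spec()].
#' @param adjustment `"af"`, `"etiology"`, or `"none"` (univariable only).
#' @return A list with `univariable` and (unless `"none"`) `multivariable`
#'   `cox_result`s; the device term is `crtd`.
#' @export
device_cox <- function(records, spec = endpoint_spec("all_cause_death"),
                       adjustment = c("af", "etiology", "none")) {
  adjustment <- match.arg(adjustment)
  te <- apply_endpoint(records, spec)
  crtd <- as.integer(records$device == "CRT-D")
  uni <- cox_fit(te$time, te$event, data.frame(crtd = crtd))
  out <- list(univariable = uni)
  if (adjustment != "none") {
    extra <- if (adjustment == "af") c("age", "sex", "af", "va") else
      c("age", "sex", "ischemic", "va")
    missing_cols <- setdiff(extra, names(records))
    if (length(missing_cols)) {
      stop(sprintf("records lack adjustment covariates: %s",
                   paste(missing_cols, collapse = ", ")))
    }
    covs <- cbind(data.frame(crtd = crtd), records[extra])
    out$multivariable <- cox_fit(te$time, te$event, covs)
  }
  out
}
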