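#' Kaplan-Meier product-limit curve
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event indicators (1 = event, 0 = censored).
#' @return List with `time` (unique observed times, increasing), `surv`
#'   (product-limit estimate, non-increasing), `n_risk`, `n_event`.
#' @export
km_fit <- function(times, events) {
  if (any(times < 0)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (sum(events) == 0) warning("no events: survival curve is flat at 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  list(time = fit$time, surv = fit$surv,
       n_risk = fit$n.risk, n_event = fit$n.event)
}

#' Log-rank test across groups
#'
#' @param times,events As in [km_fit()].
#' @param groups Group labels (>= 2 distinct values).
#' @return List with `chi2`, `df` (groups - 1), `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("log-rank test needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards model
#'
#' Breslow-tie Newton fit of overall survival on a set of clinical-table
#' covariates. Categorical covariates are dummy-coded against an explicit
#' reference level.
#'
#' @param clinical `data.frame` with `os_time`, `os_event` and the covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param ref_levels Optional named list giving the reference level of each
#'   categorical covariate (e.g. `list(subtype = "LH")`).
#' @return List with `coefficients` (data.frame: term, beta, hr, se, p),
#'   `loglik`, `n`, `n_event`, and the underlying `coxph` fit.
#' @export
cox_multivariate <- function(clinical, covariates, ref_levels = list()) {
  missing_cols <- setdiff(covariates, names(clinical))
  if (length(missing_cols))
    stop("covariate column(s) missing: ", paste(missing_cols, collapse = ", "))
  if (sum(clinical$os_event) < length(covariates))
    stop("fewer events than covariates: model not identifiable")
  dat <- clinical
  for (cv in covariates) {
    v <- dat[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- as.factor(v)
      if (!is.null(ref_levels[[cv]])) v <- stats::relevel(v, ref_levels[[cv]])
      dat[[cv]] <- v
    } else if (stats::sd(v) == 0) {
      stop("constant covariate: ", cv)
    }
  }
  fml <- stats::as.formula(paste("survival::Surv(os_time, os_event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "breslow"),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w)))
  s <- summary(fit)
  co <- s$coefficients
  list(coefficients = data.frame(term = rownames(co),
                                 beta = co[, "coef"],
                                 hr = co[, "exp(coef)"],
                                 se = co[, "se(coef)"],
                                 p = co[, "Pr(>|z|)"],
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
       loglik = fit$loglik[2L], n = s$n, n_event = s$nevent, fit = fit)
}

#' Harrell's concordance index
#'
#' Fraction of usable (comparable) pairs in which the sample with the higher
#' risk score fails earlier; tied risk scores count 1/2.
#'
#' @param risk Per-sample risk scores (higher = worse expected survival).
#' @param times,events As in [km_fit()].
#' @return Scalar concordance in [0, 1].
#' @export
c_index <- function(risk, times, events) {
  cf <- survival::concordance(survival::Surv(times, events) ~ risk,
                              reverse = TRUE)
  counts <- cf$count
  if (counts[["concordant"]] + counts[["discordant"]] + counts[["tied.x"]] == 0)
    stop("no comparable pairs")
  unname(cf$concordance)
}

#' Restricted mean survival time of each group
#'
#' Area under each group's Kaplan-Meier curve up to a common horizon; a
#' simple scalar summary for ordering groups by survival.
#'
#' @param times,events As in [km_fit()].
#' @param groups Group labels.
#' @param tau Horizon; defaults to the largest time observed in every group.
#' @return Named numeric vector of per-group restricted means.
#' @export
rmst_by_group <- function(times, events, groups, tau = NULL) {
  groups <- as.factor(groups)
  if (is.null(tau))
    tau <- min(tapply(times, groups, max))
  vapply(levels(groups), function(g) {
    sel <- groups == g
    km <- km_fit(times[sel], events[sel])
    tt <- c(0, km$time[km$time <= tau], tau)
    ss <- c(1, km$surv[km$time <= tau], NA)
    sum(diff(tt) * ss[-length(ss)])
  }, numeric(1L))
}
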