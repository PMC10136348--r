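#' Kaplan-Meier estimate with median and log-log confidence interval
#'
#' Product-limit estimation of overall survival; simultaneous deaths are
#' processed before censorings at tied times. The median is the smallest
#' time at which the survival estimate drops to 0.5 or below; its 95 %
#' confidence interval uses the complementary log-log transform.
#'
#' @param records `data.frame` with columns `time` (positive) and `event`
#'   (0/1).
#' @return a list of class `km_result`: `median_months` (`Inf` when the
#'   curve never reaches 0.5), `ci_low`, `ci_high`, `n`, `n_events`, and
#'   `curve` (a `data.frame` of `(time, surv)` at event times).
#' @export
km_estimate <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no records supplied")
  if (any(records$time <= 0)) stop("survival times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  structure(list(
    median_months = if (is.na(med)) Inf else med,
    ci_low = unname(tab["0.95LCL"]),
    ci_high = unname(tab["0.95UCL"]),
    n = nrow(records),
    n_events = sum(records$event),
    curve = data.frame(time = fit$time, surv = fit$surv,
                       lower = fit$lower, upper = fit$upper),
    fit = fit
  ), class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> n=%d, events=%d, median %s months (95%% CI %s-%s)\n",
              x$n, x$n_events,
              if (is.finite(x$median_months)) format(x$median_months) else "not reached",
              format(x$ci_low), format(x$ci_high)))
  invisible(x)
}

build_cox_formula <- function(covariates, center_adjustment) {
  rhs <- covariates
  if (center_adjustment == "stratified") rhs <- c(rhs, "strata(center)")
  if (center_adjustment == "fixed_effects") rhs <- c(rhs, "factor(center)")
  stats::reformulate(rhs, response = quote(survival::Surv(time, event)))
}

#' Centre-adjusted Cox regression with robust standard errors
#'
#' Partial-likelihood fit (Efron tie handling by default) with the baseline
#' hazard either stratified by centre (default) or with centre indicator
#' terms, and sandwich standard errors clustered by centre. Confidence
#' intervals are `exp(coef -/+ 1.96 * robust SE)`; p-values are two-sided
#' Wald.
#'
#' @param records cohort `data.frame` with `time`, `event`, `center` and the
#'   covariate columns.
#' @param covariates character vector of covariate names to fit jointly.
#' @param center_adjustment `"stratified"` or `"fixed_effects"`.
#' @param ties tie method passed to [survival::coxph()] (default `"efron"`).
#' @param robust sandwich variance estimation (default `TRUE`).
#' @param cluster clustering unit for the sandwich variance: `"center"`
#'   (default; the plausible unit for a multicentre analysis) or
#'   `"subject"` (each record its own unit).
#' @return a `data.frame` of class `cox_result` with one row per requested
#'   covariate: `covariate`, `coef`, `hr`, `robust_se`, `ci_low`, `ci_high`,
#'   `p`, `n`, `n_events`. The underlying `coxph` fit is attached as
#'   attribute `"fit"`.
#' @export
cox_fit <- function(records, covariates,
                    center_adjustment = c("stratified", "fixed_effects"),
                    ties = "efron", robust = TRUE,
                    cluster = c("center", "subject")) {
  center_adjustment <- match.arg(center_adjustment)
  cluster <- match.arg(cluster)
  if (length(covariates) == 0L) stop("at least one covariate is required")
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov)) {
    stop(sprintf("covariate(s) not present: %s", paste(missing_cov, collapse = ", ")))
  }
  for (nm in covariates) {
    if (length(unique(records[[nm]])) < 2L) {
      stop(sprintf("covariate '%s' is constant and not identifiable", nm))
    }
  }
  if (length(unique(records$time[records$event == 1])) < 2L) {
    stop("at least two distinct event times are required")
  }
  f <- build_cox_formula(covariates, center_adjustment)
  ctl <- survival::coxph.control(eps = 1e-9, iter.max = 50)
  fit <- if (robust && cluster == "center") {
    survival::coxph(f, data = records, ties = ties, control = ctl,
                    cluster = center, x = FALSE, y = FALSE)
  } else if (robust) {
    survival::coxph(f, data = records, ties = ties, control = ctl,
                    robust = TRUE, x = FALSE, y = FALSE)
  } else {
    survival::coxph(f, data = records, ties = ties, control = ctl,
                    x = FALSE, y = FALSE)
  }
  co <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  names(se) <- names(co)
  keep <- intersect(names(co), covariates)
  z <- co[keep] / se[keep]
  out <- data.frame(
    covariate = keep,
    coef = unname(co[keep]),
    hr = unname(exp(co[keep])),
    robust_se = unname(se[keep]),
    ci_low = unname(exp(co[keep] - 1.96 * se[keep])),
    ci_high = unname(exp(co[keep] + 1.96 * se[keep])),
    p = unname(2 * stats::pnorm(-abs(z))),
    n = fit$n,
    n_events = fit$nevent,
    stringsAsFactors = FALSE
  )
  attr(out, "fit") <- fit
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Univariate Cox screen over a covariate list
#'
#' Fits one centre-adjusted model per covariate and binds the rows — the
#' layout of a univariate analysis table.
#'
#' @inheritParams cox_fit
#' @return a `cox_result` data frame with one row per covariate.
#' @export
cox_univariate_table <- function(records, covariates,
                                 center_adjustment = "stratified",
                                 ties = "efron") {
  rows <- lapply(covariates, function(nm) {
    cox_fit(records, nm, center_adjustment = center_adjustment, ties = ties)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Forward stepwise model selection by AIC
#'
#' Starts from the null (centre-stratified) model and at each step adds the
#' candidate covariate that minimises `AIC = -2 * partial log-likelihood +
#' 2k`, stopping when no addition lowers the AIC. Ties are broken by
#' candidate order. Candidates whose fit fails are recorded and skipped.
#'
#' @param records cohort `data.frame`.
#' @param candidate_covariates character vector (may be empty: null model).
#' @param center_adjustment `"stratified"` or `"fixed_effects"`.
#' @param ties tie method for the underlying fits.
#' @return a list of class `model_selection`: `selected` (in entry order),
#'   `trajectory` (`data.frame` of step, covariate entered, AIC),
#'   `aic_null`, `final` (a [cox_fit()] result, `NULL` for the null model)
#'   and `failed` (named list of fit errors).
#' @export
stepwise_aic <- function(records, candidate_covariates,
                         center_adjustment = c("stratified", "fixed_effects"),
                         ties = "efron") {
  center_adjustment <- match.arg(center_adjustment)
  ctl <- survival::coxph.control(eps = 1e-9, iter.max = 50)
  fit_ll <- function(covs) {
    f <- build_cox_formula(covs, center_adjustment)
    fit <- suppressWarnings(
      survival::coxph(f, data = records, ties = ties, control = ctl))
    co <- stats::coef(fit)
    if (any(!is.finite(co))) {
      stop(sprintf("covariate '%s' is not identifiable in this model",
                   paste(names(co)[!is.finite(co)], collapse = ", ")))
    }
    ll <- fit$loglik
    list(aic = -2 * ll[length(ll)] + 2 * length(co), ll0 = ll[1])
  }
  failed <- list()
  selected <- character(0)
  if (length(candidate_covariates) == 0L) {
    return(structure(list(selected = character(0),
                          trajectory = data.frame(step = integer(0),
                                                  covariate = character(0),
                                                  aic = numeric(0)),
                          aic_null = NA_real_, final = NULL, failed = failed),
                     class = "model_selection"))
  }
  # null partial log-likelihood shared by all nested fits
  probe <- NULL
  for (nm in candidate_covariates) {
    probe <- tryCatch(fit_ll(nm), error = function(e) NULL)
    if (!is.null(probe)) break
  }
  if (is.null(probe)) stop("no candidate covariate could be fitted")
  aic_cur <- -2 * probe$ll0
  aic_null <- aic_cur
  remaining <- candidate_covariates
  traj <- data.frame(step = integer(0), covariate = character(0), aic = numeric(0))
  repeat {
    best <- NULL
    for (nm in remaining) {
      res <- tryCatch(fit_ll(c(selected, nm)), error = function(e) e)
      if (inherits(res, "error")) {
        failed[[nm]] <- conditionMessage(res)
        next
      }
      if (is.null(best) || res$aic < best$aic) best <- list(name = nm, aic = res$aic)
    }
    if (is.null(best) || best$aic >= aic_cur) break
    selected <- c(selected, best$name)
    remaining <- setdiff(remaining, c(best$name, names(failed)))
    aic_cur <- best$aic
    traj <- rbind(traj, data.frame(step = length(selected),
                                   covariate = best$name, aic = best$aic))
    if (length(remaining) == 0L) break
  }
  final <- if (length(selected)) {
    cox_fit(records, selected, center_adjustment = center_adjustment, ties = ties)
  } else NULL
  structure(list(selected = selected, trajectory = traj, aic_null = aic_null,
                 final = final, failed = failed),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  if (length(x$selected) == 0L) {
    cat("<model_selection> null model retained\n")
  } else {
    cat("<model_selection> entered:", paste(x$selected, collapse = " -> "), "\n")
    print(x$trajectory, row.names = FALSE)
  }
  invisible(x)
}
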