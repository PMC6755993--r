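#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`. A group with
#' no events yields a flat curve at 1 with a warning.
#'
#' @param time Nonnegative follow-up times (months).
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A data.frame (class `km_curve`): `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` at each distinct observed time.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0, 1)))
  if (!any(event == 1)) warning("all observations censored: survival curve is flat at 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test between groups
#'
#' Accumulates observed and (hypergeometric) expected events per group across
#' distinct event times; for two groups the statistic is
#' `(O1 - E1)^2 / V` with 1 degree of freedom.
#'
#' @param time,event Survival times and event indicators.
#' @param group Group labels (>= 2 non-empty groups).
#' @return A list (class `logrank_result`): `chi_square`, `df`, `p_value`,
#'   `observed`, `expected`, `variance` (for 2 groups, the variance of
#'   O1 - E1).
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) < 2 || any(table(g) == 0)) {
    stop_validation("need >= 2 non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(g) - 1
  chi <- unname(sd$chisq)
  structure(
    list(chi_square = chi, df = df,
         p_value = pchisq(chi, df, lower.tail = FALSE),
         observed = setNames(as.numeric(sd$obs), levels(g)),
         expected = setNames(as.numeric(sd$exp), levels(g)),
         variance = if (df == 1) sd$var[1, 1] else sd$var),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi^2 = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Stratify samples by cohort-mean expression
#'
#' The stratification used for the survival figures: `high` when a sample's
#' expression strictly exceeds the cohort mean, `low` otherwise (values equal
#' to the mean go to `low`). A constant vector yields all-low with a warning.
#'
#' @param values Numeric vector of per-sample expression.
#' @param sample_ids Optional names for the returned labels.
#' @return Factor with levels `low`, `high`.
#' @export
stratify_by_mean <- function(values, sample_ids = NULL) {
  if (length(values) < 2) stop_validation("need >= 2 samples to stratify")
  if (length(unique(values)) == 1) {
    warning("constant expression: all samples stratified to 'low'")
  }
  lab <- factor(ifelse(values > mean(values), "high", "low"),
                levels = c("low", "high"))
  if (!is.null(sample_ids)) names(lab) <- sample_ids
  lab
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Newton-Raphson maximization of the Breslow partial likelihood via the
#' survival package, reporting hazard ratios with 95% confidence intervals.
#' A monotone likelihood (a coefficient escaping beyond 10 in absolute
#' value) is flagged as non-convergence and no hazard ratio is reported for
#' that fit.
#'
#' @param time,event Survival times and event indicators (>= 1 event).
#' @param covariates Data.frame of finite numeric covariates (no constant
#'   column). A single-column frame gives a univariate fit.
#' @return A list (class `cox_fit`): `table` (term, beta, hr, se, ci_lower,
#'   ci_upper, p_value), `loglik` (log partial likelihood at the optimum),
#'   `converged`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (sum(event) < 1) stop_validation("need at least one event")
  if (!all(vapply(covariates, function(v) all(is.finite(v)), logical(1)))) {
    stop_validation("covariates must be finite")
  }
  constant <- vapply(covariates, function(v) length(unique(v)) == 1, logical(1))
  if (any(constant)) {
    stop_validation("constant covariate(s): %s",
                    paste(names(covariates)[constant], collapse = ", "))
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  converged <- all(abs(beta) <= 10) && all(is.finite(se))
  tab <- data.frame(
    term = names(covariates),
    beta = unname(beta),
    hr = if (converged) exp(unname(beta)) else NA_real_,
    se = unname(se),
    ci_lower = if (converged) exp(unname(beta) - 1.96 * unname(se)) else NA_real_,
    ci_upper = if (converged) exp(unname(beta) + 1.96 * unname(se)) else NA_real_,
    p_value = 2 * pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE
  )
  if (!converged) warning("monotone likelihood suspected: fit flagged as non-converged")
  structure(list(table = tab, loglik = fit$loglik[2], converged = converged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s):\n", if (x$converged) "converged" else "NOT converged"))
  print(x$table)
  invisible(x)
}
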