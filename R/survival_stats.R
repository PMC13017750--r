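#' Two-group log-rank test
#'
#' Standard log-rank statistic over the distinct event times (observed minus
#' expected under the hypergeometric law, normalized by its variance),
#' referred to a chi-square distribution with 1 degree of freedom.
#'
#' @param ipd an `ipd_dataset` containing both groups.
#' @param group_a,group_b arm labels to compare.
#' @return A list with `chi2` and `p`.
#' @export
logrank_test <- function(ipd, group_a, group_b) {
  d <- subset_two_groups(ipd, group_a, group_b)
  if (sum(d$event) == 0)
    stop("no events in either group; log-rank test undefined", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = d)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Two-group Cox proportional-hazards comparison
#'
#' Maximizes the two-group Cox partial likelihood (Efron tie correction by
#' default; reconstruction places events on a grid, so ties are common) and
#' returns the hazard ratio of `group_a` relative to `group_b` with a Wald
#' 95% confidence interval and two-sided Wald p-value, plus the log-rank
#' test and the additivity classification. In the intended use `group_a` is
#' the observed combination cohort and `group_b` the cohort reconstructed
#' from the independent-action prediction, so HR < 1 favors the observed arm.
#'
#' The 97.5% normal quantile is fixed at 1.959964 so the confidence bounds
#' satisfy `exp(log(hr) +/- 1.959964 * se_log_hr)` exactly.
#'
#' @inheritParams logrank_test
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return A `comparison_result`: `hr`, `ci_low`, `ci_high`, `se_log_hr`,
#'   `logrank_chi2`, `p_cox`, `p_logrank`, `classification`, `n_obs`,
#'   `n_pred`, `events_obs`, `events_pred` (the `_obs` fields refer to
#'   `group_a`, the `_pred` fields to `group_b`).
#' @export
cox_fit <- function(ipd, group_a, group_b, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  d <- subset_two_groups(ipd, group_a, group_b)
  ev_a <- sum(d$event[d$arm == group_a])
  ev_b <- sum(d$event[d$arm == group_b])
  if (ev_a == 0 || ev_b == 0)
    stop("each group needs at least one event for a finite hazard-ratio ",
         "estimate", call. = FALSE)
  d$arm <- factor(d$arm, levels = c(group_b, group_a))  # group_b = reference

  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ arm, data = d, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (monotone || !is.finite(beta) || !is.finite(se))
    stop("hazard ratio non-estimable: monotone partial likelihood ",
         "(all events in one group precede the other's at-risk overlap)",
         call. = FALSE)

  z <- 1.959964
  hr <- exp(beta)
  ci_low <- exp(beta - z * se)
  ci_high <- exp(beta + z * se)
  lr <- logrank_test(ipd, group_a, group_b)

  structure(list(
    hr = hr, ci_low = ci_low, ci_high = ci_high, se_log_hr = se,
    logrank_chi2 = lr$chi2,
    p_cox = 2 * stats::pnorm(-abs(beta / se)), p_logrank = lr$p,
    classification = classify_interaction(hr, ci_low, ci_high),
    ties = ties,
    n_obs = sum(d$arm == group_a), n_pred = sum(d$arm == group_b),
    events_obs = ev_a, events_pred = ev_b,
    group_a = group_a, group_b = group_b),
    class = "comparison_result")
}

subset_two_groups <- function(ipd, group_a, group_b) {
  stopifnot(is.data.frame(ipd), all(c("time", "event", "arm") %in% names(ipd)))
  for (g in c(group_a, group_b))
    if (!any(ipd$arm == g))
      stop("group '", g, "' absent from the dataset", call. = FALSE)
  ipd[ipd$arm %in% c(group_a, group_b), , drop = FALSE]
}

#' Classify a combination effect against the additive expectation
#'
#' Decision rule on the observed-vs-predicted hazard ratio: an HR below 1
#' with a 95% CI excluding 1 indicates a greater-than-additive (synergistic)
#' effect; an HR above 1 with a CI excluding 1 indicates a less-than-additive
#' effect; a CI crossing 1 is consistent with additivity.
#'
#' @param hr hazard ratio (> 0).
#' @param ci_low,ci_high 95% confidence bounds, `0 < ci_low <= hr <= ci_high`.
#' @return One of `"greater_than_additive"`, `"consistent_with_additive"`,
#'   `"less_than_additive"`.
#' @export
classify_interaction <- function(hr, ci_low, ci_high) {
  if (!(is.finite(hr) && is.finite(ci_low) && is.finite(ci_high)))
    stop("non-finite hazard ratio or confidence bound", call. = FALSE)
  if (ci_low <= 0 || ci_low > hr + 1e-12 || hr > ci_high + 1e-12)
    stop("inverted or invalid confidence bounds: require 0 < ci_low <= hr ",
         "<= ci_high", call. = FALSE)
  if (ci_high < 1) "greater_than_additive"
  else if (ci_low > 1) "less_than_additive"
  else "consistent_with_additive"
}

#' @export
print.comparison_result <- function(x, digits = 3, ...) {
  cat("Observed ('", x$group_a, "') vs predicted ('", x$group_b,
      "') comparison\n", sep = "")
  cat(sprintf("  HR %.*f, 95%% CI %.*f-%.*f (Wald, %s ties), P = %.3g\n",
              digits, x$hr, digits, x$ci_low, digits, x$ci_high, x$ties,
              x$p_cox))
  cat(sprintf("  log-rank chi2 = %.*f, P = %.3g\n", digits, x$logrank_chi2,
              x$p_logrank))
  cat("  classification: ", x$classification, "\n", sep = "")
  cat(sprintf("  n = %d vs %d; events = %d vs %d\n", x$n_obs, x$n_pred,
              x$events_obs, x$events_pred))
  invisible(x)
}
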