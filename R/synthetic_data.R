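#' Simulation scenario for a two-trial synergy analysis
#'
#' Describes the generative model used to validate the pipeline: two parallel
#' randomized trials with exponential event times. Trial 1 contributes the
#' combination arm (hazard `psi * (lambda_A + lambda_B - lambda_control)`)
#' and doublet A (hazard `lambda_A`); trial 2 contributes doublet B (hazard
#' `lambda_B`) and its control (hazard `lambda_control`). Under exponential
#' hazards the independent-action product formula has an exact closed form:
#' the additive null is the exponential with hazard
#' `lambda_A + lambda_B - lambda_control`, so the synergy multiplier `psi` is
#' exactly the hazard ratio of the simulated combination arm against the
#' prediction (`psi = 1`: additive; `psi < 1`: synergistic). Subjects are
#' censored by an independent exponential process at `censor_rate` and
#' administratively at `censor_admin_time` months after study start
#' (optionally with uniform staggered accrual over `accrual_months`).
#'
#' Default rates are of the order seen in metastatic castration-sensitive
#' prostate cancer trials of ADT backbones (control median survival around
#' 8-9 months per 0.08/month here corresponds to an aggressive population;
#' treatment arms at 0.04-0.05/month), with 6-monthly risk tables and about
#' 25 digitized coordinates per curve, mirroring how such figures are
#' published and extracted.
#'
#' @param lambda_control control-arm event hazard per month.
#' @param lambda_A doublet A event hazard per month.
#' @param lambda_B doublet B event hazard per month.
#' @param psi synergy multiplier (> 0) on the additive combination hazard.
#' @param n_per_arm subjects per arm (>= 10).
#' @param censor_admin_time administrative censoring time, months.
#' @param censor_rate hazard per month of random (dropout) censoring; 0
#'   disables it.
#' @param accrual_months uniform accrual window, months (0 = simultaneous
#'   entry); administrative censoring applies `censor_admin_time` months
#'   after study start, i.e. at `censor_admin_time - entry` of follow-up.
#' @param risk_table_step spacing of the emulated published risk table,
#'   months.
#' @param n_coordinates number of curve coordinates the emulated digitization
#'   extracts (>= 10).
#' @param seed master integer seed; per-arm streams are derived from it.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(lambda_control = 0.08, lambda_A = 0.05,
                                lambda_B = 0.04, psi = 1, n_per_arm = 700,
                                censor_admin_time = 60, censor_rate = 0.005,
                                accrual_months = 0, risk_table_step = 6,
                                n_coordinates = 25, seed = 1L) {
  if (any(c(lambda_control, lambda_A, lambda_B) <= 0))
    stop("all hazards must be positive", call. = FALSE)
  if (lambda_A + lambda_B - lambda_control <= 0)
    stop("lambda_A + lambda_B - lambda_control must be positive; otherwise ",
         "the additive model implies an improper survival function",
         call. = FALSE)
  if (psi <= 0) stop("psi must be positive", call. = FALSE)
  if (n_per_arm < 10) stop("n_per_arm must be at least 10", call. = FALSE)
  if (censor_admin_time <= 0 || censor_rate < 0 || accrual_months < 0)
    stop("invalid censoring specification", call. = FALSE)
  if (accrual_months >= censor_admin_time)
    stop("accrual window must end before administrative censoring",
         call. = FALSE)
  if (risk_table_step <= 0) stop("risk_table_step must be > 0", call. = FALSE)
  if (n_coordinates < 10) stop("n_coordinates must be >= 10", call. = FALSE)
  structure(list(lambda_control = lambda_control, lambda_A = lambda_A,
                 lambda_B = lambda_B, psi = psi,
                 n_per_arm = as.integer(n_per_arm),
                 censor_admin_time = censor_admin_time,
                 censor_rate = censor_rate, accrual_months = accrual_months,
                 risk_table_step = risk_table_step,
                 n_coordinates = as.integer(n_coordinates),
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("Two-trial simulation scenario\n")
  cat(sprintf("  hazards/month: control %.4g, doublet A %.4g, doublet B %.4g\n",
              x$lambda_control, x$lambda_A, x$lambda_B))
  cat(sprintf("  combination: psi = %.3g x additive hazard %.4g = %.4g\n",
              x$psi, x$lambda_A + x$lambda_B - x$lambda_control,
              x$psi * (x$lambda_A + x$lambda_B - x$lambda_control)))
  cat(sprintf("  n = %d/arm; admin censor %g mo, dropout %.4g/mo, accrual %g mo\n",
              x$n_per_arm, x$censor_admin_time, x$censor_rate,
              x$accrual_months))
  cat(sprintf("  risk table every %g mo; %d digitized coordinates; seed %d\n",
              x$risk_table_step, x$n_coordinates, x$seed))
  invisible(x)
}

#' Simulate the two-trial arm structure
#'
#' Draws the four arms (control, doublet A, doublet B, combination) as
#' individual-patient datasets. Each arm uses its own random stream derived
#' from the master seed, so one arm's draws are reproducible even if another
#' arm's size changes.
#'
#' @param scenario a [simulation_scenario].
#' @return A named list of four `ipd_dataset`s (`control`, `doublet_A`,
#'   `doublet_B`, `combination`) with attribute `truth` holding the arm
#'   hazards, `psi` and the true observed-vs-predicted hazard ratio (= `psi`).
#' @export
simulate_trials <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  hz <- c(control = scenario$lambda_control,
          doublet_A = scenario$lambda_A,
          doublet_B = scenario$lambda_B,
          combination = scenario$psi *
            (scenario$lambda_A + scenario$lambda_B - scenario$lambda_control))
  set.seed(scenario$seed)
  arm_seeds <- sample.int(.Machine$integer.max - 1L, length(hz))
  out <- vector("list", length(hz))
  names(out) <- names(hz)
  for (k in seq_along(hz)) {
    set.seed(arm_seeds[k])
    n <- scenario$n_per_arm
    ev <- stats::rexp(n, rate = hz[k])
    entry <- if (scenario$accrual_months > 0)
      stats::runif(n, 0, scenario$accrual_months) else rep(0, n)
    admin <- scenario$censor_admin_time - entry
    drop <- if (scenario$censor_rate > 0)
      stats::rexp(n, rate = scenario$censor_rate) else rep(Inf, n)
    cens <- pmin(admin, drop)
    d <- data.frame(time = pmin(ev, cens),
                    event = as.integer(ev <= cens),
                    arm = names(hz)[k], stringsAsFactors = FALSE)
    class(d) <- c("ipd_dataset", "data.frame")
    out[[k]] <- d
  }
  attr(out, "truth") <- list(hazards = hz, psi = scenario$psi,
                             true_hr_vs_predicted = scenario$psi)
  out
}

#' Emulate figure digitization of a simulated arm
#'
#' Computes the arm's exact Kaplan-Meier step function, samples coordinates
#' from it the way a curve is digitized from a published figure (all drop
#' points when there are few, otherwise points evenly spaced in time plus all
#' risk-table times and the end of follow-up), optionally adds truncated
#' normal vertical jitter (monotone repair happens downstream, as for real
#' digitized data), and tabulates the true at-risk counts at multiples of
#' `risk_table_step`.
#'
#' @param ipd one arm's `ipd_dataset`.
#' @param n_coordinates number of coordinates to sample (>= 10).
#' @param risk_table_step risk-table spacing in months.
#' @param jitter_sd standard deviation of vertical jitter on the survival
#'   scale (0 = exact coordinates); jittered values are truncated to \[0, 1\]
#'   and the origin stays at 1.
#' @param seed optional seed for the jitter stream.
#' @param arm_label label for the coordinates; defaults to the arm in `ipd`.
#' @return A list with elements `coordinates` ([km_coordinates]) and
#'   `risk_table` ([risk_table]).
#' @export
digitize_like <- function(ipd, n_coordinates = 25, risk_table_step = 6,
                          jitter_sd = 0, seed = NULL, arm_label = NULL) {
  stopifnot(is.data.frame(ipd), nrow(ipd) > 0)
  if (n_coordinates < 10) stop("n_coordinates must be >= 10", call. = FALSE)
  if (is.null(arm_label)) arm_label <- unique(ipd$arm)[1]
  fit <- km_estimate(ipd, arm_label = arm_label)
  t_end <- max(ipd$time[ipd$arm == arm_label])
  rt_times <- seq(0, t_end + 1e-9, by = risk_table_step)
  rt_times <- rt_times[rt_times <= t_end + 1e-9]
  drops <- fit$time[-1][diff(fit$surv) < 0]
  ct <- if (length(drops) <= n_coordinates)
    sort(unique(c(0, drops, rt_times, t_end)))
  else
    sort(unique(c(seq(0, t_end, length.out = n_coordinates), rt_times, t_end)))
  sv <- km_survival_at(fit, ct)
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sv <- pmin(pmax(sv + stats::rnorm(length(sv), 0, jitter_sd), 0), 1)
    sv[ct == 0] <- 1
  }
  n_risk <- n_at_risk(ipd, rt_times, arm_label = arm_label)
  list(coordinates = km_coordinates(ct, sv, arm_label = arm_label),
       risk_table = risk_table(rt_times, n_risk))
}
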