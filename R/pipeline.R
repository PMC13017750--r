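#' End-to-end observed-vs-predicted analysis from digitized curves
#'
#' Runs the full chain on in-memory objects: monotone repair of the four
#' digitized curves, interpolation onto a common grid (extent = the shortest
#' curve's follow-up), independent-action prediction from doublet A, doublet
#' B and control, reconstruction of individual patient data for the observed
#' combination cohort (from its own risk table) and for the predicted cohort
#' (risk table borrowed from doublet A, see [borrow_risk_table()]), and the
#' log-rank / Cox comparison with the additivity classification.
#'
#' @param coords_combination,coords_doublet_a,coords_doublet_b,coords_control
#'   [km_coordinates] for the four arms; doublet A is the combination's
#'   same-trial comparator.
#' @param rt_combination [risk_table] of the observed combination arm.
#' @param rt_doublet_a [risk_table] of doublet A (lends its censoring pattern
#'   to the predicted cohort).
#' @param grid_step common grid step, months.
#' @param epsilon control-survival floor for the prediction.
#' @param ties Cox tie-handling method.
#' @param total_events_observed,total_events_predicted optional published /
#'   assumed event totals for the two reconstructed cohorts.
#' @param endpoint label carried into the report (e.g. `"OS"`).
#' @param out_dir optional directory; when given, the results JSON, both IPD
#'   CSVs, the predicted-curve CSV and an observed-vs-predicted plot (PNG)
#'   are written there.
#' @return An object of class `ida_analysis`: list with `result`
#'   (`comparison_result`), `prediction` (`ida_prediction`), `curves`,
#'   `ipd` (both cohorts), `metadata` (grid step, epsilon, truncation time,
#'   clamp and monotone-repair counts, risk-table provenance).
#' @export
ida_analysis <- function(coords_combination, coords_doublet_a,
                         coords_doublet_b, coords_control,
                         rt_combination, rt_doublet_a,
                         grid_step = 0.5, epsilon = 0.01,
                         ties = "efron",
                         total_events_observed = NULL,
                         total_events_predicted = NULL,
                         endpoint = "OS", out_dir = NULL) {
  coords <- list(combination = coords_combination, doublet_a = coords_doublet_a,
                 doublet_b = coords_doublet_b, control = coords_control)
  stopifnot(all(vapply(coords, inherits, logical(1), "km_coordinates")))
  mono <- lapply(coords, enforce_monotone)
  repairs <- vapply(mono, function(x) attr(x, "n_repaired"), integer(1))
  t_max <- common_t_max(mono)
  curves <- lapply(mono, interpolate_to_grid, grid_step = grid_step,
                   t_max = t_max)

  pred <- predict_independent_action(curves$doublet_a, curves$doublet_b,
                                     curves$control, epsilon = epsilon)
  pred_curve <- as_km_curve(pred, arm_label = "predicted")

  # the common grid may truncate an arm below its published risk-table extent
  rt_combination <- clip_risk_table(rt_combination,
                                    max(curves$combination$grid_times))
  ipd_obs <- reconstruct_ipd(curves$combination, risk_table = rt_combination,
                             total_events = total_events_observed,
                             arm_label = "observed")
  rt_pred <- borrow_risk_table(pred_curve, curves$doublet_a, rt_doublet_a)
  ipd_pred <- reconstruct_ipd(pred_curve, risk_table = rt_pred,
                              total_events = total_events_predicted,
                              arm_label = "predicted")
  ipd <- rbind(ipd_obs, ipd_pred)
  class(ipd) <- c("ipd_dataset", "data.frame")

  result <- cox_fit(ipd, "observed", "predicted", ties = ties)

  metadata <- list(
    endpoint = endpoint, grid_step = grid_step, epsilon = epsilon,
    t_max = t_max, truncation_time = pred$truncation_time,
    clamp_count = pred$clamp_count,
    monotone_repairs = as.list(repairs),
    predicted_risk_table = paste0(
      "borrowed from arm '", curves$doublet_a$arm_label,
      "', at-risk counts rescaled by S_pred/S_comparator"),
    arms = vapply(coords, function(x) x$arm_label, character(1)))

  out <- structure(list(result = result, prediction = pred,
                        curves = c(curves, list(predicted = pred_curve)),
                        ipd = ipd, metadata = metadata),
                   class = "ida_analysis")
  if (!is.null(out_dir)) write_analysis_artifacts(out, out_dir)
  out
}

#' @export
print.ida_analysis <- function(x, ...) {
  cat("Independent-drug-action analysis (", x$metadata$endpoint, ")\n",
      sep = "")
  cat("  grid ", format(x$metadata$grid_step), " mo to ",
      format(x$metadata$t_max), " mo; prediction truncated at ",
      format(x$metadata$truncation_time), " mo; ",
      x$metadata$clamp_count, " clamped point(s)\n", sep = "")
  print(x$result)
  invisible(x)
}

write_analysis_artifacts <- function(analysis, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ipd_csv(analysis$ipd[analysis$ipd$arm == "observed", ],
                file.path(out_dir, "ipd_observed.csv"))
  write_ipd_csv(analysis$ipd[analysis$ipd$arm == "predicted", ],
                file.path(out_dir, "ipd_predicted.csv"))
  write_km_csv(analysis$prediction, file.path(out_dir, "predicted_curve.csv"))
  write_results_json(analysis, file.path(out_dir, "results.json"))
  grDevices::png(file.path(out_dir, "km_observed_vs_predicted.png"),
                 width = 900, height = 650)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(analysis)
  invisible(out_dir)
}

#' Write the analysis report as JSON
#'
#' All comparison fields plus the analysis metadata (grid step, epsilon,
#' truncation time, clamp counts, risk-table provenance of the predicted
#' cohort), so every reported number is auditable against the exported
#' intermediate artifacts.
#'
#' @param analysis an `ida_analysis`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(analysis, path) {
  stopifnot(inherits(analysis, "ida_analysis"))
  r <- analysis$result
  payload <- list(
    hr = r$hr, ci_low = r$ci_low, ci_high = r$ci_high,
    se_log_hr = r$se_log_hr, logrank_chi2 = r$logrank_chi2,
    p_cox = r$p_cox, p_logrank = r$p_logrank,
    classification = r$classification, ties = r$ties,
    n_obs = r$n_obs, n_pred = r$n_pred,
    events_obs = r$events_obs, events_pred = r$events_pred,
    metadata = analysis$metadata)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Plot observed versus predicted Kaplan-Meier curves
#'
#' @param x an `ida_analysis`.
#' @param ... ignored.
#' @export
plot.ida_analysis <- function(x, ...) {
  obs <- km_estimate(x$ipd, "observed")
  prd <- km_estimate(x$ipd, "predicted")
  r <- x$result
  graphics::plot(NA, xlim = c(0, x$metadata$t_max), ylim = c(0, 1),
                 xlab = "Time (months)", ylab = "Survival probability",
                 main = paste0("Observed vs predicted (",
                               x$metadata$endpoint, ")"))
  graphics::lines(obs$time, obs$surv, type = "s", col = "black", lwd = 2)
  graphics::lines(prd$time, prd$surv, type = "s", col = "red", lwd = 2)
  graphics::legend("bottomleft", bty = "n", lwd = 2, col = c("black", "red"),
                   legend = c("Observed combination",
                              "Predicted (independent action)"))
  graphics::mtext(sprintf("HR %.3f (95%% CI %.3f-%.3f), P = %.3g; %s",
                          r$hr, r$ci_low, r$ci_high, r$p_cox,
                          r$classification), side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}

#' Run the analysis from a configuration
#'
#' File-based front end over [ida_analysis()]. The configuration is a named
#' list, or a path to a YAML/JSON file with the same structure:
#'
#' ```yaml
#' curves:
#'   combination: path.csv     # observed combination arm, trial 1
#'   doublet_a:   path.csv     # same-trial comparator, trial 1
#'   doublet_b:   path.csv     # treatment arm, trial 2
#'   control:     path.csv     # control arm, trial 2
#' risk_tables:
#'   combination: path.csv
#'   doublet_a:   path.csv
#' endpoint: OS
#' grid_step: 0.5
#' epsilon: 0.01
#' ties: efron
#' total_events: {observed: null, predicted: null}
#' out_dir: results/
#' ```
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return The `ida_analysis` object, invisibly; artifacts are written to
#'   `out_dir` when set.
#' @export
run_analysis <- function(config) {
  cfg <- load_analysis_config(config)
  co <- lapply(names(cfg$curves), function(nm)
    read_km_csv(cfg$curves[[nm]], arm_label = nm))
  names(co) <- names(cfg$curves)
  invisible(ida_analysis(
    co$combination, co$doublet_a, co$doublet_b, co$control,
    rt_combination = read_risk_table_csv(cfg$risk_tables$combination),
    rt_doublet_a = read_risk_table_csv(cfg$risk_tables$doublet_a),
    grid_step = cfg$grid_step, epsilon = cfg$epsilon, ties = cfg$ties,
    total_events_observed = cfg$total_events$observed,
    total_events_predicted = cfg$total_events$predicted,
    endpoint = cfg$endpoint, out_dir = cfg$out_dir))
}

load_analysis_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(endpoint = "OS", grid_step = 0.5, epsilon = 0.01,
                   ties = "efron", total_events = list(), out_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  need_curves <- c("combination", "doublet_a", "doublet_b", "control")
  for (nm in need_curves)
    if (is.null(cfg$curves[[nm]]))
      stop("config field 'curves$", nm, "' is missing", call. = FALSE)
  for (nm in c("combination", "doublet_a"))
    if (is.null(cfg$risk_tables[[nm]]))
      stop("config field 'risk_tables$", nm, "' is missing", call. = FALSE)
  for (p in c(unlist(cfg$curves), unlist(cfg$risk_tables)))
    if (!file.exists(p)) stop("config references a missing file: ", p,
                              call. = FALSE)
  if (cfg$grid_step <= 0) stop("grid_step must be > 0", call. = FALSE)
  if (cfg$epsilon <= 0 || cfg$epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  cfg
}

#' Run one simulated scenario through the full pipeline
#'
#' Simulates the four arms, emulates digitization of each, and hands the
#' digitized material to [ida_analysis()]. Ground truth: the observed-vs-
#' predicted hazard ratio equals the scenario's `psi`.
#'
#' @param scenario a [simulation_scenario].
#' @param jitter_sd vertical digitization jitter passed to [digitize_like()].
#' @param ... further arguments passed to [ida_analysis()] (e.g. `out_dir`).
#' @return The `ida_analysis` object.
#' @export
run_simulated_analysis <- function(scenario, jitter_sd = 0, ...) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  arms <- simulate_trials(scenario)
  dig <- lapply(arms, digitize_like, n_coordinates = scenario$n_coordinates,
                risk_table_step = scenario$risk_table_step,
                jitter_sd = jitter_sd, seed = scenario$seed)
  ida_analysis(dig$combination$coordinates, dig$doublet_A$coordinates,
               dig$doublet_B$coordinates, dig$control$coordinates,
               rt_combination = dig$combination$risk_table,
               rt_doublet_a = dig$doublet_A$risk_table, ...)
}

#' Operating-characteristics study over a grid of synergy multipliers
#'
#' Repeats the full simulated pipeline `replicates` times per value of `psi`
#' and summarizes the recovered hazard ratios and additivity classifications.
#' Deterministic given `seed`. A failed replicate (e.g. a degenerate
#' reconstruction at small n) is recorded with its message, not fatal to the
#' grid.
#'
#' @param psi numeric vector of synergy multipliers to study.
#' @param replicates replicates per `psi` value (>= 1).
#' @param scenario template [simulation_scenario]; its `psi` and `seed` are
#'   overridden per replicate.
#' @param seed master seed for the study.
#' @param jitter_sd digitization jitter, as in [run_simulated_analysis()].
#' @param out_csv optional path; the summary table is written there as CSV.
#' @return A list with `results` (one row per replicate: psi, replicate, hr,
#'   ci bounds, classification, error) and `summary` (per psi: mean and SD of
#'   the HR and classification rates).
#' @export
run_simulation_study <- function(psi = c(0.8, 1, 1.25), replicates = 1,
                                 scenario = simulation_scenario(),
                                 seed = 1L, jitter_sd = 0, out_csv = NULL) {
  stopifnot(replicates >= 1)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             replicates * length(psi)),
                  nrow = replicates)
  rows <- vector("list", replicates * length(psi))
  k <- 0L
  for (j in seq_along(psi)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      sc <- scenario
      sc$psi <- psi[j]
      sc$seed <- seeds[r, j]
      rows[[k]] <- tryCatch({
        a <- run_simulated_analysis(sc, jitter_sd = jitter_sd)
        data.frame(psi = psi[j], replicate = r, hr = a$result$hr,
                   ci_low = a$result$ci_low, ci_high = a$result$ci_high,
                   classification = a$result$classification,
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(psi = psi[j], replicate = r, hr = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   classification = NA_character_,
                   error = conditionMessage(e), stringsAsFactors = FALSE))
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$psi), function(d) {
    ok <- !is.na(d$hr)
    data.frame(psi = d$psi[1], n_ok = sum(ok), n_failed = sum(!ok),
               mean_hr = mean(d$hr[ok]), sd_hr = stats::sd(d$hr[ok]),
               rate_greater_than_additive =
                 mean(d$classification[ok] == "greater_than_additive"),
               rate_consistent_with_additive =
                 mean(d$classification[ok] == "consistent_with_additive"),
               rate_less_than_additive =
                 mean(d$classification[ok] == "less_than_additive"))
  }))
  rownames(summ) <- NULL
  if (!is.null(out_csv))
    utils::write.csv(summ, out_csv, row.names = FALSE, quote = FALSE)
  list(results = results, summary = summ)
}
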