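#' Digitized Kaplan-Meier coordinates
#'
#' Constructs a validated set of digitized Kaplan-Meier coordinates, the raw
#' material of the whole pipeline. Coordinates are typically extracted from a
#' published figure (e.g. with WebPlotDigitizer) and are therefore noisy:
#' the constructor sorts by time, collapses duplicate times to their minimum
#' survival value, clamps survival values in (1, 1 + 1e-6] to 1, and anchors
#' the curve at (0, 1) -- prepending that point when absent, since a
#' Kaplan-Meier curve starts at 1 by definition and digitization often omits
#' the origin.
#'
#' @param time numeric vector of times in months, all >= 0.
#' @param survival numeric vector of survival probabilities in \[0, 1\].
#' @param arm_label label of the trial arm the curve belongs to.
#' @param source_trial optional label of the source trial.
#' @return An object of class `km_coordinates`: a list with elements `time`,
#'   `survival`, `arm_label`, `source_trial`.
#' @seealso [read_km_csv()], [enforce_monotone()], [interpolate_to_grid()]
#' @export
km_coordinates <- function(time, survival, arm_label = "arm",
                           source_trial = NA_character_) {
  if (!is.numeric(time) || !is.numeric(survival))
    stop("'time' and 'survival' must be numeric", call. = FALSE)
  if (length(time) != length(survival))
    stop("'time' and 'survival' must have equal length", call. = FALSE)
  if (anyNA(time) || anyNA(survival) || any(!is.finite(time)) ||
      any(!is.finite(survival)))
    stop("non-numeric or missing cell in Kaplan-Meier coordinates",
         call. = FALSE)
  if (any(time < 0))
    stop("negative time in Kaplan-Meier coordinates", call. = FALSE)
  if (any(survival > 1 + 1e-6))
    stop("survival values above 1 found (max ", format(max(survival)),
         "); curves must be fractions in [0, 1], not percent", call. = FALSE)
  if (any(survival < -1e-6))
    stop("negative survival probability", call. = FALSE)
  survival <- pmin(pmax(survival, 0), 1)

  ord <- order(time, survival)
  time <- time[ord]; survival <- survival[ord]
  # duplicate digitized times collapse to their minimum survival value
  if (anyDuplicated(time)) {
    survival <- unname(vapply(split(survival, match(time, unique(time))),
                              min, numeric(1)))
    time <- unique(time)
  }
  if (time[1] > 0) {
    time <- c(0, time)
    survival <- c(1, survival)
  } else {
    if (survival[1] < 0.95)
      stop("survival at time 0 is ", format(survival[1]),
           "; a Kaplan-Meier curve must start at 1", call. = FALSE)
    survival[1] <- 1
  }
  if (length(time) < 2)
    stop("at least 2 coordinate points are required", call. = FALSE)

  structure(list(time = time, survival = survival,
                 arm_label = as.character(arm_label),
                 source_trial = as.character(source_trial)),
            class = "km_coordinates")
}

#' @export
print.km_coordinates <- function(x, ...) {
  cat("Digitized KM coordinates: arm '", x$arm_label, "'",
      if (!is.na(x$source_trial)) paste0(" (", x$source_trial, ")"), "\n",
      sep = "")
  cat("  ", length(x$time), " points over [0, ", format(max(x$time)),
      "] months; survival range [", format(min(x$survival)), ", 1]\n",
      sep = "")
  invisible(x)
}

#' Read digitized Kaplan-Meier coordinates from CSV
#'
#' Reads one arm's digitized curve. The dialect is two numeric columns named
#' `time_months` and `survival` (a fraction in \[0, 1\]; percent input is
#' rejected, not rescaled), UTF-8, `.` decimal separator, optional lines
#' starting with `#` ignored.
#'
#' @param path path to the CSV file.
#' @inheritParams km_coordinates
#' @return A [km_coordinates] object.
#' @export
read_km_csv <- function(path, arm_label = "arm", source_trial = NA_character_) {
  if (!file.exists(path))
    stop("curve CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("time_months", "survival")
  if (!all(need %in% names(df)))
    stop("curve CSV ", path, " must have columns 'time_months,survival'",
         call. = FALSE)
  for (col in need)
    if (!is.numeric(df[[col]]))
      stop("non-numeric cell in column '", col, "' of ", path, call. = FALSE)
  km_coordinates(df$time_months, df$survival, arm_label, source_trial)
}

#' Number-at-risk table
#'
#' The published counts of patients still at risk at scheduled times beneath
#' a Kaplan-Meier plot; required by the individual-patient-data
#' reconstruction. The first entry must be at time 0 and equals the arm's
#' sample size.
#'
#' @param time numeric vector of times in months, strictly increasing,
#'   starting at 0.
#' @param n_at_risk nonnegative non-increasing integer counts.
#' @return An object of class `risk_table`.
#' @export
risk_table <- function(time, n_at_risk) {
  if (!is.numeric(time) || !is.numeric(n_at_risk))
    stop("'time' and 'n_at_risk' must be numeric", call. = FALSE)
  if (length(time) != length(n_at_risk) || length(time) < 1)
    stop("'time' and 'n_at_risk' must be non-empty and of equal length",
         call. = FALSE)
  if (anyNA(time) || anyNA(n_at_risk))
    stop("missing value in risk table", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("risk-table times must be strictly increasing", call. = FALSE)
  if (abs(time[1]) > 1e-9)
    stop("risk table must start at time 0 with the arm sample size",
         call. = FALSE)
  if (any(n_at_risk < 0) || any(abs(n_at_risk - round(n_at_risk)) > 1e-9))
    stop("n_at_risk must be nonnegative integers", call. = FALSE)
  n_at_risk <- as.integer(round(n_at_risk))
  if (is.unsorted(rev(n_at_risk)))
    stop("n_at_risk must be non-increasing over time", call. = FALSE)
  structure(list(time = as.numeric(time), n_at_risk = n_at_risk),
            class = "risk_table")
}

#' Read a number-at-risk table from CSV
#'
#' Dialect: columns `time_months,n_at_risk`, optional `#` comment lines.
#'
#' @param path path to the CSV file.
#' @return A [risk_table] object.
#' @export
read_risk_table_csv <- function(path) {
  if (!file.exists(path))
    stop("risk-table CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("time_months", "n_at_risk")
  if (!all(need %in% names(df)))
    stop("risk-table CSV ", path,
         " must have columns 'time_months,n_at_risk'", call. = FALSE)
  risk_table(df$time_months, df$n_at_risk)
}

#' Enforce monotone decrease of a digitized curve
#'
#' Digitization noise can produce locally increasing survival values; they
#' are repaired by replacing the survival series with its running minimum
#' (times unchanged). The number of altered points is recorded in the
#' `n_repaired` attribute. Idempotent.
#'
#' @param coords a [km_coordinates] object.
#' @return The repaired `km_coordinates`.
#' @export
enforce_monotone <- function(coords) {
  stopifnot(inherits(coords, "km_coordinates"))
  fixed <- cummin(coords$survival)
  n_rep <- sum(fixed < coords$survival - 1e-12)
  coords$survival <- fixed
  attr(coords, "n_repaired") <- n_rep
  coords
}

#' Interpolate a digitized curve onto a common time grid
#'
#' Places the curve on a uniform grid (default step 0.5 months) by linear
#' interpolation between the digitized coordinates; values are exact at the
#' coordinates themselves. Curves are truncated at `t_max`, never
#' extrapolated: requesting a grid beyond the last coordinate is an error.
#'
#' @param coords a monotone [km_coordinates] object (see
#'   [enforce_monotone()]).
#' @param grid_step grid step in months (> 0), default 0.5.
#' @param t_max grid extent in months; must not exceed the last coordinate
#'   time. Defaults to the last coordinate time.
#' @param risk_table optional [risk_table] carried along for reconstruction.
#' @param total_events optional published total event count for the arm.
#' @return An object of class `km_curve`: list with `grid_times`,
#'   `survival`, `grid_step`, `arm_label`, `risk_table`, `total_events`.
#' @export
interpolate_to_grid <- function(coords, grid_step = 0.5,
                                t_max = max(coords$time),
                                risk_table = NULL, total_events = NULL) {
  stopifnot(inherits(coords, "km_coordinates"))
  if (!is.numeric(grid_step) || grid_step <= 0)
    stop("grid_step must be > 0", call. = FALSE)
  last_t <- max(coords$time)
  if (t_max > last_t + 1e-9)
    stop("t_max (", format(t_max), ") exceeds last coordinate time (",
         format(last_t), "): extrapolation is not supported", call. = FALSE)
  if (any(diff(coords$survival) > 1e-12))
    stop("coordinates are not monotone non-increasing; ",
         "apply enforce_monotone() first", call. = FALSE)
  grid <- round(seq(0, t_max + 1e-9, by = grid_step), 9)
  grid <- grid[grid <= t_max + 1e-9]
  s <- stats::approx(coords$time, coords$survival, xout = grid,
                     method = "linear", ties = "ordered")$y
  s <- cummin(pmin(pmax(s, 0), 1))  # guard against float dust only
  new_km_curve(grid, s, grid_step, coords$arm_label, risk_table, total_events)
}

new_km_curve <- function(grid_times, survival, grid_step, arm_label,
                         risk_table = NULL, total_events = NULL) {
  if (!is.null(risk_table)) stopifnot(inherits(risk_table, "risk_table"))
  if (!is.null(total_events)) {
    stopifnot(is.numeric(total_events), total_events >= 0)
    total_events <- as.integer(round(total_events))
  }
  stopifnot(abs(survival[1] - 1) < 1e-9, !is.unsorted(rev(survival)))
  structure(list(grid_times = grid_times, survival = survival,
                 grid_step = grid_step, arm_label = as.character(arm_label),
                 risk_table = risk_table, total_events = total_events),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("KM curve on grid: arm '", x$arm_label, "', step ",
      format(x$grid_step), " months, extent [0, ",
      format(max(x$grid_times)), "], ", length(x$grid_times), " points\n",
      sep = "")
  if (!is.null(x$risk_table))
    cat("  risk table: ", length(x$risk_table$time), " entries, n(0) = ",
        x$risk_table$n_at_risk[1], "\n", sep = "")
  invisible(x)
}

#' Common grid extent across several digitized curves
#'
#' The analysis grid extends to the minimum of the curves' last coordinate
#' times: the independent-action ratio is undefined beyond any component
#' curve's follow-up, and curves are never extrapolated.
#'
#' @param ... [km_coordinates] objects (or a single list of them).
#' @return The common `t_max` in months.
#' @export
common_t_max <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "km_coordinates")) xs <- xs[[1]]
  stopifnot(length(xs) >= 1,
            all(vapply(xs, inherits, logical(1), "km_coordinates")))
  min(vapply(xs, function(k) max(k$time), numeric(1)))
}

#' Write a curve to the package's CSV dialect
#'
#' Writes `time_months,survival` rows (with a `#` provenance comment) so
#' predicted curves can be audited and re-imported by [read_km_csv()].
#'
#' @param x a `km_curve`, [km_coordinates] or `ida_prediction` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(x, path) {
  if (inherits(x, "km_coordinates")) {
    tm <- x$time; sv <- x$survival; lab <- x$arm_label
  } else if (inherits(x, c("km_curve", "ida_prediction"))) {
    tm <- x$grid_times; sv <- x$survival
    lab <- if (inherits(x, "ida_prediction"))
      paste0("IDA prediction from ", paste(x$source_labels, collapse = ", "))
    else x$arm_label
  } else stop("cannot write object of class ", class(x)[1], call. = FALSE)
  writeLines(c(paste0("# ", lab), "time_months,survival",
               paste(format(tm, trim = TRUE, digits = 12),
                     format(sv, trim = TRUE, digits = 12), sep = ",")),
             con = path)
  invisible(path)
}
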