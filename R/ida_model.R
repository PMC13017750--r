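#' Predicted combination curve under independent drug action
#'
#' Computes the survival curve a combination regimen would show if its two
#' component regimens acted independently. With `P_A(t)` the survival of
#' doublet A (e.g. chemotherapy + backbone, observed in the combination's own
#' trial), `P_B(t)` the survival of doublet B and `P_0(t)` its control
#' (observed in a second trial), the law of probabilistic independence gives
#'
#' \deqn{P_{pred}(t) = P_A(t) \cdot \frac{P_B(t)}{P_0(t)}}
#'
#' where the ratio is the relative survival benefit of the agent added by
#' doublet B over its control. All three curves must live on the identical
#' analysis grid. Two numerical repairs are applied, and counted, because
#' digitized curves are noisy: raw products above 1 are clamped to 1, and the
#' series is made non-increasing by a running minimum. The grid is truncated
#' at the first point where the control survival falls below `epsilon`; the
#' ratio is numerically unstable as the control curve approaches zero.
#'
#' @param curve_a `km_curve` for doublet A (same-trial comparator of the
#'   combination).
#' @param curve_b `km_curve` for doublet B (second trial, treatment arm).
#' @param curve_control `km_curve` for doublet B's control arm.
#' @param epsilon floor on the control survival (default 0.01); grid points
#'   where `P_0(t) < epsilon` are dropped.
#' @return An object of class `ida_prediction`: `grid_times`, `survival`,
#'   `grid_step`, `source_labels`, `clamp_count` (points adjusted by either
#'   repair) and `truncation_time` (retained grid extent in months).
#' @seealso [relative_benefit()], [as_km_curve()]
#' @export
predict_independent_action <- function(curve_a, curve_b, curve_control,
                                       epsilon = 0.01) {
  stopifnot(inherits(curve_a, "km_curve"), inherits(curve_b, "km_curve"),
            inherits(curve_control, "km_curve"))
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  gt <- curve_a$grid_times
  if (length(gt) != length(curve_b$grid_times) ||
      length(gt) != length(curve_control$grid_times) ||
      max(abs(gt - curve_b$grid_times)) > 1e-8 ||
      max(abs(gt - curve_control$grid_times)) > 1e-8)
    stop("curves are not on the identical grid; interpolate all arms with ",
         "the same grid_step and t_max", call. = FALSE)

  s0 <- curve_control$survival
  if (s0[1] < epsilon)
    stop("control curve below epsilon at t = 0", call. = FALSE)
  first_bad <- match(TRUE, s0 < epsilon)
  keep <- if (is.na(first_bad)) seq_along(gt) else seq_len(first_bad - 1L)
  if (length(keep) == 0)
    stop("empty retained grid after control-floor truncation", call. = FALSE)

  raw <- curve_a$survival[keep] * (curve_b$survival[keep] / s0[keep])
  capped <- pmin(raw, 1)
  mono <- cummin(capped)
  clamp_count <- sum(raw > 1 + 1e-12) + sum(mono < capped - 1e-12)

  structure(list(grid_times = gt[keep], survival = mono,
                 grid_step = curve_a$grid_step,
                 source_labels = c(arm_a = curve_a$arm_label,
                                   arm_b = curve_b$arm_label,
                                   arm_control = curve_control$arm_label),
                 clamp_count = as.integer(clamp_count),
                 truncation_time = max(gt[keep])),
            class = "ida_prediction")
}

#' @export
print.ida_prediction <- function(x, ...) {
  cat("Independent-drug-action prediction\n")
  cat("  sources: A = '", x$source_labels[["arm_a"]], "', B = '",
      x$source_labels[["arm_b"]], "', control = '",
      x$source_labels[["arm_control"]], "'\n", sep = "")
  cat("  grid: ", length(x$grid_times), " points, truncated at ",
      format(x$truncation_time), " months; ", x$clamp_count,
      " point(s) repaired (cap at 1 / running minimum)\n", sep = "")
  invisible(x)
}

#' Relative survival benefit of a treatment over its control
#'
#' The pointwise ratio `P_B(t) / P_0(t)` on the shared grid: how much more
#' probable survival to time t is under the treatment than under its own
#' trial's control. Equals 1 at t = 0.
#'
#' @inheritParams predict_independent_action
#' @return A data frame with columns `time` and `ratio`.
#' @export
relative_benefit <- function(curve_b, curve_control, epsilon = 0.01) {
  stopifnot(inherits(curve_b, "km_curve"), inherits(curve_control, "km_curve"))
  gt <- curve_b$grid_times
  if (length(gt) != length(curve_control$grid_times) ||
      max(abs(gt - curve_control$grid_times)) > 1e-8)
    stop("curves are not on the identical grid", call. = FALSE)
  s0 <- curve_control$survival
  if (any(s0 < epsilon))
    stop("control survival falls below the division floor epsilon = ",
         format(epsilon), " at t = ", format(gt[match(TRUE, s0 < epsilon)]),
         " months", call. = FALSE)
  data.frame(time = gt, ratio = curve_b$survival / s0)
}

#' Coerce a prediction to a grid curve
#'
#' Converts an `ida_prediction` into a `km_curve` so the downstream stages
#' (reconstruction, export) treat predicted and observed curves identically.
#'
#' @param x object to coerce.
#' @param arm_label arm label for the resulting curve.
#' @param ... passed on to methods.
#' @return A `km_curve`.
#' @export
as_km_curve <- function(x, ...) UseMethod("as_km_curve")

#' @rdname as_km_curve
#' @export
as_km_curve.ida_prediction <- function(x, arm_label = "predicted", ...) {
  new_km_curve(x$grid_times, x$survival, x$grid_step, arm_label)
}
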