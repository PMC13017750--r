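# Kaplan-Meier inversion: recover pseudo individual patient data from a
# digitized curve plus its published number-at-risk table. The scheme follows
# the standard KM-inversion approach used for published trial curves: within
# each risk interval the censoring count is iterated until the implied
# at-risk count reproduces the published one, events are read off the curve's
# drops through the product-limit recursion, and censoring times are spread
# deterministically across the interval.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Reconstruct individual patient data from a Kaplan-Meier curve
#'
#' Inverts a gridded Kaplan-Meier curve plus a number-at-risk table into
#' records of (time, event indicator) whose product-limit estimate reproduces
#' the input curve. The inversion is fully deterministic.
#'
#' For each risk interval `[T_i, T_(i+1))`: a censoring count is guessed,
#' censoring times are placed at equal spacing strictly inside the interval,
#' the curve's drop points are walked computing event counts `d_k` from the
#' product-limit recursion `S_k = S_(k-1) (1 - d_k / n_k)` (with `S_(k-1)`
#' the running reconstructed estimate and counts rounded half away from
#' zero), and the implied at-risk count at `T_(i+1)` is compared with the
#' published value; the censoring count is adjusted by the discrepancy and
#' the interval is re-walked, up to `max_iter` times or until the same guess
#' repeats (the nearest-feasible count is then accepted). Published at-risk
#' counts are always matched exactly: if they are unattainable with zero
#' censoring (rounding can overshoot event counts by a unit), event counts at
#' the interval's latest drops are trimmed by the deficit; a deficit larger
#' than the interval's event total, or a published count exceeding the
#' entering at-risk count, is reported as an infeasible risk table naming the
#' interval. After the last published risk time, if `total_events` is given,
#' the tail censoring count is chosen so the arm's event count matches it
#' exactly. Patients still at risk at the end of the curve are censored at
#' the last grid time.
#'
#' @param curve a `km_curve` (see [interpolate_to_grid()]).
#' @param risk_table a [risk_table]; defaults to the one carried by `curve`.
#' @param total_events optional published total event count for the arm.
#' @param arm_label label stored in the output records.
#' @param max_iter maximum censoring-count iterations per interval.
#' @return An `ipd_dataset`: a data frame with columns `time` (months),
#'   `event` (1 = event, 0 = censored) and `arm`, with attribute
#'   `at_risk_check` (data frame of published vs implied at-risk counts).
#' @seealso [km_estimate()] to validate the round trip.
#' @export
reconstruct_ipd <- function(curve, risk_table = curve$risk_table,
                            total_events = curve$total_events,
                            arm_label = curve$arm_label, max_iter = 50L) {
  stopifnot(inherits(curve, "km_curve"))
  if (is.null(risk_table))
    stop("a risk table is required for reconstruction", call. = FALSE)
  stopifnot(inherits(risk_table, "risk_table"))
  tt <- curve$grid_times
  ss <- curve$survival
  t_end <- max(tt)
  rt_t <- risk_table$time
  rt_n <- risk_table$n_at_risk
  if (any(rt_t > t_end + 1e-8))
    stop("risk-table times extend beyond the curve (last grid time ",
         format(t_end), ")", call. = FALSE)
  if (!is.null(total_events)) {
    stopifnot(is.numeric(total_events), total_events >= 0)
    total_events <- as.integer(round(total_events))
  }

  n_cur <- rt_n[1]
  s_hat <- 1
  ev_time <- numeric(0); ev_n <- integer(0); cens_time <- numeric(0)
  implied <- integer(length(rt_t)); implied[1] <- n_cur

  # walk one interval with cc censorings; optionally override event counts
  walk <- function(idx, cc, t_lo, t_hi, n0, s0, d_override = NULL) {
    ct <- if (cc > 0) t_lo + seq_len(cc) * (t_hi - t_lo) / (cc + 1)
          else numeric(0)
    n <- n0; sh <- s0; cj <- 1L
    d_out <- integer(length(idx))
    for (m in seq_along(idx)) {
      tk <- tt[idx[m]]
      while (cj <= cc && ct[cj] < tk - 1e-12) { n <- n - 1L; cj <- cj + 1L }
      if (n <= 0L || sh <= 0) break
      d <- if (is.null(d_override))
        as.integer(round_half_away(n * (1 - ss[idx[m]] / sh)))
      else d_override[m]
      d <- max(0L, min(d, n))
      if (d > 0L) { sh <- sh * (1 - d / n); n <- n - d }
      d_out[m] <- d
    }
    n <- max(0L, n - max(0L, cc - cj + 1L))  # censorings after the last drop
    list(n_end = n, d = d_out, s_end = sh, cens = ct)
  }

  n_iv <- length(rt_t)
  for (i in seq_len(n_iv)) {
    t_lo <- rt_t[i]
    is_tail <- i == n_iv
    t_hi <- if (is_tail) t_end else rt_t[i + 1]
    idx <- which(tt > 1e-12 & tt >= t_lo - 1e-9 &
                   (if (is_tail) tt <= t_hi + 1e-9 else tt < t_hi - 1e-9))
    target <- if (is_tail) NA_integer_ else rt_n[i + 1]
    if (!is_tail && target > n_cur)
      stop("infeasible risk table: published at-risk count ", target,
           " at t = ", format(t_hi), " exceeds the ", n_cur,
           " patients entering the interval", call. = FALSE)

    if (is_tail && is.null(total_events)) {
      w <- walk(idx, 0L, t_lo, t_hi, n_cur, s_hat)
      cc <- 0L
    } else {
      # iterate the censoring count toward the interval's target
      score <- function(w)
        if (is_tail) sum(ev_n) + sum(w$d) - total_events else w$n_end - target
      cc <- 0L; seen <- integer(0)
      best <- NULL; best_diff <- NA_integer_
      for (it in seq_len(max_iter)) {
        w <- walk(idx, cc, t_lo, t_hi, n_cur, s_hat)
        diff <- score(w)
        if (is.null(best) || abs(diff) < abs(best_diff)) {
          best <- w; best_diff <- diff; best_cc <- cc
        }
        if (diff == 0L) break
        seen <- c(seen, cc)
        cc_next <- max(0L, cc + diff)
        if (cc_next %in% seen) break  # fixed-point stall
        cc <- cc_next
      }
      w <- best; cc <- best_cc
      if (best_diff != 0L) {
        # nearest-feasible repair: adjust event counts at the latest drops.
        # surplus > 0 means the walk produced too many events (equivalently,
        # in an interior interval, too few patients left at risk).
        surplus <- if (is_tail) best_diff else -best_diff
        d <- w$d
        if (surplus > 0L) {
          for (m in rev(seq_along(d))) {
            take <- min(d[m], surplus)
            d[m] <- d[m] - take; surplus <- surplus - take
            if (surplus == 0L) break
          }
          if (surplus > 0L)
            stop("infeasible risk table in interval [", format(t_lo), ", ",
                 format(t_hi), "): published count unattainable for any ",
                 "nonnegative censoring count", call. = FALSE)
        } else {
          want <- -surplus
          room <- n_cur - cc - sum(d)
          add <- min(want, max(0L, room))
          if (length(d) > 0L && add > 0L) d[length(d)] <- d[length(d)] + add
          else add <- 0L
          if (add < want && !is_tail)
            stop("infeasible risk table in interval [", format(t_lo), ", ",
                 format(t_hi), "): cannot reach published at-risk count ",
                 target, call. = FALSE)
        }
        w <- walk(idx, cc, t_lo, t_hi, n_cur, s_hat, d_override = d)
      }
    }

    pos <- w$d > 0L
    ev_time <- c(ev_time, rep(tt[idx][pos], w$d[pos]))
    ev_n <- c(ev_n, w$d[pos])
    cens_time <- c(cens_time, w$cens)
    n_cur <- w$n_end
    s_hat <- w$s_end
    if (!is_tail) implied[i + 1] <- n_cur
  }

  # anyone still at risk is administratively censored at end of follow-up
  if (n_cur > 0L) cens_time <- c(cens_time, rep(t_end, n_cur))

  out <- data.frame(
    time = c(ev_time, cens_time),
    event = c(rep(1L, length(ev_time)), rep(0L, length(cens_time))),
    arm = as.character(arm_label),
    stringsAsFactors = FALSE)
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ipd_dataset", "data.frame")
  attr(out, "at_risk_check") <- data.frame(time = rt_t, published = rt_n,
                                           implied = implied)
  if (!is.null(total_events) && sum(out$event) != total_events)
    stop("reconstruction could not match total_events = ", total_events,
         " (got ", sum(out$event), ")", call. = FALSE)
  out
}

#' Product-limit (Kaplan-Meier) estimate of an IPD arm
#'
#' Fits the product-limit estimator to one arm of an `ipd_dataset` (censoring
#' at a time is processed after events at the same time, the usual
#' convention). Used to validate reconstruction round trips and to plot
#' observed-versus-predicted curves.
#'
#' @param ipd a data frame with columns `time`, `event`, `arm`.
#' @param arm_label which arm to estimate; defaults to the only arm present.
#' @return An object of class `km_fit`: step-function representation with
#'   `time` (starting at 0), `surv` (starting at 1), `n`, `events`,
#'   `arm_label`.
#' @export
km_estimate <- function(ipd, arm_label = NULL) {
  stopifnot(is.data.frame(ipd), all(c("time", "event", "arm") %in% names(ipd)))
  if (is.null(arm_label)) {
    arms <- unique(ipd$arm)
    if (length(arms) != 1)
      stop("several arms present; specify arm_label", call. = FALSE)
    arm_label <- arms
  }
  d <- ipd[ipd$arm == arm_label, , drop = FALSE]
  if (nrow(d) == 0)
    stop("no records for arm '", arm_label, "'", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  structure(list(time = c(0, fit$time), surv = c(1, fit$surv),
                 n = nrow(d), events = sum(d$event),
                 arm_label = as.character(arm_label)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param fit a `km_fit` from [km_estimate()].
#' @param times times (months) at which to evaluate; the estimator is
#'   right-continuous, so `S(t)` is the value at the latest step time `<= t`.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(fit, times) {
  stopifnot(inherits(fit, "km_fit"), all(times >= 0))
  fit$surv[findInterval(times + 1e-12, fit$time)]
}

#' Number at risk in an IPD dataset
#'
#' Counts records with `time >= t` per requested time, the convention under
#' published Kaplan-Meier plots.
#'
#' @inheritParams km_estimate
#' @param times times (months) at which to count.
#' @return Integer vector of at-risk counts.
#' @export
n_at_risk <- function(ipd, times, arm_label = NULL) {
  stopifnot(is.data.frame(ipd))
  d <- if (is.null(arm_label)) ipd else ipd[ipd$arm == arm_label, ]
  vapply(times, function(tm) sum(d$time >= tm - 1e-9), integer(1))
}

#' Risk table for a predicted cohort, borrowed from a comparator arm
#'
#' A predicted curve has no published risk table. The least-assumption choice
#' is to borrow the censoring pattern of the same-trial comparator arm: the
#' comparator's published at-risk counts are rescaled by the survival ratio
#' `S_pred(T_i) / S_comp(T_i)` and rounded, keeping the comparator's sample
#' size at t = 0 and enforcing monotone decrease. This convention is surfaced
#' in the analysis metadata.
#'
#' @param pred_curve `km_curve` of the predicted cohort.
#' @param comparator_curve `km_curve` of the comparator arm on the same grid.
#' @param comparator_rt the comparator's published [risk_table].
#' @return A [risk_table] for the predicted cohort.
#' @export
borrow_risk_table <- function(pred_curve, comparator_curve, comparator_rt) {
  stopifnot(inherits(pred_curve, "km_curve"),
            inherits(comparator_curve, "km_curve"),
            inherits(comparator_rt, "risk_table"))
  t_max <- max(pred_curve$grid_times)
  keep <- comparator_rt$time <= t_max + 1e-8
  tms <- comparator_rt$time[keep]
  n_c <- comparator_rt$n_at_risk[keep]
  sp <- pred_curve$survival[match_grid(pred_curve$grid_times, tms)]
  sc <- comparator_curve$survival[match_grid(comparator_curve$grid_times, tms)]
  n_p <- round(n_c * sp / sc)
  n_p[1] <- n_c[1]
  n_p <- cummin(pmax(n_p, 0))
  risk_table(tms, n_p)
}

clip_risk_table <- function(rt, t_max) {
  keep <- rt$time <= t_max + 1e-8
  risk_table(rt$time[keep], rt$n_at_risk[keep])
}

match_grid <- function(grid, times) {
  idx <- vapply(times, function(tm) {
    j <- which(abs(grid - tm) < 1e-8)
    if (length(j) != 1)
      stop("time ", format(tm), " is not a grid point", call. = FALSE)
    j
  }, integer(1))
  idx
}

#' Write / read IPD in the package CSV dialect
#'
#' Columns `time_months,event,arm` with `event` in \{0, 1\}; round-trippable
#' into [km_estimate()].
#'
#' @param ipd an `ipd_dataset`.
#' @param path file path.
#' @return `path` (write) or an `ipd_dataset` (read).
#' @export
write_ipd_csv <- function(ipd, path) {
  stopifnot(is.data.frame(ipd))
  utils::write.csv(data.frame(time_months = ipd$time, event = ipd$event,
                              arm = ipd$arm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ipd_csv
#' @export
read_ipd_csv <- function(path) {
  if (!file.exists(path)) stop("IPD CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("time_months", "event", "arm")
  if (!all(need %in% names(df)))
    stop("IPD CSV must have columns 'time_months,event,arm'", call. = FALSE)
  if (!all(df$event %in% c(0L, 1L)))
    stop("event indicator must be 0 or 1", call. = FALSE)
  if (any(df$time_months <= 0))
    stop("IPD times must be positive", call. = FALSE)
  out <- data.frame(time = df$time_months, event = as.integer(df$event),
                    arm = as.character(df$arm), stringsAsFactors = FALSE)
  class(out) <- c("ipd_dataset", "data.frame")
  out
}
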