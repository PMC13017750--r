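# Independent oracles and fixture builders shared across the suite.

# Brute-force maximizer of the written-out two-group Cox partial likelihood
# (x is the 0/1 group indicator). Deliberately independent of survival::coxph.
oracle_cox_beta <- function(time, event, x, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  neg_logpl <- function(beta) {
    ll <- 0
    for (tj in sort(unique(time[event == 1]))) {
      dset <- which(event == 1 & abs(time - tj) < 1e-12)
      rset <- which(time >= tj - 1e-12)
      d <- length(dset)
      ll <- ll + beta * sum(x[dset])
      rsum <- sum(exp(beta * x[rset]))
      dsum <- sum(exp(beta * x[dset]))
      if (ties == "breslow") {
        ll <- ll - d * log(rsum)
      } else {
        for (l in seq_len(d) - 1) ll <- ll - log(rsum - (l / d) * dsum)
      }
    }
    -ll
  }
  stats::optimize(neg_logpl, interval = c(-5, 5), tol = 1e-10)$minimum
}

# Hand-rolled hypergeometric log-rank tabulation over distinct event times.
oracle_logrank_chi2 <- function(time, event, x) {
  o_minus_e <- 0; v <- 0
  for (tj in sort(unique(time[event == 1]))) {
    at_risk <- time >= tj - 1e-12
    dead <- event == 1 & abs(time - tj) < 1e-12
    n <- sum(at_risk); n1 <- sum(at_risk & x == 1); d <- sum(dead)
    o_minus_e <- o_minus_e + sum(dead & x == 1) - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Exponential survival curve sampled on its own grid (knots = grid points,
# so linear interpolation is exact there).
exp_curve <- function(lambda, t_end = 60, step = 0.5, label = "arm") {
  g <- round(seq(0, t_end, by = step), 9)
  interpolate_to_grid(enforce_monotone(
    km_coordinates(g, exp(-lambda * g), arm_label = label)),
    grid_step = step, t_max = t_end)
}

# Arbitrary monotone survival values placed on their own uniform grid,
# going through the public constructors only.
new_km_curve_for_test <- function(grid, surv, step, label) {
  interpolate_to_grid(enforce_monotone(km_coordinates(grid, surv, label)),
                      grid_step = step, t_max = max(grid))
}

# Small IPD fixture as a plain data frame with an arm column.
make_ipd <- function(time, event, arm) {
  d <- data.frame(time = time, event = as.integer(event),
                  arm = as.character(arm), stringsAsFactors = FALSE)
  class(d) <- c("ipd_dataset", "data.frame")
  d
}
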