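test_that("log-rank is zero for exchangeable groups and label-symmetric", {
  tm <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 1, 0, 1, 0, 1)
  ipd <- rbind(make_ipd(tm, ev, "a"), make_ipd(tm, ev, "b"))
  lr <- logrank_test(ipd, "a", "b")
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  lr2 <- logrank_test(ipd, "b", "a")
  expect_equal(lr2$chi2, lr$chi2)
})

test_that("log-rank matches the hand hypergeometric tabulation", {
  # group a events at 1,2; group b events at 3,4; no censoring:
  # O-E = 2 - (1/2 + 1/3) = 7/6, V = 1/4 + 2/9 = 17/36, chi2 = 49/17
  ipd <- rbind(make_ipd(c(1, 2), c(1, 1), "a"),
               make_ipd(c(3, 4), c(1, 1), "b"))
  lr <- logrank_test(ipd, "a", "b")
  expect_equal(lr$chi2, 49 / 17, tolerance = 1e-9)
  expect_equal(lr$chi2,
               oracle_logrank_chi2(ipd$time, ipd$event, ipd$arm == "a"),
               tolerance = 1e-9)
  expect_error(logrank_test(ipd, "a", "zzz"), "absent")
  none <- rbind(make_ipd(1:2, c(0, 0), "a"), make_ipd(1:2, c(0, 0), "b"))
  expect_error(logrank_test(none, "a", "b"), "no events")
})

test_that("cox_fit matches brute-force partial likelihood on tiny fixtures", {
  set.seed(404)
  for (r in 1:12) {
    n <- sample(4:8, 1)
    tm <- sample(1:5, n, replace = TRUE)     # forces ties
    ev <- rbinom(n, 1, 0.8)
    gr <- rep(c("a", "b"), length.out = n)
    if (sum(ev[gr == "a"]) == 0 || sum(ev[gr == "b"]) == 0) next
    ipd <- make_ipd(tm, ev, gr)
    for (ties in c("efron", "breslow")) {
      fit <- tryCatch(cox_fit(ipd, "a", "b", ties = ties),
                      error = function(e) NULL)
      if (is.null(fit)) next    # monotone likelihood fixtures are tested below
      beta_hat <- log(fit$hr)
      beta_star <- oracle_cox_beta(tm, ev, as.integer(gr == "a"), ties)
      expect_lt(abs(beta_hat - beta_star), 1e-6)
    }
  }
})

test_that("relabeling the groups inverts the hazard ratio", {
  set.seed(11)
  ipd <- rbind(make_ipd(rexp(40, 0.1), rbinom(40, 1, 0.8), "a"),
               make_ipd(rexp(40, 0.2), rbinom(40, 1, 0.8), "b"))
  f1 <- cox_fit(ipd, "a", "b")
  f2 <- cox_fit(ipd, "b", "a")
  expect_equal(f1$hr, 1 / f2$hr, tolerance = 1e-9)
  expect_equal(f1$ci_low, 1 / f2$ci_high, tolerance = 1e-9)
  expect_equal(f1$ci_high, 1 / f2$ci_low, tolerance = 1e-9)
})

test_that("large-sample fit recovers the true hazard ratio", {
  set.seed(314)
  n <- 2000
  ev_a <- rexp(n, 0.05); ev_b <- rexp(n, 0.10)           # true HR 0.5
  cn_a <- runif(n, 0, 120); cn_b <- runif(n, 0, 120)     # ~20% censoring
  ipd <- rbind(make_ipd(pmin(ev_a, cn_a), ev_a <= cn_a, "a"),
               make_ipd(pmin(ev_b, cn_b), ev_b <= cn_b, "b"))
  fit <- cox_fit(ipd, "a", "b")
  expect_gt(fit$hr, 0.45); expect_lt(fit$hr, 0.55)
  # Wald and log-rank p agree to an order of magnitude for a moderate effect
  # (both are asymptotically equivalent under proportional hazards)
  ev_c <- rexp(n, 0.0575)
  ipd3 <- rbind(make_ipd(pmin(ev_a, cn_a), ev_a <= cn_a, "a"),
                make_ipd(pmin(ev_c, cn_b), ev_c <= cn_b, "c"))
  f3 <- cox_fit(ipd3, "a", "c")
  expect_lt(abs(log10(f3$p_cox) - log10(f3$p_logrank)), 1)
  # exchangeable relabeling of one big sample: HR ~ 1
  half <- rep(c("g1", "g2"), n)
  ipd2 <- make_ipd(rep(pmin(ev_a, cn_a), each = 2),
                   rep(ev_a <= cn_a, each = 2), half)
  f2 <- cox_fit(ipd2, "g1", "g2")
  expect_gt(f2$hr, 0.99); expect_lt(f2$hr, 1.01)
})

test_that("confidence bounds are the exact Wald transform of the SE", {
  set.seed(21)
  ipd <- rbind(make_ipd(rexp(60, 0.1), rbinom(60, 1, 0.9), "a"),
               make_ipd(rexp(60, 0.15), rbinom(60, 1, 0.9), "b"))
  f <- cox_fit(ipd, "a", "b")
  expect_equal(f$ci_low, exp(log(f$hr) - 1.959964 * f$se_log_hr),
               tolerance = 1e-9)
  expect_equal(f$ci_high, exp(log(f$hr) + 1.959964 * f$se_log_hr),
               tolerance = 1e-9)
  expect_true(f$ci_low <= f$hr && f$hr <= f$ci_high)
  cls <- classify_interaction(f$hr, f$ci_low, f$ci_high)
  expect_identical(cls, f$classification)
})

test_that("interaction classification follows the CI decision rule", {
  expect_identical(classify_interaction(0.824, 0.681, 0.998),
                   "greater_than_additive")
  expect_identical(classify_interaction(0.90, 0.70, 1.10),
                   "consistent_with_additive")
  expect_identical(classify_interaction(1.30, 1.05, 1.60),
                   "less_than_additive")
  expect_identical(classify_interaction(0.95, 0.90, 1.00),
                   "consistent_with_additive")  # CI touching 1 crosses it
  expect_error(classify_interaction(1.0, 1.2, 0.9), "inverted|invalid")
  expect_error(classify_interaction(1.0, -0.1, 1.2), "inverted|invalid")
})

test_that("degenerate comparisons are reported as non-estimable", {
  # complete separation of event times: monotone partial likelihood
  ipd <- rbind(make_ipd(c(1, 2, 3), c(1, 1, 1), "a"),
               make_ipd(c(10, 11, 12), c(1, 1, 1), "b"))
  expect_error(cox_fit(ipd, "a", "b"), "non-estimable")
  # no events in one group
  ipd2 <- rbind(make_ipd(c(1, 2), c(1, 1), "a"),
                make_ipd(c(3, 4), c(0, 0), "b"))
  expect_error(cox_fit(ipd2, "a", "b"), "at least one event")
})
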