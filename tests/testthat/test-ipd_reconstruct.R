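test_that("single-drop curve inverts to the stated events and censorings", {
  cu <- interpolate_to_grid(km_coordinates(c(0, 5), c(1, 0.5), "x"),
                            grid_step = 5)
  ipd <- reconstruct_ipd(cu, risk_table(0, 10), total_events = 5)
  expect_equal(nrow(ipd), 10L)
  expect_equal(sum(ipd$event), 5L)
  expect_true(all(ipd$time[ipd$event == 1] == 5))
  expect_true(all(ipd$time[ipd$event == 0] == 5))  # censored at follow-up end
})

test_that("two-drop curve follows the hand product-limit recursion", {
  # S: 1 -> 0.75 (d = 4*(1-0.75) = 1 at t=1) -> 0.50 (0.5 = 0.75(1-d/3), d=1)
  cu <- interpolate_to_grid(km_coordinates(0:2, c(1, 0.75, 0.5), "x"),
                            grid_step = 1)
  ipd <- reconstruct_ipd(cu, risk_table(0, 4))
  expect_equal(ipd$time[ipd$event == 1], c(1, 2))
  expect_equal(sum(ipd$event == 0), 2L)
  expect_true(all(ipd$time[ipd$event == 0] == 2))
})

test_that("round trip on simulated data reproduces curve and risk counts", {
  set.seed(2024)
  n <- 300
  ev <- rexp(n, 0.06)
  cens <- pmin(runif(n, 0, 80), 60)
  ipd0 <- make_ipd(pmin(ev, cens), ev <= cens, "sim")
  dig <- digitize_like(ipd0, n_coordinates = 25, risk_table_step = 6)
  cu <- interpolate_to_grid(enforce_monotone(dig$coordinates),
                            grid_step = 0.5,
                            t_max = floor(max(dig$coordinates$time) * 2) / 2)
  rec <- reconstruct_ipd(cu, dig$risk_table, arm_label = "sim")
  fit <- km_estimate(rec, "sim")
  expect_lt(max(abs(km_survival_at(fit, cu$grid_times) - cu$survival)), 0.02)
  expect_equal(n_at_risk(rec, dig$risk_table$time),
               dig$risk_table$n_at_risk)
  expect_equal(nrow(rec), n)
})

test_that("event totals are conserved exactly when supplied", {
  set.seed(5)
  n <- 200
  ev <- rexp(n, 0.05); cens <- pmin(rexp(n, 0.02), 48)
  ipd0 <- make_ipd(pmin(ev, cens), ev <= cens, "sim")
  k <- sum(ipd0$event)
  dig <- digitize_like(ipd0, 25, 6)
  cu <- interpolate_to_grid(enforce_monotone(dig$coordinates), 0.5,
                            floor(max(dig$coordinates$time) * 2) / 2)
  rec <- reconstruct_ipd(cu, dig$risk_table, total_events = k)
  expect_equal(sum(rec$event), k)
  expect_error(reconstruct_ipd(cu, dig$risk_table, total_events = 1),
               "infeasible|total_events")
})

test_that("reconstruction is deterministic and never negative", {
  set.seed(9)
  ev <- rexp(150, 0.07); cens <- pmin(rexp(150, 0.01), 36)
  ipd0 <- make_ipd(pmin(ev, cens), ev <= cens, "a")
  dig <- digitize_like(ipd0, 20, 6)
  cu <- interpolate_to_grid(enforce_monotone(dig$coordinates), 0.5,
                            floor(max(dig$coordinates$time) * 2) / 2)
  r1 <- reconstruct_ipd(cu, dig$risk_table)
  r2 <- reconstruct_ipd(cu, dig$risk_table)
  expect_identical(r1$time, r2$time)
  expect_identical(r1$event, r2$event)
  expect_true(all(r1$time > 0))
  expect_true(all(r1$event %in% c(0L, 1L)))
})

test_that("risk tables beyond the curve and impossible targets error", {
  cu <- interpolate_to_grid(km_coordinates(c(0, 10), c(1, 0.6), "x"), 1)
  expect_error(reconstruct_ipd(cu, risk_table(c(0, 12), c(50, 10))),
               "beyond the curve")
  expect_error(reconstruct_ipd(cu, risk_table = NULL), "risk table")
})

test_that("product-limit estimate matches hand calculation", {
  ipd <- make_ipd(c(1, 2, 3, 3), c(1, 1, 0, 0), "z")
  fit <- km_estimate(ipd)
  expect_equal(km_survival_at(fit, c(0.5, 1, 2, 3)), c(1, 0.75, 0.5, 0.5))
  # all censored: flat at 1
  flat <- km_estimate(make_ipd(c(2, 4), c(0, 0), "z"))
  expect_equal(km_survival_at(flat, c(1, 4)), c(1, 1))
  # single subject with an event: drops to 0
  one <- km_estimate(make_ipd(2, 1, "z"))
  expect_equal(km_survival_at(one, c(1.9, 2)), c(1, 0))
  expect_error(km_estimate(ipd, "missing-arm"), "no records")
})

test_that("IPD CSV round trip preserves the dataset", {
  ipd <- make_ipd(c(1.5, 2, 3), c(1, 0, 1), "obs")
  f <- withr::local_tempfile(fileext = ".csv")
  write_ipd_csv(ipd, f)
  back <- read_ipd_csv(f)
  expect_equal(back$time, ipd$time)
  expect_equal(back$event, ipd$event)
  expect_equal(back$arm, ipd$arm)
})

test_that("borrowed risk tables rescale by the survival ratio", {
  a <- exp_curve(0.05, 24, label = "A")
  pred <- as_km_curve(predict_independent_action(
    a, exp_curve(0.04, 24), exp_curve(0.08, 24)))
  rt_a <- risk_table(c(0, 6, 12, 18, 24), c(1000, 700, 480, 330, 220))
  rt_p <- borrow_risk_table(pred, a, rt_a)
  expect_equal(rt_p$n_at_risk[1], 1000L)
  # S_pred/S_A = exp(0.04 t)
  expect_equal(rt_p$n_at_risk[2], round(700 * exp(0.04 * 6)))
  expect_true(all(diff(rt_p$n_at_risk) <= 0))
})
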