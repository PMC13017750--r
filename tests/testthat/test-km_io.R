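test_that("curve CSVs parse, deduplicate and validate", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# digitized test curve", "time_months,survival",
               "0,1.0", "6,0.93", "12,0.85"), p)
  co <- read_km_csv(p, arm_label = "doublet")
  expect_s3_class(co, "km_coordinates")
  expect_equal(co$time, c(0, 6, 12))
  expect_equal(co$survival, c(1, 0.93, 0.85))

  # duplicate digitized times collapse to the minimum survival value
  writeLines(c("time_months,survival", "0,1", "6,0.93", "6,0.92", "12,0.85"), p)
  co <- read_km_csv(p, "doublet")
  expect_equal(co$time, c(0, 6, 12))
  expect_equal(co$survival[2], 0.92)

  writeLines(c("time_months,survival", "0,1", "6,1.2"), p)
  expect_error(read_km_csv(p, "x"), "not percent")
  writeLines(c("time_months,survival", "0,1", "6,abc"), p)
  expect_error(read_km_csv(p, "x"), "non-numeric")
  writeLines(c("time,surv", "0,1", "6,0.9"), p)
  expect_error(read_km_csv(p, "x"), "time_months")
  expect_error(read_km_csv(file.path(tempdir(), "nope.csv"), "x"),
               "not found")
})

test_that("coordinate normalization anchors the origin and rejects bad input", {
  co <- km_coordinates(c(2, 6), c(0.9, 0.8), "x")
  expect_equal(co$time[1], 0)
  expect_equal(co$survival[1], 1)
  expect_error(km_coordinates(c(-1, 2), c(1, 0.9), "x"), "negative time")
  expect_error(km_coordinates(0, 1, "x"), "at least 2")
  # values just above 1 clamp; far above error
  co <- km_coordinates(c(0, 3), c(1 + 5e-7, 0.9), "x")
  expect_equal(co$survival[1], 1)
  expect_error(km_coordinates(c(0, 3), c(1, -0.2), "x"), "negative survival")
})

test_that("monotone enforcement is a running minimum and idempotent", {
  co <- km_coordinates(0:3, c(1.0, 0.95, 0.97, 0.90), "x")
  m1 <- enforce_monotone(co)
  expect_equal(m1$survival, c(1.0, 0.95, 0.95, 0.90))
  expect_equal(attr(m1, "n_repaired"), 1L)
  m2 <- enforce_monotone(m1)
  expect_equal(m2$survival, m1$survival)
  expect_equal(attr(m2, "n_repaired"), 0L)
  # ties allowed, already-monotone input untouched
  co <- km_coordinates(0:2, c(1, 1, 0.99), "x")
  expect_equal(enforce_monotone(co)$survival, c(1, 1, 0.99))
})

test_that("grid interpolation is linear, exact at knots, never extrapolates", {
  co <- km_coordinates(c(0, 1), c(1, 0.9), "x")
  cu <- interpolate_to_grid(co, grid_step = 0.5)
  expect_equal(cu$survival[cu$grid_times == 0.5], 0.95)
  co <- km_coordinates(c(0, 2, 4), c(1, 0.8, 0.8), "x")
  cu <- interpolate_to_grid(co, grid_step = 0.5, t_max = 4)
  expect_equal(cu$survival[cu$grid_times == 2], 0.8)    # knot exact
  expect_equal(cu$survival[cu$grid_times == 3], 0.8)    # flat segment
  expect_error(interpolate_to_grid(co, 0.5, t_max = 5), "extrapolation")
  expect_error(interpolate_to_grid(
    km_coordinates(0:2, c(1, 0.8, 0.9), "x"), 0.5), "enforce_monotone")
})

test_that("interpolation preserves monotonicity and reproduces grid-sampled curves", {
  set.seed(31)
  for (r in 1:20) {
    tm <- sort(c(0, runif(15, 0, 40)))
    sv <- cummin(c(1, runif(15, 0.1, 1)))
    co <- enforce_monotone(km_coordinates(tm, sv, "x"))
    cu <- interpolate_to_grid(co, 0.5, t_max = floor(max(tm) * 2) / 2)
    expect_true(all(diff(cu$survival) <= 1e-12))
    # round trip: re-interpolating a curve already on the grid is exact
    co2 <- km_coordinates(cu$grid_times, cu$survival, "x")
    cu2 <- interpolate_to_grid(co2, 0.5, t_max = max(cu$grid_times))
    expect_equal(cu2$survival, cu$survival, tolerance = 1e-12)
  }
})

test_that("risk tables validate and read from CSV", {
  rt <- risk_table(c(0, 6, 12), c(100, 80, 50))
  expect_s3_class(rt, "risk_table")
  expect_error(risk_table(c(0, 6), c(80, 100)), "non-increasing")
  expect_error(risk_table(c(6, 12), c(100, 80)), "start at time 0")
  expect_error(risk_table(c(0, 0), c(100, 80)), "strictly increasing")
  expect_error(risk_table(c(0, 6), c(100, -1)), "nonnegative")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_months,n_at_risk", "0,100", "6,80"), p)
  expect_equal(read_risk_table_csv(p)$n_at_risk, c(100L, 80L))
})

test_that("curves export to CSV and re-import identically", {
  cu <- exp_curve(0.05, t_end = 24, label = "arm A")
  p <- withr::local_tempfile(fileext = ".csv")
  write_km_csv(cu, p)
  back <- read_km_csv(p, "arm A")
  expect_equal(back$time, cu$grid_times)
  expect_equal(back$survival, cu$survival, tolerance = 1e-10)
})

test_that("common grid extent is the shortest follow-up", {
  a <- km_coordinates(c(0, 10), c(1, 0.5), "a")
  b <- km_coordinates(c(0, 30), c(1, 0.4), "b")
  expect_equal(common_t_max(a, b), 10)
  expect_equal(common_t_max(list(a, b)), 10)
})
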