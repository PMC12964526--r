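test_that("regression recovers exact linear responses", {
  pts <- data.frame(delta_calc = c(0, 50, 100, 200),
                    delta_measured = c(0, 50, 100, 200))
  m <- build_regression(pts)
  expect_equal(m$slope, 1)
  expect_equal(m$intercept, 0)
  pts$delta_measured <- 0.8 * pts$delta_calc + 2
  m <- build_regression(pts, fragment = "F99", element = "C")
  expect_equal(m$slope, 0.8, tolerance = 1e-9)
  expect_equal(m$intercept, 2, tolerance = 1e-9)
  expect_error(build_regression(data.frame(delta_calc = c(5, 5),
                                           delta_measured = c(1, 2))),
               "degenerate")
})

test_that("noisy regression recovers the slope within 3 SE", {
  set.seed(77)
  calc <- c(0, 50, 100, 200)
  meas <- 0.85 * calc + rnorm(4, 0, 2)
  m <- build_regression(data.frame(delta_calc = calc, delta_measured = meas))
  expect_lt(abs(m$slope - 0.85), 3 * m$slope_se)
})

test_that("mean recovered slope over 200 simulations is within 2% of truth", {
  set.seed(78)
  calc <- c(0, 50, 100, 200)
  slopes <- replicate(200, {
    meas <- 0.85 * calc + rnorm(4, 0, 2)
    build_regression(data.frame(delta_calc = calc,
                                delta_measured = meas))$slope
  })
  expect_lt(abs(mean(slopes) / 0.85 - 1), 0.02)
})

test_that("two-point calibration inverts the standard line", {
  expect_equal(two_point_calibrate(0, c(0, 0), c(100, 80)), 0)
  expect_equal(two_point_calibrate(80, c(0, 0), c(100, 80)), 100)
  expect_equal(two_point_calibrate(40, c(0, 0), c(100, 80)), 50)
  # identity instrument
  expect_equal(two_point_calibrate(37.2, c(0, 0), c(100, 100)), 37.2)
  expect_error(two_point_calibrate(1, c(0, 5), c(100, 5)), "identical")
})

test_that("two-point calibration exactly inverts any linear response", {
  set.seed(3)
  for (i in 1:25) {
    slope <- runif(1, 0.5, 1.5); icpt <- runif(1, -10, 10)
    lo <- runif(1, -20, 40); hi <- lo + runif(1, 30, 200)
    truth <- runif(1, -50, 250)
    measured <- icpt + slope * truth
    cal <- two_point_calibrate(measured,
                               c(lo, icpt + slope * lo),
                               c(hi, icpt + slope * hi))
    expect_equal(cal, truth, tolerance = 1e-12)
  }
})

test_that("two_point_model and build_regression agree on two points", {
  lo <- c(0, 1.5); hi <- c(100, 82)
  m1 <- two_point_model(lo, hi)
  m2 <- build_regression(data.frame(delta_calc = c(lo[1], hi[1]),
                                    delta_measured = c(lo[2], hi[2])))
  expect_equal(m1$slope, m2$slope)
  expect_equal(m1$intercept, m2$intercept)
  for (x in c(-10, 12.5, 140)) {
    expect_equal(apply_calibration(m1, x)$delta,
                 apply_calibration(m2, x)$delta)
    expect_equal(apply_calibration(m1, x)$delta,
                 two_point_calibrate(x, lo, hi))
  }
})

test_that("apply_calibration inverse-maps and scales uncertainty", {
  ident <- two_point_model(c(0, 0), c(100, 100))
  out <- apply_calibration(ident, 42, 1.3)
  expect_equal(out$delta, 42)
  expect_equal(out$sigma, 1.3)
  half <- two_point_model(c(0, 0), c(100, 50))
  out <- apply_calibration(half, 4, 1)
  expect_equal(out$delta, 8)
  expect_equal(out$sigma, 2)
  m08 <- two_point_model(c(0, 0), c(100, 80))
  expect_equal(apply_calibration(m08, 4)$delta, 5)
  flat <- two_point_model(c(0, 0), c(100, 1))
  expect_error(apply_calibration(flat, 1), "uncalibratable")
  # optional true-value (EA-IRMS) error enters by quadrature
  out <- apply_calibration(ident, 10, 3, extra_sigma_true = 4)
  expect_equal(out$sigma, 5)
})

test_that("identical-treatment check compares pathway tags", {
  expect_true(identical_treatment_check("lc_blocks/column",
                                        "lc_blocks/column"))
  bad <- identical_treatment_check("direct", "column")
  expect_false(as.logical(bad))
  expect_match(attr(bad, "message"), "identical-treatment violation")
  expect_error(identical_treatment_check(NULL, "column"), "missing")
  expect_error(identical_treatment_check("", "column"), "missing")
})

test_that("standard_def derives delta_calc by mass balance", {
  s <- standard_def("A3", "F92", "N", 66.6)
  expect_equal(s$delta_calc, 66.6 * 3)  # 1 of 3 N in F92
  s <- standard_def("D3", "F99", "N", 133.2)
  expect_equal(s$delta_calc, 133.2 * 3 / 2)
})

test_that("build_calibrations fits per fragment/element and checks counts", {
  standards <- data.frame(
    standard_id = c("A3", "D3"), fragment = "F99", element = "N",
    delta_bulk_shift = c(0, 133.2), sd = 0.3, stringsAsFactors = FALSE)
  measured <- data.frame(
    standard_id = c("A3", "D3"), fragment = "F99", element = "N",
    delta.permil = c(0, 0.8 * 133.2 * 1.5), stringsAsFactors = FALSE)
  models <- build_calibrations(measured, standards)
  expect_named(models, "F99.N")
  expect_equal(models$F99.N$kind, "two_point")
  expect_equal(models$F99.N$slope, 0.8)
  expect_error(build_calibrations(measured[1, ], standards),
               "insufficient standards")
})
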