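V_DEFAULT <- 4.364143e-14  # pi * 2.1^2 * 3.15 um^3 in litres

test_that("the linear estimator spans ~4 fM to ~40 pM over one chip", {
  # one positive in 10,000 chambers
  lo <- estimate_concentration(1e-4, V_DEFAULT)
  expect_equal(lo, 1e-4 / (V_DEFAULT * 6.02214076e23))
  expect_equal(lo, 3.805e-15, tolerance = 1e-3)
  # fraction 0 and full occupancy
  expect_equal(estimate_concentration(0, V_DEFAULT), 0)
  expect_equal(estimate_concentration(1, V_DEFAULT), 3.805e-11,
               tolerance = 1e-3)
  expect_error(estimate_concentration(1.2, V_DEFAULT), "0, 1")
  expect_error(estimate_concentration(0.5, -1), "positive")
})

test_that("Poisson correction inverts the loading law", {
  # f = 0.0903 corresponds to lambda ~ 0.0946 -> 3.6 pM
  expect_equal(estimate_concentration_poisson(0.0903, V_DEFAULT), 3.6e-12,
               tolerance = 2e-3)
  # small-f limit: corrected / linear -> 1
  f <- 1e-6
  expect_equal(estimate_concentration_poisson(f, V_DEFAULT) /
                 estimate_concentration(f, V_DEFAULT), 1, tolerance = 1e-5)
  # f = 0.5: corrected exceeds linear by ln(2)/0.5
  expect_equal(estimate_concentration_poisson(0.5, V_DEFAULT) /
                 estimate_concentration(0.5, V_DEFAULT), log(2) / 0.5)
  # corrected >= linear always, equality iff f = 0
  for (f in c(0, 0.01, 0.1, 0.5, 0.9)) {
    expect_gte(estimate_concentration_poisson(f, V_DEFAULT),
               estimate_concentration(f, V_DEFAULT))
  }
  expect_equal(estimate_concentration_poisson(0, V_DEFAULT), 0)
  expect_error(estimate_concentration_poisson(1, V_DEFAULT), "dilute")
})

test_that("concentration estimates scale inversely with chamber volume", {
  expect_equal(estimate_concentration(0.1, V_DEFAULT / 2),
               2 * estimate_concentration(0.1, V_DEFAULT))
  expect_equal(estimate_concentration_poisson(0.1, V_DEFAULT / 2),
               2 * estimate_concentration_poisson(0.1, V_DEFAULT))
})

test_that("detection time follows the initially-quiet trigger rule", {
  tc <- time_course(seq(0, 10, 2), c(0, 1, 2, 5, 11, 30), 10000)
  expect_equal(detection_time(tc), 8)
  # never exceeded
  tc2 <- time_course(seq(0, 10, 2), c(0, 1, 2, 5, 9, 10), 10000)
  expect_true(is.na(detection_time(tc2)))
  # precondition violation: warning, result still computed
  tc3 <- time_course(seq(0, 6, 2), c(12, 50, 80, 90), 10000)
  expect_warning(dt3 <- detection_time(tc3), "initial_max")
  expect_equal(dt3, 0)
  expect_error(time_course(numeric(0), integer(0), 100), "empty")
  expect_error(time_course(c(0, 2), c(1, 2, 3), 100), "equal length")
})

test_that("quantification time finds the first sub-20% consecutive change", {
  tc <- time_course(seq(0, 12, 2), c(0, 2, 12, 40, 80, 100, 110), 10000)
  # |110-100|/100 = 0.10 < 0.2; every earlier post-detection pair >= 0.2
  expect_equal(quantification_time(tc, detection_t = 4), 12)
  # constant counts after detection: first frame after detection
  tcc <- time_course(seq(0, 8, 2), c(0, 11, 11, 11, 11), 100)
  expect_equal(quantification_time(tcc, detection_t = 2), 4)
  # exponential growth (50% change each frame): never satisfied
  tce <- time_course(seq(0, 10, 2), round(12 * 1.5^(0:5)), 1e5)
  expect_true(is.na(quantification_time(tce, detection_t = 0)))
  # zero previous count is skipped, not divided by
  tcz <- time_course(seq(0, 6, 2), c(0, 0, 11, 12), 100)
  expect_equal(quantification_time(tcz, detection_t = 4), 6)
  expect_error(quantification_time(tc, detection_t = 3), "acquisition times")
})

test_that("time metrics ignore frames appended after the quantification time", {
  tc <- time_course(seq(0, 12, 2), c(0, 2, 12, 40, 80, 100, 110), 10000)
  dt <- detection_time(tc)
  qt <- quantification_time(tc, dt)
  tc_ext <- time_course(seq(0, 20, 2),
                        c(0, 2, 12, 40, 80, 100, 110, 112, 113, 113, 500),
                        10000)
  expect_equal(detection_time(tc_ext), dt)
  expect_equal(quantification_time(tc_ext, dt), qt)
})

test_that("replicate CV is the percent sample SD over the mean", {
  expect_equal(replicate_cv(c(10, 10, 10)), 0)
  # sd([8, 12]) = 2.8284 (n - 1 denominator), mean = 10
  expect_equal(replicate_cv(c(8, 12)), 100 * sqrt(8) / 10)
  expect_equal(replicate_cv(c(8, 12)), 28.28, tolerance = 1e-3)
  # scale invariance
  expect_equal(replicate_cv(c(3, 5, 9) * 17), replicate_cv(c(3, 5, 9)))
  expect_error(replicate_cv(5), "at least 2")
  expect_error(replicate_cv(c(-2, 2)), "positive")
})

test_that("quantify_chambers assembles a consistent summary", {
  m <- structure(
    data.frame(roi_id = 1:20, center_x_px = 0, center_y_px = 0,
               mean_intensity = c(rep(500, 4), rep(100, 16)), rog = 4,
               excluded = FALSE, label = c(rep("positive", 4),
                                           rep("negative", 16))),
    class = c("chamber_measurements", "data.frame"))
  q <- quantify_chambers(m, V_DEFAULT)
  expect_equal(q$n_total, 20)
  expect_equal(q$n_positive, 4)
  expect_equal(q$positive_fraction, 0.2)
  expect_equal(q$concentration_estimate_M,
               estimate_concentration(0.2, V_DEFAULT))
  expect_equal(q$concentration_poisson_M,
               estimate_concentration_poisson(0.2, V_DEFAULT))
  expect_gte(q$concentration_poisson_M, q$concentration_estimate_M)
})
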