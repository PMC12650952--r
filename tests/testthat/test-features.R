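test_that("radius of gyration reproduces closed-form and brute-force values", {
  # uniform 16x16: per-axis sum of (x - 7.5)^2 is 340 -> 340/16 = 21.25
  # per axis, ROG = sqrt(42.5)
  expect_equal(radius_of_gyration(matrix(1, 16, 16)), sqrt(42.5))
  expect_equal(radius_of_gyration(matrix(123.4, 16, 16)), sqrt(42.5))
  # single bright pixel at (x, y) = (8, 8): distance to (7.5, 7.5)
  m <- matrix(0, 16, 16); m[9, 9] <- 5
  expect_equal(radius_of_gyration(m), sqrt(0.5))
  # centred disk of radius 5: inside the derived band, below uniform
  d <- disk_crop(16, 5, 100)
  expect_equal(radius_of_gyration(d), rog_brute(d), tolerance = 1e-12)
  expect_gt(radius_of_gyration(d), 3.0)
  expect_lt(radius_of_gyration(d), 4.2)
  # non-square crops agree with the brute-force oracle too
  r <- matrix(runif(12 * 20), 12, 20)
  expect_equal(radius_of_gyration(r), rog_brute(r), tolerance = 1e-12)
  # errors
  expect_error(radius_of_gyration(matrix(-1, 4, 4)), "nonnegative")
  expect_error(radius_of_gyration(matrix(0, 4, 4)),
               class = "digitalchip_zero_mass")
})

test_that("ROG properties: scale invariant, offset sensitive, spot-bounded", {
  set.seed(101)
  rmax <- sqrt(2) * 7.5  # largest centre distance in a 16x16 crop
  for (i in 1:50) {
    crop <- matrix(runif(256, 0, 100), 16, 16)
    rog <- radius_of_gyration(crop)
    expect_equal(rog, rog_brute(crop), tolerance = 1e-10)
    # multiplicative rescaling leaves ROG unchanged
    expect_equal(radius_of_gyration(crop * 7.3), rog)
    # additive offsets change it (pull toward the uniform value)
    expect_false(isTRUE(all.equal(radius_of_gyration(crop + 50), rog)))
    # hard bound: ROG is a weighted RMS centre distance
    expect_lte(rog, rmax)
  }
  # chamber-like crops (background + centred spot) never exceed the
  # uniform-crop ROG; equality only when the spot vanishes
  for (i in 1:20) {
    crop <- matrix(runif(1, 1, 50), 16, 16) +
      disk_crop(16, runif(1, 2, 6), runif(1, 10, 500))
    expect_lt(radius_of_gyration(crop), sqrt(42.5))
  }
  expect_equal(radius_of_gyration(matrix(2, 16, 16)), sqrt(42.5))
  spot <- matrix(1, 16, 16); spot[8, 8] <- 10
  expect_lt(radius_of_gyration(spot), sqrt(42.5))
})

test_that("mean ROI intensity averages pixels inside the circle", {
  # constant image
  expect_equal(mean_roi_intensity(matrix(4.2, 30, 30), 15, 15, 10), 4.2)
  # 10-px hard disk of 100 on 0, concentric ROI: mean >= 95
  img <- matrix(0, 40, 40)
  xy <- 0:39
  mask <- outer((xy - 20)^2, (xy - 20)^2, "+") <= 25
  img[mask] <- 100
  expect_gte(mean_roi_intensity(img, 20, 20, 10), 95)
  # exact oracle: ROI pixel set equals the disk pixel set here
  expect_equal(mean_roi_intensity(img, 20, 20, 10), 100)
  # linearity
  expect_equal(mean_roi_intensity(img * 2, 20, 20, 10),
               2 * mean_roi_intensity(img, 20, 20, 10))
  expect_error(mean_roi_intensity(img, 2, 2, 10), "beyond")
})

test_that("vectorised chamber measurement equals the scalar operations", {
  g <- small_geometry(6)
  tr <- simulate_loading(2e-11, g, seed = 7)
  fr <- render_frame(tr, g, seed = 7, noise = noise_model(artifact_rate = 0))
  rois <- detect_chambers(fr$reference, 10, 0.6 * chamber_pitch_px(g))
  m <- measure_chambers(fr$signal, rois)
  for (i in sample.int(nrow(m), 10)) {
    expect_equal(m$mean_intensity[i],
                 mean_roi_intensity(fr$signal, m$center_x_px[i],
                                    m$center_y_px[i], 10))
    expect_equal(m$rog[i],
                 rog_brute(crop_region(fr$signal, m$center_x_px[i],
                                       m$center_y_px[i], 16)),
                 tolerance = 1e-10)
  }
})

test_that("Gaussian histogram fit recovers mu + k*sigma thresholds", {
  set.seed(2)
  x <- rnorm(10000, 100, 5)
  th <- fit_intensity_threshold(x, k_sd = 15)
  expect_equal(th$method, "gaussian_fit")
  expect_lt(abs(th$intensity_threshold - 175), 3)
  expect_gt(th$intensity_threshold, th$intensity_mu)

  # 5% bright contamination: fit locks onto the dominant mode while the
  # plain mean is pulled to ~115
  set.seed(3)
  xc <- c(rnorm(9500, 100, 5), rnorm(500, 400, 10))
  thc <- fit_intensity_threshold(xc, k_sd = 15)
  expect_gt(mean(xc), 110)
  expect_gte(thc$intensity_mu, 98)
  expect_lte(thc$intensity_mu, 102)

  # degenerate and undersized inputs
  expect_error(fit_intensity_threshold(rep(7, 500)),
               class = "digitalchip_degenerate")
  expect_error(fit_intensity_threshold(rnorm(50)), "at least 100")
})

test_that("the logic tree classifies by ROG gate first, then intensity", {
  th <- digitalchip:::threshold_set(intensity_mu = 100, intensity_sigma = 5,
                                    k_sd = 15, intensity_threshold = 175,
                                    rog_threshold = 5.5)
  mk <- function(rog, mi, excluded = FALSE)
    structure(data.frame(roi_id = 1L, center_x_px = 0, center_y_px = 0,
                         mean_intensity = mi, rog = rog,
                         excluded = excluded),
              class = c("chamber_measurements", "data.frame"))
  lab <- function(m) classify_chambers(m, th)$label
  # high ROG vetoes even a very bright chamber
  expect_equal(lab(mk(6.4, 1750)), "negative")
  # boundary: ties are negative (strict comparisons)
  expect_equal(lab(mk(3.5, 175)), "negative")
  expect_equal(lab(mk(3.5, 175 + 1e-9)), "positive")
  expect_equal(lab(mk(5.5, 200)), "positive")   # rog == threshold passes
  expect_equal(lab(mk(5.5 + 1e-9, 200)), "negative")
  # undefined ROG -> negative
  expect_equal(lab(mk(NA_real_, 1e6)), "negative")
  # excluded chambers are always negative
  expect_equal(lab(mk(3.5, 1e6, excluded = TRUE)), "negative")
  # pure function: repeated calls agree
  expect_identical(lab(mk(3.5, 200)), lab(mk(3.5, 200)))
})

test_that("manual exclusions adjust the post-exclusion denominator only", {
  m <- structure(
    data.frame(roi_id = 1:10, center_x_px = 0, center_y_px = 0,
               mean_intensity = c(rep(500, 3), rep(100, 7)),
               rog = 4, excluded = FALSE),
    class = c("chamber_measurements", "data.frame"))
  th <- digitalchip:::threshold_set(100, 5, 15, 175, 5.5)

  expect_identical(apply_exclusions(m, integer(0)), m)
  expect_error(apply_exclusions(m, c(3, 99)), "unknown roi_id")

  base <- quantify_chambers(classify_chambers(m, th), 4.364e-14)
  expect_equal(base$n_positive, 3)
  expect_equal(base$positive_fraction, 0.3)

  # excluding k chambers reduces the denominator by k
  ex <- quantify_chambers(classify_chambers(apply_exclusions(m, c(5, 6)), th),
                          4.364e-14)
  expect_equal(ex$n_total, 10)
  expect_equal(ex$n_excluded, 2)
  expect_equal(ex$positive_fraction, 3 / 8)

  # excluding all positives zeroes the count but not the raw total
  ex2 <- quantify_chambers(classify_chambers(apply_exclusions(m, 1:3), th),
                           4.364e-14)
  expect_equal(ex2$n_positive, 0)
  expect_equal(ex2$n_total, 10)
})
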