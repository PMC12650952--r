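test_that("Poisson loading hits the expected occupancy and edge cases", {
  g <- chip_geometry()  # 10,000 chambers, V = 43.64 fL

  # zero concentration: empty chip
  t0 <- simulate_loading(0, g, seed = 1)
  expect_true(all(t0$n_templates == 0))
  expect_equal(sum(t0$is_positive), 0)

  # 3.6 pM: lambda = c * V * N_A ~ 0.0946, occupied fraction ~ 0.090
  lam <- 3.6e-12 * chamber_volume(4.2, 3.15) * 6.02214076e23
  expect_equal(lam, 0.0946, tolerance = 1e-3)
  tr <- simulate_loading(3.6e-12, g, seed = 2)
  p <- 1 - exp(-lam)
  se <- sqrt(p * (1 - p) / nrow(tr))
  expect_lt(abs(mean(tr$n_templates >= 1) - p), 3 * se)
  # efficiency 1: every occupied chamber is positive
  expect_equal(tr$is_positive, tr$n_templates >= 1)
  # onset times only for positives, nonnegative
  expect_true(all(is.na(tr$onset_time_min[!tr$is_positive])))
  expect_true(all(tr$onset_time_min[tr$is_positive] >= 0))

  # efficiency 0: occupancy unchanged, zero positives
  tz <- simulate_loading(3.6e-12, g, amplification_efficiency = 0, seed = 2)
  expect_gt(sum(tz$n_templates >= 1), 0)
  expect_equal(sum(tz$is_positive), 0)

  expect_error(simulate_loading(-1e-12, g), "nonnegative")
  expect_error(simulate_loading(3.6e-12, g, amplification_efficiency = 1.5),
               "0, 1")
})

test_that("occupancy law holds over 1e5 chambers within 3 binomial SE", {
  g <- chip_geometry(n_rows = 250, n_cols = 400)
  tr <- simulate_loading(3.6e-12, g, seed = 11)
  lam <- attr(tr, "lambda")
  p <- 1 - exp(-lam)
  phat <- mean(tr$n_templates >= 1)
  expect_lt(abs(phat - p), 3 * sqrt(phat * (1 - phat) / nrow(tr)))
})

test_that("loading is deterministic under a fixed seed", {
  g <- small_geometry(8)
  a <- simulate_loading(3.6e-12, g, seed = 42)
  b <- simulate_loading(3.6e-12, g, seed = 42)
  expect_identical(a, b)
  c <- simulate_loading(3.6e-12, g, seed = 43)
  expect_false(identical(a$n_templates, c$n_templates))
})

test_that("rendered frames follow the kinetics limits", {
  g <- small_geometry(6)
  kin <- kinetics_model()
  tr <- simulate_loading(2e-11, g, kinetics = kin, seed = 3)
  expect_gt(sum(tr$is_positive), 0)
  nf <- noise_free()

  # pre-onset: a positive with onset > 5 min is indistinguishable from a
  # negative at t = 0
  early <- render_frame(tr, g, time_min = 0, kinetics = kin, noise = nf,
                        seed = 3)
  ip <- which(tr$is_positive & tr$onset_time_min > 5)[1]
  ineg <- which(!tr$is_positive)[1]
  mi_pos <- mean_roi_intensity(early$signal, tr$center_x_px[ip],
                               tr$center_y_px[ip])
  mi_neg <- mean_roi_intensity(early$signal, tr$center_x_px[ineg],
                               tr$center_y_px[ineg])
  expect_lt(abs(mi_pos - mi_neg) / mi_neg, 0.05)

  # t -> infinity: positive disk mean approaches the plateau
  late <- render_frame(tr, g, time_min = 1e4, kinetics = kin, noise = nf,
                       seed = 3)
  core <- crop_region(late$signal, round(tr$center_x_px[ip]),
                      round(tr$center_y_px[ip]), 4)
  expect_equal(mean(core), nf$background_level + kin$plateau,
               tolerance = 1e-3)

  # noise-free positive crop: ROG strictly below the uniform 16x16 value
  crop <- crop_region(late$signal, round(tr$center_x_px[ip]),
                      round(tr$center_y_px[ip]), 16)
  expect_lt(radius_of_gyration(crop), sqrt(42.5))
  expect_equal(radius_of_gyration(crop), rog_brute(crop), tolerance = 1e-12)

  expect_error(render_frame(tr, g, time_min = -1), ">= 0")
})

test_that("time series share truth and artifacts but draw noise per frame", {
  g <- small_geometry(6)
  nf <- noise_free()
  tr <- simulate_loading(2e-11, g, seed = 4)

  # singleton series identical to a single frame at the same seed
  ts1 <- render_timeseries(tr, g, times_min = 0, noise = nf, seed = 9)
  fr <- render_frame(tr, g, time_min = 0, noise = nf, seed = 9)
  expect_identical(ts1$frames[[1]]$signal, fr$signal)
  expect_identical(ts1$frames[[1]]$reference, fr$reference)

  # monotone noise-free positive intensity across frames
  ts <- render_timeseries(tr, g, times_min = seq(0, 30, 5), noise = nf,
                          seed = 9)
  ip <- which(tr$is_positive)[1]
  mi <- vapply(ts$frames, function(f)
    mean_roi_intensity(f$signal, tr$center_x_px[ip], tr$center_y_px[ip]),
    numeric(1))
  expect_true(all(diff(mi) >= 0))

  # noisy series: independent per-frame noise
  tsn <- render_timeseries(tr, g, times_min = c(0, 2), seed = 9,
                           noise = noise_model(artifact_rate = 0))
  expect_false(identical(tsn$frames[[1]]$reference,
                         tsn$frames[[2]]$reference))

  expect_error(render_timeseries(tr, g, times_min = numeric(0)),
               "at least one")
  expect_error(render_timeseries(tr, g, times_min = c(0, 0)),
               "strictly increasing")

  # determinism: same seed, bit-identical images
  a <- render_timeseries(tr, g, times_min = c(0, 10), seed = 5)
  b <- render_timeseries(tr, g, times_min = c(0, 10), seed = 5)
  expect_identical(a, b)
})

test_that("positive-count curve saturates at the truth's positive count", {
  g <- small_geometry(10)
  tr <- simulate_loading(2e-11, g, seed = 6)
  ts <- render_timeseries(tr, g, times_min = seq(0, 30, 2),
                          noise = noise_free(), seed = 6)
  tl <- analyze_timelapse(ts$frames, ts$times_min,
                          min_separation_px = 0.6 * chamber_pitch_px(g))
  counts <- tl$tc$n_positive
  # sigmoidal: quiet start, saturated end at the true positive count
  expect_lte(counts[1], 2)
  expect_equal(counts[length(counts)], sum(tr$is_positive))
  expect_equal(max(counts), sum(tr$is_positive))
})

test_that("artifact sampling respects the size invariant and flags coverage", {
  g <- small_geometry(10)
  nz <- noise_model(artifact_rate = 5)
  expect_error(
    sample_artifacts(noise_model(artifact_rate = 1,
                                 artifact_diameter_px_range = c(4, 8)),
                     g, seed = 1),
    "exceed the chamber diameter")
  art <- sample_artifacts(nz, g, seed = 21)
  expect_true(all(art$diameter_px > chamber_diameter_px(g)))
  tr <- simulate_loading(3.6e-12, g, seed = 21)
  tr2 <- flag_artifact_coverage(tr, art)
  # coverage flags match a direct distance check
  for (i in sample.int(nrow(tr2), 20)) {
    manual <- any((tr2$center_x_px[i] - art$x_px)^2 +
                    (tr2$center_y_px[i] - art$y_px)^2 <=
                    (art$diameter_px / 2)^2)
    expect_identical(tr2$covered_by_artifact[i], manual)
  }
})
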