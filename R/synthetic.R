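#' Amplification kinetics model for synthetic chips
#'
#' Parameterises the fluorescence time course of an amplification-positive
#' chamber as a logistic rise: intensity(t) = baseline +
#' (plateau - baseline) * sigmoid((t - onset) / rise_tau). Onset times vary
#' from chamber to chamber (single-molecule stochasticity) and are drawn
#' from a normal distribution truncated at zero.
#'
#' @param baseline Pre-amplification chamber intensity (a.u.) above the
#'   image background.
#' @param plateau Saturated post-amplification chamber intensity (a.u.).
#' @param onset_mean_min,onset_sd_min Mean and SD of the per-chamber onset
#'   time (minutes).
#' @param rise_tau_min Time constant of the logistic rise (minutes).
#' @return An object of class `kinetics_model`.
#' @export
kinetics_model <- function(baseline = 120, plateau = 800,
                           onset_mean_min = 10, onset_sd_min = 3,
                           rise_tau_min = 2) {
  stopifnot(baseline >= 0, plateau > baseline,
            onset_sd_min >= 0, rise_tau_min > 0)
  structure(
    list(baseline = baseline, plateau = plateau,
         onset_mean_min = onset_mean_min, onset_sd_min = onset_sd_min,
         rise_tau_min = rise_tau_min),
    class = "kinetics_model"
  )
}

#' Imaging noise and artifact model for synthetic chips
#'
#' Shot noise treats pixel values as photon counts (Poisson with mean equal
#' to the noiseless value); read noise is additive Gaussian. Artifacts
#' emulate large diffuse autofluorescent objects (air bubbles, aggregates)
#' that can cover several chambers in the signal channel; their diameters
#' must exceed the chamber diameter, which is what makes them separable by
#' the radius-of-gyration gate.
#'
#' @param read_noise_sd Additive Gaussian noise SD (a.u.).
#' @param background_level Constant image background (a.u.).
#' @param shot_noise_enabled Apply Poisson shot noise before read noise?
#' @param artifact_rate Expected number of artifacts per image (Poisson).
#' @param artifact_diameter_px_range Min/max artifact diameter in pixels.
#' @param artifact_intensity_range Min/max artifact peak intensity (a.u.).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(read_noise_sd = 5, background_level = 100,
                        shot_noise_enabled = TRUE, artifact_rate = 2,
                        artifact_diameter_px_range = c(30, 80),
                        artifact_intensity_range = c(150, 400)) {
  stopifnot(read_noise_sd >= 0, background_level >= 0, artifact_rate >= 0,
            length(artifact_diameter_px_range) == 2,
            length(artifact_intensity_range) == 2,
            all(artifact_diameter_px_range > 0),
            diff(artifact_diameter_px_range) >= 0,
            all(artifact_intensity_range >= 0),
            diff(artifact_intensity_range) >= 0)
  structure(
    list(read_noise_sd = read_noise_sd, background_level = background_level,
         shot_noise_enabled = isTRUE(shot_noise_enabled),
         artifact_rate = artifact_rate,
         artifact_diameter_px_range = artifact_diameter_px_range,
         artifact_intensity_range = artifact_intensity_range),
    class = "noise_model"
  )
}

#' A noiseless, artifact-free noise model
#'
#' Convenience constructor for ideal-rendering experiments (exact
#' round-trip tests, estimator calibration).
#' @return A [noise_model()] with all noise sources off.
#' @export
noise_free <- function() {
  noise_model(read_noise_sd = 0, background_level = 100,
              shot_noise_enabled = FALSE, artifact_rate = 0)
}

#' Simulate Poisson single-molecule loading of a chamber array
#'
#' Each chamber draws its template-molecule count from a Poisson law with
#' mean lambda = concentration * V * N_A, where V is the chamber volume.
#' An occupied chamber (>= 1 template) becomes amplification-positive with
#' probability `amplification_efficiency`; positives receive a fluorescence
#' onset time drawn from the kinetics model.
#'
#' Draw order under `set.seed(seed)`: template counts for all chambers
#' (row-major), then amplification-success uniforms, then onset times.
#'
#' @param concentration_M Template concentration in mol/L. Must be >= 0.
#' @param geometry A [chip_geometry()].
#' @param amplification_efficiency Probability in `[0, 1]` that an occupied
#'   chamber amplifies. Default 1.
#' @param kinetics A [kinetics_model()] supplying onset-time parameters.
#' @param seed Integer seed; the truth table is a deterministic function of
#'   the seed and parameters.
#' @return A data frame of class `assay_truth` with one row per chamber:
#'   `row`, `col`, `center_x_px`, `center_y_px` (0-based pixel centres),
#'   `n_templates`, `is_positive`, `onset_time_min` (NA for negatives) and
#'   `covered_by_artifact`. The expected occupancy `lambda`, the geometry
#'   and the input concentration are attached as attributes.
#' @examples
#' truth <- simulate_loading(3.6e-12, chip_geometry(n_rows = 20, n_cols = 20),
#'                           seed = 1)
#' mean(truth$n_templates >= 1)  # ~ 1 - exp(-0.0946)
#' @export
simulate_loading <- function(concentration_M, geometry = chip_geometry(),
                             amplification_efficiency = 1,
                             kinetics = kinetics_model(), seed = 1L) {
  if (!is.numeric(concentration_M) || length(concentration_M) != 1 ||
      is.na(concentration_M) || concentration_M < 0)
    stop("concentration_M must be a single nonnegative number", call. = FALSE)
  if (amplification_efficiency < 0 || amplification_efficiency > 1)
    stop("amplification_efficiency must be in [0, 1]", call. = FALSE)

  vol <- chamber_volume(geometry$chamber_diameter_um,
                        geometry$chamber_depth_um)
  lambda <- chamber_lambda(concentration_M, vol)
  truth <- chamber_centers(geometry)
  n <- nrow(truth)

  set.seed(as.integer(seed))
  truth$n_templates <- stats::rpois(n, lambda)
  amplified <- stats::runif(n) <= amplification_efficiency
  truth$is_positive <- truth$n_templates >= 1 & amplified
  onset <- pmax(0, stats::rnorm(n, kinetics$onset_mean_min,
                                kinetics$onset_sd_min))
  truth$onset_time_min <- ifelse(truth$is_positive, onset, NA_real_)
  truth$covered_by_artifact <- FALSE

  structure(truth,
            lambda = lambda,
            concentration_M = concentration_M,
            geometry = geometry,
            seed = as.integer(seed),
            class = c("assay_truth", "data.frame"))
}

#' Sample diffuse autofluorescent artifacts
#'
#' Draws Poisson(`artifact_rate`) artifact positions uniformly over the
#' image, with diameters and peak intensities uniform in the configured
#' ranges. Artifacts represent physical objects (bubbles, aggregates), so a
#' time-lapse series shares one artifact set across frames.
#'
#' @param noise A [noise_model()].
#' @param geometry A [chip_geometry()].
#' @param seed Integer seed.
#' @return Data frame with columns `x_px`, `y_px`, `diameter_px`,
#'   `intensity`.
#' @export
sample_artifacts <- function(noise, geometry, seed = 1L) {
  if (noise$artifact_rate > 0 &&
      min(noise$artifact_diameter_px_range) <= chamber_diameter_px(geometry))
    stop("artifact diameters must exceed the chamber diameter", call. = FALSE)
  dims <- chip_image_dim(geometry)
  set.seed(as.integer(seed))
  k <- stats::rpois(1, noise$artifact_rate)
  data.frame(
    x_px = stats::runif(k, 0, dims["width"] - 1),
    y_px = stats::runif(k, 0, dims["height"] - 1),
    diameter_px = stats::runif(k, noise$artifact_diameter_px_range[1],
                               noise$artifact_diameter_px_range[2]),
    intensity = stats::runif(k, noise$artifact_intensity_range[1],
                             noise$artifact_intensity_range[2])
  )
}

#' Flag chambers covered by artifacts
#'
#' Marks `covered_by_artifact` for every chamber whose centre lies within
#' an artifact radius of the artifact centre.
#'
#' @param truth An `assay_truth` table.
#' @param artifacts Output of [sample_artifacts()].
#' @return The truth table with `covered_by_artifact` updated.
#' @export
flag_artifact_coverage <- function(truth, artifacts) {
  covered <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(artifacts))) {
    r2 <- (artifacts$diameter_px[i] / 2)^2
    covered <- covered |
      ((truth$center_x_px - artifacts$x_px[i])^2 +
       (truth$center_y_px - artifacts$y_px[i])^2) <= r2
  }
  truth$covered_by_artifact <- covered
  truth
}

# Soft-disk stamp: weight = pnorm((R - r)/edge_sd) on a (2*ext+1)^2 grid,
# cached per fractional centre offset (the lattice pitch is a rational
# number of pixels, so only a few distinct offsets occur).
disk_stamp_cache <- new.env(parent = emptyenv())

disk_stamp <- function(fx, fy, radius, edge_sd = 0.5) {
  key <- sprintf("%.6f_%.6f_%.4f_%.4f", fx, fy, radius, edge_sd)
  got <- disk_stamp_cache[[key]]
  if (!is.null(got)) return(got)
  ext <- ceiling(radius + 3 * edge_sd)
  rel <- seq.int(-ext, ext)
  r <- sqrt(outer((rel - fy)^2, (rel - fx)^2, "+"))
  w <- stats::pnorm((radius - r) / edge_sd)
  out <- list(w = w, ext = ext)
  disk_stamp_cache[[key]] <- out
  out
}

# Add soft disks (or Gaussian blobs) to an image. 0-based centres.
add_disks <- function(img, cx, cy, amplitude, radius, edge_sd = 0.5) {
  h <- nrow(img); w <- ncol(img)
  for (i in seq_along(cx)) {
    if (amplitude[i] == 0) next
    bx <- floor(cx[i]); by <- floor(cy[i])
    st <- disk_stamp(cx[i] - bx, cy[i] - by, radius, edge_sd)
    ext <- st$ext
    xs <- (bx - ext):(bx + ext)
    ys <- (by - ext):(by + ext)
    keep_x <- xs >= 0 & xs <= w - 1
    keep_y <- ys >= 0 & ys <= h - 1
    img[ys[keep_y] + 1L, xs[keep_x] + 1L] <-
      img[ys[keep_y] + 1L, xs[keep_x] + 1L] +
      amplitude[i] * st$w[keep_y, keep_x, drop = FALSE]
  }
  img
}

add_blobs <- function(img, artifacts) {
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(nrow(artifacts))) {
    sigma <- artifacts$diameter_px[i] / 4
    ext <- ceiling(3 * sigma)
    bx <- round(artifacts$x_px[i]); by <- round(artifacts$y_px[i])
    xs <- max(0, bx - ext):min(w - 1, bx + ext)
    ys <- max(0, by - ext):min(h - 1, by + ext)
    r2 <- outer((ys - artifacts$y_px[i])^2, (xs - artifacts$x_px[i])^2, "+")
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] +
      artifacts$intensity[i] * exp(-r2 / (2 * sigma^2))
  }
  img
}

apply_noise <- function(img, noise) {
  if (noise$shot_noise_enabled) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                  nrow = nrow(img))
  }
  if (noise$read_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise$read_noise_sd)
  }
  pmax(img, 0)
}

#' Render one two-channel chip frame
#'
#' The reference channel shows every chamber as a uniform soft-edged disk
#' of the chamber diameter above background (emulating a reference dye
#' filling all chambers). The signal channel shows positives at
#' `baseline + (plateau - baseline) * sigmoid((t - onset)/rise_tau)` and
#' negatives at baseline; diffuse artifacts are then added to the signal
#' channel and noise is applied last to both channels.
#'
#' Disk edges get ~1 px of Gaussian softening (error-function profile,
#' `edge_sd` = 0.5 px) to emulate optical blur.
#'
#' Seed usage: artifacts are sampled under `seed` (when not supplied) and
#' pixel noise under `seed + 1`, so [render_timeseries()] frames can share
#' artifacts while drawing independent noise.
#'
#' @param truth An `assay_truth` table from [simulate_loading()].
#' @param geometry A [chip_geometry()] (defaults to the one stored in
#'   `truth`).
#' @param time_min Acquisition time in minutes (>= 0).
#' @param kinetics A [kinetics_model()].
#' @param noise A [noise_model()].
#' @param seed Integer seed for artifacts and noise.
#' @param artifacts Optional pre-sampled artifact table (shared across a
#'   series); if `NULL`, sampled from `seed`.
#' @param ref_amplitude Reference-channel disk amplitude above background
#'   (a.u.).
#' @return An object of class `chip_frame`: list with `reference` and
#'   `signal` matrices (row = y, column = x), `time_min` and `artifacts`.
#' @export
render_frame <- function(truth, geometry = attr(truth, "geometry"),
                         time_min = 30, kinetics = kinetics_model(),
                         noise = noise_model(), seed = 1L,
                         artifacts = NULL, ref_amplitude = 500) {
  if (time_min < 0) stop("time_min must be >= 0", call. = FALSE)
  if (is.null(geometry)) stop("geometry required", call. = FALSE)
  dims <- chip_image_dim(geometry)
  if (any(dims < 2 * geometry$margin_px))
    stop("geometry too small to place the chamber grid", call. = FALSE)
  radius <- chamber_diameter_px(geometry) / 2

  if (is.null(artifacts)) artifacts <- sample_artifacts(noise, geometry, seed)

  ref <- matrix(noise$background_level, dims["height"], dims["width"])
  ref <- add_disks(ref, truth$center_x_px, truth$center_y_px,
                   rep(ref_amplitude, nrow(truth)), radius)

  amp <- rep(kinetics$baseline, nrow(truth))
  pos <- which(truth$is_positive)
  if (length(pos)) {
    amp[pos] <- kinetics$baseline +
      (kinetics$plateau - kinetics$baseline) *
      stats::plogis((time_min - truth$onset_time_min[pos]) /
                    kinetics$rise_tau_min)
  }
  sig <- matrix(noise$background_level, dims["height"], dims["width"])
  sig <- add_disks(sig, truth$center_x_px, truth$center_y_px, amp, radius)
  if (nrow(artifacts)) sig <- add_blobs(sig, artifacts)

  set.seed(as.integer(seed) + 1L)
  ref <- apply_noise(ref, noise)
  sig <- apply_noise(sig, noise)

  structure(list(reference = ref, signal = sig, time_min = time_min,
                 artifacts = artifacts),
            class = "chip_frame")
}

#' Render a time-lapse series of chip frames
#'
#' One frame per acquisition time. Chamber positions, ground truth and
#' artifacts are identical across frames; pixel noise is drawn
#' independently per frame (frame `i` uses noise seed `seed + i`).
#'
#' @inheritParams render_frame
#' @param times_min Strictly increasing acquisition times in minutes.
#' @return An object of class `chip_series`: list with `frames` (list of
#'   `chip_frame`), `times_min` and `artifacts`.
#' @export
render_timeseries <- function(truth, geometry = attr(truth, "geometry"),
                              times_min = seq(0, 30, by = 2),
                              kinetics = kinetics_model(),
                              noise = noise_model(), seed = 1L,
                              ref_amplitude = 500) {
  if (length(times_min) == 0)
    stop("times_min must contain at least one time point", call. = FALSE)
  if (any(diff(times_min) <= 0))
    stop("times_min must be strictly increasing", call. = FALSE)
  artifacts <- sample_artifacts(noise, geometry, seed)
  frames <- lapply(seq_along(times_min), function(i) {
    render_frame(truth, geometry, times_min[i], kinetics, noise,
                 seed = as.integer(seed) + i - 1L, artifacts = artifacts,
                 ref_amplitude = ref_amplitude)
  })
  structure(list(frames = frames, times_min = times_min,
                 artifacts = artifacts),
            class = "chip_series")
}

#' Simulate a complete synthetic chip experiment
#'
#' Convenience wrapper: Poisson loading, artifact sampling, artifact
#' coverage flags, and rendering of either a single endpoint frame or a
#' full time series.
#'
#' @inheritParams simulate_loading
#' @inheritParams render_frame
#' @param times_min `NULL` for a single endpoint frame at `time_min`, or a
#'   strictly increasing time vector for a series.
#' @return List with `truth` (artifact flags filled in), `geometry`, and
#'   either `frame` or `series`.
#' @export
simulate_chip <- function(concentration_M, geometry = chip_geometry(),
                          amplification_efficiency = 1,
                          kinetics = kinetics_model(),
                          noise = noise_model(), time_min = 30,
                          times_min = NULL, seed = 1L,
                          ref_amplitude = 500) {
  truth <- simulate_loading(concentration_M, geometry,
                            amplification_efficiency, kinetics, seed)
  if (is.null(times_min)) {
    frame <- render_frame(truth, geometry, time_min, kinetics, noise,
                          seed = seed, ref_amplitude = ref_amplitude)
    truth <- flag_artifact_coverage(truth, frame$artifacts)
    list(truth = truth, geometry = geometry, frame = frame)
  } else {
    series <- render_timeseries(truth, geometry, times_min, kinetics, noise,
                                seed = seed, ref_amplitude = ref_amplitude)
    truth <- flag_artifact_coverage(truth, series$artifacts)
    list(truth = truth, geometry = geometry, series = series)
  }
}
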