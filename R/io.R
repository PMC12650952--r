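# --- image I/O -------------------------------------------------------------

#' Write chip frames to a 16-bit multi-page TIFF
#'
#' Pages are channel-major per time point: reference then signal for frame
#' 1, reference then signal for frame 2, and so on. Intensities (a.u.) are
#' rounded to integers and stored as 16-bit unsigned samples.
#'
#' @param x A `chip_frame`, a `chip_series`, or a list of frames each with
#'   `reference` and `signal` matrices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chip_tiff <- function(x, path) {
  frames <- if (inherits(x, "chip_frame")) list(x)
    else if (inherits(x, "chip_series")) x$frames
    else x
  pages <- list()
  for (fr in frames) {
    pages <- c(pages, list(fr$reference, fr$signal))
  }
  pages <- lapply(pages, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Read a two-channel chip TIFF
#'
#' Inverse of [write_chip_tiff()]: pages are grouped channel-major into
#' frames of `reference` and `signal` matrices holding integer
#' intensities.
#'
#' @param path TIFF file path.
#' @param channel_order Page order within a time point; the default
#'   `c("reference", "signal")` matches [write_chip_tiff()].
#' @return List of frames (each a list with `reference` and `signal`).
#' @export
read_chip_tiff <- function(path, channel_order = c("reference", "signal")) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channel_order)
  if (length(pages) %% nc != 0)
    stop("page count is not a multiple of the channel count", call. = FALSE)
  lapply(seq_len(length(pages) / nc), function(i) {
    fr <- pages[(i - 1) * nc + seq_len(nc)]
    names(fr) <- channel_order
    lapply(fr, function(m) {
      storage.mode(m) <- "numeric"
      m
    })
  })
}

# --- tabular I/O -----------------------------------------------------------

#' Write / read a simulation ground-truth table as CSV
#'
#' Columns: row, col, center_x_px, center_y_px, n_templates, is_positive,
#' onset_time_min, covered_by_artifact.
#'
#' @param truth An `assay_truth` table.
#' @param path CSV file path.
#' @return `path` invisibly; `read_truth_csv` returns the data frame.
#' @export
write_truth_csv <- function(truth, path) {
  cols <- c("row", "col", "center_x_px", "center_y_px", "n_templates",
            "is_positive", "onset_time_min", "covered_by_artifact")
  utils::write.csv(as.data.frame(truth)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path)
}

#' Write per-chamber measurements as CSV
#'
#' Columns: roi_id, center_x_px, center_y_px, mean_intensity, rog, label,
#' excluded.
#'
#' @param measurements A classified `chamber_measurements` table.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_chamber_csv <- function(measurements, path) {
  cols <- c("roi_id", "center_x_px", "center_y_px", "mean_intensity",
            "rog", "label", "excluded")
  utils::write.csv(as.data.frame(measurements)[, cols], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a positive-count time course as CSV
#'
#' Columns: time_min, n_positive, n_total.
#'
#' @param tc A [time_course()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  out <- data.frame(time_min = tc$time_min, n_positive = tc$n_positive,
                    n_total = attr(tc, "n_total"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# --- configuration ---------------------------------------------------------

#' Default run configuration
#'
#' All tunable constants of the simulator and the analysis surfaced as
#' named keys: chip geometry, kinetics, noise, the mean + `k_sd` SD
#' intensity rule, the ROG gate, ROI/crop sizes, the 2-minute frame
#' interval, and the detection (`trigger`, `initial_max`) and
#' quantification (`rel_change`) rules. Round-trips losslessly through
#' YAML via [write_run_config()] / [read_run_config()].
#'
#' @param geometry A [chip_geometry()].
#' @param kinetics A [kinetics_model()].
#' @param noise A [noise_model()].
#' @param concentration_M Simulated template concentration (mol/L).
#' @param amplification_efficiency Per-occupied-chamber amplification
#'   success probability.
#' @param time_min Endpoint acquisition time (minutes).
#' @param times_min Optional time-lapse acquisition times.
#' @param ref_amplitude Reference-channel disk amplitude (a.u.).
#' @param k_sd,rog_threshold Classification thresholds.
#' @param roi_diameter_px,crop_size_px,expected_diameter_px Analysis
#'   geometry (pixels).
#' @param min_separation_factor Detection minimum separation as a fraction
#'   of the pitch in pixels.
#' @param frame_interval_min Nominal time-lapse frame interval (minutes).
#' @param initial_max,trigger,rel_change Time-metric rules.
#' @param seed Integer seed.
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(geometry = chip_geometry(),
                       kinetics = kinetics_model(),
                       noise = noise_model(),
                       concentration_M = 3.6e-12,
                       amplification_efficiency = 1,
                       time_min = 30, times_min = NULL,
                       ref_amplitude = 500,
                       k_sd = 15, rog_threshold = 5.5,
                       roi_diameter_px = 10, crop_size_px = 16,
                       expected_diameter_px = 10,
                       min_separation_factor = 0.6,
                       frame_interval_min = 2,
                       initial_max = 2, trigger = 10, rel_change = 0.2,
                       seed = 1L) {
  structure(
    list(schema_version = 1L,
         geometry = geometry,
         kinetics = kinetics,
         noise = noise,
         simulate = list(concentration_M = concentration_M,
                         amplification_efficiency = amplification_efficiency,
                         time_min = time_min, times_min = times_min,
                         ref_amplitude = ref_amplitude),
         thresholds = list(k_sd = k_sd, rog_threshold = rog_threshold),
         analysis = list(roi_diameter_px = roi_diameter_px,
                         crop_size_px = crop_size_px,
                         expected_diameter_px = expected_diameter_px,
                         min_separation_factor = min_separation_factor,
                         frame_interval_min = frame_interval_min,
                         initial_max = initial_max, trigger = trigger,
                         rel_change = rel_change),
         seed = as.integer(seed)),
    class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly; `read_run_config` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  for (nm in c("geometry", "kinetics", "noise"))
    plain[[nm]] <- unclass(plain[[nm]])
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (blk in c("simulate", "thresholds", "analysis"))
    for (nm in names(raw[[blk]]))
      if (!is.null(raw[[blk]][[nm]]))
        cfg[[blk]][[nm]] <- raw[[blk]][[nm]]
  if (!is.null(cfg$simulate$times_min))
    cfg$simulate$times_min <- unlist(cfg$simulate$times_min)
  cfg$schema_version <- raw$schema_version
  cfg$geometry <- do.call(chip_geometry, raw$geometry)
  cfg$kinetics <- do.call(kinetics_model, raw$kinetics)
  noise_args <- raw$noise
  noise_args$artifact_diameter_px_range <-
    unlist(noise_args$artifact_diameter_px_range)
  noise_args$artifact_intensity_range <-
    unlist(noise_args$artifact_intensity_range)
  cfg$noise <- do.call(noise_model, noise_args)
  cfg$seed <- as.integer(raw$seed)
  class(cfg) <- "run_config"
  cfg
}

config_geometry <- function(config) {
  g <- config$geometry
  if (!inherits(g, "chip_geometry")) g <- do.call(chip_geometry, g)
  g
}

# Provenance block for summary JSON files: config hash (md5 of its YAML
# serialisation), seed and versions.
provenance_block <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  list(config_md5 = unname(tools::md5sum(tmp)),
       seed = config$seed,
       digitalchip_version =
         as.character(utils::packageVersion("digitalchip")),
       r_version = as.character(getRversion()))
}

# --- file-level runners (the CLI surface) ---------------------------------

#' Simulate a chip and write image, truth and config files
#'
#' Writes `chip.tif` (16-bit multi-page, channel-major), `truth.csv` and a
#' `config.yaml` echo into `out_dir`. With `times_min` set in the config,
#' the TIFF holds the whole time series.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Named list of output paths, invisibly.
#' @export
run_simulate <- function(config = run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- config_geometry(config)
  sim <- simulate_chip(
    concentration_M = config$simulate$concentration_M,
    geometry = geometry,
    amplification_efficiency = config$simulate$amplification_efficiency,
    kinetics = do.call(kinetics_model, unclass(config$kinetics)),
    noise = do.call(noise_model, unclass(config$noise)),
    time_min = config$simulate$time_min,
    times_min = config$simulate$times_min,
    seed = config$seed,
    ref_amplitude = config$simulate$ref_amplitude)
  paths <- list(image = file.path(out_dir, "chip.tif"),
                truth = file.path(out_dir, "truth.csv"),
                config = file.path(out_dir, "config.yaml"))
  write_chip_tiff(if (is.null(sim$frame)) sim$series else sim$frame,
                  paths$image)
  write_truth_csv(sim$truth, paths$truth)
  write_run_config(config, paths$config)
  invisible(paths)
}

#' Analyse an endpoint chip image from files
#'
#' Reads a two-channel TIFF (and a matched negative-control TIFF for
#' threshold fitting), runs [analyze_chip()] and writes `chambers.csv` and
#' `summary.json` (counts, fraction, both concentration estimators,
#' warnings, and a provenance block).
#'
#' @param image_path Two-channel TIFF of the chip to analyse.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @param negative_path Two-channel TIFF of a matched negative control.
#' @param exclusion_path Optional text file of `roi_id`s (one per line) to
#'   exclude.
#' @return The `chip_analysis`, invisibly.
#' @export
run_analyze <- function(image_path, out_dir, config = run_config(),
                        negative_path = NULL, exclusion_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- config_geometry(config)
  frames <- read_chip_tiff(image_path)
  neg <- if (!is.null(negative_path)) read_chip_tiff(negative_path)
  excl <- if (!is.null(exclusion_path))
    as.integer(readLines(exclusion_path))

  warns <- character(0)
  ana <- withCallingHandlers(
    analyze_chip(
      frames[[1]]$reference, frames[[1]]$signal,
      chamber_volume_L = chamber_volume(geometry$chamber_diameter_um,
                                        geometry$chamber_depth_um),
      negative_reference = if (!is.null(neg)) neg[[1]]$reference,
      negative_signal = if (!is.null(neg)) neg[[1]]$signal,
      expected_diameter_px = config$analysis$expected_diameter_px,
      min_separation_px = config$analysis$min_separation_factor *
        chamber_pitch_px(geometry),
      roi_diameter_px = config$analysis$roi_diameter_px,
      crop_size_px = config$analysis$crop_size_px,
      k_sd = config$thresholds$k_sd,
      rog_threshold = config$thresholds$rog_threshold,
      exclusion_ids = excl),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  write_chamber_csv(ana$measurements, file.path(out_dir, "chambers.csv"))
  write_summary_json(ana$quant, file.path(out_dir, "summary.json"),
                     config = config, thresholds = ana$thresholds,
                     warnings = warns)
  invisible(ana)
}

#' Analyse a time-lapse chip series from files
#'
#' Reads a multi-frame two-channel TIFF, assigns acquisition times from the
#' configured frame interval, runs [analyze_timelapse()] (thresholds from
#' the first frame) and writes `timecourse.csv` and `summary.json`
#' including the detection and quantification times.
#'
#' @param series_path Multi-frame two-channel TIFF.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return The `timelapse_analysis`, invisibly.
#' @export
run_timelapse <- function(series_path, out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- config_geometry(config)
  frames <- read_chip_tiff(series_path)
  if (length(frames) < 2)
    stop("time-lapse input must contain at least two frames", call. = FALSE)
  times <- if (!is.null(config$simulate$times_min))
    config$simulate$times_min
  else (seq_along(frames) - 1) * config$analysis$frame_interval_min

  warns <- character(0)
  ana <- withCallingHandlers(
    analyze_timelapse(
      frames, times,
      chamber_volume_L = chamber_volume(geometry$chamber_diameter_um,
                                        geometry$chamber_depth_um),
      expected_diameter_px = config$analysis$expected_diameter_px,
      min_separation_px = config$analysis$min_separation_factor *
        chamber_pitch_px(geometry),
      roi_diameter_px = config$analysis$roi_diameter_px,
      crop_size_px = config$analysis$crop_size_px,
      k_sd = config$thresholds$k_sd,
      rog_threshold = config$thresholds$rog_threshold,
      initial_max = config$analysis$initial_max,
      trigger = config$analysis$trigger,
      rel_change = config$analysis$rel_change),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  write_timecourse_csv(ana$tc, file.path(out_dir, "timecourse.csv"))
  write_summary_json(ana$quant, file.path(out_dir, "summary.json"),
                     config = config, thresholds = ana$thresholds,
                     detection_time_min = ana$detection_time_min,
                     quantification_time_min = ana$quantification_time_min,
                     warnings = warns)
  invisible(ana)
}

#' Write a quantification summary as JSON
#'
#' Full-precision machine-readable summary: counts, positive fraction,
#' chamber volume, both concentration estimators (the Poisson-corrected
#' one labelled as such), optional time metrics, accumulated warnings, and
#' a provenance block (config hash, seed, versions).
#'
#' @param quant A `quant_result`.
#' @param path Output JSON path.
#' @param config Optional [run_config()] for the provenance block.
#' @param thresholds Optional `threshold_set` echoed into the file.
#' @param detection_time_min,quantification_time_min Optional time-lapse
#'   metrics (NA becomes JSON null).
#' @param warnings Character vector of warnings raised during analysis.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(quant, path, config = NULL,
                               thresholds = NULL,
                               detection_time_min = NULL,
                               quantification_time_min = NULL,
                               warnings = character(0)) {
  null_if_na <- function(x)
    if (is.null(x) || is.na(x)) NULL else x
  out <- list(
    n_total = quant$n_total,
    n_positive = quant$n_positive,
    n_excluded = quant$n_excluded,
    positive_fraction = quant$positive_fraction,
    chamber_volume_L = quant$chamber_volume_L,
    concentration_estimate_M = quant$concentration_estimate_M,
    concentration_poisson_M = null_if_na(quant$concentration_poisson_M),
    poisson_corrected_is_nondefault = TRUE,
    detection_time_min = null_if_na(detection_time_min),
    quantification_time_min = null_if_na(quantification_time_min),
    warnings = warnings)
  if (!is.null(thresholds))
    out$thresholds <- list(mu = thresholds$intensity_mu,
                           sigma = thresholds$intensity_sigma,
                           k_sd = thresholds$k_sd,
                           intensity_threshold =
                             thresholds$intensity_threshold,
                           rog_threshold = thresholds$rog_threshold,
                           method = thresholds$method)
  if (!is.null(config)) out$provenance <- provenance_block(config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
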