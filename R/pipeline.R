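# Threshold fitting with a pipeline-level fallback for the degenerate
# zero-spread case (noise-free simulations): threshold = max(negatives),
# so anything strictly brighter than every negative is positive.
thresholds_from_negatives <- function(intensities, k_sd, rog_threshold) {
  tryCatch(
    fit_intensity_threshold(intensities, k_sd = k_sd,
                            rog_threshold = rog_threshold),
    digitalchip_degenerate = function(e) {
      warning(paste("negative intensities have zero spread (noise-free",
                    "input); using their maximum as the threshold"),
              call. = FALSE)
      threshold_set(intensity_mu = stats::median(intensities),
                    intensity_sigma = 0, k_sd = k_sd,
                    intensity_threshold = max(intensities),
                    rog_threshold = rog_threshold,
                    method = "degenerate_max")
    })
}

#' End-to-end analysis of one two-channel chip image
#'
#' Runs the full endpoint pipeline: chamber detection on the reference
#' channel, mean-intensity and radius-of-gyration measurement on the
#' signal channel, two-stage classification against negative-control
#' thresholds, optional manual exclusions, and digital quantification.
#'
#' Thresholds come from, in order of precedence: the `thresholds`
#' argument; or a matched negative-control image pair
#' (`negative_reference` / `negative_signal`) analysed with the same
#' settings.
#'
#' @param reference,signal 2D numeric matrices, the reference and signal
#'   channels of the chip image.
#' @param chamber_volume_L Mean chamber volume in litres.
#' @param thresholds Optional pre-fitted `threshold_set`.
#' @param negative_reference,negative_signal Optional negative-control
#'   image pair used to fit thresholds.
#' @param expected_diameter_px,min_separation_px Detection parameters, see
#'   [detect_chambers()].
#' @param roi_diameter_px,crop_size_px Measurement geometry.
#' @param k_sd Intensity threshold multiplier (default 15).
#' @param rog_threshold Radius-of-gyration gate in pixels (default 5.5).
#' @param exclusion_ids Optional `roi_id`s to exclude manually.
#' @return An object of class `chip_analysis`: `rois`, `measurements`
#'   (classified), `thresholds`, `quant` (a `quant_result`) and the
#'   analysis parameters.
#' @export
analyze_chip <- function(reference, signal,
                         chamber_volume_L = chamber_volume(),
                         thresholds = NULL,
                         negative_reference = NULL, negative_signal = NULL,
                         expected_diameter_px = 10,
                         min_separation_px = 1.2 * expected_diameter_px,
                         roi_diameter_px = 10, crop_size_px = 16,
                         k_sd = 15, rog_threshold = 5.5,
                         exclusion_ids = NULL) {
  rois <- detect_chambers(reference, expected_diameter_px,
                          min_separation_px, roi_diameter_px, crop_size_px)
  meas <- measure_chambers(signal, rois)

  if (is.null(thresholds)) {
    if (is.null(negative_signal))
      stop("supply either thresholds or a negative-control image pair",
           call. = FALSE)
    if (is.null(negative_reference)) negative_reference <- reference
    nrois <- detect_chambers(negative_reference, expected_diameter_px,
                             min_separation_px, roi_diameter_px,
                             crop_size_px)
    nmeas <- measure_chambers(negative_signal, nrois)
    thresholds <- thresholds_from_negatives(nmeas$mean_intensity, k_sd,
                                            rog_threshold)
  }

  meas <- apply_exclusions(meas, exclusion_ids)
  meas <- classify_chambers(meas, thresholds)
  quant <- quantify_chambers(meas, chamber_volume_L)

  structure(
    list(rois = rois, measurements = meas, thresholds = thresholds,
         quant = quant,
         params = list(expected_diameter_px = expected_diameter_px,
                       min_separation_px = min_separation_px,
                       roi_diameter_px = roi_diameter_px,
                       crop_size_px = crop_size_px, k_sd = k_sd,
                       rog_threshold = rog_threshold,
                       chamber_volume_L = chamber_volume_L)),
    class = "chip_analysis")
}

#' @export
print.chip_analysis <- function(x, ...) {
  cat("Microchamber chip analysis\n")
  cat(sprintf("  detected chambers: %d\n", nrow(x$rois)))
  print(x$quant)
  invisible(x)
}

#' @export
summary.chip_analysis <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$thresholds)
  lab <- table(object$measurements$label)
  cat(sprintf("\n  labels: %s\n",
              paste(names(lab), lab, sep = " = ", collapse = ", ")))
  invisible(object)
}

#' Time-lapse analysis of a chip image series
#'
#' Chambers are detected once, on the reference channel of the first
#' frame; classification thresholds are fitted from the first frame's own
#' signal-channel intensities (the series starts before amplification, so
#' nearly every chamber is then a negative control). Each frame is then
#' classified with those fixed thresholds, and the positive-count time
#' course is reduced to a detection time (count exceeds `trigger`) and a
#' quantification time (consecutive-frame change below `rel_change`).
#' Concentration is estimated from the final frame.
#'
#' @param frames List of frames, each a list with `reference` and `signal`
#'   matrices (a `chip_series$frames` works directly).
#' @param times_min Acquisition times, one per frame, strictly increasing.
#' @param chamber_volume_L Mean chamber volume in litres.
#' @inheritParams analyze_chip
#' @param initial_max,trigger Detection-time rule, see [detection_time()].
#' @param rel_change Quantification-time rule, see
#'   [quantification_time()].
#' @return An object of class `timelapse_analysis`: `tc` (a
#'   [time_course()]), `detection_time_min`, `quantification_time_min`,
#'   `thresholds`, `rois`, `quant` (final frame) and `params`.
#' @export
analyze_timelapse <- function(frames, times_min,
                              chamber_volume_L = chamber_volume(),
                              expected_diameter_px = 10,
                              min_separation_px = 1.2 * expected_diameter_px,
                              roi_diameter_px = 10, crop_size_px = 16,
                              k_sd = 15, rog_threshold = 5.5,
                              initial_max = 2, trigger = 10,
                              rel_change = 0.2) {
  if (length(frames) < 2)
    stop("a time-lapse needs at least two frames", call. = FALSE)
  if (length(frames) != length(times_min))
    stop("one acquisition time per frame required", call. = FALSE)

  rois <- detect_chambers(frames[[1]]$reference, expected_diameter_px,
                          min_separation_px, roi_diameter_px, crop_size_px)
  first <- measure_chambers(frames[[1]]$signal, rois)
  thresholds <- thresholds_from_negatives(first$mean_intensity, k_sd,
                                          rog_threshold)

  counts <- vapply(seq_along(frames), function(i) {
    m <- if (i == 1) first else measure_chambers(frames[[i]]$signal, rois)
    m <- classify_chambers(m, thresholds)
    sum(m$label == "positive")
  }, integer(1))

  tc <- time_course(times_min, counts, n_total = nrow(rois),
                    frame_interval_min = if (length(times_min) > 1)
                      times_min[2] - times_min[1] else NA_real_)
  dt <- detection_time(tc, initial_max, trigger)
  qt <- if (is.na(dt)) NA_real_ else quantification_time(tc, dt, rel_change)

  final <- classify_chambers(
    measure_chambers(frames[[length(frames)]]$signal, rois), thresholds)
  quant <- quantify_chambers(final, chamber_volume_L)

  structure(
    list(tc = tc, detection_time_min = dt, quantification_time_min = qt,
         thresholds = thresholds, rois = rois, quant = quant,
         params = list(k_sd = k_sd, rog_threshold = rog_threshold,
                       initial_max = initial_max, trigger = trigger,
                       rel_change = rel_change,
                       chamber_volume_L = chamber_volume_L)),
    class = "timelapse_analysis")
}

#' @export
print.timelapse_analysis <- function(x, ...) {
  cat("Microchamber time-lapse analysis\n")
  cat(sprintf("  frames: %d (%g to %g min), chambers: %d\n",
              nrow(x$tc), min(x$tc$time_min), max(x$tc$time_min),
              attr(x$tc, "n_total")))
  cat(sprintf("  detection time: %s min, quantification time: %s min\n",
              format(x$detection_time_min),
              format(x$quantification_time_min)))
  print(x$quant)
  invisible(x)
}

#' Plot a time-lapse positive-count curve
#'
#' Positive-chamber count against time, with the detection and
#' quantification times marked as vertical lines.
#'
#' @param x A `timelapse_analysis`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.timelapse_analysis <- function(x, ...) {
  graphics::plot(x$tc$time_min, x$tc$n_positive, type = "b", pch = 16,
                 xlab = "time (min)", ylab = "positive chambers", ...)
  if (!is.na(x$detection_time_min))
    graphics::abline(v = x$detection_time_min, lty = 2, col = "darkgreen")
  if (!is.na(x$quantification_time_min))
    graphics::abline(v = x$quantification_time_min, lty = 2, col = "purple")
  graphics::legend("bottomright", lty = 2, col = c("darkgreen", "purple"),
                   legend = c("detection", "quantification"), bty = "n")
  invisible(x)
}
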