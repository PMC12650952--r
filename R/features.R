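#' Radius of gyration of an image crop
#'
#' Intensity-weighted RMS distance of the crop's signal from the crop
#' centre, computed from raw image moments:
#' `ROG = sqrt((m20 + m02) / m00)` with
#' `m20 = sum_x sum_y (x - (N-1)/2)^2 g(x, y)`,
#' `m02 = sum_x sum_y (y - (M-1)/2)^2 g(x, y)` and `m00 = sum g(x, y)`,
#' where M and N are the crop height and width in pixels and `g` the raw
#' pixel intensity (no background subtraction). A concentrated central spot
#' gives a small ROG; a uniform 16 x 16 crop gives the maximal
#' `sqrt(42.5) ~ 6.519`.
#'
#' @param crop M x N numeric matrix (row = y, column = x), nonnegative and
#'   not all zero.
#' @return ROG in pixels.
#' @examples
#' radius_of_gyration(matrix(1, 16, 16))  # sqrt(42.5)
#' @export
radius_of_gyration <- function(crop) {
  if (!is.matrix(crop) || !is.numeric(crop))
    stop("crop must be a numeric matrix", call. = FALSE)
  if (any(crop < 0)) stop("crop must be nonnegative", call. = FALSE)
  m00 <- sum(crop)
  if (m00 == 0)
    stop(errorCondition("all-zero crop: radius of gyration undefined",
                        class = c("digitalchip_zero_mass", "error",
                                  "condition")))
  M <- nrow(crop); N <- ncol(crop)
  xs <- (seq_len(N) - 1) - (N - 1) / 2
  ys <- (seq_len(M) - 1) - (M - 1) / 2
  m20 <- sum(colSums(crop) * xs^2)
  m02 <- sum(rowSums(crop) * ys^2)
  sqrt((m20 + m02) / m00)
}

#' Mean intensity over a circular ROI
#'
#' Arithmetic mean of the pixels whose centres lie within
#' `roi_diameter_px / 2` (inclusive) of the ROI centre.
#'
#' @param image 2D numeric matrix (row = y, column = x).
#' @param center_x_px,center_y_px ROI centre, 0-based pixel coordinates.
#' @param roi_diameter_px ROI diameter in pixels (default 10).
#' @return Mean intensity (a.u.).
#' @export
mean_roi_intensity <- function(image, center_x_px, center_y_px,
                               roi_diameter_px = 10) {
  r <- roi_diameter_px / 2
  x0 <- floor(center_x_px - r); x1 <- ceiling(center_x_px + r)
  y0 <- floor(center_y_px - r); y1 <- ceiling(center_y_px + r)
  if (x0 < 0 || y0 < 0 || x1 > ncol(image) - 1 || y1 > nrow(image) - 1)
    stop("ROI extends beyond the image", call. = FALSE)
  xs <- x0:x1; ys <- y0:y1
  inside <- outer((ys - center_y_px)^2, (xs - center_x_px)^2, "+") <= r^2
  vals <- image[ys + 1L, xs + 1L, drop = FALSE]
  mean(vals[inside])
}

#' Measure all detected chambers in a signal-channel image
#'
#' For each ROI: the mean signal intensity over the circular ROI and the
#' radius of gyration of the square crop. Crops with zero total intensity
#' get `rog = NA` (they will classify as negative).
#'
#' @param signal_image 2D numeric matrix of the signal channel.
#' @param rois A `chamber_rois` table from [detect_chambers()].
#' @param roi_diameter_px,crop_size_px Measurement geometry; default to the
#'   values stored in `rois`.
#' @return Data frame of class `chamber_measurements`: `roi_id`,
#'   `center_x_px`, `center_y_px`, `mean_intensity`, `rog`, `excluded`.
#' @export
measure_chambers <- function(signal_image, rois,
                             roi_diameter_px = attr(rois, "roi_diameter_px"),
                             crop_size_px = attr(rois, "crop_size_px")) {
  if (is.null(roi_diameter_px)) roi_diameter_px <- 10
  if (is.null(crop_size_px)) crop_size_px <- 16
  n <- nrow(rois)
  cx <- rois$center_x_px; cy <- rois$center_y_px
  integer_centers <- n > 0 && all(cx == round(cx) & cy == round(cy))
  if (integer_centers) {
    # fast path: shared pixel-offset masks indexed into the image
    h <- nrow(signal_image)
    r <- roi_diameter_px / 2
    ext <- ceiling(r)
    rel <- seq.int(-ext, ext)
    in_roi <- outer(rel^2, rel^2, "+") <= r^2
    roi_off <- (rep(rel, each = length(rel)) +       # dy
                  rep(rel, times = length(rel)) * h)[as.vector(t(in_roi))]
    base <- cy + 1 + cx * h
    roi_idx <- outer(base, roi_off, "+")
    mi <- rowMeans(matrix(signal_image[roi_idx], nrow = n))

    half <- (crop_size_px - 1) / 2
    crel <- seq.int(0, crop_size_px - 1)
    w2 <- (crel - half)^2
    wgt <- rep(w2, times = crop_size_px) + rep(w2, each = crop_size_px)
    crop_off <- rep(crel, times = crop_size_px) +
      rep(crel, each = crop_size_px) * h
    cbase <- (round(cy - half)) + 1 + (round(cx - half)) * h
    g <- matrix(signal_image[outer(cbase, crop_off, "+")], nrow = n)
    m00 <- rowSums(g)
    num <- as.vector(g %*% wgt)
    rog <- ifelse(m00 > 0, sqrt(num / m00), NA_real_)
  } else {
    mi <- numeric(n); rog <- numeric(n)
    for (i in seq_len(n)) {
      mi[i] <- mean_roi_intensity(signal_image, cx[i], cy[i],
                                  roi_diameter_px)
      crop <- crop_region(signal_image, cx[i], cy[i], crop_size_px)
      rog[i] <- tryCatch(radius_of_gyration(crop),
                         digitalchip_zero_mass = function(e) NA_real_)
    }
  }
  structure(
    data.frame(roi_id = rois$roi_id, center_x_px = rois$center_x_px,
               center_y_px = rois$center_y_px, mean_intensity = mi,
               rog = rog, excluded = FALSE),
    roi_diameter_px = roi_diameter_px, crop_size_px = crop_size_px,
    class = c("chamber_measurements", "data.frame"))
}

#' Fit the positive-calling intensity threshold from negative controls
#'
#' Histograms the negative-control chamber intensities (Freedman-Diaconis
#' bin width), least-squares fits a Gaussian `a * exp(-(x - mu)^2 /
#' (2 sigma^2))` to the bin counts, and sets the threshold at
#' `mu + k_sd * sigma`. If the fit fails, falls back to the median and
#' `1.4826 * MAD` with a warning; a zero-spread sample is rejected with an
#' error of class `digitalchip_degenerate`.
#'
#' Fitting the histogram peak (rather than taking plain moments) keeps the
#' threshold anchored to the dominant negative mode even when a small
#' fraction of bright outliers contaminates the control.
#'
#' @param negative_intensities Numeric vector of >= 100 chamber mean
#'   intensities from a negative control.
#' @param k_sd Threshold multiplier (default 15: mean + 15 SD).
#' @param rog_threshold Radius-of-gyration gate carried alongside the
#'   intensity threshold (px, default 5.5 for 16 x 16 crops).
#' @return An object of class `threshold_set`: `intensity_mu`,
#'   `intensity_sigma`, `k_sd`, `intensity_threshold`, `rog_threshold`,
#'   `method` ("gaussian_fit" or "robust_fallback") and `fit` diagnostics.
#' @examples
#' set.seed(1)
#' thr <- fit_intensity_threshold(rnorm(1000, 100, 5))
#' thr$intensity_threshold  # ~ 175
#' @export
fit_intensity_threshold <- function(negative_intensities, k_sd = 15,
                                    rog_threshold = 5.5) {
  v <- negative_intensities[is.finite(negative_intensities)]
  if (length(v) < 100)
    stop("need at least 100 negative-control intensities", call. = FALSE)
  if (k_sd <= 0) stop("k_sd must be positive", call. = FALSE)

  degenerate <- function()
    stop(errorCondition(
      "negative-control intensities have zero spread; cannot fit a threshold",
      class = c("digitalchip_degenerate", "error", "condition")))

  bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)
  fit <- NULL
  if (bw > 0) {
    breaks <- seq(min(v) - bw, max(v) + bw, by = bw)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    mids <- h$mids; counts <- h$counts
    start <- list(a = max(counts), mu = mids[which.max(counts)],
                  sigma = max(stats::sd(v), bw))
    fit <- tryCatch(
      minpack.lm::nlsLM(counts ~ a * exp(-(mids - mu)^2 / (2 * sigma^2)),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    mu <- unname(cf["mu"]); sigma <- abs(unname(cf["sigma"]))
    method <- "gaussian_fit"
    diag <- list(n = length(v), bin_width = bw,
                 n_bins = length(mids),
                 rss = sum(stats::resid(fit)^2),
                 amplitude = unname(cf["a"]))
    if (sigma <= 0) fit <- NULL
  }
  if (is.null(fit)) {
    mu <- stats::median(v)
    sigma <- 1.4826 * stats::mad(v, constant = 1)
    if (sigma <= 0) degenerate()
    warning("Gaussian histogram fit failed; using median and 1.4826*MAD",
            call. = FALSE)
    method <- "robust_fallback"
    diag <- list(n = length(v), bin_width = bw)
  }

  structure(
    list(intensity_mu = mu, intensity_sigma = sigma, k_sd = k_sd,
         intensity_threshold = mu + k_sd * sigma,
         rog_threshold = rog_threshold, method = method, fit = diag),
    class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Chamber classification thresholds\n")
  cat(sprintf("  intensity: mu = %.4g, sigma = %.4g, threshold = mu + %g SD = %.4g (%s)\n",
              x$intensity_mu, x$intensity_sigma, x$k_sd,
              x$intensity_threshold, x$method))
  cat(sprintf("  ROG gate:  > %.3g px => negative\n", x$rog_threshold))
  invisible(x)
}

# Bare threshold_set constructor for the degenerate noise-free fallback
# and for user-supplied thresholds.
threshold_set <- function(intensity_mu, intensity_sigma, k_sd,
                          intensity_threshold, rog_threshold = 5.5,
                          method = "manual") {
  structure(
    list(intensity_mu = intensity_mu, intensity_sigma = intensity_sigma,
         k_sd = k_sd, intensity_threshold = intensity_threshold,
         rog_threshold = rog_threshold, method = method, fit = NULL),
    class = "threshold_set")
}

#' Classify chambers with the two-stage logic tree
#'
#' Stage 1 (shape gate): a chamber with `rog > rog_threshold` -- diffuse
#' signal filling the crop, as produced by empty chambers or large
#' autofluorescent objects -- is negative. Stage 2 (intensity gate): the
#' remaining chambers are positive iff `mean_intensity >
#' intensity_threshold`. Comparisons are strict, so ties are negative, and
#' an undefined (NA) ROG is negative. Excluded chambers are always
#' negative and tallied separately.
#'
#' @param measurements A `chamber_measurements` table.
#' @param thresholds A `threshold_set`.
#' @return The measurements with a `label` column (`"positive"` /
#'   `"negative"`).
#' @export
classify_chambers <- function(measurements, thresholds) {
  rog_ok <- !is.na(measurements$rog) &
    measurements$rog <= thresholds$rog_threshold
  pos <- rog_ok & measurements$mean_intensity > thresholds$intensity_threshold
  pos[measurements$excluded] <- FALSE
  measurements$label <- ifelse(pos, "positive", "negative")
  measurements
}

#' Mark chambers as manually excluded
#'
#' Implements reproducible manual exclusion of by-eye false positives
#' (e.g. chambers under bubbles or aggregates): the flagged chambers are
#' marked `excluded`, always classify as negative, and are removed from the
#' denominator of the post-exclusion positive fraction while raw totals are
#' still reported.
#'
#' @param measurements A `chamber_measurements` table.
#' @param exclusion_ids Vector of `roi_id` values to exclude. Every id must
#'   exist.
#' @return The measurements with `excluded` updated.
#' @export
apply_exclusions <- function(measurements, exclusion_ids) {
  if (length(exclusion_ids) == 0) return(measurements)
  unknown <- setdiff(exclusion_ids, measurements$roi_id)
  if (length(unknown))
    stop("unknown roi_id in exclusion list: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  measurements$excluded <- measurements$excluded |
    measurements$roi_id %in% exclusion_ids
  measurements
}
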