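# Separable box maximum filter with half-width w (border replicated by
# construction: shifted comparisons just use fewer terms at the edges).
box_max_filter <- function(m, w) {
  h <- nrow(m); wd <- ncol(m)
  out <- m
  if (w >= 1) {
    for (d in seq_len(min(w, h - 1))) {
      out[1:(h - d), ] <- pmax(out[1:(h - d), ], m[(1 + d):h, ])
      out[(1 + d):h, ] <- pmax(out[(1 + d):h, ], m[1:(h - d), ])
    }
    m2 <- out
    for (d in seq_len(min(w, wd - 1))) {
      out[, 1:(wd - d)] <- pmax(out[, 1:(wd - d)], m2[, (1 + d):wd])
      out[, (1 + d):wd] <- pmax(out[, (1 + d):wd], m2[, 1:(wd - d)])
    }
  }
  out
}

# Greedy non-maximum suppression: keep candidates in decreasing response
# order, dropping any within min_sep of an already kept one ("merge to the
# brighter"). Cell hashing keeps it near-linear.
merge_close_peaks <- function(x, y, response, min_sep) {
  n <- length(x)
  if (n <= 1) return(seq_len(n))
  ord <- order(-response, y, x)
  cs <- min_sep
  ci <- floor(x / cs); cj <- floor(y / cs)
  grid <- new.env(hash = TRUE, parent = emptyenv())
  kept <- integer(0)
  for (idx in ord) {
    ok <- TRUE
    for (di in -1:1) {
      for (dj in -1:1) {
        key <- paste(ci[idx] + di, cj[idx] + dj)
        others <- grid[[key]]
        if (!is.null(others) &&
            any((x[idx] - x[others])^2 + (y[idx] - y[others])^2 < cs^2)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) {
      kept <- c(kept, idx)
      key0 <- paste(ci[idx], cj[idx])
      grid[[key0]] <- c(grid[[key0]], idx)
    }
  }
  kept
}

#' Detect microchambers in a reference-channel image
#'
#' Chambers appear as bright disks of roughly `expected_diameter_px` on a
#' regular lattice. Detection is a band-pass (difference of Gaussians tuned
#' to the chamber diameter) followed by local-maximum extraction: a pixel
#' is a candidate centre if it carries the maximal band-pass response in a
#' square neighbourhood of half-width `min_separation_px / 2` and its
#' response exceeds an adaptive threshold (median + 30 percent of the
#' median-to-max response span). Candidates closer than `min_separation_px`
#' are merged to the brighter one; chambers whose `crop_size_px` square
#' crop would cross the image border are dropped; results are sorted
#' row-major (by y, then x).
#'
#' A constant (or empty) image yields an empty ROI table, not an error.
#'
#' @param reference_image 2D numeric matrix (row = y, column = x),
#'   nonnegative.
#' @param expected_diameter_px Expected chamber diameter in pixels (>= 3).
#' @param min_separation_px Minimum centre separation in pixels; detections
#'   closer than this are considered duplicates. Must exceed
#'   `expected_diameter_px / 2`. For a chip of known geometry use
#'   0.6 x pitch-in-pixels.
#' @param roi_diameter_px Diameter of the measurement ROI attached to each
#'   detection (default 10).
#' @param crop_size_px Side of the square crop used downstream (default 16);
#'   also defines the border-exclusion zone.
#' @return Data frame of class `chamber_rois` with columns `roi_id`,
#'   `center_x_px`, `center_y_px` (0-based integer pixel positions) and
#'   `response`. `roi_diameter_px` and `crop_size_px` are attached as
#'   attributes.
#' @export
detect_chambers <- function(reference_image, expected_diameter_px = 10,
                            min_separation_px = 1.2 * expected_diameter_px,
                            roi_diameter_px = 10, crop_size_px = 16) {
  if (!is.matrix(reference_image) || !is.numeric(reference_image))
    stop("reference_image must be a 2D numeric matrix", call. = FALSE)
  if (expected_diameter_px < 3)
    stop("expected_diameter_px must be >= 3", call. = FALSE)
  if (min_separation_px <= expected_diameter_px / 2)
    stop("min_separation_px must exceed expected_diameter_px / 2",
         call. = FALSE)

  empty <- structure(
    data.frame(roi_id = integer(0), center_x_px = numeric(0),
               center_y_px = numeric(0), response = numeric(0)),
    roi_diameter_px = roi_diameter_px, crop_size_px = crop_size_px,
    class = c("chamber_rois", "data.frame"))

  rng <- range(reference_image)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(empty)

  s1 <- expected_diameter_px / 4
  s2 <- 2 * s1
  img <- matrix(as.numeric(reference_image), nrow = nrow(reference_image))
  dog <- EBImage::gblur(img, sigma = s1) - EBImage::gblur(img, sigma = s2)

  thr <- {
    med <- stats::median(dog)
    med + 0.3 * (max(dog) - med)
  }
  w <- max(1L, floor(min_separation_px / 2))
  is_peak <- dog > thr & dog == box_max_filter(dog, w)
  idx <- which(is_peak)
  if (!length(idx)) return(empty)

  y <- (idx - 1L) %% nrow(dog)        # 0-based row
  x <- (idx - 1L) %/% nrow(dog)       # 0-based col
  resp <- dog[idx]

  kept <- merge_close_peaks(x, y, resp, min_separation_px)
  x <- x[kept]; y <- y[kept]; resp <- resp[kept]

  # border filter: the full crop must fit inside the image
  half <- (crop_size_px - 1) / 2
  sx <- round(x - half); sy <- round(y - half)
  inb <- sx >= 0 & sy >= 0 &
    sx + crop_size_px <= ncol(img) & sy + crop_size_px <= nrow(img)
  x <- x[inb]; y <- y[inb]; resp <- resp[inb]

  ord <- order(y, x)
  structure(
    data.frame(roi_id = seq_along(ord), center_x_px = x[ord],
               center_y_px = y[ord], response = resp[ord]),
    roi_diameter_px = roi_diameter_px, crop_size_px = crop_size_px,
    class = c("chamber_rois", "data.frame"))
}

#' Crop a square region around a chamber centre
#'
#' The crop is axis-aligned with the chamber's nominal centre mapped to
#' crop coordinate `((crop_size - 1)/2, (crop_size - 1)/2)`; for the
#' default 16 x 16 crop that is (7.5, 7.5). The start index is
#' `round(center - (crop_size - 1)/2)` (ties round to even, as in base
#' `round()`), so a centre at (50, 50) yields columns and rows 42..57.
#' Pixel values are copied unmodified.
#'
#' @param image 2D numeric matrix (row = y, column = x).
#' @param center_x_px,center_y_px Chamber centre, 0-based pixel
#'   coordinates.
#' @param crop_size_px Side length of the square crop (default 16).
#' @return `crop_size_px` x `crop_size_px` numeric matrix.
#' @export
crop_region <- function(image, center_x_px, center_y_px, crop_size_px = 16) {
  half <- (crop_size_px - 1) / 2
  sx <- round(center_x_px - half)
  sy <- round(center_y_px - half)
  if (sx < 0 || sy < 0 ||
      sx + crop_size_px > ncol(image) || sy + crop_size_px > nrow(image))
    stop("crop crosses the image border; ROI should have been filtered",
         call. = FALSE)
  image[(sy + 1):(sy + crop_size_px), (sx + 1):(sx + crop_size_px),
        drop = FALSE]
}

#' Fill in lattice positions missed by detection
#'
#' Optional post-step for gridded chips: fits a square lattice to the
#' detected centres (median nearest-neighbour spacing along rows and
#' columns) and adds ROIs at lattice nodes with no detection within half a
#' pitch. Off by default in the pipeline.
#'
#' @param rois Output of [detect_chambers()].
#' @param pitch_px Lattice pitch in pixels.
#' @param crop_size_px Border-exclusion crop size.
#' @param image_dim `c(height, width)` of the source image.
#' @return Augmented `chamber_rois` table (recovered nodes have
#'   `response = NA`).
#' @export
refine_chamber_grid <- function(rois, pitch_px, crop_size_px = 16,
                                image_dim) {
  if (nrow(rois) < 4) return(rois)
  ox <- stats::median(rois$center_x_px %% pitch_px)
  oy <- stats::median(rois$center_y_px %% pitch_px)
  gx <- seq(ox, image_dim[2] - 1, by = pitch_px)
  gy <- seq(oy, image_dim[1] - 1, by = pitch_px)
  half <- (crop_size_px - 1) / 2
  nodes <- expand.grid(x = gx, y = gy)
  sx <- round(nodes$x - half); sy <- round(nodes$y - half)
  nodes <- nodes[sx >= 0 & sy >= 0 & sx + crop_size_px <= image_dim[2] &
                   sy + crop_size_px <= image_dim[1], ]
  miss <- vapply(seq_len(nrow(nodes)), function(i) {
    min((rois$center_x_px - nodes$x[i])^2 +
        (rois$center_y_px - nodes$y[i])^2) > (pitch_px / 2)^2
  }, logical(1))
  if (!any(miss)) return(rois)
  add <- data.frame(roi_id = NA_integer_,
                    center_x_px = round(nodes$x[miss]),
                    center_y_px = round(nodes$y[miss]),
                    response = NA_real_)
  out <- rbind(as.data.frame(rois), add)
  out <- out[order(out$center_y_px, out$center_x_px), ]
  out$roi_id <- seq_len(nrow(out))
  structure(out,
            roi_diameter_px = attr(rois, "roi_diameter_px"),
            crop_size_px = attr(rois, "crop_size_px"),
            class = c("chamber_rois", "data.frame"))
}
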