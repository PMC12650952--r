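# Physical constants
AVOGADRO <- 6.02214076e23  # mol^-1
UM3_PER_L <- 1e15          # 1 L = 1e15 um^3

#' Microchamber chip geometry
#'
#' Describes the physical layout of a microchamber array chip and the pixel
#' scale at which it is imaged. Defaults correspond to a fluoropolymer chip
#' with cylindrical chambers of 4.2 um diameter and 3.15 um depth on a 9 um
#' square lattice, imaged such that one chamber spans about 10 pixels.
#'
#' @param chamber_diameter_um Chamber diameter in micrometres.
#' @param chamber_depth_um Chamber depth in micrometres.
#' @param pitch_um Centre-to-centre chamber spacing in micrometres. Must
#'   exceed the chamber diameter.
#' @param n_rows,n_cols Number of chamber rows and columns in the array.
#' @param pixel_size_um Physical size of one image pixel in micrometres.
#' @param margin_px Blank border, in pixels, rendered around the chamber
#'   grid. Must be at least 8 so that a 16 x 16 crop around any chamber
#'   stays inside the image.
#'
#' @return An object of class `chip_geometry`.
#' @examples
#' g <- chip_geometry()
#' chamber_diameter_px(g)  # ~10 px
#' @export
chip_geometry <- function(chamber_diameter_um = 4.2,
                          chamber_depth_um = 3.15,
                          pitch_um = 9,
                          n_rows = 100,
                          n_cols = 100,
                          pixel_size_um = 0.42,
                          margin_px = 12) {
  stopifnot(
    chamber_diameter_um > 0, chamber_depth_um > 0, pitch_um > 0,
    n_rows >= 1, n_cols >= 1, pixel_size_um > 0
  )
  if (chamber_diameter_um >= pitch_um)
    stop("chamber_diameter_um must be smaller than pitch_um", call. = FALSE)
  if (margin_px < 8)
    stop("margin_px must be at least 8 px (crop border requirement)",
         call. = FALSE)
  structure(
    list(
      chamber_diameter_um = chamber_diameter_um,
      chamber_depth_um = chamber_depth_um,
      pitch_um = pitch_um,
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols),
      pixel_size_um = pixel_size_um,
      margin_px = margin_px
    ),
    class = "chip_geometry"
  )
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat("Microchamber chip geometry\n")
  cat(sprintf("  chambers: %d x %d (%d total)\n",
              x$n_rows, x$n_cols, x$n_rows * x$n_cols))
  cat(sprintf("  chamber:  d = %.2f um, h = %.2f um (V = %.3g fL)\n",
              x$chamber_diameter_um, x$chamber_depth_um,
              chamber_volume(x$chamber_diameter_um, x$chamber_depth_um) * 1e15))
  cat(sprintf("  pitch:    %.2f um (%.2f px at %.3f um/px)\n",
              x$pitch_um, chamber_pitch_px(x), x$pixel_size_um))
  cat(sprintf("  chamber diameter in image: %.2f px\n",
              chamber_diameter_px(x)))
  invisible(x)
}

#' Chamber diameter and pitch in pixels
#'
#' @param geometry A [chip_geometry()].
#' @return Length in pixels.
#' @export
chamber_diameter_px <- function(geometry) {
  geometry$chamber_diameter_um / geometry$pixel_size_um
}

#' @rdname chamber_diameter_px
#' @export
chamber_pitch_px <- function(geometry) {
  geometry$pitch_um / geometry$pixel_size_um
}

#' Cylindrical chamber volume in litres
#'
#' Volume of one microchamber, modelled as a cylinder:
#' `V = pi * (d/2)^2 * h`, converted from cubic micrometres to litres
#' (1 um^3 = 1e-15 L).
#'
#' @param diameter_um Chamber diameter in micrometres.
#' @param depth_um Chamber depth in micrometres.
#' @return Volume in litres.
#' @examples
#' chamber_volume(4.2, 3.15)  # ~4.36e-14 L = 43.6 fL
#' @export
chamber_volume <- function(diameter_um = 4.2, depth_um = 3.15) {
  if (any(diameter_um <= 0) || any(depth_um <= 0))
    stop("diameter_um and depth_um must be positive", call. = FALSE)
  pi * (diameter_um / 2)^2 * depth_um / UM3_PER_L
}

# Expected per-chamber occupancy for a molar concentration.
chamber_lambda <- function(concentration_M, volume_L) {
  concentration_M * volume_L * AVOGADRO
}

# Image dimensions (rows = height, cols = width) covering the grid + margin.
chip_image_dim <- function(geometry) {
  d <- chamber_diameter_px(geometry)
  p <- chamber_pitch_px(geometry)
  h <- ceiling(2 * (geometry$margin_px + d / 2) + (geometry$n_rows - 1) * p)
  w <- ceiling(2 * (geometry$margin_px + d / 2) + (geometry$n_cols - 1) * p)
  c(height = as.integer(h), width = as.integer(w))
}

# Chamber centres (0-based pixel coordinates, pixel-centre convention),
# row-major over the grid.
chamber_centers <- function(geometry) {
  d <- chamber_diameter_px(geometry)
  p <- chamber_pitch_px(geometry)
  row <- rep(seq_len(geometry$n_rows) - 1L, each = geometry$n_cols)
  col <- rep(seq_len(geometry$n_cols) - 1L, times = geometry$n_rows)
  data.frame(
    row = row,
    col = col,
    center_x_px = geometry$margin_px + d / 2 + col * p,
    center_y_px = geometry$margin_px + d / 2 + row * p
  )
}
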