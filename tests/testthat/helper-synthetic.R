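# Independent brute-force oracle for the radius of gyration: plain double
# loop over pixels, no shared code with the package implementation.
rog_brute <- function(g) {
  M <- nrow(g); N <- ncol(g)
  m00 <- 0; m20 <- 0; m02 <- 0
  for (y in 0:(M - 1)) {
    for (x in 0:(N - 1)) {
      v <- g[y + 1, x + 1]
      m00 <- m00 + v
      m20 <- m20 + (x - (N - 1) / 2)^2 * v
      m02 <- m02 + (y - (M - 1) / 2)^2 * v
    }
  }
  sqrt((m20 + m02) / m00)
}

# Hard (binary) centred disk crop: value inside radius, 0 outside.
disk_crop <- function(size = 16, radius = 5, value = 1) {
  c0 <- (size - 1) / 2
  xy <- seq_len(size) - 1
  mask <- outer((xy - c0)^2, (xy - c0)^2, "+") <= radius^2
  m <- matrix(0, size, size)
  m[mask] <- value
  m
}

# Greedy nearest-neighbour matching of detections to truth at <= tol px.
# Returns c(n_matched, n_detected, n_truth).
match_detections <- function(det_x, det_y, true_x, true_y, tol = 2) {
  used <- rep(FALSE, length(true_x))
  matched <- 0L
  for (i in seq_along(det_x)) {
    d2 <- (det_x[i] - true_x)^2 + (det_y[i] - true_y)^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= tol^2) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  c(matched = matched, detected = length(det_x), truth = length(true_x))
}

# Small chip used across tests.
small_geometry <- function(n = 10) {
  chip_geometry(n_rows = n, n_cols = n)
}
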