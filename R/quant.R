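#' Concentration from the positive-chamber fraction (linear estimator)
#'
#' The assay's printed estimator: `cE = lambda_exp / (V * N_A)` where
#' `lambda_exp` is the fraction of reaction-positive chambers, `V` the
#' average chamber volume in litres and `N_A` Avogadro's number
#' (6.02214076e23 / mol). Linear in the fraction: it ignores multiple
#' occupancy, a bias below 5 percent for fractions under ~0.1.
#'
#' @param positive_fraction Fraction of positive chambers, in `[0, 1]`.
#' @param chamber_volume_L Mean chamber volume in litres.
#' @return Concentration in mol/L.
#' @examples
#' estimate_concentration(1e-4, chamber_volume())  # ~3.8e-15 M (~4 fM)
#' estimate_concentration(1,    chamber_volume())  # ~3.8e-11 M (~40 pM)
#' @export
estimate_concentration <- function(positive_fraction, chamber_volume_L) {
  if (any(positive_fraction < 0) || any(positive_fraction > 1))
    stop("positive_fraction must be in [0, 1]", call. = FALSE)
  if (any(chamber_volume_L <= 0))
    stop("chamber_volume_L must be positive", call. = FALSE)
  positive_fraction / (chamber_volume_L * AVOGADRO)
}

#' Poisson-corrected concentration estimator
#'
#' Standard digital-assay correction for multiple occupancy: the mean
#' per-chamber occupancy implied by a positive fraction `f` under Poisson
#' loading is `-ln(1 - f)`, so `c = -ln(1 - f) / (V * N_A)`. Always at
#' least the linear estimate, with equality only at `f = 0`. Reported as
#' "poisson_corrected" and never the default in summaries.
#'
#' @inheritParams estimate_concentration
#' @return Concentration in mol/L.
#' @examples
#' estimate_concentration_poisson(0.0903, chamber_volume())  # ~3.6e-12 M
#' @export
estimate_concentration_poisson <- function(positive_fraction,
                                           chamber_volume_L) {
  if (any(positive_fraction < 0) || any(positive_fraction > 1))
    stop("positive_fraction must be in [0, 1]", call. = FALSE)
  if (any(positive_fraction == 1))
    stop("all chambers positive: assay saturated; dilute the sample",
         call. = FALSE)
  if (any(chamber_volume_L <= 0))
    stop("chamber_volume_L must be positive", call. = FALSE)
  -log(1 - positive_fraction) / (chamber_volume_L * AVOGADRO)
}

#' Digital quantification summary from classified chambers
#'
#' Counts positives and exclusions and converts the post-exclusion
#' positive fraction into concentration with both estimators. Excluded
#' chambers leave both the numerator and the denominator.
#'
#' @param measurements A classified `chamber_measurements` table (with
#'   `label` and `excluded` columns).
#' @param chamber_volume_L Mean chamber volume in litres.
#' @return An object of class `quant_result`: `n_total`, `n_positive`,
#'   `n_excluded`, `positive_fraction`, `chamber_volume_L`,
#'   `concentration_estimate_M` (linear), `concentration_poisson_M`
#'   (NA at saturation).
#' @export
quantify_chambers <- function(measurements, chamber_volume_L =
                                chamber_volume()) {
  n_total <- nrow(measurements)
  n_excluded <- sum(measurements$excluded)
  n_eff <- n_total - n_excluded
  n_positive <- sum(measurements$label == "positive" &
                      !measurements$excluded)
  f <- if (n_eff > 0) n_positive / n_eff else 0
  structure(
    list(n_total = n_total, n_positive = n_positive,
         n_excluded = n_excluded, positive_fraction = f,
         chamber_volume_L = chamber_volume_L,
         concentration_estimate_M =
           estimate_concentration(f, chamber_volume_L),
         concentration_poisson_M =
           if (f < 1) estimate_concentration_poisson(f, chamber_volume_L)
           else NA_real_),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("Digital assay quantification\n")
  cat(sprintf("  chambers: %d total, %d positive, %d excluded\n",
              x$n_total, x$n_positive, x$n_excluded))
  cat(sprintf("  positive fraction: %.4g\n", x$positive_fraction))
  cat(sprintf("  chamber volume: %.3g fL\n", x$chamber_volume_L * 1e15))
  cat(sprintf("  concentration: %.2g M (linear), %.2g M (poisson_corrected)\n",
              x$concentration_estimate_M, x$concentration_poisson_M))
  invisible(x)
}

#' Positive-count time course
#'
#' @param times_min Strictly increasing acquisition times (minutes).
#' @param positive_counts Positive-chamber count per frame.
#' @param n_total Total chamber count.
#' @param frame_interval_min Nominal frame interval (minutes, default 2).
#' @return An object of class `time_course` (a data frame with `time_min`
#'   and `n_positive`; `n_total` and `frame_interval_min` as attributes).
#' @export
time_course <- function(times_min, positive_counts, n_total,
                        frame_interval_min = 2) {
  if (length(times_min) == 0) stop("empty time course", call. = FALSE)
  if (length(times_min) != length(positive_counts))
    stop("times_min and positive_counts must have equal length",
         call. = FALSE)
  if (any(diff(times_min) <= 0))
    stop("times_min must be strictly increasing", call. = FALSE)
  structure(data.frame(time_min = times_min, n_positive = positive_counts),
            n_total = n_total, frame_interval_min = frame_interval_min,
            class = c("time_course", "data.frame"))
}

#' Detection time of a positive-count time course
#'
#' The earliest acquisition time at which the positive count exceeds
#' `trigger` (default 10, about 0.1 percent of a 10,000-chamber array).
#' The rule presumes a quiet start: if the first frame already has more
#' than `initial_max` positives (default 2), a warning is raised but the
#' time is still computed.
#'
#' @param tc A [time_course()].
#' @param initial_max Largest acceptable first-frame count (default 2).
#' @param trigger Count that must be exceeded (default 10).
#' @return Detection time in minutes, or `NA` if the count never exceeds
#'   `trigger`.
#' @examples
#' tc <- time_course(seq(0, 10, 2), c(0, 1, 2, 5, 11, 30), 10000)
#' detection_time(tc)  # 8
#' @export
detection_time <- function(tc, initial_max = 2, trigger = 10) {
  if (nrow(tc) == 0) stop("empty time course", call. = FALSE)
  if (tc$n_positive[1] > initial_max)
    warning(sprintf(
      "first-frame positive count (%d) exceeds initial_max (%g)",
      tc$n_positive[1], initial_max), call. = FALSE)
  hit <- which(tc$n_positive > trigger)
  if (!length(hit)) return(NA_real_)
  tc$time_min[hit[1]]
}

#' Quantification time of a positive-count time course
#'
#' The first time after the detection time at which the relative change in
#' positive count between consecutive frames falls below `rel_change`
#' (default 20 percent of the previous frame). Frame pairs whose previous
#' count is zero are skipped.
#'
#' @param tc A [time_course()].
#' @param detection_t Detection time; must be one of the acquisition
#'   times.
#' @param rel_change Relative-change criterion (default 0.2).
#' @return Quantification time in minutes, or `NA` if never satisfied.
#' @export
quantification_time <- function(tc, detection_t, rel_change = 0.2) {
  if (is.na(detection_t) || !detection_t %in% tc$time_min)
    stop("detection_t must be one of the acquisition times", call. = FALSE)
  for (i in seq_len(nrow(tc))[-1]) {
    if (tc$time_min[i] <= detection_t) next
    prev <- tc$n_positive[i - 1]
    if (prev == 0) next
    if (abs(tc$n_positive[i] - prev) / prev < rel_change)
      return(tc$time_min[i])
  }
  NA_real_
}

#' Coefficient of variation of replicate measurements
#'
#' `100 * sample SD / mean` (n - 1 denominator), as used to summarise
#' day-to-day replicate positive-chamber counts.
#'
#' @param values Numeric vector of >= 2 replicate counts or
#'   concentrations with positive mean.
#' @return CV in percent.
#' @export
replicate_cv <- function(values) {
  if (length(values) < 2)
    stop("need at least 2 replicate values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("replicate mean must be positive", call. = FALSE)
  100 * stats::sd(values) / m
}
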