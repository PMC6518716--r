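#' Shape deformation factors of an area sequence
#'
#' Converts the per-frame silhouette areas of one camera into shape
#' deformation factors: the area of every frame divided by the area of the
#' reference frame. The reference defaults to the first frame of the
#' sequence, acquired with the vessel motionless, so the factor of the
#' reference frame is 1 by construction.
#'
#' @param areas Numeric vector of per-frame areas (px^2), all positive,
#'   length at least 2.
#' @param reference_index Index of the reference frame (1-based, default 1).
#' @param frame_rate Optional frame rate (frames/s), carried along.
#' @param camera_index Optional camera index, carried along.
#' @return An object of class `deformation_series`: fields `areas`,
#'   `reference_area`, `factors`, `reference_index`, `frame_rate`,
#'   `camera_index`.
#' @export
deformation_factors <- function(areas, reference_index = 1L,
                                frame_rate = NA_real_,
                                camera_index = NA_integer_) {
  if (length(areas) < 2) stop("need at least 2 frames")
  bad <- which(!is.finite(areas) | areas <= 0)
  if (length(bad))
    stop(sprintf("invalid measurement: non-positive area at frame %d", bad[1]))
  if (reference_index < 1 || reference_index > length(areas))
    stop("reference_index outside the sequence")
  structure(list(areas = as.numeric(areas),
                 reference_area = as.numeric(areas[reference_index]),
                 factors = as.numeric(areas) / areas[reference_index],
                 reference_index = as.integer(reference_index),
                 frame_rate = frame_rate,
                 camera_index = camera_index),
            class = "deformation_series")
}

#' @export
print.deformation_series <- function(x, ...) {
  cat(sprintf("Deformation series: %d frames, reference area %.6g px^2 (frame %d)\n",
              length(x$factors), x$reference_area, x$reference_index))
  cat(sprintf("  factor range: [%.4f, %.4f]\n",
              min(x$factors), max(x$factors)))
  invisible(x)
}

#' @export
plot.deformation_series <- function(x, ...) {
  t <- if (is.finite(x$frame_rate)) (seq_along(x$factors) - 1) / x$frame_rate
       else seq_along(x$factors) - 1
  xlab <- if (is.finite(x$frame_rate)) "time (s)" else "frame"
  graphics::plot(t, x$factors, type = "l", xlab = xlab,
                 ylab = "shape deformation factor", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Convert deformation factors to millimetre wall displacement
#'
#' Maps each area-ratio factor to an equivalent-circle radial displacement:
#' the reference silhouette is assigned its equivalent-circle radius
#' `r_ref = sqrt(F_ref / pi) * mm_per_pixel`, and the displacement of frame
#' i is `r_ref * (sqrt(n_i) - 1)` mm, positive for expansion. Exact for
#' concentric circular dilation; for irregular silhouettes it is the
#' area-equivalent mean radial excursion.
#'
#' @param series A [deformation_factors()] object.
#' @param scale A [pixel_scale()] object.
#' @return Numeric vector of displacements (mm), one per frame.
#' @export
factor_to_displacement <- function(series, scale) {
  if (series$reference_area <= 0) stop("reference area must be positive")
  r_ref <- sqrt(series$reference_area / pi) * scale$mm_per_pixel
  r_ref * (sqrt(series$factors) - 1)
}

#' Per-cycle deformation amplitudes
#'
#' Splits a displacement series into consecutive windows of one pulsation
#' cycle (60 / pulse_rate seconds) and reports the amplitude of each
#' complete cycle as its max - min displacement. A trailing partial cycle
#' is discarded.
#'
#' @param displacements Numeric displacement series (mm).
#' @param frame_rate Frames per second of the series.
#' @param pulse_rate Pulsation rate in min^-1.
#' @return Numeric vector of per-cycle amplitudes (mm).
#' @export
cycle_amplitudes <- function(displacements, frame_rate, pulse_rate) {
  cycle_s <- 60 / pulse_rate
  frames_per_cycle <- frame_rate * cycle_s
  n <- length(displacements)
  n_cycles <- floor(n / frames_per_cycle)
  if (n_cycles < 1)
    stop(sprintf("insufficient data: need at least %.0f frames for one cycle, got %d",
                 ceiling(frames_per_cycle), n))
  vapply(seq_len(n_cycles), function(k) {
    i0 <- floor((k - 1) * frames_per_cycle) + 1
    i1 <- floor(k * frames_per_cycle)
    win <- displacements[i0:i1]
    max(win) - min(win)
  }, numeric(1))
}

#' Average wall deformation over positions and probes
#'
#' Summarises a complete table of per-position, per-probe deformation
#' amplitudes for one subject into the average wall deformation (AWD):
#' the mean of all position x probe values, with the sample standard
#' deviation (n - 1 denominator). Values are reported rounded to two
#' decimals alongside full precision.
#'
#' @param values Either a numeric `positions x probes` matrix, or a data
#'   frame with columns `position`, `probe`, `amplitude_mm`.
#' @param positions,probes Expected table dimensions (default 4 x 4:
#'   anterior 0, left 90, posterior 180, right 270 degrees; four repeated
#'   probes each).
#' @return An object of class `wall_deformation_summary`: `awd`, `sd`
#'   (full precision), `awd_2dp`, `sd_2dp`, `n`, `values`.
#' @export
summarize_wall_deformation <- function(values, positions = 4L, probes = 4L) {
  if (is.data.frame(values)) {
    need <- c("position", "probe", "amplitude_mm")
    if (!all(need %in% names(values)))
      stop("data frame input needs columns position, probe, amplitude_mm")
    tab <- tapply(values$amplitude_mm, list(values$position, values$probe),
                  function(v) v[1])
    values <- unname(tab)
  }
  values <- as.matrix(values)
  if (any(is.na(values)) || nrow(values) != positions || ncol(values) != probes)
    stop(sprintf("incomplete table: expected a complete %d x %d value grid",
                 positions, probes))
  v <- as.numeric(values)
  structure(list(awd = mean(v), sd = stats::sd(v),
                 awd_2dp = round(mean(v), 2), sd_2dp = round(stats::sd(v), 2),
                 n = length(v), values = values),
            class = "wall_deformation_summary")
}

#' @export
print.wall_deformation_summary <- function(x, ...) {
  cat(sprintf("Average wall deformation: %.2f +/- %.2f mm (n = %d)\n",
              x$awd, x$sd, x$n))
  invisible(x)
}

#' Static silhouette diameter from largest-object measurements
#'
#' Converts the maximum caliper width of each camera's segmented
#' silhouette to millimetres and averages over cameras, giving the static
#' (no-flow) diameter estimate of the object.
#'
#' @param measures A single `object_measure` or a list of them (one per
#'   camera).
#' @param scale A [pixel_scale()] object.
#' @return List with `diameter_mm` (mean over cameras) and
#'   `per_camera_mm`.
#' @export
static_diameter <- function(measures, scale) {
  if (inherits(measures, "object_measure")) measures <- list(measures)
  if (length(measures) < 1) stop("need measurements from at least 1 camera")
  per_cam <- vapply(measures, function(m) {
    if (m$max_caliper_px <= 0) stop("degenerate contour: zero caliper width")
    m$max_caliper_px * scale$mm_per_pixel
  }, numeric(1))
  list(diameter_mm = mean(per_cam), per_camera_mm = per_cam)
}

#' Write a per-camera deformation table as CSV
#'
#' @param series A [deformation_factors()] object.
#' @param displacements_mm Displacement vector from
#'   [factor_to_displacement()] (optional).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_deformation_csv <- function(series, displacements_mm = NULL, path) {
  df <- data.frame(camera = series$camera_index,
                   frame = seq_along(series$areas),
                   area_px = series$areas,
                   n_i = series$factors)
  if (!is.null(displacements_mm)) df$displacement_mm <- displacements_mm
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
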