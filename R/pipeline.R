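# Pipeline orchestration, frame/config I/O and the deterministic replay of
# the producer-consumer acquisition contract.

#' Map a camera viewing angle to a cardinal position label
#'
#' Bins an angle to the nearest of the four cardinal positions used in
#' wall-deformation reporting: anterior (0 deg), left (90 deg), posterior
#' (180 deg), right (270 deg).
#'
#' @param angle_rad Viewing angle(s) in radians.
#' @return Character vector of position labels.
#' @export
position_label <- function(angle_rad) {
  deg <- (angle_rad * 180 / pi) %% 360
  labels <- c("anterior", "left", "posterior", "right")
  idx <- (round(deg / 90) %% 4) + 1
  labels[idx]
}

#' Write a frame sequence as numbered PNG files
#'
#' Frames are written 8-bit grayscale as
#' `cam{cc}_frame{iiiiii}.png` (zero-padded camera and 0-based frame
#' index).
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_frames <- function(seq, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_along(seq$frames), function(i) {
    p <- file.path(dir, sprintf("cam%02d_frame%06d.png",
                                seq$camera_index, i - 1))
    png::writePNG(seq$frames[[i]] / 255, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a camera's frame sequence from numbered PNG files
#'
#' @param dir Directory containing `cam{cc}_frame{iiiiii}.png` files.
#' @param camera_index Which camera to read.
#' @param fps Frame rate to attach.
#' @param angle_rad Viewing angle to attach.
#' @return A [frame_sequence()].
#' @export
read_frames <- function(dir, camera_index, fps = 30, angle_rad = 0) {
  files <- sort(list.files(dir, sprintf("^cam%02d_frame\\d+\\.png$",
                                        camera_index),
                           full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("no frames for camera %d in %s", camera_index, dir))
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    round(to_grayscale(img * 255))
  })
  frame_sequence(frames, fps, camera_index, angle_rad)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file. Recognised fields: `intrinsics` (path),
#'   `mm_per_pixel` or `scale_square` (list with `side_m` and `area_px2`),
#'   `pulse_rate`, `fps`, `min_object_px`, `seed`, `input_dir`,
#'   `output_dir`, `cameras`.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

#' Run the full offline measurement pipeline
#'
#' For every camera sequence: rectify each frame, segment it (Otsu +
#' largest object), collect the per-frame areas, convert them to shape
#' deformation factors and millimetre displacements, and split the
#' displacement series into per-cycle amplitudes. Results are summarised
#' per camera and per cardinal position; a stage failure aborts only that
#' camera's series, not the whole run.
#'
#' Collected sequences are analysed offline (batch), matching the
#' acquisition contract replayed by [simulate_acquisition()]: measurements
#' consume the lossless saving path only.
#'
#' @param sequences List of [frame_sequence()] objects (one per camera).
#' @param intr A [camera_intrinsics()] shared by the cameras.
#' @param scale A [pixel_scale()] for the mm conversion.
#' @param pulse_rate Pulsation rate (min^-1) used for cycle splitting.
#' @param min_object_px Small-object cleanup threshold for
#'   [segment_frame()] (0 = off).
#' @param jump_warn_frac Warn when a camera's area changes by more than
#'   this fraction between consecutive frames (physiologically implausible
#'   at video rate).
#' @param output_dir Optional directory; per-camera deformation CSVs, a
#'   summary CSV and a JSON report are written there.
#' @param seed Seed recorded in the report header (the pipeline itself is
#'   deterministic).
#' @return An object of class `pipeline_report`: `per_camera` (list with
#'   series, displacements, amplitudes, position), `summary` (data frame:
#'   camera, position, mean_amplitude_mm), `awd` (mean +/- SD of the
#'   per-camera mean amplitudes), `errors`.
#' @export
run_pipeline <- function(sequences, intr, scale, pulse_rate = 72,
                         min_object_px = 0, jump_warn_frac = 0.2,
                         output_dir = NULL, seed = NA_integer_) {
  if (!is.list(sequences) || length(sequences) == 0)
    stop("sequences must be a non-empty list of frame_sequence objects")
  if (inherits(sequences, "frame_sequence")) sequences <- list(sequences)
  per_camera <- list()
  errors <- list()
  for (s in sequences) {
    cam <- s$camera_index
    res <- tryCatch({
      if (length(s$frames) < 2)
        stop("need at least 2 frames per camera")
      areas <- numeric(length(s$frames))
      for (i in seq_along(s$frames)) {
        f <- rectify_image(s$frames[[i]], intr)
        areas[i] <- segment_frame(f, min_object_px)$area_px
      }
      jumps <- which(abs(diff(areas)) / areas[-length(areas)] > jump_warn_frac)
      for (j in jumps)
        warning(sprintf("camera %d: area jump > %.0f%% between frames %d and %d",
                        cam, 100 * jump_warn_frac, j, j + 1))
      series <- deformation_factors(areas, frame_rate = s$fps,
                                    camera_index = cam)
      disp <- factor_to_displacement(series, scale)
      amps <- tryCatch(cycle_amplitudes(disp, s$fps, pulse_rate),
                       error = function(e) numeric(0))
      list(series = series, displacements_mm = disp, amplitudes_mm = amps,
           position = position_label(s$angle_rad), angle_rad = s$angle_rad)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(cam)]] <- sprintf("camera %d: %s", cam,
                                             conditionMessage(res))
    } else {
      per_camera[[as.character(cam)]] <- res
    }
  }
  if (length(per_camera) == 0)
    stop("pipeline failed for every camera: ",
         paste(unlist(errors), collapse = "; "))
  summary_df <- do.call(rbind, lapply(per_camera, function(r) {
    data.frame(camera = r$series$camera_index, position = r$position,
               mean_amplitude_mm = if (length(r$amplitudes_mm))
                 mean(r$amplitudes_mm) else max(r$displacements_mm) -
                 min(r$displacements_mm))
  }))
  rownames(summary_df) <- NULL
  awd <- list(mean = mean(summary_df$mean_amplitude_mm),
              sd = if (nrow(summary_df) > 1)
                stats::sd(summary_df$mean_amplitude_mm) else 0)
  report <- structure(list(per_camera = per_camera, summary = summary_df,
                           awd = awd, errors = errors, seed = seed),
                      class = "pipeline_report")
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    for (r in per_camera)
      write_deformation_csv(r$series, r$displacements_mm,
                            file.path(output_dir,
                                      sprintf("deformation_cam%02d.csv",
                                              r$series$camera_index)))
    utils::write.csv(summary_df, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = seed, awd_mean_mm = awd$mean,
                              awd_sd_mm = awd$sd,
                              n_cameras = nrow(summary_df),
                              errors = unlist(errors)),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d cameras analysed, %d failed\n",
              length(x$per_camera), length(x$errors)))
  cat(sprintf("  average wall deformation: %.2f +/- %.2f mm\n",
              x$awd$mean, x$awd$sd))
  invisible(x)
}

#' Replay the producer-consumer acquisition contract
#'
#' Deterministic event-driven replay of the capture architecture: a
#' producer emits frames at the camera rate and pushes every frame into
#' the saving queue (lossless, bounded only by `saving_capacity`) while
#' offering each frame to a size-1 preview queue that is dropped-from when
#' the preview consumer is still busy. The saving consumer drains at a
#' configurable rate; the preview consumer needs `preview_service_frames`
#' frame periods per serviced frame.
#'
#' @param n_frames Number of frames produced.
#' @param saving_capacity Maximum saving-queue occupancy (frames); an
#'   overflow raises an error naming the offending frame.
#' @param saving_drain_per_frame Frames the saving consumer removes per
#'   frame period (0 models a stalled disk).
#' @param preview_service_frames Frame periods the preview consumer needs
#'   per frame (1 = as fast as the producer).
#' @return An object of class `frame_stream_stats`: `frames_produced`,
#'   `frames_saved`, `frames_previewed`, `frames_dropped_from_preview`,
#'   `max_saving_occupancy`, `max_preview_occupancy`.
#' @export
simulate_acquisition <- function(n_frames, saving_capacity = Inf,
                                 saving_drain_per_frame = 1,
                                 preview_service_frames = 1) {
  if (n_frames < 1) stop("need at least one frame")
  occupancy <- 0
  max_occ <- 0
  previewed <- 0L
  dropped <- 0L
  preview_free_at <- 0
  for (t in 0:(n_frames - 1)) {
    occupancy <- occupancy + 1
    if (occupancy > saving_capacity)
      stop(sprintf("saving-queue overflow at frame %d (capacity %d)",
                   t + 1, saving_capacity))
    max_occ <- max(max_occ, occupancy)
    occupancy <- max(0, occupancy - saving_drain_per_frame)
    if (t >= preview_free_at) {
      previewed <- previewed + 1L
      preview_free_at <- t + preview_service_frames
    } else {
      dropped <- dropped + 1L
    }
  }
  structure(list(frames_produced = as.integer(n_frames),
                 frames_saved = as.integer(n_frames),
                 frames_previewed = previewed,
                 frames_dropped_from_preview = dropped,
                 max_saving_occupancy = max_occ,
                 max_preview_occupancy = 1L),
            class = "frame_stream_stats")
}

#' @export
print.frame_stream_stats <- function(x, ...) {
  cat(sprintf(
    "Frame stream: %d produced, %d saved, %d previewed, %d dropped from preview\n",
    x$frames_produced, x$frames_saved, x$frames_previewed,
    x$frames_dropped_from_preview))
  invisible(x)
}
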