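# Plain-text scenario I/O. One directory per scenario:
#   sensor.csv     time_s, gyro_x, gyro_y, gyro_z
#   phase.csv      frame, time_s, <sin/cos per event>, phase_rate,
#                  pelvis_vel, hip_ang, knee_ang
#   keypoints.csv  frame, time_s, joint, x_px, y_px, confidence
#   segment.json   {t_start_s, t_end_s, distance_m, view}
#   truth.json     ground-truth events (for validation against truth)
#   config.json    the synthetic_config that produced the files

#' Write a complete synthetic scenario to a directory
#'
#' @param dir Output directory (created if missing).
#' @param truth,gyro,phase,keypoints Objects from the generator stage.
#' @param config The [synthetic_config()] used to make them.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(dir, truth, gyro, phase, keypoints, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(gyro), file.path(dir, "sensor.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(phase), file.path(dir, "phase.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(keypoints), file.path(dir, "keypoints.csv"),
                   row.names = FALSE)
  seg <- list(t_start_s = truth$t_s, t_end_s = truth$t_e,
              distance_m = truth$segment_distance_m, view = truth$view)
  jsonlite::write_json(seg, file.path(dir, "segment.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- unclass(truth)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a gyroscope trace CSV
#'
#' @param path CSV with columns `time_s`, `gyro_x`, `gyro_y`, `gyro_z`.
#' @param nominal_rate_hz Nominal sampling rate attached as an attribute.
#' @return A `gyro_trace` data frame.
#' @export
read_gyro_csv <- function(path, nominal_rate_hz = 562.5) {
  x <- utils::read.csv(path)
  need <- c("time_s", "gyro_z")
  if (!all(need %in% names(x))) {
    stop("sensor CSV ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  attr(x, "nominal_rate_hz") <- nominal_rate_hz
  class(x) <- c("gyro_trace", "data.frame")
  x
}

#' Read a gait phase-series CSV
#' @param path CSV written by [write_scenario()] (or same schema).
#' @return A `gait_phase_series` data frame.
#' @export
read_phase_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("time_s", "lfc_sin", "lfc_cos", "rfc_sin", "rfc_cos",
            "phase_rate", "pelvis_vel", "hip_ang", "knee_ang")
  if (!all(need %in% names(x))) {
    stop("phase CSV ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  class(x) <- c("gait_phase_series", "data.frame")
  x
}

#' Read a keypoint-track CSV
#' @param path CSV with columns `frame`, `joint`, `x_px`, `y_px`,
#'   `confidence`.
#' @param width_px,height_px Image dimensions in pixels.
#' @param prosthetic_side Which side's ankle carries the quality rule.
#' @return A `keypoint_track` data frame.
#' @export
read_keypoints_csv <- function(path, width_px = 1080, height_px = 1920,
                               prosthetic_side = "right") {
  x <- utils::read.csv(path)
  need <- c("frame", "joint", "x_px", "y_px", "confidence")
  if (!all(need %in% names(x))) {
    stop("keypoint CSV ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  attr(x, "width_px") <- width_px
  attr(x, "height_px") <- height_px
  attr(x, "prosthetic_side") <- prosthetic_side
  class(x) <- c("keypoint_track", "data.frame")
  x
}

#' Read a timed-segment annotation JSON
#' @param path JSON with fields `t_start_s`, `t_end_s`, `distance_m`,
#'   `view`.
#' @return A [timed_segment()].
#' @export
read_segment_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  timed_segment(x$t_start_s, x$t_end_s,
                distance_m = x$distance_m %||% 10,
                view = x$view %||% "frontal")
}

#' Read ground truth back from a scenario directory
#' @param path `truth.json` written by [write_scenario()].
#' @return A `gait_truth` object.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(x) <- "gait_truth"
  x
}
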