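# Video-side processing: sliding-window output assembly, quadrature
# event decoding, segment cadence/velocity, and keypoint-quality rules.

#' Annotated timed walking segment
#'
#' A manually annotated 10-m walk window. The ground-truth velocity is
#' `distance_m / (t_end_s - t_start_s)`.
#'
#' @param t_start_s,t_end_s Segment boundaries, seconds (`t_end_s >
#'   t_start_s`).
#' @param distance_m Marked walking distance, metres (default 10).
#' @param view View label: `"frontal"`, `"sagittal"` or `"mixed"`.
#' @return A `timed_segment` list with the fields above plus
#'   `velocity_truth_ms`.
#' @export
#' @examples
#' timed_segment(0, 8)$velocity_truth_ms  # 10 m in 8 s -> 1.25 m/s
timed_segment <- function(t_start_s, t_end_s, distance_m = 10,
                          view = c("frontal", "sagittal", "mixed")) {
  view <- match.arg(view)
  stopifnot(is.numeric(t_start_s), is.numeric(t_end_s),
            t_end_s > t_start_s, distance_m > 0)
  out <- list(t_start_s = t_start_s, t_end_s = t_end_s,
              distance_m = distance_m, view = view,
              velocity_truth_ms = distance_m / (t_end_s - t_start_s))
  class(out) <- "timed_segment"
  out
}

#' Shift a timed segment into another timebase
#' @param segment A [timed_segment()].
#' @param offset_s Seconds to add to both boundaries.
#' @return A shifted `timed_segment`.
#' @export
shift_segment <- function(segment, offset_s) {
  timed_segment(segment$t_start_s + offset_s, segment$t_end_s + offset_s,
                distance_m = segment$distance_m, view = segment$view)
}

#' Assemble per-frame outputs from a sliding-window model
#'
#' Sequence models trained on short gait-lab bouts do not generalize to
#' long clinic recordings, so inference runs on a sliding window of 90
#' frames (3 s at 30 fps) and the per-frame output is stitched from the
#' window centres: output frame `t` (0-based, `45 <= t <= N-46`) takes
#' row 45 of the window starting at `t - 45`; the first 45 frames take
#' rows 0..44 of the first window and the last 45 frames rows 45..89 of
#' the last window.
#'
#' @param model A function mapping a `window_size`-row matrix/data frame
#'   of per-frame inputs to a `window_size`-row output.
#' @param frames Matrix or data frame of per-frame inputs, `N >= 90`
#'   rows.
#' @param window_size Window length in frames (default 90).
#' @return The stitched output with `N` rows.
#' @export
assemble_sliding_window <- function(model, frames, window_size = 90L) {
  if (is.vector(frames)) frames <- matrix(frames, ncol = 1L)
  n <- nrow(frames)
  if (n < window_size) {
    stop("need at least ", window_size, " frames, got ", n, call. = FALSE)
  }
  half <- window_size %/% 2L  # 45 for the default window
  run_window <- function(start) {
    out <- model(frames[start:(start + window_size - 1L), , drop = FALSE])
    if (is.vector(out)) out <- matrix(out, ncol = 1L)
    if (nrow(out) != window_size) {
      stop("model returned ", nrow(out), " rows for a ", window_size,
           "-frame window", call. = FALSE)
    }
    out
  }
  first <- run_window(1L)
  pieces <- vector("list", n)
  for (t1 in seq_len(half)) pieces[[t1]] <- first[t1, , drop = FALSE]
  mid_top <- n - half  # last output frame taken from a window centre
  if (mid_top >= half + 1L) {
    for (t1 in (half + 1L):mid_top) {
      w <- run_window(t1 - half)
      pieces[[t1]] <- w[half + 1L, , drop = FALSE]
    }
  }
  last <- run_window(n - window_size + 1L)
  for (r in (half + 1L):window_size) {
    pieces[[n - window_size + r]] <- last[r, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# Positively directed zero crossings of a quadrature pair, sub-frame
# located by linear interpolation; crossings with interpolated cos <= 0
# are the mid-cycle crossings of a noisy circle and are rejected.
decode_quadrature <- function(time_s, s, c) {
  n <- length(s)
  if (n < 2L) stop("need at least 2 frames to decode events", call. = FALSE)
  i <- which(s[-n] <= 0 & s[-1] > 0)
  if (length(i) == 0L) return(numeric(0))
  frac <- -s[i] / (s[i + 1L] - s[i])
  tc <- time_s[i] + frac * (time_s[i + 1L] - time_s[i])
  cc <- c[i] + frac * (c[i + 1L] - c[i])
  tc[cc > 0]
}

#' Decode foot-contact times from quadrature channels
#'
#' Foot contacts are the positively directed zero crossings of that
#' leg's foot-contact sin channel, located to sub-frame precision by
#' linear interpolation; the cos channel must be positive at the
#' crossing (the event sits at phase 0, where cos is near +1).
#'
#' @param series A `gait_phase_series`.
#' @param leg `"left"` or `"right"`.
#' @param event `"contact"` or `"toe_off"`.
#' @return Numeric vector of event times, seconds (possibly empty).
#' @export
decode_foot_contacts <- function(series, leg = c("left", "right"),
                                 event = c("contact", "toe_off")) {
  leg <- match.arg(leg)
  event <- match.arg(event)
  stub <- paste0(substr(leg, 1, 1), if (event == "contact") "fc" else "to")
  decode_quadrature(series$time_s,
                    series[[paste0(stub, "_sin")]],
                    series[[paste0(stub, "_cos")]])
}

# Trapezoidal integral of a per-frame channel over [t_s, t_e], with
# partial frames at the ends handled by linear interpolation.
segment_trapz <- function(time_s, value, t_s, t_e) {
  eps <- 1e-9
  if (t_s < time_s[1] - eps || t_e > time_s[length(time_s)] + eps) {
    stop(sprintf("segment [%.3f, %.3f] s lies outside the series range [%.3f, %.3f] s",
                 t_s, t_e, time_s[1], time_s[length(time_s)]), call. = FALSE)
  }
  inner <- time_s[time_s > t_s & time_s < t_e]
  xs <- c(t_s, inner, t_e)
  ys <- stats::approx(time_s, value, xout = xs, rule = 2)$y
  trapz_int(xs, ys)
}

#' Cadence from the video phase-rate channel
#'
#' Averages the gait-cycle phase rate over the timed segment and
#' converts strides in rad/s to steps/min:
#' `c_v = 120 / (2 * pi * (t_e - t_s)) * integral of phase rate`.
#'
#' @param series A `gait_phase_series` with a `phase_rate` column
#'   (rad/s).
#' @param segment A [timed_segment()] inside the series time range.
#' @return Cadence in steps/min.
#' @export
#' @examples
#' s <- data.frame(time_s = seq(0, 10, 1/30), phase_rate = 2 * pi)
#' compute_video_cadence(s, timed_segment(1, 9))  # 120 steps/min
compute_video_cadence <- function(series, segment) {
  stopifnot(inherits(segment, "timed_segment"))
  dt <- segment$t_end_s - segment$t_start_s
  120 / (2 * pi * dt) *
    segment_trapz(series$time_s, series$phase_rate,
                  segment$t_start_s, segment$t_end_s)
}

#' Walking velocity from the pelvis-velocity channel
#'
#' Trapezoidal time average of the pelvis-velocity channel over the
#' segment; the ground-truth comparator is the annotated
#' `distance / (t_e - t_s)`.
#'
#' @inheritParams compute_video_cadence
#' @return Velocity in m/s.
#' @export
compute_segment_velocity <- function(series, segment) {
  stopifnot(inherits(segment, "timed_segment"))
  dt <- segment$t_end_s - segment$t_start_s
  segment_trapz(series$time_s, series$pelvis_vel,
                segment$t_start_s, segment$t_end_s) / dt
}

#' Edge-clipping and ankle-quality summary for a segment
#'
#' A frame is clipped when any leg keypoint lies within `margin_px` of
#' the image border; a segment is clipped when the clipped-frame
#' fraction exceeds `clip_fraction`. Also reports the mean confidence of
#' the prosthetic-side ankle over the segment (bilateral users: mean of
#' both ankles).
#'
#' @param track A `keypoint_track`.
#' @param segment Optional [timed_segment()]; `NULL` uses all frames.
#' @param margin_px Border margin in pixels (default 10).
#' @param clip_fraction Clipped-frame fraction above which the segment
#'   is flagged (default 0.01).
#' @param prosthetic_side `"right"`, `"left"` or `"both"`; defaults to
#'   the track attribute.
#' @return A `segment_quality` list: `mean_ankle_confidence`,
#'   `clipped_fraction`, `clipped`, `n_frames`.
#' @export
flag_clipping <- function(track, segment = NULL, margin_px = 10,
                          clip_fraction = 0.01,
                          prosthetic_side = attr(track, "prosthetic_side")) {
  width <- attr(track, "width_px") %||% 1080
  height <- attr(track, "height_px") %||% 1920
  x <- as.data.frame(track)
  if (!is.null(segment)) {
    stopifnot(inherits(segment, "timed_segment"))
    x <- x[x$time_s >= segment$t_start_s & x$time_s <= segment$t_end_s, ]
  }
  if (nrow(x) == 0L) {
    out <- list(mean_ankle_confidence = NA_real_, clipped_fraction = 0,
                clipped = FALSE, n_frames = 0L)
    class(out) <- "segment_quality"
    return(out)
  }
  pt_clipped <- x$x_px < margin_px | x$x_px > width - margin_px |
    x$y_px < margin_px | x$y_px > height - margin_px
  frame_clipped <- tapply(pt_clipped, x$frame, any)
  frac <- mean(frame_clipped)
  side <- prosthetic_side %||% "right"
  ankle_joints <- if (identical(side, "both")) {
    c("ankle_left", "ankle_right")
  } else {
    paste0("ankle_", side)
  }
  conf <- x$confidence[x$joint %in% ankle_joints]
  out <- list(
    mean_ankle_confidence = if (length(conf)) mean(conf) else NA_real_,
    clipped_fraction = unname(frac),
    clipped = unname(frac > clip_fraction),
    n_frames = length(frame_clipped)
  )
  class(out) <- "segment_quality"
  out
}

#' Partition segments by ankle-keypoint quality
#'
#' A segment is included when its mean prosthetic-ankle confidence is at
#' least `threshold` (strictly-below is excluded) and it is not flagged
#' as clipped.
#'
#' @param qualities A list of `segment_quality` objects (or a data frame
#'   with `mean_ankle_confidence` and `clipped` columns).
#' @param threshold Quality threshold (default 0.7).
#' @return Data frame with `mean_ankle_confidence`, `clipped_fraction`,
#'   `clipped` and `included` per segment.
#' @export
filter_by_ankle_quality <- function(qualities, threshold = 0.7) {
  if (inherits(qualities, "segment_quality")) qualities <- list(qualities)
  if (is.data.frame(qualities)) {
    df <- qualities
  } else {
    df <- do.call(rbind, lapply(qualities, function(q) {
      data.frame(mean_ankle_confidence = q$mean_ankle_confidence,
                 clipped_fraction = q$clipped_fraction %||% NA_real_,
                 clipped = q$clipped)
    }))
  }
  df$included <- !is.na(df$mean_ankle_confidence) &
    df$mean_ankle_confidence >= threshold & !df$clipped
  rownames(df) <- NULL
  df
}
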