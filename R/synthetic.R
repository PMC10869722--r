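# Synthetic gait generator: paired sensor-side and video-side recordings
# with known ground truth, emulating a prosthesis user walking a timed
# 10-m segment recorded at 30 fps while wearing a shank IMU at 562.5 Hz.

#' Configuration for the synthetic gait generator
#'
#' Bundles every knob of the synthetic walking scenario. Defaults describe
#' a typical self-paced indoor walk: cadence 100 steps/min, 1.0 m/s,
#' stance fraction 0.62, a 10-m timed segment, IMU at 562.5 Hz and video
#' at 30 fps. The recording duration, when not given, is sized so the
#' timed segment fits with a stride or two of margin on either side.
#'
#' @param cadence_spm Mean cadence in steps per minute (> 0).
#' @param stride_cv Coefficient of variation of per-leg stride time
#'   (unitless, >= 0). Jitter is drawn from a normal truncated at
#'   +/- 3 SD so durations stay positive and contacts stay interleaved.
#' @param velocity_ms Mean walking velocity in m/s (> 0).
#' @param stance_fraction Fraction of the stride spent in stance,
#'   in (0, 1). 0.62 is typical adult gait.
#' @param duration_s Recording duration in seconds, or `NULL` to size it
#'   automatically around the timed segment.
#' @param sensor_rate_hz IMU sampling rate in Hz (default 562.5).
#' @param video_rate_hz Video frame rate in Hz (default 30).
#' @param clock_offset_s Sensor clock minus video clock, in seconds:
#'   the amount added to world/video time to get sensor timestamps.
#' @param gyro_noise_sd SD of additive Gaussian gyroscope noise, deg/s.
#' @param glitch_prob Probability that a swing contains a toe-catch
#'   glitch (brief angular-velocity reversal mid-swing).
#' @param glitch_duration_s Nominal glitch duration in seconds; must be
#'   below the 0.36 s median-filter span so deglitching is exercised
#'   rather than defeated. The reversal is a smooth cosine dip whose
#'   sign-negative core spans the central half of this duration.
#' @param edge_scenario If `TRUE`, a fraction of frames place one leg
#'   keypoint within 10 px of the image border (simulating a subject
#'   walking out of frame).
#' @param edge_fraction Expected fraction of near-edge frames when
#'   `edge_scenario` is on.
#' @param ankle_confidence Target mean keypoint confidence in \[0, 1\].
#' @param confidence_jitter_sd SD of per-frame confidence jitter.
#' @param prosthetic_side `"right"` or `"left"`.
#' @param swing_peak_dps Peak shank angular velocity during swing, deg/s.
#' @param stance_level_dps Constant (negative) angular velocity during
#'   stance, deg/s; keeps gyro sign crossings unambiguous.
#' @param velocity_modulation Amplitude (m/s) of an optional zero-mean
#'   within-stride modulation of the pelvis-velocity channel; 0 keeps
#'   the velocity ground truth exact.
#' @param segment_distance_m Length of the timed walking segment (m).
#' @param view Segment view label: `"frontal"`, `"sagittal"` or `"mixed"`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_events()], [synthesize_gyro()],
#'   [synthesize_phase_series()], [synthesize_keypoints()]
#' @export
#' @examples
#' cfg <- synthetic_config(cadence_spm = 120, stride_cv = 0, seed = 1)
#' truth <- generate_events(cfg)
#' diff(truth$contacts$left)[1]  # exactly one 1.0 s stride
synthetic_config <- function(cadence_spm = 100,
                             stride_cv = 0.05,
                             velocity_ms = 1.0,
                             stance_fraction = 0.62,
                             duration_s = NULL,
                             sensor_rate_hz = 562.5,
                             video_rate_hz = 30,
                             clock_offset_s = 0,
                             gyro_noise_sd = 0,
                             glitch_prob = 0,
                             glitch_duration_s = 0.2,
                             edge_scenario = FALSE,
                             edge_fraction = 0.05,
                             ankle_confidence = 0.85,
                             confidence_jitter_sd = 0.02,
                             prosthetic_side = c("right", "left"),
                             swing_peak_dps = 300,
                             stance_level_dps = -20,
                             velocity_modulation = 0,
                             segment_distance_m = 10,
                             view = c("frontal", "sagittal", "mixed"),
                             seed = 1L) {
  prosthetic_side <- match.arg(prosthetic_side)
  view <- match.arg(view)
  stopifnot(
    cadence_spm > 0, stride_cv >= 0, velocity_ms > 0,
    stance_fraction > 0, stance_fraction < 1,
    sensor_rate_hz > 0, video_rate_hz > 0,
    gyro_noise_sd >= 0, glitch_prob >= 0, glitch_prob <= 1,
    glitch_duration_s > 0,
    edge_fraction >= 0, edge_fraction <= 1,
    ankle_confidence >= 0, ankle_confidence <= 1,
    confidence_jitter_sd >= 0,
    swing_peak_dps > 0, stance_level_dps < 0,
    segment_distance_m > 0
  )
  if (glitch_duration_s >= 0.36) {
    stop("glitch_duration_s must be < 0.36 s (the median-filter span), ",
         "otherwise deglitching is defeated by construction", call. = FALSE)
  }
  if (is.null(duration_s)) {
    # lead-in 2 s, segment, then tail margin for the trailing strides
    duration_s <- 2 + segment_distance_m / velocity_ms + 2.5
  }
  stopifnot(duration_s > 0)
  cfg <- list(
    cadence_spm = cadence_spm, stride_cv = stride_cv,
    velocity_ms = velocity_ms, stance_fraction = stance_fraction,
    duration_s = duration_s, sensor_rate_hz = sensor_rate_hz,
    video_rate_hz = video_rate_hz, clock_offset_s = clock_offset_s,
    gyro_noise_sd = gyro_noise_sd, glitch_prob = glitch_prob,
    glitch_duration_s = glitch_duration_s,
    edge_scenario = isTRUE(edge_scenario), edge_fraction = edge_fraction,
    ankle_confidence = ankle_confidence,
    confidence_jitter_sd = confidence_jitter_sd,
    prosthetic_side = prosthetic_side,
    swing_peak_dps = swing_peak_dps, stance_level_dps = stance_level_dps,
    velocity_modulation = velocity_modulation,
    segment_distance_m = segment_distance_m, view = view,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate ground-truth gait events for a synthetic walk
#'
#' Lays down alternating left/right foot contacts with per-step jitter,
#' derives toe-offs from the stance fraction, and annotates the timed
#' 10-m segment boundaries. Jitter is applied at the step (half-stride)
#' level with SD `stride_cv * stride / sqrt(2)` so per-leg stride times
#' have the configured mean and CV while contacts always alternate.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `gait_truth`: lists of per-leg foot-contact
#'   and toe-off times (s, world clock), per-leg stride durations, the
#'   configured cadence and velocity, segment boundaries `t_s`/`t_e`, the
#'   recording duration and prosthetic side.
#' @export
generate_events <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  stride_mean <- 120 / config$cadence_spm
  step_mean <- stride_mean / 2
  t0 <- 0.5  # first foot contact
  if (config$duration_s < t0 + stride_mean) {
    stop("recording duration (", config$duration_s,
         " s) too short to contain one full stride", call. = FALSE)
  }
  n_steps <- ceiling((config$duration_s - t0) / step_mean) + 4L
  steps <- withr::with_seed(
    config$seed,
    rtrunc_norm3(n_steps, step_mean, config$stride_cv * stride_mean / sqrt(2))
  )
  contacts <- t0 + cumsum(c(0, steps))
  leg <- rep(c("left", "right"), length.out = length(contacts))
  keep <- contacts <= config$duration_s
  contacts <- contacts[keep]
  leg <- leg[keep]

  truth <- list(contacts = list(), toe_offs = list(), strides = list())
  for (side in c("left", "right")) {
    co <- contacts[leg == side]
    if (length(co) < 2L) {
      stop("recording too short: fewer than two ", side,
           "-foot contacts generated", call. = FALSE)
    }
    st <- diff(co)
    truth$contacts[[side]] <- co
    truth$strides[[side]] <- st
    truth$toe_offs[[side]] <- co[-length(co)] + config$stance_fraction * st
  }

  t_s <- t0 + 1.5
  t_e <- t_s + config$segment_distance_m / config$velocity_ms
  if (t_e + 1 > config$duration_s) {
    stop("recording duration too short for the timed ",
         config$segment_distance_m, "-m segment at ",
         config$velocity_ms, " m/s", call. = FALSE)
  }
  truth$cadence_spm <- config$cadence_spm
  truth$velocity_ms <- config$velocity_ms
  truth$t_s <- t_s
  truth$t_e <- t_e
  truth$segment_distance_m <- config$segment_distance_m
  truth$view <- config$view
  truth$duration_s <- config$duration_s
  truth$prosthetic_side <- config$prosthetic_side
  class(truth) <- "gait_truth"
  truth
}

#' Ground-truth swing intervals of one leg
#'
#' Pairs each toe-off with the next foot contact of the same leg.
#'
#' @param truth A `gait_truth` object.
#' @param side `"left"` or `"right"`.
#' @return Data frame with columns `start_s` (toe-off) and `end_s`
#'   (following foot contact).
#' @export
truth_swings <- function(truth, side = truth$prosthetic_side) {
  co <- truth$contacts[[side]]
  to <- truth$toe_offs[[side]]
  n <- min(length(to), length(co) - 1L)
  data.frame(start_s = to[seq_len(n)], end_s = co[seq_len(n) + 1L])
}

# Noiseless shank angular-velocity template: half-sine lobe of height
# `peak` during each swing, constant `stance_level` otherwise.
gyro_template <- function(t, swings, peak, stance_level) {
  z <- rep(stance_level, length(t))
  if (nrow(swings) == 0L) return(z)
  idx <- findInterval(t, swings$start_s)
  ins <- idx >= 1L
  ins[ins] <- t[ins] < swings$end_s[idx[ins]]
  k <- idx[ins]
  frac <- (t[ins] - swings$start_s[k]) / (swings$end_s[k] - swings$start_s[k])
  z[ins] <- peak * sin(pi * frac)
  z
}

#' Synthesize the shank gyroscope trace
#'
#' The z channel is a smooth positive half-sine lobe during each
#' prosthetic-side swing and a small negative constant during stance, so
#' the positive-to-negative crossing of the noiseless template coincides
#' with the end of swing. Optional toe-catch glitches multiply the
#' template by `cos(2*pi*frac)` over the glitch interval, producing a
#' brief mid-swing sign reversal. Samples are timestamped in the sensor
#' timebase (world time + configured clock offset) and carry additive
#' Gaussian noise.
#'
#' @param truth A `gait_truth` from [generate_events()].
#' @param config The matching [synthetic_config()].
#' @return A `gyro_trace`: data frame with columns `time_s`, `gyro_x`,
#'   `gyro_y`, `gyro_z` (deg/s) and a `nominal_rate_hz` attribute. The x
#'   and y channels carry noise only; downstream analysis consumes z.
#' @export
synthesize_gyro <- function(truth, config) {
  stopifnot(inherits(truth, "gait_truth"), inherits(config, "synthetic_config"))
  t <- seq(0, truth$duration_s, by = 1 / config$sensor_rate_hz)
  sw <- truth_swings(truth, truth$prosthetic_side)
  z <- gyro_template(t, sw, config$swing_peak_dps, config$stance_level_dps)
  n <- length(t)
  out <- withr::with_seed(config$seed + 101L, {
    if (config$glitch_prob > 0 && nrow(sw) > 0L) {
      hit <- stats::runif(nrow(sw)) < config$glitch_prob
      L <- config$glitch_duration_s
      for (k in which(hit)) {
        dur <- sw$end_s[k] - sw$start_s[k]
        if (L >= 0.9 * dur) next  # glitch would swallow the swing
        lo <- sw$start_s[k] + 0.05 * dur
        hi <- sw$end_s[k] - 0.05 * dur - L
        g0 <- if (hi > lo) stats::runif(1, lo, hi) else sw$start_s[k] + (dur - L) / 2
        gi <- which(t >= g0 & t < g0 + L)
        z[gi] <- z[gi] * cos(2 * pi * (t[gi] - g0) / L)
      }
    }
    data.frame(
      time_s = t + config$clock_offset_s,
      gyro_x = stats::rnorm(n, 0, config$gyro_noise_sd),
      gyro_y = stats::rnorm(n, 0, config$gyro_noise_sd),
      gyro_z = z + stats::rnorm(n, 0, config$gyro_noise_sd)
    )
  })
  attr(out, "nominal_rate_hz") <- config$sensor_rate_hz
  class(out) <- c("gyro_trace", "data.frame")
  out
}

# Phase of a cyclic event train: advances linearly from 0 to 2*pi between
# consecutive occurrences; extrapolated with the first/last interval
# outside the observed events.
event_phase <- function(t, events) {
  if (length(events) < 2L) {
    stop("need at least two occurrences of an event to define its phase",
         call. = FALSE)
  }
  d <- diff(events)
  idx <- pmin(pmax(findInterval(t, events), 1L), length(events) - 1L)
  2 * pi * (t - events[idx]) / d[idx]
}

# Instantaneous stride rate (rad/s) implied by an event train.
event_rate <- function(t, events) {
  d <- diff(events)
  idx <- pmin(pmax(findInterval(t, events), 1L), length(events) - 1L)
  2 * pi / d[idx]
}

#' Synthesize per-frame video-model outputs
#'
#' Emits, at the video frame rate, the quadrature (sin, cos) encoding of
#' each of the four gait events (left/right foot contact and toe-off), the
#' gait-cycle phase rate, the pelvis velocity, and hip/knee sagittal
#' angles. Each event phase advances 0 to 2*pi between consecutive
#' occurrences of that event, so foot contacts sit at the positively
#' directed zero crossings of the sin channel. The hip and knee angles are
#' constructed so the derivative of their sum reproduces the shank
#' angular-velocity waveform, which is what makes the clock-offset
#' objective identifiable.
#'
#' @inheritParams synthesize_gyro
#' @return A `gait_phase_series`: data frame with columns `frame`
#'   (0-based), `time_s`, `lfc_sin`/`lfc_cos`, `rfc_sin`/`rfc_cos`,
#'   `lto_sin`/`lto_cos`, `rto_sin`/`rto_cos`, `phase_rate` (rad/s),
#'   `pelvis_vel` (m/s), `hip_ang` and `knee_ang` (deg).
#' @export
synthesize_phase_series <- function(truth, config) {
  stopifnot(inherits(truth, "gait_truth"), inherits(config, "synthetic_config"))
  t <- seq(0, truth$duration_s, by = 1 / config$video_rate_hz)
  ev <- list(
    lfc = truth$contacts$left, rfc = truth$contacts$right,
    lto = truth$toe_offs$left, rto = truth$toe_offs$right
  )
  out <- data.frame(frame = seq_along(t) - 1L, time_s = t)
  for (nm in names(ev)) {
    phi <- event_phase(t, ev[[nm]])
    out[[paste0(nm, "_sin")]] <- sin(phi)
    out[[paste0(nm, "_cos")]] <- cos(phi)
  }
  out$phase_rate <- (event_rate(t, truth$contacts$left) +
                       event_rate(t, truth$contacts$right)) / 2
  phi_p <- event_phase(t, truth$contacts[[truth$prosthetic_side]])
  out$pelvis_vel <- config$velocity_ms +
    config$velocity_modulation * sin(phi_p)
  # shank angle = integral of the angular-velocity template; split across
  # hip and knee and detrended so the channels stay bounded
  sw <- truth_swings(truth, truth$prosthetic_side)
  zt <- gyro_template(t, sw, config$swing_peak_dps, config$stance_level_dps)
  theta <- cumtrapz_int(t, zt)
  theta <- stats::residuals(stats::lm(theta ~ t))
  out$hip_ang <- 0.65 * theta
  out$knee_ang <- 0.35 * theta
  attr(out, "video_rate_hz") <- config$video_rate_hz
  class(out) <- c("gait_phase_series", "data.frame")
  out
}

#' Synthesize 2D leg-keypoint tracks with confidences
#'
#' Places the six leg keypoints (hips, knees, ankles; left/right) of a
#' walking figure in a 1080 x 1920 portrait frame, oscillating with the
#' gait phase, with per-joint confidence at the configured level plus
#' clamped jitter. With `edge_scenario` on, a random subset of frames
#' (expected fraction `edge_fraction`) moves the left ankle to within
#' 10 px of the image border.
#'
#' @inheritParams synthesize_gyro
#' @return A `keypoint_track`: long data frame with columns `frame`,
#'   `time_s`, `joint` (`hip_left`, ..., `ankle_right`), `x_px`, `y_px`,
#'   `confidence`; attributes `width_px` (1080), `height_px` (1920) and
#'   `prosthetic_side`.
#' @export
synthesize_keypoints <- function(truth, config) {
  stopifnot(inherits(truth, "gait_truth"), inherits(config, "synthetic_config"))
  t <- seq(0, truth$duration_s, by = 1 / config$video_rate_hz)
  n <- length(t)
  width <- 1080; height <- 1920
  phi <- list(
    left = event_phase(t, truth$contacts$left),
    right = event_phase(t, truth$contacts$right)
  )
  cx <- width / 2
  joints <- c("hip", "knee", "ankle")
  base_y <- c(hip = 950, knee = 1250, ankle = 1550)
  amp_x <- c(hip = 15, knee = 35, ankle = 70)
  rows <- list()
  kp <- withr::with_seed(config$seed + 202L, {
    for (side in c("left", "right")) {
      sgn <- if (side == "left") -1 else 1
      for (j in joints) {
        x <- cx + sgn * 90 + amp_x[[j]] * sin(phi[[side]])
        y <- base_y[[j]] + 10 * sin(2 * phi[[side]])
        conf <- pmin(pmax(
          config$ankle_confidence +
            stats::rnorm(n, 0, config$confidence_jitter_sd), 0), 1)
        rows[[paste(j, side, sep = "_")]] <- data.frame(
          frame = seq_along(t) - 1L, time_s = t,
          joint = paste(j, side, sep = "_"),
          x_px = x, y_px = y, confidence = conf
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (config$edge_scenario && config$edge_fraction > 0) {
      near <- stats::runif(n) < config$edge_fraction
      if (any(near)) {
        sel <- out$joint == "ankle_left" & out$frame %in% (which(near) - 1L)
        out$x_px[sel] <- stats::runif(sum(sel), 0, 9.5)
      }
    }
    out
  })
  attr(kp, "width_px") <- width
  attr(kp, "height_px") <- height
  attr(kp, "prosthetic_side") <- config$prosthetic_side
  class(kp) <- c("keypoint_track", "data.frame")
  kp
}

#' @export
print.gait_truth <- function(x, ...) {
  cat("Synthetic gait ground truth\n")
  cat(sprintf("  duration %.1f s, cadence %.1f steps/min, velocity %.2f m/s\n",
              x$duration_s, x$cadence_spm, x$velocity_ms))
  cat(sprintf("  contacts: %d left, %d right; prosthetic side: %s\n",
              length(x$contacts$left), length(x$contacts$right),
              x$prosthetic_side))
  cat(sprintf("  timed segment [%.2f, %.2f] s over %g m (%s view)\n",
              x$t_s, x$t_e, x$segment_distance_m, x$view))
  invisible(x)
}
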