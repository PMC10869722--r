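# Sensor-side processing: sensor-timebase calibration and detection of
# prosthetic-limb swing phases from the shank gyroscope z channel.

#' Calibrate the sensor timebase against host (phone) time
#'
#' Wearable packets arrive with a host timestamp and a cumulative sample
#' index; an ordinary least-squares line through (index, host time) gives
#' the effective sampling rate, which on real hardware typically differs
#' from the nominal value by 1-2 Hz.
#'
#' @param packet_host_times Host arrival times, seconds.
#' @param packet_sample_indices Cumulative sample index of each packet.
#' @return A `timebase_fit`: list with `rate_hz` (effective rate,
#'   1/slope), `intercept_s`, `residual_sd_s` and `n`.
#' @export
#' @examples
#' calibrate_timebase(c(0, 10), c(0, 5625))$rate_hz  # 562.5
calibrate_timebase <- function(packet_host_times, packet_sample_indices) {
  stopifnot(length(packet_host_times) == length(packet_sample_indices))
  if (length(packet_host_times) < 2L) {
    stop("need at least 2 packets to calibrate the timebase", call. = FALSE)
  }
  if (stats::var(packet_sample_indices) == 0) {
    stop("sample indices have zero variance; cannot fit a rate",
         call. = FALSE)
  }
  fit <- stats::lm(packet_host_times ~ packet_sample_indices)
  slope <- unname(stats::coef(fit)[2])  # seconds per sample
  if (slope <= 0) stop("non-positive fitted slope", call. = FALSE)
  out <- list(
    rate_hz = 1 / slope,
    intercept_s = unname(stats::coef(fit)[1]),
    residual_sd_s = if (length(packet_host_times) > 2L)
      summary(fit)$sigma else 0,
    n = length(packet_host_times)
  )
  class(out) <- "timebase_fit"
  out
}

# Design the swing-detection low-pass once per call.
swing_filter <- function(order, ripple_db, cutoff_hz, rate_hz) {
  signal::cheby1(order, ripple_db, cutoff_hz / (rate_hz / 2))
}

#' Detect swing phases from the shank gyroscope
#'
#' Pipeline: (1) low-pass the z channel with an 8th-order Chebyshev
#' type-I filter (0.5 dB ripple, 35 Hz passband edge) applied
#' forward-backward so event times are not shifted by group delay;
#' (2) rectify by zeroing negative values; (3) deglitch with a running
#' median spanning 360 ms (brief toe-catch reversals vanish, because
#' their rectified zero-run is shorter than half the window); (4) take
#' maximal runs of strictly positive samples as swings. The swing start
#' is the first positive sample of a run and the swing end the first
#' non-positive sample after it; the end of swing is the foot-contact
#' proxy used downstream. Runs touching the trace boundary are dropped
#' as incomplete.
#'
#' @param trace A `gyro_trace` (columns `time_s`, `gyro_z`).
#' @param filter_order Chebyshev filter order (default 8).
#' @param cutoff_hz Passband edge, Hz (default 35).
#' @param ripple_db Passband ripple, dB (default 0.5).
#' @param median_span_s Running-median span, seconds (default 0.36).
#' @param return_signal If `TRUE`, attach the deglitched signal as the
#'   `deglitched` attribute (for diagnostics).
#' @param prefiltered If `TRUE`, skip the Chebyshev low-pass (for input
#'   that is already band-limited, e.g. the detector's own deglitched
#'   output).
#' @return A `swing_events` data frame with columns `start_s`, `end_s`;
#'   end-of-swing times are `end_s`.
#' @export
detect_swings <- function(trace, filter_order = 8L, cutoff_hz = 35,
                          ripple_db = 0.5, median_span_s = 0.36,
                          return_signal = FALSE, prefiltered = FALSE) {
  t <- trace$time_s
  z <- trace$gyro_z
  n <- length(t)
  if (n < 2L || (t[n] - t[1]) <= median_span_s) {
    stop("trace shorter than the median-filter span (",
         median_span_s, " s)", call. = FALSE)
  }
  dt <- stats::median(diff(t))
  rate <- 1 / dt
  nominal <- attr(trace, "nominal_rate_hz")
  if (!is.null(nominal) && abs(rate - nominal) > 0.2 * nominal) {
    stop(sprintf("observed rate %.1f Hz deviates >20%% from nominal %.1f Hz",
                 rate, nominal), call. = FALSE)
  }
  zf <- if (prefiltered) {
    z
  } else {
    signal::filtfilt(swing_filter(filter_order, ripple_db, cutoff_hz, rate), z)
  }
  zr <- pmax(zf, 0)
  k <- round(median_span_s * rate)
  if (k %% 2L == 0L) k <- k + 1L
  zd <- stats::runmed(zr, k)

  pos <- zd > 0
  r <- rle(pos)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  runs <- which(r$values)
  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (length(runs) > 0L) {
    s_i <- starts_idx[runs]
    e_i <- ends_idx[runs]
    complete <- s_i > 1L & e_i < n
    # end of swing = first non-positive sample after the run
    out <- data.frame(start_s = t[s_i[complete]],
                      end_s = t[e_i[complete] + 1L])
  }
  class(out) <- c("swing_events", "data.frame")
  if (return_signal) {
    attr(out, "deglitched") <- zd
    attr(out, "time_s") <- t
  }
  out
}

#' Restrict swing events to a timed segment
#'
#' Keeps swings whose end-of-swing time falls inside the closed interval
#' `[t_s, t_e]` and records the indices of the first and last retained
#' swing in the original list (the `i` and `j` of the sensor-cadence
#' formula).
#'
#' @param events A `swing_events` data frame.
#' @param segment A [timed_segment()].
#' @return The retained `swing_events`, with attributes `idx_first` and
#'   `idx_last` (or `NA` when nothing is retained).
#' @export
swings_in_segment <- function(events, segment) {
  stopifnot(inherits(segment, "timed_segment"))
  keep <- which(events$end_s >= segment$t_start_s &
                  events$end_s <= segment$t_end_s)
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("swing_events", "data.frame")
  attr(out, "idx_first") <- if (length(keep)) keep[1] else NA_integer_
  attr(out, "idx_last") <- if (length(keep)) keep[length(keep)] else NA_integer_
  out
}

#' @export
print.timebase_fit <- function(x, ...) {
  cat(sprintf(
    "Sensor timebase fit: %.3f Hz effective rate, intercept %.4f s, residual SD %.2g s (n = %d packets)\n",
    x$rate_hz, x$intercept_s, x$residual_sd_s, x$n))
  invisible(x)
}
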