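# Clock synchronization, sensor cadence, event matching and agreement
# metrics between the video and sensor pipelines.

#' Estimate the video-to-sensor clock offset
#'
#' The video stream starts with some latency relative to the sensor
#' timestamps. Because the shank angular velocity is (up to scale) the
#' derivative of the summed hip + knee sagittal angle, the offset is
#' recovered by minimizing the mean squared error between the
#' standardized low-passed gyroscope z channel and the standardized
#' derivative of `hip_ang + knee_ang`, over a dense grid of candidate
#' offsets. The returned offset is the amount to add to video times to
#' land in the sensor timebase.
#'
#' The objective is evaluated on sensor samples decimated to roughly
#' 125 Hz; this is alias-free after the 35 Hz low-pass, and offset
#' resolution comes from the interpolation and the 1 ms grid, not the
#' evaluation sample spacing.
#'
#' @param gyro A `gyro_trace`.
#' @param series A `gait_phase_series` with `hip_ang`/`knee_ang`.
#' @param search_range_s Half-width of the offset grid, seconds
#'   (default 0.5).
#' @param step_s Grid step, seconds (default 0.001).
#' @param cutoff_hz,filter_order,ripple_db Low-pass applied to the gyro
#'   before matching (same design as [detect_swings()]).
#' @return An `offset_estimate`: list with `offset_s`, `objective`
#'   (MSE at the optimum), `search_range_s`, `step_s`.
#' @export
estimate_clock_offset <- function(gyro, series, search_range_s = 0.5,
                                  step_s = 0.001, cutoff_hz = 35,
                                  filter_order = 8L, ripple_db = 0.5) {
  tg <- gyro$time_s
  tv <- series$time_s
  if (diff(range(tg)) < 3 || diff(range(tv)) < 3) {
    stop("need at least 3 s of sensor and video signal to estimate the clock offset",
         call. = FALSE)
  }
  ang <- series$hip_ang + series$knee_ang
  if (stats::sd(ang) == 0) {
    stop("hip + knee angle channel is flat; offset is unidentifiable",
         call. = FALSE)
  }
  dtv <- stats::median(diff(tv))
  # central-difference derivative of the summed angle, deg/s
  n <- length(ang)
  dang <- c(ang[2] - ang[1],
            (ang[3:n] - ang[1:(n - 2)]) / 2,
            ang[n] - ang[n - 1]) / dtv
  za <- zscore(dang, "angle derivative")

  rate <- 1 / stats::median(diff(tg))
  ch <- swing_filter(filter_order, ripple_db, cutoff_hz, rate)
  gz <- signal::filtfilt(ch, gyro$gyro_z)
  if (stats::sd(gz) == 0) {
    stop("gyroscope z channel is flat; offset is unidentifiable",
         call. = FALSE)
  }
  zg <- zscore(gz, "gyroscope")
  dec <- max(1L, floor(rate / 125))
  idx <- seq(1L, length(tg), by = dec)
  tgd <- tg[idx]
  zgd <- zg[idx]

  grid <- seq(-search_range_s, search_range_s, by = step_s)
  obj <- vapply(grid, function(d) {
    av <- stats::approx(tv + d, za, xout = tgd, rule = 1)$y
    ok <- !is.na(av)
    if (sum(ok) < 100L) return(Inf)
    mean((zgd[ok] - av[ok])^2)
  }, numeric(1))
  best <- which.min(obj)
  out <- list(offset_s = grid[best], objective = obj[best],
              search_range_s = search_range_s, step_s = step_s)
  class(out) <- "offset_estimate"
  out
}

#' Cadence from sensor end-of-swing times
#'
#' Average prosthetic-limb stride time over the timed segment:
#' `c_s = 120 * (j - i) / (s_j - s_i)` where `s_i`, `s_j` are the first
#' and last end-of-swing times inside the segment and `j - i` the
#' number of strides between them.
#'
#' @param swings A `swing_events` data frame (sensor timebase).
#' @param segment A [timed_segment()] in the same timebase.
#' @return Cadence in steps/min, or `NA_real_` (with a warning and a
#'   `"reason"` attribute) when fewer than two in-segment swings exist.
#' @export
#' @examples
#' sw <- data.frame(start_s = c(0.6, 1.6, 2.6), end_s = c(1, 2, 3))
#' class(sw) <- c("swing_events", "data.frame")
#' compute_sensor_cadence(sw, timed_segment(0.5, 3.5))  # 120
compute_sensor_cadence <- function(swings, segment) {
  inseg <- swings_in_segment(swings, segment)
  ends <- inseg$end_s
  if (length(ends) < 2L) {
    warning("fewer than 2 end-of-swing times inside the segment; ",
            "sensor cadence undefined", call. = FALSE)
    out <- NA_real_
    attr(out, "reason") <- sprintf(
      "%d end-of-swing time(s) in [%.2f, %.2f] s",
      length(ends), segment$t_start_s, segment$t_end_s)
    return(out)
  }
  120 * (length(ends) - 1L) / (ends[length(ends)] - ends[1])
}

# Signed difference to the nearest value of a sorted vector.
nearest_diff <- function(x, v) {
  i <- findInterval(x, v)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(v))
  d_lo <- x - v[lo]
  d_hi <- x - v[hi]
  ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi)
}

#' Match sensor end-of-swing times to video foot contacts
#'
#' First fits the per-segment alignment offset as the minimizer, over a
#' 1 ms grid spanning +/- 0.4 s around the median nearest-neighbour
#' difference, of the mean absolute nearest-neighbour residual (the
#' data-driven centre makes the fit equivariant under arbitrary time
#' shifts). Then pairs events greedily, one-to-one, in order of
#' ascending absolute residual, accepting pairs within the detection
#' window. Unmatched sensor events are missed.
#'
#' @param sensor_events Sorted end-of-swing times, seconds (sensor
#'   timebase).
#' @param video_events Sorted foot-contact times, seconds.
#' @param window_s Detection window, seconds (default 0.5).
#' @param search_s Half-width of the offset grid (default 0.4).
#' @param step_s Offset grid step (default 0.001).
#' @return A `match_result`: `offset_s`, `pairs` (data frame
#'   `sensor_s`, `video_s`, `residual_s` with residual = video + offset
#'   - sensor), `n_matched`, `n_missed`, `detected_fraction`, `mae_s`.
#' @export
match_events <- function(sensor_events, video_events, window_s = 0.5,
                         search_s = 0.4, step_s = 0.001) {
  if (length(sensor_events) == 0L) {
    stop("no sensor events; nothing to validate against", call. = FALSE)
  }
  s <- sort(sensor_events)
  v <- sort(video_events)
  empty_pairs <- data.frame(sensor_s = numeric(0), video_s = numeric(0),
                            residual_s = numeric(0))
  if (length(v) == 0L) {
    out <- list(offset_s = NA_real_, pairs = empty_pairs,
                n_matched = 0L, n_missed = length(s),
                detected_fraction = 0, mae_s = NA_real_,
                window_s = window_s)
    class(out) <- "match_result"
    return(out)
  }
  # coarse centring: every pairwise difference s_i - v_j is a candidate
  # alignment; the best one centres the fine grid. This keeps the fit
  # equivariant under arbitrary global time shifts.
  cand_off <- unique(as.vector(outer(s, v, `-`)))
  cand_obj <- vapply(cand_off, function(d) mean(abs(nearest_diff(s - d, v))),
                     numeric(1))
  centre <- cand_off[which.min(cand_obj)]
  grid <- centre + seq(-search_s, search_s, by = step_s)
  obj <- vapply(grid, function(d) mean(abs(nearest_diff(s - d, v))),
                numeric(1))
  offset <- grid[which.min(obj)]

  v2 <- v + offset
  # candidate pairs within the window: nearest and next-nearest video
  # neighbours of each sensor event
  i <- findInterval(s, v2)
  cand <- rbind(
    data.frame(si = seq_along(s), vi = pmax(i, 1L)),
    data.frame(si = seq_along(s), vi = pmin(i + 1L, length(v2)))
  )
  cand <- unique(cand)
  cand$residual <- v2[cand$vi] - s[cand$si]
  cand <- cand[abs(cand$residual) <= window_s, , drop = FALSE]
  cand <- cand[order(abs(cand$residual)), , drop = FALSE]
  used_s <- logical(length(s))
  used_v <- logical(length(v2))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    si <- cand$si[r]; vi <- cand$vi[r]
    if (!used_s[si] && !used_v[vi]) {
      used_s[si] <- TRUE
      used_v[vi] <- TRUE
      keep[r] <- TRUE
    }
  }
  m <- cand[keep, , drop = FALSE]
  m <- m[order(m$si), , drop = FALSE]
  pairs <- data.frame(sensor_s = s[m$si], video_s = v[m$vi],
                      residual_s = m$residual)
  rownames(pairs) <- NULL
  n_matched <- nrow(pairs)
  n_missed <- length(s) - n_matched
  out <- list(
    offset_s = offset, pairs = pairs,
    n_matched = n_matched, n_missed = n_missed,
    detected_fraction = n_matched / length(s),
    mae_s = if (n_matched) mean(abs(pairs$residual_s)) else NA_real_,
    window_s = window_s
  )
  class(out) <- "match_result"
  out
}

#' Correlation and mean absolute error between paired estimates
#'
#' The per-segment agreement summary: Pearson r and
#' `MAE = mean(|estimate - reference|)`.
#'
#' @param estimate,reference Paired numeric vectors (video estimate and
#'   reference value per segment).
#' @return An `agreement_summary`: list with `n`, `r` (NA when `n < 2`
#'   or either side has zero variance) and `mae`.
#' @export
#' @examples
#' summarize_agreement(c(1, 2, 3), c(1, 2, 3))  # r = 1, MAE = 0
summarize_agreement <- function(estimate, reference) {
  stopifnot(length(estimate) == length(reference))
  ok <- is.finite(estimate) & is.finite(reference)
  e <- estimate[ok]
  r <- reference[ok]
  n <- length(e)
  if (n < 1L) stop("no finite pairs to summarize", call. = FALSE)
  rr <- NA_real_
  if (n >= 2L) {
    if (stats::sd(r) == 0 || stats::sd(e) == 0) {
      warning("zero variance in paired values; correlation undefined",
              call. = FALSE)
    } else {
      rr <- stats::cor(e, r)
    }
  }
  out <- list(n = n, r = rr, mae = mean(abs(e - r)))
  class(out) <- "agreement_summary"
  out
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf("Clock offset: %+.3f s (MSE %.4f at optimum, grid +/- %.2f s @ %.0f ms)\n",
              x$offset_s, x$objective, x$search_range_s, 1000 * x$step_s))
  invisible(x)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Event matching: offset %+.3f s, %d matched / %d missed (fraction %.3f)\n",
              x$offset_s %||% NA_real_, x$n_matched, x$n_missed,
              x$detected_fraction))
  if (is.finite(x$mae_s %||% NA_real_)) {
    cat(sprintf("  residual MAE %.1f ms over matched pairs\n", 1000 * x$mae_s))
  }
  invisible(x)
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Agreement over n = %d segments: r = %s, MAE = %.4g\n",
              x$n, if (is.na(x$r)) "undefined" else sprintf("%.3f", x$r),
              x$mae))
  invisible(x)
}
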