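# Orchestration: configuration, scenario simulation, end-to-end
# validation and reporting, with all stage parameters in one place.

#' Pipeline run configuration
#'
#' One object holding every stage parameter so sensitivity analyses
#' (e.g. a 0.6 instead of 0.7 quality threshold) are one-argument
#' changes. Defaults are the reference analysis settings: 8th-order
#' Chebyshev at 35 Hz with 0.5 dB ripple, 360 ms median span, 0.7
#' ankle-quality threshold, 10 px clipping margin with a 1% frame
#' fraction, 0.5 s match window, 90-frame model window.
#'
#' @param filter_order,cutoff_hz,ripple_db Swing-detection low-pass.
#' @param median_span_s Deglitching median span, seconds.
#' @param quality_threshold Minimum mean prosthetic-ankle confidence.
#' @param clip_margin_px Border margin defining a clipped keypoint.
#' @param clip_fraction Clipped-frame fraction above which a segment is
#'   excluded.
#' @param match_window_s Detection window for event matching, seconds.
#' @param match_search_s Half-width of the match-offset grid, seconds.
#' @param offset_search_s Half-width of the clock-offset grid, seconds.
#' @param offset_step_s Offset grid step, seconds.
#' @param window_frames Sliding-window length in frames.
#' @param seed Base seed for scenario generation.
#' @param scenarios List of per-scenario parameter lists; each entry is
#'   a set of [synthetic_config()] overrides.
#' @return A `gait_run_config` list.
#' @export
run_config <- function(filter_order = 8L, cutoff_hz = 35, ripple_db = 0.5,
                       median_span_s = 0.36, quality_threshold = 0.7,
                       clip_margin_px = 10, clip_fraction = 0.01,
                       match_window_s = 0.5, match_search_s = 0.4,
                       offset_search_s = 0.5, offset_step_s = 0.001,
                       window_frames = 90L, seed = 1L,
                       scenarios = list(list())) {
  stopifnot(filter_order > 0, cutoff_hz > 0, median_span_s > 0,
            quality_threshold >= 0, quality_threshold <= 1,
            clip_margin_px >= 0, clip_fraction >= 0, clip_fraction <= 1,
            match_window_s > 0, offset_search_s > 0, offset_step_s > 0,
            window_frames >= 2, is.list(scenarios))
  cfg <- list(
    filter_order = as.integer(filter_order), cutoff_hz = cutoff_hz,
    ripple_db = ripple_db, median_span_s = median_span_s,
    quality_threshold = quality_threshold,
    clip_margin_px = clip_margin_px, clip_fraction = clip_fraction,
    match_window_s = match_window_s, match_search_s = match_search_s,
    offset_search_s = offset_search_s, offset_step_s = offset_step_s,
    window_frames = as.integer(window_frames), seed = as.integer(seed),
    scenarios = scenarios
  )
  class(cfg) <- "gait_run_config"
  cfg
}

#' Write/read a run configuration (JSON or YAML by file extension)
#' @param config A [run_config()].
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path` (write) or the reloaded `gait_run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "gait_run_config"))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sc <- x$scenarios
  if (is.data.frame(sc)) {
    sc <- lapply(seq_len(nrow(sc)), function(i) {
      row <- as.list(sc[i, , drop = FALSE])
      row[!vapply(row, function(v) is.null(v) || all(is.na(v)), TRUE)]
    })
  } else if (is.null(sc) || length(sc) == 0L) {
    sc <- list(list())
  }
  x$scenarios <- sc
  do.call(run_config, x)
}

#' Simulate scenarios to disk
#'
#' Generates one subdirectory (`scenario_001`, ...) per entry of
#' `config$scenarios`, each holding the sensor, phase-series and
#' keypoint CSVs plus segment/truth/config JSON, and writes a top-level
#' `manifest.json` recording seeds and parameters. Scenario `k` uses
#' seed `config$seed + k` unless the scenario overrides it.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress the per-run message.
#' @return Character vector of scenario directories, invisibly.
#' @export
run_simulate <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "gait_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  dirs <- character(0)
  manifest <- list(seed = config$seed, scenarios = list())
  for (k in seq_along(config$scenarios)) {
    over <- config$scenarios[[k]]
    if (is.null(over$seed)) over$seed <- config$seed + k
    sc <- do.call(synthetic_config, over)
    truth <- generate_events(sc)
    gyro <- synthesize_gyro(truth, sc)
    phase <- synthesize_phase_series(truth, sc)
    kp <- synthesize_keypoints(truth, sc)
    d <- file.path(out_dir, sprintf("scenario_%03d", k))
    write_scenario(d, truth, gyro, phase, kp, sc)
    dirs <- c(dirs, d)
    manifest$scenarios[[k]] <- list(dir = basename(d), seed = sc$seed,
                                    params = over)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!quiet) {
    message("simulated ", length(dirs), " scenario(s) under ", out_dir)
  }
  invisible(dirs)
}

# Validate one scenario directory; returns a one-row metrics data frame.
validate_scenario <- function(dir, config, quiet = TRUE) {
  for (f in c("sensor.csv", "phase.csv", "keypoints.csv", "segment.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop("scenario ", dir, " is missing ", f, call. = FALSE)
    }
  }
  sc_cfg <- NULL
  if (file.exists(file.path(dir, "config.json"))) {
    sc_cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  }
  side <- sc_cfg$prosthetic_side %||% "right"
  gyro <- read_gyro_csv(file.path(dir, "sensor.csv"),
                        nominal_rate_hz = sc_cfg$sensor_rate_hz %||% 562.5)
  phase <- read_phase_csv(file.path(dir, "phase.csv"))
  kp <- read_keypoints_csv(file.path(dir, "keypoints.csv"),
                           prosthetic_side = side)
  seg <- read_segment_json(file.path(dir, "segment.json"))

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", label, "] failed for ", dir, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  swings <- stage("sensor_events", detect_swings(
    gyro, filter_order = config$filter_order, cutoff_hz = config$cutoff_hz,
    ripple_db = config$ripple_db, median_span_s = config$median_span_s))
  clock <- stage("sync_clock", estimate_clock_offset(
    gyro, phase, search_range_s = config$offset_search_s,
    step_s = config$offset_step_s, cutoff_hz = config$cutoff_hz,
    filter_order = config$filter_order, ripple_db = config$ripple_db))
  contacts <- stage("video_gait", decode_foot_contacts(phase, side))
  quality <- stage("video_quality", flag_clipping(
    kp, seg, margin_px = config$clip_margin_px,
    clip_fraction = config$clip_fraction, prosthetic_side = side))

  c_v <- stage("video_cadence", compute_video_cadence(phase, seg))
  v_video <- stage("video_velocity", compute_segment_velocity(phase, seg))
  seg_sensor <- shift_segment(seg, clock$offset_s)
  c_s <- suppressWarnings(compute_sensor_cadence(swings, seg_sensor))

  sens_in <- swings_in_segment(swings, seg_sensor)$end_s
  vid_shift <- contacts + clock$offset_s
  vid_in <- vid_shift[vid_shift >= seg_sensor$t_start_s &
                        vid_shift <= seg_sensor$t_end_s]
  if (length(sens_in) > 0L) {
    m <- stage("sync_match", match_events(
      sens_in, vid_in, window_s = config$match_window_s,
      search_s = config$match_search_s))
    n_matched <- m$n_matched; n_missed <- m$n_missed
    det_frac <- m$detected_fraction
    resid_mae <- m$mae_s; match_off <- m$offset_s
  } else {
    n_matched <- 0L; n_missed <- 0L
    det_frac <- NA_real_; resid_mae <- NA_real_; match_off <- NA_real_
  }

  row <- data.frame(
    segment_id = basename(dir), view = seg$view,
    v_video = v_video, v_truth = seg$velocity_truth_ms,
    c_v = c_v, c_s = as.numeric(c_s),
    n_matched = n_matched, n_missed = n_missed,
    detected_fraction = det_frac,
    residual_mae_s = resid_mae,
    clock_offset_s = clock$offset_s, match_offset_s = match_off,
    mean_ankle_confidence = quality$mean_ankle_confidence,
    clipped_fraction = quality$clipped_fraction,
    clipped = quality$clipped,
    stringsAsFactors = FALSE
  )
  # window-local ground-truth references, when the generator truth is
  # on disk (validation-against-truth mode)
  row$c_truth <- NA_real_
  row$clock_offset_truth_s <- NA_real_
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    truth <- read_truth_json(tf)
    co <- truth$contacts[[side]]
    co <- co[co >= seg$t_start_s & co <= seg$t_end_s]
    if (length(co) >= 2L) {
      row$c_truth <- 120 * (length(co) - 1L) / (co[length(co)] - co[1])
    }
    row$clock_offset_truth_s <- sc_cfg$clock_offset_s %||% NA_real_
  }
  if (!quiet) {
    message(sprintf(
      "%s: %d swings, %d contacts, %d matched / %d missed, clock offset %+.0f ms",
      basename(dir), nrow(swings), length(contacts), n_matched, n_missed,
      1000 * clock$offset_s))
  }
  row
}

#' Validate simulated (or imported) scenarios end-to-end
#'
#' Runs sensor swing detection, clock synchronization, video decoding,
#' cadence/velocity estimation, event matching and the quality filters
#' on every `scenario_*` subdirectory of `dir` (or on `dir` itself when
#' it holds the scenario files directly), then writes `metrics.csv`
#' (one row per segment) and `summary.json` (agreement r/MAE/n for
#' velocity and cadence over included segments, plus event totals).
#'
#' @param dir Directory produced by [run_simulate()].
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log messages.
#' @return The per-segment metrics data frame, invisibly.
#' @export
run_validate <- function(dir, config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "gait_run_config"))
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "sensor.csv"))]
  if (length(subs) == 0L && file.exists(file.path(dir, "sensor.csv"))) {
    subs <- dir
  }
  if (length(subs) == 0L) {
    stop("no scenario directories with sensor.csv under ", dir,
         call. = FALSE)
  }
  rows <- lapply(subs, validate_scenario, config = config, quiet = quiet)
  metrics <- do.call(rbind, rows)
  qual <- filter_by_ankle_quality(
    data.frame(mean_ankle_confidence = metrics$mean_ankle_confidence,
               clipped_fraction = metrics$clipped_fraction,
               clipped = metrics$clipped),
    threshold = config$quality_threshold)
  metrics$included <- qual$included

  utils::write.csv(metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  inc <- metrics[metrics$included, , drop = FALSE]
  summarize_or_na <- function(e, r) {
    ok <- is.finite(e) & is.finite(r)
    if (sum(ok) < 1L) return(list(n = 0L, r = NA, mae = NA))
    s <- suppressWarnings(summarize_agreement(e[ok], r[ok]))
    list(n = s$n, r = s$r, mae = s$mae)
  }
  summary <- list(
    n_segments = nrow(metrics),
    n_included = nrow(inc),
    n_excluded_quality = sum(!qual$included & !metrics$clipped),
    n_clipped = sum(metrics$clipped),
    velocity = summarize_or_na(inc$v_video, inc$v_truth),
    cadence = summarize_or_na(inc$c_v, inc$c_s),
    events = list(
      n_matched = sum(metrics$n_matched, na.rm = TRUE),
      n_missed = sum(metrics$n_missed, na.rm = TRUE),
      detected_fraction = {
        tot <- sum(metrics$n_matched, na.rm = TRUE) +
          sum(metrics$n_missed, na.rm = TRUE)
        if (tot > 0) sum(metrics$n_matched, na.rm = TRUE) / tot else NA
      },
      residual_mae_s = if (any(is.finite(metrics$residual_mae_s))) {
        stats::weighted.mean(metrics$residual_mae_s, metrics$n_matched,
                             na.rm = TRUE)
      } else NA
    )
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!quiet) {
    message(sprintf(
      "validated %d segment(s): %d included, %d excluded by quality, %d clipped; %d events matched, %d missed",
      summary$n_segments, summary$n_included, summary$n_excluded_quality,
      summary$n_clipped, summary$events$n_matched, summary$events$n_missed))
  }
  invisible(metrics)
}

#' Human-readable agreement report
#'
#' Prints r, MAE and n for velocity and cadence, stratified by view
#' label and inclusion status, in the style of a validation figure's
#' text insets.
#'
#' @param metrics Per-segment metrics data frame from [run_validate()],
#'   or the path to a `metrics.csv`.
#' @param file Connection or filename for output (default stdout).
#' @return The metrics data frame, invisibly.
#' @export
run_report <- function(metrics, file = stdout()) {
  if (is.character(metrics)) metrics <- utils::read.csv(metrics)
  out <- function(...) cat(..., "\n", sep = "", file = file, append = TRUE)
  if (is.null(metrics) || nrow(metrics) == 0L) {
    out("Gait validation report: no segments.")
    return(invisible(metrics))
  }
  out("Gait validation report")
  out(sprintf("  %d segment(s); %d included after quality filtering",
              nrow(metrics), sum(metrics$included)))
  strata <- split(metrics, list(metrics$view, metrics$included),
                  drop = TRUE)
  for (nm in names(strata)) {
    s <- strata[[nm]]
    lab <- sprintf("view %s / %s", s$view[1],
                   if (s$included[1]) "included" else "excluded")
    if (nrow(s) == 0L) next
    out("  -- ", lab, " (n = ", nrow(s), ") --")
    for (metric in list(c("velocity (m/s)", "v_video", "v_truth"),
                        c("cadence (steps/min)", "c_v", "c_s"))) {
      e <- s[[metric[2]]]; r <- s[[metric[3]]]
      ok <- is.finite(e) & is.finite(r)
      if (!any(ok)) {
        out("    ", metric[1], ": no paired values")
        next
      }
      a <- suppressWarnings(summarize_agreement(e[ok], r[ok]))
      out(sprintf("    %s: r = %s, MAE = %.3f, n = %d", metric[1],
                  if (is.na(a$r)) "undefined (n < 2)" else
                    sprintf("%.3f", a$r),
                  a$mae, a$n))
    }
    if (any(is.finite(s$residual_mae_s))) {
      out(sprintf("    foot-contact residual MAE = %.1f ms (%d matched, %d missed)",
                  1000 * stats::weighted.mean(s$residual_mae_s, s$n_matched,
                                              na.rm = TRUE),
                  sum(s$n_matched, na.rm = TRUE),
                  sum(s$n_missed, na.rm = TRUE)))
    }
  }
  invisible(metrics)
}
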