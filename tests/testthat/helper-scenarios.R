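# Build a full synthetic scenario in memory.
make_scenario <- function(..., seed = 1L) {
  cfg <- synthetic_config(..., seed = seed)
  truth <- generate_events(cfg)
  list(
    config = cfg,
    truth = truth,
    gyro = synthesize_gyro(truth, cfg),
    phase = synthesize_phase_series(truth, cfg),
    keypoints = synthesize_keypoints(truth, cfg)
  )
}

# Ground-truth cadence over a window from true contact times (the same
# first-to-last-event formula the sensor cadence uses).
truth_cadence_in_window <- function(truth, t_s, t_e,
                                    side = truth$prosthetic_side) {
  co <- truth$contacts[[side]]
  co <- co[co >= t_s & co <= t_e]
  if (length(co) < 2L) return(NA_real_)
  120 * (length(co) - 1L) / (co[length(co)] - co[1])
}

# Run the full sensor+video+sync pipeline on an in-memory scenario and
# return the per-segment measures.
pipeline_measures <- function(sc) {
  truth <- sc$truth
  seg <- timed_segment(truth$t_s, truth$t_e,
                       distance_m = truth$segment_distance_m)
  swings <- detect_swings(sc$gyro)
  clock <- estimate_clock_offset(sc$gyro, sc$phase)
  seg_sensor <- shift_segment(seg, clock$offset_s)
  contacts <- decode_foot_contacts(sc$phase, truth$prosthetic_side)
  ends <- swings_in_segment(swings, seg_sensor)$end_s
  vid <- contacts + clock$offset_s
  vid <- vid[vid >= seg_sensor$t_start_s & vid <= seg_sensor$t_end_s]
  m <- match_events(ends, vid)
  list(
    c_v = compute_video_cadence(sc$phase, seg),
    c_s = suppressWarnings(compute_sensor_cadence(swings, seg_sensor)),
    v_video = compute_segment_velocity(sc$phase, seg),
    v_truth = seg$velocity_truth_ms,
    c_truth = truth_cadence_in_window(truth, truth$t_s, truth$t_e),
    clock_offset = clock$offset_s,
    match = m
  )
}
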