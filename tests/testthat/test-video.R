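test_that("sliding-window assembly stitches window centres correctly", {
  # one-window case: output is the window's output verbatim
  frames <- matrix(seq_len(90), ncol = 1)
  ident <- function(w) w
  expect_equal(assemble_sliding_window(ident, frames), frames)

  # identity bookkeeping: row r of window starting at w holds the global
  # frame index, so output frame t must map to t for all t
  n <- 200
  frames <- matrix(seq_len(n), ncol = 1)
  out <- assemble_sliding_window(ident, frames)
  expect_equal(out[, 1], seq_len(n))

  # window-start model: enumerate the expected assembly by hand
  n <- 300
  starts <- function(w) matrix(rep(w[1, 1], 90), ncol = 1)
  out <- assemble_sliding_window(starts, matrix(seq_len(n), ncol = 1))
  # 0-based: frames 0..44 from window 0; t in 45..N-46 from window t-45;
  # last 45 frames from the last window (start N-90)
  expected <- c(rep(1, 45), (46:(n - 45)) - 45, rep(n - 89, 45))
  expect_equal(out[, 1], expected)

  expect_error(assemble_sliding_window(ident, matrix(1:89, ncol = 1)),
               "at least 90")
})

test_that("quadrature decoding finds positively directed zero crossings", {
  t <- seq(0, 5 - 1 / 30, by = 1 / 30)
  s <- data.frame(time_s = t, rfc_sin = sin(2 * pi * t),
                  rfc_cos = cos(2 * pi * t))
  ev <- decode_foot_contacts(s, "right")
  expect_equal(length(ev), 5L)
  expect_lt(max(abs(ev - 0:4)), 1 / 60)

  # no crossing -> empty
  s2 <- data.frame(time_s = t, rfc_sin = rep(0.5, length(t)),
                   rfc_cos = rep(0.5, length(t)))
  expect_identical(decode_foot_contacts(s2, "right"), numeric(0))

  # downward crossings (cos < 0) are rejected: sin crosses zero upward
  # once per cycle at phase 0 and the decoder must not double-count the
  # phase-pi crossing of a noisy circle
  phi <- 2 * pi * t + 0.03 * sin(17 * t)
  s3 <- data.frame(time_s = t, rfc_sin = sin(phi), rfc_cos = cos(phi))
  expect_equal(length(decode_foot_contacts(s3, "right")), 5L)
})

test_that("video cadence integrates the phase rate over the segment", {
  t <- seq(0, 20, by = 1 / 30)
  s <- data.frame(time_s = t, phase_rate = rep(2 * pi, length(t)))
  expect_equal(compute_video_cadence(s, timed_segment(2, 12)), 120)
  expect_equal(compute_video_cadence(s, timed_segment(0.37, 19.93)), 120)
  s$phase_rate <- rep(pi, length(t))
  expect_equal(compute_video_cadence(s, timed_segment(1, 9)), 60)
  expect_error(compute_video_cadence(s, timed_segment(15, 25)), "outside")
})

test_that("video cadence tracks the generated gait within 1 step/min", {
  sc <- make_scenario(cadence_spm = 100, stride_cv = 0.05, seed = 13)
  seg <- timed_segment(sc$truth$t_s, sc$truth$t_e)
  c_v <- compute_video_cadence(sc$phase, seg)
  c_ref <- truth_cadence_in_window(sc$truth, seg$t_start_s, seg$t_end_s)
  expect_lt(abs(c_v - c_ref), 1)
})

test_that("cadence is invariant to a uniform time translation", {
  sc <- make_scenario(cadence_spm = 110, stride_cv = 0.05, seed = 14)
  seg <- timed_segment(sc$truth$t_s, sc$truth$t_e)
  c0 <- compute_video_cadence(sc$phase, seg)
  for (delta in c(-3.7, 12.25)) {
    shifted <- sc$phase
    shifted$time_s <- shifted$time_s + delta
    expect_equal(compute_video_cadence(shifted, shift_segment(seg, delta)),
                 c0, tolerance = 1e-9)
  }
})

test_that("segment velocity averages the pelvis channel exactly", {
  t <- seq(0, 15, by = 1 / 30)
  s <- data.frame(time_s = t, pelvis_vel = rep(1.0, length(t)))
  expect_equal(compute_segment_velocity(s, timed_segment(2, 10)), 1.0)

  # annotated comparator: 10 m in 8.0 s
  expect_equal(timed_segment(2, 10)$velocity_truth_ms, 1.25)

  sc <- make_scenario(velocity_ms = 1.1, stride_cv = 0.05, seed = 15)
  seg <- timed_segment(sc$truth$t_s, sc$truth$t_e)
  expect_equal(compute_segment_velocity(sc$phase, seg), 1.1)
  expect_equal(seg$velocity_truth_ms, 1.1, tolerance = 1e-12)
})

test_that("clipping follows the 10 px / 1 percent rules", {
  mk <- function(x, y, n = 150) {
    kp <- data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1) / 30,
                     joint = "ankle_right", x_px = x, y_px = y,
                     confidence = 0.9)
    attr(kp, "width_px") <- 1080; attr(kp, "height_px") <- 1920
    attr(kp, "prosthetic_side") <- "right"
    class(kp) <- c("keypoint_track", "data.frame")
    kp
  }
  # keypoint at x = 5 -> that frame is clipped
  one <- flag_clipping(mk(c(5, rep(540, 149)), 960))
  expect_equal(one$clipped_fraction, 1 / 150)
  # all keypoints central -> nothing clipped
  centre <- flag_clipping(mk(rep(540, 150), 960))
  expect_identical(centre$clipped_fraction, 0)
  expect_false(centre$clipped)
  # 2 of 150 frames clipped -> fraction ~1.33% > 1% -> segment clipped
  two <- flag_clipping(mk(c(5, 1075, rep(540, 148)), 960))
  expect_equal(two$clipped_fraction, 2 / 150)
  expect_true(two$clipped)
  # y borders count too
  ybad <- flag_clipping(mk(540, c(rep(960, 145), rep(1915, 5))))
  expect_true(ybad$clipped)
  # monotone in the number of clipped frames
  fr <- vapply(0:5, function(k) {
    flag_clipping(mk(c(rep(5, k), rep(540, 150 - k)), 960))$clipped_fraction
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("ankle-quality partition uses >= 0.7 and the clipped flag", {
  df <- data.frame(
    mean_ankle_confidence = c(0.65, 0.70, 0.90, 0.90),
    clipped_fraction = c(0, 0, 0, 0.05),
    clipped = c(FALSE, FALSE, FALSE, TRUE))
  out <- filter_by_ankle_quality(df)
  expect_identical(out$included, c(FALSE, TRUE, TRUE, FALSE))
  out6 <- filter_by_ankle_quality(df, threshold = 0.6)
  expect_identical(out6$included, c(TRUE, TRUE, TRUE, FALSE))
})
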