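test_that("config validation rejects impossible scenarios", {
  expect_error(synthetic_config(cadence_spm = -1))
  expect_error(synthetic_config(stance_fraction = 1.2))
  expect_error(synthetic_config(glitch_duration_s = 0.4), "0.36")
  expect_error(
    generate_events(synthetic_config(cadence_spm = 120, duration_s = 0.8)),
    "too short")
})

test_that("zero-variance gait has exact stride times and segment timing", {
  cfg <- synthetic_config(cadence_spm = 120, stride_cv = 0,
                          velocity_ms = 1.25, seed = 1)
  truth <- generate_events(cfg)
  expect_equal(unique(round(truth$strides$left, 12)), 1.0)
  expect_equal(unique(round(truth$strides$right, 12)), 1.0)
  # 10 m at 1.25 m/s -> an 8 s timed window
  expect_equal(truth$t_e - truth$t_s, 8)
  # toe-off strictly between consecutive contacts of the same leg
  for (side in c("left", "right")) {
    co <- truth$contacts[[side]]
    to <- truth$toe_offs[[side]]
    expect_true(all(to > co[-length(co)] & to < co[-1]))
    expect_true(all(diff(co) > 0))
  }
})

test_that("generators are reproducible under a fixed seed", {
  a <- make_scenario(cadence_spm = 100, stride_cv = 0.05, gyro_noise_sd = 5,
                     glitch_prob = 0.5, edge_scenario = TRUE, seed = 7)
  b <- make_scenario(cadence_spm = 100, stride_cv = 0.05, gyro_noise_sd = 5,
                     glitch_prob = 0.5, edge_scenario = TRUE, seed = 7)
  expect_identical(a$truth, b$truth)
  expect_identical(a$gyro$gyro_z, b$gyro$gyro_z)
  expect_identical(a$phase, b$phase)
  expect_identical(a$keypoints, b$keypoints)
})

test_that("stride-time distribution has the configured mean", {
  # 1000+ strides at cadence 100 (1.2 s stride), CV 0.05
  cfg <- synthetic_config(cadence_spm = 100, stride_cv = 0.05,
                          duration_s = 1250, seed = 42)
  truth <- generate_events(cfg)
  st <- c(truth$strides$left, truth$strides$right)
  expect_gt(length(st), 2000)
  se <- sd(st) / sqrt(length(st))
  expect_lt(abs(mean(st) - 1.2), 3 * se)
  # CV close to nominal (truncation at 3 SD trims ~3% of the SD)
  expect_lt(abs(sd(st) / mean(st) - 0.05), 0.005)
})

test_that("noiseless gyro changes sign only at swing boundaries", {
  sc <- make_scenario(stride_cv = 0, gyro_noise_sd = 0, glitch_prob = 0,
                      seed = 2)
  z <- sc$gyro$gyro_z
  t <- sc$gyro$time_s
  flips <- which(diff(sign(z)) != 0)
  cross_t <- t[flips + 1L]
  sw <- truth_swings(sc$truth)
  bounds <- sort(c(sw$start_s, sw$end_s))
  expect_equal(length(cross_t), length(bounds))
  expect_lt(max(abs(cross_t - bounds)), 1.5 / sc$config$sensor_rate_hz)
})

test_that("toe-catch glitches put extra sign reversals inside every swing", {
  sc <- make_scenario(stride_cv = 0, gyro_noise_sd = 0, glitch_prob = 1,
                      glitch_duration_s = 0.2, seed = 3)
  z <- sc$gyro$gyro_z
  t <- sc$gyro$time_s
  sw <- truth_swings(sc$truth)
  for (k in seq_len(nrow(sw))) {
    ins <- t > sw$start_s[k] + 0.01 & t < sw$end_s[k] - 0.01
    expect_gte(sum(diff(sign(z[ins])) != 0), 2)
  }
})

test_that("injected clock offset shows up as a cross-correlation lag", {
  delta <- 0.17
  sc0 <- make_scenario(stride_cv = 0, clock_offset_s = 0, seed = 9)
  sc1 <- make_scenario(stride_cv = 0, clock_offset_s = delta, seed = 9)
  # brute-force oracle: sample both traces as functions of time on a
  # common grid and scan the cross-correlation over integer-sample lags
  dt <- 1 / sc0$config$sensor_rate_hz
  grid <- seq(1, sc0$truth$duration_s - 1, by = dt)
  f0 <- approx(sc0$gyro$time_s, sc0$gyro$gyro_z, xout = grid)$y
  lags <- seq(-300, 300)
  cc <- vapply(lags, function(l) {
    g <- approx(sc1$gyro$time_s, sc1$gyro$gyro_z, xout = grid + l * dt,
                rule = 1)$y
    ok <- !is.na(g)
    sum(f0[ok] * g[ok]) / sum(ok)
  }, numeric(1))
  lag_hat <- lags[which.max(cc)] * dt
  expect_lt(abs(lag_hat - delta), 1.5 * dt)
})

test_that("quadrature channels are unit-circle clean and events decodable", {
  sc <- make_scenario(cadence_spm = 120, stride_cv = 0, seed = 4)
  p <- sc$phase
  for (stub in c("lfc", "rfc", "lto", "rto")) {
    r2 <- p[[paste0(stub, "_sin")]]^2 + p[[paste0(stub, "_cos")]]^2
    expect_equal(max(abs(r2 - 1)), 0, tolerance = 1e-12)
  }
  # constant 1.0 s stride -> phase rate exactly 2*pi everywhere
  expect_equal(range(p$phase_rate), c(2 * pi, 2 * pi))
  # sin crosses zero upward within half a video frame of each contact
  # (events must be bracketable: at least one frame inside the series)
  dt <- 1 / 30
  for (side in c("left", "right")) {
    fc <- decode_foot_contacts(p, side)
    tr <- sc$truth$contacts[[side]]
    tr <- tr[tr >= min(p$time_s) + dt & tr <= max(p$time_s) - dt]
    near <- vapply(tr, function(x) min(abs(fc - x)), numeric(1))
    expect_lt(max(near), 1 / 60)
  }
})

test_that("decoder and generator are mutual inverses on noiseless data", {
  sc <- make_scenario(cadence_spm = 95, stride_cv = 0.05, seed = 21)
  for (side in c("left", "right")) {
    for (ev in c("contact", "toe_off")) {
      dec <- decode_foot_contacts(sc$phase, side, ev)
      tr <- if (ev == "contact") sc$truth$contacts[[side]] else
        sc$truth$toe_offs[[side]]
      tr <- tr[tr >= min(sc$phase$time_s) + 1 / 30 &
                 tr <= max(sc$phase$time_s) - 1 / 30]
      err <- vapply(tr, function(x) min(abs(dec - x)), numeric(1))
      expect_lt(max(err), 1 / 60)
    }
  }
})

test_that("keypoint tracks respect the edge-proximity scenario flag", {
  off <- make_scenario(edge_scenario = FALSE, seed = 5)
  q_off <- flag_clipping(off$keypoints)
  expect_identical(q_off$clipped_fraction, 0)
  expect_false(q_off$clipped)

  on <- make_scenario(edge_scenario = TRUE, edge_fraction = 0.05, seed = 5)
  q_on <- flag_clipping(on$keypoints)
  n <- q_on$n_frames
  tol <- 3 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(q_on$clipped_fraction - 0.05), tol)
  expect_true(q_on$clipped)

  # configured confidence level is honoured
  conf <- on$keypoints$confidence[on$keypoints$joint == "ankle_right"]
  expect_gt(mean(conf), 0.80)
  expect_lt(mean(conf), 0.90)
})

test_that("scenario files round-trip through disk", {
  sc <- make_scenario(seed = 6)
  d <- withr::local_tempdir()
  write_scenario(d, sc$truth, sc$gyro, sc$phase, sc$keypoints, sc$config)
  expect_setequal(
    list.files(d),
    c("sensor.csv", "phase.csv", "keypoints.csv", "segment.json",
      "truth.json", "config.json"))
  g <- read_gyro_csv(file.path(d, "sensor.csv"))
  expect_equal(g$gyro_z, sc$gyro$gyro_z, tolerance = 1e-12)
  p <- read_phase_csv(file.path(d, "phase.csv"))
  expect_equal(p$phase_rate, sc$phase$phase_rate, tolerance = 1e-12)
  seg <- read_segment_json(file.path(d, "segment.json"))
  expect_equal(seg$t_start_s, sc$truth$t_s)
  expect_equal(seg$velocity_truth_ms,
               sc$truth$segment_distance_m / (sc$truth$t_e - sc$truth$t_s))
})
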