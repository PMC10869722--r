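# prosgait

Validation tooling for video-based gait analysis of lower-limb prosthesis
users, benchmarked against a gyroscope worn on the prosthetic shank.

Smartphone video plus a pose/sequence model can estimate clinically useful
gait measures — cadence, walking velocity, foot-contact timing — without a
gait lab. Before such estimates can be trusted in prosthetics clinics, they
need validation against an independent wearable reference. `prosgait`
implements that validation pipeline end-to-end for people who build or
evaluate markerless gait-analysis systems: the sensor-side event detector,
the video-side decoder, the clock synchronization between the two, the
segment-level gait measures, the event-matching metrics, and the
keypoint-quality rules that decide which walking segments are usable. A
synthetic gait generator with known ground truth makes every stage testable
without clinical recordings.

## The method

**Sensor side.** The z channel of a shank-mounted gyroscope (562.5 Hz
nominal) shows a large positive lobe while the shank rotates forward in
swing. Swings are segmented by an 8th-order Chebyshev type-I low-pass
(35 Hz, 0.5 dB ripple, applied forward–backward so event times are not
delayed), rectification (negatives zeroed), and a 360 ms running median
that removes brief toe-catch reversals. Maximal positive runs are swings;
the end of swing `s_i` is the foot-contact proxy. The sensor timebase is
calibrated against host time by linear regression on packet timestamps.

**Video side.** A sliding-window sequence model (90 frames at 30 fps,
stitched at window centres) emits per frame a quadrature pair
`(sin φ, cos φ)` for each of four gait events, a gait-cycle phase rate
`ω̇` (rad/s), a pelvis velocity, and hip/knee sagittal angles. Foot
contacts are the positively directed zero crossings of the sin channel
(interpolated to sub-frame precision, gated on `cos φ > 0`).

**Segment measures.** Over an annotated 10-m timed segment
`[t_s, t_e]`:

- video cadence `c_v = 120 / (2π (t_e − t_s)) · ∫ ω̇ dt` (steps/min),
- sensor cadence `c_s = 120 (j − i) / (s_j − s_i)` from the first and
  last in-segment end-of-swing times,
- video velocity = time average of the pelvis-velocity channel, against
  the annotated `10 m / (t_e − t_s)`.

**Synchronization and matching.** The video stream starts with latency
relative to the sensor clock; the offset is recovered by minimizing the
MSE between the standardized gyro and the standardized derivative of the
summed hip+knee angle over a 1 ms grid. Sensor end-of-swing times are then
matched one-to-one to video foot contacts (best-alignment offset on a 1 ms
grid, greedy pairing, 500 ms detection window), yielding residual timing
MAE, missed-event counts and a detected fraction. Segments with mean
prosthetic-ankle keypoint confidence below 0.7, or with leg keypoints
within 10 px of the image border on more than 1 % of frames, are excluded.

## Worked example

Simulate three noisy walking scenarios (one with poor ankle tracking),
validate them end-to-end, and report agreement:

```r
library(prosgait)
cfg <- run_config(seed = 7, scenarios = list(
  list(cadence_spm = 95,  velocity_ms = 1.1, stride_cv = 0.05,
       gyro_noise_sd = 10, clock_offset_s = 0.17),
  list(cadence_spm = 115, velocity_ms = 1.4, stride_cv = 0.05,
       gyro_noise_sd = 10, clock_offset_s = 0.12),
  list(cadence_spm = 80,  velocity_ms = 0.8, stride_cv = 0.05,
       gyro_noise_sd = 10, ankle_confidence = 0.55)))
run_simulate(cfg, "demo")
metrics <- run_validate("demo", cfg)
run_report(metrics)
```

```
simulated 3 scenario(s) under demo
scenario_001: 9 swings, 10 contacts, 7 matched / 0 missed, clock offset +170 ms
scenario_002: 10 swings, 12 contacts, 7 matched / 0 missed, clock offset +120 ms
scenario_003: 10 swings, 11 contacts, 9 matched / 0 missed, clock offset +0 ms
validated 3 segment(s): 2 included, 1 excluded by quality, 0 clipped; 23 events matched, 0 missed
Gait validation report
  3 segment(s); 2 included after quality filtering
  -- view frontal / excluded (n = 1) --
    velocity (m/s): r = undefined (n < 2), MAE = 0.000, n = 1
    cadence (steps/min): r = undefined (n < 2), MAE = 0.163, n = 1
    foot-contact residual MAE = 0.9 ms (9 matched, 0 missed)
  -- view frontal / included (n = 2) --
    velocity (m/s): r = 1.000, MAE = 0.000, n = 2
    cadence (steps/min): r = 1.000, MAE = 0.076, n = 2
    foot-contact residual MAE = 1.0 ms (14 matched, 0 missed)
```

Reading this: the injected 170 ms and 120 ms clock offsets were recovered
exactly; every sensor-detected foot contact found a video partner within
the 500 ms window with ~1 ms residual error; video and sensor cadence agree
to a fraction of a step/min; and the segment with mean ankle confidence
0.55 was excluded by the 0.7 quality rule, exactly as it would be in a
clinical analysis.

A command-line front-end with the same `simulate` / `validate` / `report`
subcommands is installed at `inst/scripts/gaitpipe.R`.

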