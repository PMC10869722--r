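---
title: "Methods: validating video gait measures against a shank-worn gyroscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating video gait measures against a shank-worn gyroscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosgait)
```

## The validation problem

Markerless gait analysis estimates cadence, walking velocity and
foot-contact timing for prosthesis users from a single smartphone video.
Those estimates come from a sequence model whose per-frame outputs encode
the *relative timing* of four gait events — left and right foot contact
and toe-off — as quadrature pairs, plus a gait-cycle phase rate, a pelvis
velocity and sagittal hip/knee angles. The independent reference is a
gyroscope on the prosthetic shank: while the shank rotates forward during
swing, its z channel shows a large positive lobe, and the instant the
rotation stops (the positive-to-negative sign change) is a close,
slightly-early proxy for foot contact.

`prosgait` implements both measurement chains and everything needed to
compare them: clock calibration and synchronization, per-segment gait
measures, event matching with residual timing statistics, and the
keypoint-quality rules that decide which walking segments enter the
comparison. Because clinical recordings of this kind cannot be shared, the
package ships a synthetic generator that produces paired sensor/video
recordings with known ground truth; every claim the package makes about
its own correctness is established on that generator.

## The synthetic generator

`generate_events()` lays down alternating left/right foot contacts.
Stride-time variability is applied at the *step* (half-stride) level: step
intervals are drawn from a normal distribution truncated at ±3 SD with SD
`stride_cv × stride / sqrt(2)`, so per-leg stride times (each the sum of
two consecutive steps) have exactly the configured mean and approximately
the configured CV, while contacts are guaranteed to keep alternating —
independent per-leg stride draws would let the legs drift through each
other, which real gait forbids. Symmetric truncation preserves the mean;
it trims the SD by about 3 %, which the distribution tests account for.
Toe-offs sit at a fixed stance fraction (default 0.62, typical adult
gait) of each stride. The timed segment starts 1.5 s after the first
contact and spans `distance / velocity` seconds.

`synthesize_gyro()` renders the shank template: a half-sine lobe of
configurable peak (default 300 deg/s) during each prosthetic-side swing
and a small negative constant (default −20 deg/s) in stance, so the
noiseless sign crossings coincide with swing boundaries by construction.
Samples are timestamped at `world time + clock_offset`, emulating video
start latency, with additive white Gaussian noise.

**Toe-catch glitches.** Prosthesis users occasionally catch the toe
mid-swing, producing a brief angular-velocity reversal. We model the
glitch as a smooth cosine reversal — within the glitch interval the
template is multiplied by `cos(2π·frac)` — rather than a square sign
flip. The choice matters: a running median of span `w` only erases a
rectified zero-run shorter than `w/2`. With the cosine shape the
sign-negative core occupies exactly the central half of the nominal
glitch duration `L`, so the 360 ms median filter removes any glitch with
`L < 360` ms — which is the deglitching behaviour the detector is
designed to provide — while a square reversal of the same nominal length
would survive for `L > 180` ms. The configuration therefore rejects
`glitch_duration_s ≥ 0.36`: such a glitch is a detector failure mode, not
a deglitching test.

`synthesize_phase_series()` advances each event's phase linearly from 0
to 2π between consecutive occurrences, so `sin φ` crosses zero upward at
each true event; the phase-rate channel is the mean of the two legs'
instantaneous stride rates; the pelvis-velocity channel is the configured
velocity plus an optional zero-mean within-stride sinusoid (off by
default so velocity ground truth is exact — the shape of real
within-stride pelvis-velocity fluctuation is not something we can claim
to reproduce). The hip and knee angle channels are constructed so that
the derivative of their sum reproduces the shank angular-velocity
template (angles = detrended cumulative integral of the template, split
65/35 between hip and knee). This is the physical relationship — shank
orientation is a combination of hip and knee flexion — that makes the
clock-offset objective identifiable, and it is the one modelling choice
the synchronization stage depends on.

`synthesize_keypoints()` places six leg keypoints of a walking figure in
a 1080 × 1920 portrait frame with gait-phase-locked oscillation,
per-joint confidence at the configured level with clamped jitter, and —
in the edge scenario — a Bernoulli-selected fraction of frames with the
left ankle within 10 px of the border.

What the generator deliberately does **not** emulate: pose-estimation
failure modes (identity switches to a nearby therapist, joint
hallucination on prosthetic hardware), camera motion, 2D→3D lifting
error, within-stride velocity waveforms, or any coupling between
keypoint quality and model-output quality. Passing tests therefore show
that the *analysis* is correct — formulas, filters, synchronization,
matching, filtering rules — not that a particular trained model is
accurate on real patients.

## Sensor event detection

`detect_swings()` runs the documented pipeline: 8th-order Chebyshev
type-I low-pass (35 Hz passband edge, 0.5 dB ripple), rectification,
360 ms running median, and extraction of maximal strictly-positive runs.
Numerical choices:

- **Zero-phase filtering.** The filter is applied forward–backward
  (`signal::filtfilt`), prioritizing timing fidelity: a causal 8th-order
  IIR at this cutoff would delay events by several milliseconds.
  Magnitude response is squared as a side effect, which is irrelevant to
  sign-crossing detection.
- **Median length** is `0.36 s × rate` rounded up to odd (203 samples at
  562.5 Hz). Besides deglitching, the median *sharpens* swing
  boundaries: at an edge between an all-positive and an all-zero region
  the output flips exactly where the window majority flips, i.e. at the
  crossing itself.
- **Transition convention.** Swing start/end are read at the first
  sample of the new sign, with no sub-sample interpolation: one sensor
  sample is 1.8 ms, far below every tolerance in the analysis. The only
  systematic timing effect left is the smoothing of the −20 deg/s stance
  step at the true contact, which moves detected ends ~3 ms early —
  constant, and absorbed by the matching offset.
- Runs touching the first or last sample have no observable boundary and
  are dropped. An everywhere-negative trace yields an empty event list;
  a trace shorter than the median span is an error.

`calibrate_timebase()` is an ordinary least-squares fit of packet host
time on packet sample index; the effective rate is the reciprocal slope.
Fewer than two packets, or zero index variance, are errors.

## Video decoding and segment measures

Foot contacts are decoded as positively directed zero crossings of the
event's sin channel, located by linear interpolation between bracketing
frames. A noisy quadrature circle crosses `sin = 0` upward twice per
cycle; the decoder keeps only crossings where the interpolated cos is
positive (the true event sits at phase 0 where cos ≈ +1). Events lying
closer than one frame to the series boundary are unbracketable and
undetectable by construction.

Cadence integrates the phase-rate channel over the timed segment by the
trapezoidal rule, with partial frames at the segment ends handled by
linear interpolation, then converts strides/s to steps/min (factor
`120/2π`). Velocity is the analogous trapezoidal time average of the
pelvis-velocity channel. Segment membership — for video events, sensor
end-of-swing times and cadence windows alike — uses the closed interval
`[t_s, t_e]`.

The sliding-window assembler reproduces the inference-time stitching
contract: per-frame outputs are taken from window centres (row 45 of the
window starting 45 frames earlier, 0-based), with the first and last 45
frames taken from the corresponding halves of the first and last
windows. The trained model itself is out of scope; any callable honouring
the 90-in/90-out contract can be stitched, and tests exercise the
assembler with synthetic stand-ins.

## Synchronization and matching

`estimate_clock_offset()` minimizes, over a 1 ms grid spanning ±0.5 s,
the mean squared difference between the standardized low-passed gyro and
the standardized central-difference derivative of `hip + knee`,
interpolated to the sensor grid at each candidate offset. Both signals
are z-scored so units and scale cannot bias the fit. The objective is
evaluated on sensor samples decimated to ~125 Hz — alias-free after the
35 Hz low-pass — because offset resolution comes from the interpolation
and the grid, not the evaluation sampling. Flat signals or less than 3 s
of material are errors.

`match_events()` fits a *separate* per-segment alignment offset — the
analysis keeps the global clock offset and the match offset independent,
since the sensor end-of-swing systematically precedes true foot contact
by an amount that is not a clock property. The offset is the minimizer
of the mean absolute nearest-neighbour residual over a 1 ms grid
spanning ±0.4 s; the grid is centred on the best pairwise difference
between event lists, a data-driven centre that makes the fit exactly
equivariant under global time shifts. Pairing is greedy one-to-one in
ascending absolute residual within the 0.5 s detection window: at normal
gait event spacing (≥ 0.4 s) this coincides with optimal assignment
except in pathological inputs. Unmatched sensor events count as missed;
the detected fraction is `matched / (matched + missed)`; an empty video
list is all-missed, an empty sensor list is an error (nothing to
validate). Grid ties resolve to the smallest offset, deterministically.

`compute_sensor_cadence()` with fewer than two in-segment swings returns
`NA` with a warning and a `"reason"` attribute rather than a silent
number. `summarize_agreement()` reports Pearson r (NA below n = 2 or
under zero variance) and mean absolute error.

## Quality filtering

A frame is clipped when any leg keypoint lies within 10 px of the image
border; a segment is clipped when more than 1 % of its frames are
clipped; a segment is included when it is not clipped and its mean
prosthetic-ankle confidence is at least 0.7 (strictly below 0.7
excludes; the boundary value is kept, matching the stated exclusion rule
"less than 0.7"). For bilateral users the two prosthetic ankles'
confidences are averaged. All thresholds live in `run_config()` so
sensitivity analyses are one-argument changes.

## Problem sizes and test design

The test suite establishes each property at the smallest size that
exercises it: single scenarios of 12–30 s for round-trip checks, 50
scenarios spanning cadence 70–130 steps/min and velocity 0.4–1.6 m/s
(stride CV 0.05, 10 deg/s gyro noise) for the parameter-recovery sweep,
30 seeded replicates for noisy clock-offset recovery, and closed-form
references (e.g. the folded-normal mean for agreement MAE under known
noise) where they exist. Deterministic sub-checks (formula exactness on
round numbers, clipping arithmetic, boundary conventions) are asserted
exactly. `scripts/acceptance.R` re-runs the sweep from scratch and
writes the resulting summary quantities as JSON.

## Known limitations

- The synthetic shank waveform is a stylized half-sine; real gyro traces
  have richer morphology (heel-strike transients, push-off lobes), so
  real-data swing detection accuracy must be established separately.
- The decoder operates on raw quadrature outputs; no temporal smoothing
  or state-space filter is applied, and whether smoothing would shift
  event timing on noisy model outputs is untested here.
- Keypoint confidence in the generator is statistically independent of
  the phase-series quality, so the quality filter's *selectivity* (its
  ability to remove genuinely bad segments) cannot be measured
  synthetically — only its decision rule.
- Velocity validation uses a constant-velocity ground truth; the
  annotated-timing comparator `distance/(t_e − t_s)` is exact only under
  that assumption.
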