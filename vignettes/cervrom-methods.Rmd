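---
title: "Measuring cervical range of motion from head-pose streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cervical range of motion from head-pose streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervrom)
```

## The measurement problem

A head-mounted display tracks the orientation of the wearer's head as a
stream of unit quaternions at a nominal 60 Hz. During a seated cervical
examination the subject performs six maximal movements in a fixed order —
flexion, extension, left side bend, right side bend, left rotation,
right rotation — returning to a calibrated starting position between
movements. The clinically useful outputs are the signed range of motion
(ROM) and duration of each movement, the asymmetry between paired
directions, and any *compensations*: angular excursions in planes other
than the one being tested, which indicate deviation from the intended
movement pattern.

`cervrom` implements the full chain from raw quaternion stream to these
outputs, plus a simulator rich enough to validate every step.

## Orientation model and angle decomposition

The working frame is right-handed with X pointing to the subject's
right, Y up, and Z posterior. Neutral calibration estimates the
reference orientation $q_{\mathrm{ref}}$ and every sample is re-zeroed
as $q_{\mathrm{rel}} = q_{\mathrm{ref}}^{-1} \otimes q$.

$q_{\mathrm{rel}}$ is factored by an intrinsic yaw(Y) → pitch(X) →
roll(Z) Euler decomposition. With this axis order each anatomical
movement lands on exactly one Euler angle, and the singular
configuration (gimbal lock) sits at a pitch of ±90°, i.e. a
flexion/extension no cervical spine reaches. The clinical sign map is
applied after extraction:

| channel | Euler source | positive direction |
|---|---|---|
| flexion_extension | −pitch | flexion (forward) |
| lateral_flexion | +roll | left side bend |
| rotation | −yaw | right rotation |

All angles are degrees. Internal precision is full double; reports
round to two decimals, and the goniometer twin to whole degrees (the
resolution of an analog scale). Decomposition warns — but does not fail
— beyond 85° of flexion/extension; unit-norm tolerance for quaternions
is 1e-6. Both the compose→decompose round trip (to 1e-9°) and agreement
with an independent rotation-matrix Euler extraction (to 1e-6° over
1000 random orientations) are enforced by tests.

Two points were deliberately resolved here rather than left open: the
displayed angles are taken to be the Euler reading of the headset (not
a projection onto the display grid), and the neutral is calibrated once
per session, since the protocol returns the subject to the same
indicated starting position between movements.

## Neutral calibration

The reference pose is the hemisphere-aligned component mean of the
quaternions in the initial 1 s still window. Stillness is judged by
*drift rate* — the geodesic angle between the mean orientations of the
window's first and last thirds divided by the time between them
(default limit 10 °/s) — not by per-sample angular speed: at 60 Hz,
quaternion-component noise of realistic magnitude already produces
tens of °/s of apparent per-sample speed on a perfectly still head,
while it cancels almost completely in the two means. A moving head
(e.g. 20 °/s) fails the check with an error naming the window.

## The simulator

`simulate_protocol()` generates the six-movement session: a neutral
lead-in (1.5 s), then each movement rising to its signed peak along a
minimum-jerk profile $\theta(\tau) = \theta_{\max}(10\tau^3 - 15\tau^4
+ 6\tau^5)$, holding, returning by the mirrored profile, and resting
(1 s) before the next. The minimum-jerk quintic is the standard model
of smooth voluntary point-to-point movement; its boundary conditions
(zero velocity and acceleration at both ends) and interior shape (peak
speed $1.875\,\theta_{\max}/t_{\mathrm{rise}}$) are asserted in tests.

Default peaks are mid-range healthy adult values — flexion 50°,
extension 60°, lateral flexion 40° each side, rotation 70° each side,
rise 1.5 s, hold 0.5 s. They are fixtures for exercising the pipeline,
not normative claims. Cross-plane compensations are injected as a
coupling ratio $c$: the off-plane channel receives $c \times$ the
primary profile, signed by the coupled direction's convention (so a
left-rotation coupling during left side bend produces a negative
rotation trace). Sensor noise is Gaussian, injected *in angle space*
(default SD 0.5°, a realistic optical-tracking jitter) and then
recomposed into quaternions — this keeps the noise parameter
interpretable in degrees. Streams are deterministic given the seed.

`simulate_rig_trial()` is the digital twin of a goniometer-instrumented
skull-model validation: a noise-free stream that settles at neutral,
moves in exactly one plane to the commanded angle, and holds. The twin
goniometer reads the commanded angle rounded to whole degrees. The
default validation trials are 34° flexion, 45° right rotation and 30°
right lateral flexion, plus the 0° starting-position check; the
pipeline's whole-degree reading must equal the goniometer's exactly,
and does.

What the simulator does *not* emulate: tracking drift and optical
artefacts of a real headset, biomechanical coupling of head and trunk,
fatigue, pain-limited movement, or subjects who do not return to
neutral. Passing recovery tests on simulated data therefore shows the
pipeline is correct with respect to its own measurement model, not that
any headset meets that model.

## Segmentation

Episodes are delimited on smoothed angular speed with hysteresis:
start when speed exceeds 10 °/s, end at the first sample where speed is
below 5 °/s *and* all channels are inside the ±3° neutral band (the
band condition keeps the hold-at-peak, where speed is near zero but
angles are large, inside the episode). Episodes shorter than 0.3 s or
never leaving the neutral band are discarded. All thresholds are
exposed in `segmentation_config()` and through the CLI config file.

The speed estimate is the Euclidean norm of the three per-channel
derivatives, computed from angle channels pre-smoothed by a 0.25 s
centred moving average, using a centred finite difference whose stencil
also spans ±0.25 s, and smoothed once more. The wide stencil matters:
a single-step central difference at 60 Hz amplifies 1° of angle noise
into a speed floor comparable to the hysteresis thresholds, whereas
the 0.5 s baseline keeps the floor near 1 °/s while leaving plateau
speeds of real movements (tens of °/s) untouched.

Episode peaks, ROM and compensation extrema are likewise read from the
smoothed channels: the raw maximum of a noisy series is biased upward
by the extreme order statistic of the noise, while the plateau mean is
not. On noise-free rig trials smoothing leaves the held plateau exactly
intact, which is what makes the whole-degree digital-twin agreement
exact rather than approximate.

Labelling is by dominant channel (largest absolute excursion) and the
sign of its extremum; ties break in protocol-channel order,
deterministically. An episode whose dominant channel contradicts its
protocol position keeps its data-derived label;
`validate_protocol_order()` reports the mismatch, along with missing,
repeated and out-of-order movements.

## Analysis outputs

- **ROM** — signed extremum of the primary channel in the episode
  window (a goniometer's maximal-excursion reading, not net
  displacement); duration is the episode span.
- **Asymmetry** — signed left-minus-right differences of duration and
  |ROM| for the two directions of each plane.
- **Compensations** — per off-plane channel, the signed extremum in the
  window and the coupling ratio (off-plane peak / primary peak). The
  co-movement flag fires above a 5° off-plane band — small co-movements
  are physiological — and the norm-exceedance flag when |ROM| exceeds
  the configured limit for that movement. Normative limits are
  configuration only (`normative_ranges()`, `read_norms()`): published
  normative tables disagree with one another, so the package ships no
  numbers.
- **Session summary** — per movement the min/max/arithmetic mean of
  signed ROM across sessions (no trimming) and mean duration, the shape
  of a clinical results table; `compare_sessions()` gives per-movement
  deltas between two summaries for tracking mobility over time.

## Numerical and design notes

- Quaternion hemisphere ambiguity (q vs −q) is resolved to the
  non-negative scalar part everywhere; decomposition goes through the
  rotation matrix and is hemisphere-invariant by construction.
- The matrix→quaternion conversion uses Shepperd's branching for
  stability; angle extraction clamps the asin argument to [−1, 1].
- Session CSVs serialize with 12 significant digits; the write→read
  round trip preserves every downstream result to measurement
  precision. The quaternion column order (w first) is fixed by the
  header.
- Plot geometry (the two posturographic reference lines crossing at
  90°, the trace as rotation vs flexion/extension with lateral flexion
  as line tilt) is asserted on `trajectory_plot_model()`, the data
  behind the drawing — never on rendered pixels.
- Degenerate inputs: an all-neutral series segments to an empty episode
  list (not an error); a zero quaternion is always a hard error; an
  empty episode window errors in `compute_rom()`.

Problem sizes in the test-suite: sessions of ~29 s at 60 Hz (~1700
samples), 20 seeds for recovery properties, 1000 random orientations
for the oracle-equivalence property; the full suite runs in well under
a minute on one CPU.

## Known limitations

Position channels are carried through I/O but not analysed (all outputs
are orientation-based). Segmentation is offline, not streaming, and
does not count repetitions within a movement. The simulator's noise is
white and stationary; real headset error is neither. No diagnostic
classification is attempted — the package measures, it does not
diagnose — and no statistics across participants are provided.
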