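# cervrom

Measurement of cervical spine range of motion (ROM) from head-pose
tracking streams, as recorded by a head-mounted display worn during a
seated six-movement examination. The package turns a raw stream of
timestamped unit quaternions (nominally 60 Hz) into the quantities a
physiotherapist reads off a clinical examination:

- **signed anatomical angles** per frame — flexion/extension (sagittal,
  flexion `+`), lateral flexion (frontal, left `+`), rotation
  (transverse, right `+`);
- **movement episodes** — the six maximal movements of the protocol
  (flexion, extension, left side bend, right side bend, left rotation,
  right rotation), segmented by angular-speed hysteresis and validated
  against the protocol order;
- **ROM and duration** per movement, left/right asymmetries, and
  **compensatory co-movements** (cross-plane coupling ratios and
  norm-exceedance flags);
- session file round-tripping, a posturographic-grid trajectory plot,
  and between-session comparison to track mobility over time.

It also contains a **simulator**: minimum-jerk examination sessions with
configurable peaks, couplings and sensor noise, plus a digital twin of a
goniometer-instrumented skull-rig validation experiment — so the whole
pipeline can be exercised and validated without a headset.

## Model

Head orientation is a unit quaternion `q(t)`. After neutral calibration
against the averaged starting pose `q_ref` (hemisphere-aligned component
mean over a 1 s still window), the relative orientation
`q_rel = q_ref⁻¹ ⊗ q` is factored by an intrinsic yaw(Y)–pitch(X)–roll(Z)
Euler decomposition in a right-handed frame (X = subject's right,
Y = up, Z = posterior), followed by the clinical sign map:

    flexion_extension = −pitch    (flexion +, extension −)
    lateral_flexion   = +roll     (left +, right −)
    rotation          = −yaw      (right +, left −)

This puts each anatomical movement on one Euler axis and moves gimbal
lock to |flexion| = 90°, outside cervical range. ROM per movement is the
signed extremum of the primary channel within its episode — the maximal
excursion a goniometer would read.

## Worked example

```r
library(cervrom)

sim <- simulate_protocol(protocol_config(seed = 3))  # six movements, 60 Hz, 0.5 deg noise
fit <- analyze_session(sim$stream)
fit
#> <cervrom_session> 1740 samples @ 60 Hz, 6 episode(s), protocol order OK
#>           label rom_signed_deg duration_s
#>         flexion          50.12      3.400
#>       extension         -60.05      3.433
#>    left_lateral          40.11      3.333
#>   right_lateral         -40.09      3.333
#>   left_rotation         -70.16      3.467
#>  right_rotation          70.03      3.500
```

Each row is one protocol movement: the signed peak angle (the commanded
simulator peaks were 50, 60, 40, 40, 70, 70 degrees with the
corresponding signs) and the detected episode duration. `coef(fit)`
returns the signed ROM vector, `summary(fit)` the min/max/mean table,
`plot(fit)` the trajectory on the posturographic grid (two fixed
reference lines crossing at 90°).

The skull-rig digital twin reproduces the validation experiment in which
an analog goniometer and the tracking pipeline read the same angles:

```r
rig_validation_table()
#>           plane commanded_deg app_deg goniometer_deg identical
#>         flexion            34      34             34      TRUE
#>  right_rotation            45      45             45      TRUE
#>   right_lateral            30      30             30      TRUE
```

A command-line interface wraps the same functions
(`exec/cervrom simulate|analyze|rig-validate|compare`).

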