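# hipkin

Hip joint kinematics from paired wearable magneto-inertial sensors.

`hipkin` estimates 3D hip joint angles — flexion-extension (FE),
ad/abduction (AA) and internal-external rotation (IER) — from two
body-worn magnetic and inertial measurement units (MIMUs), one on the
pelvis/lumbar region and one on the thigh. It is aimed at movement
scientists and biomechanists who want joint angles outside the motion
capture lab: the method needs no particular sensor orientation or
placement and only minimal calibration motions (quiet standing plus a short
trial that exercises the hip in all three planes).

The package implements the full pipeline:

* **SSRO** — a Kalman filter for the *sensor-to-sensor relative
  orientation*: the state is `[g1; g2; q21]`, the gravity direction in each
  sensor frame plus the quaternion rotating thigh-sensor vectors into the
  pelvis-sensor frame. Gyroscopes drive the prediction; accelerometers
  measure gravity through a first-order model of body acceleration
  (`a = g + a_tilde`, `a_tilde_k = c a_tilde_{k-1} + eps`); gravity
  estimates plus magnetometers yield a direct quaternion measurement whose
  noise grows with `mu (||a_tilde_1||^2 + ||a_tilde_2||^2)`. Magnetic
  disturbances are assumed *shared* by the two nearby sensors, so they
  cancel from the relative orientation instead of corrupting it.
* **Functional joint centers** — both sensors must agree on the
  joint-center acceleration:
  `a1 - (w1x w1x + w1dot x) r1 = R21 (a2 - (w2x w2x + w2dot x) r2)`;
  stacking >= 1500 high-angular-velocity samples gives a least-squares
  estimate of the offsets `r1`, `r2`. For the quasi-1D knee, the flexion
  axis is found from `||w1 x j1|| = ||w2 x j2||` and the center estimate is
  corrected to the perpendicular foot point.
* **Anatomical calibration** — ISB-convention pelvis and thigh frames from
  the joint-center geometry and the most still period of a standing trial.
* **Joint angles** — the joint coordinate system (`e1` = pelvis Z,
  `e3` = thigh y, `e2 = e3 x e1`) evaluated per sample.
* **Agreement metrics** — RMSE with 360-degree wrap correction, regression
  slope/intercept, range of motion (ROM) with start-up exclusion, and drift.
* **A rigid-body IMU simulator** — ground-truthed synthetic recordings
  (ball and hinge joints, arbitrary mountings, gravity, shared magnetic
  field, sensor noise) so the whole pipeline is testable without any
  recorded data.

## Worked example

Simulate a full measurement protocol (static standing, star-like
calibration, one minute of walking; five sensors with random mounting
orientations), run the pipeline, and score the walking trial against the
prescribed angles:

```r
library(hipkin)

proto <- simulate_protocol(seed = 42)   # nominal sensor noise
res <- run_pipeline(proto$static, proto$star, proto$walking)

est <- res$angles$right                  # angle_trace: t, fe, aa, ier
ref <- proto$truth$angles$walking$right
agreement_stats(est$fe, ref$fe, est$t)
```

```
#> <agreement_stats> n = 7680
#>   RMSE 0.237 deg | slope 0.993 | intercept -0.008 deg | r 1.000
#>   ROMD 0.178 deg | drift 0.0029 deg/s (p = 1.63e-77)
```

The flexion trace tracks the prescribed profile to 0.24 degrees RMSE with
slope 0.99 (changes tracked one-to-one), negligible bias, a range-of-motion
error of 0.18 degrees, and a drift rate far below the level that would
matter over a one-minute trial. The calibration itself is inspectable and
persistable:

```r
res$joint_centers$right$hip          # r1/r2 offsets with fit residual
#> <joint_center_result> n_obs = 1500, residual = 0.05877 m/s^2
#>   r1 = (0.0448, 0.1651, 0.0072) m
#>   r2 = (-0.1829, -0.0486, -0.0859) m
save_calibration(res$calibration, "calibration.yaml")
```

A thin command-line front end over the same functions lives at
`inst/cli/hipkin.R` (`simulate`, `ssro`, `calibrate`, `angles`,
`evaluate` subcommands; columnar CSV in and out):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hipkin.R", package = "hipkin"))')" \
    simulate --seed 1 --out-dir data/
```

## Vignette

`vignettes/hip-kinematics-methods.Rmd` documents the models, the parameter
semantics and defaults, the numerical choices, what the simulator does and
does not emulate, and known limitations.
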