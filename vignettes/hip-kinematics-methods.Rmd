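---
title: "Estimating 3D hip angles from paired magneto-inertial sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating 3D hip angles from paired magneto-inertial sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hipkin estimates 3D hip joint angles from two body-worn magnetic and
inertial measurement units (MIMUs) — one on the pelvis/lumbar region, one
on the thigh — without requiring specific sensor placement or an extensive
calibration routine. This vignette describes the models behind each stage,
the tunable parameters, the numerical choices, what the bundled simulator
does and does not emulate, and the known limitations.

## Pipeline overview

1. **Preprocessing** — zero-phase low-pass filtering of all channels
   (15 Hz default), angular acceleration by central differences (filtered
   at 12 Hz).
2. **Sensor-to-sensor relative orientation (SSRO)** — a Kalman filter
   estimating the quaternion rotating thigh-sensor vectors into the
   pelvis-sensor frame, together with the gravity direction in each sensor
   frame.
3. **Functional joint centers** — the hip center located from the
   rigid-body constraint that both sensors must agree on the joint-center
   acceleration; the knee center likewise, with a hinge-axis correction for
   its unobservable axial component.
4. **Anatomical frames** — constant sensor-to-segment rotations built from
   the joint-center geometry and a still standing pose, following ISB axis
   conventions.
5. **Hip angles** — flexion-extension (FE), ad/abduction (AA) and
   internal-external rotation (IER) from the joint coordinate system at
   every sample.

Every stage is exercised end to end by `run_pipeline()` and validated
against the rigid-body simulator (`simulate_protocol()`).

## The SSRO filter

The state is the 10-vector $\chi = [g_1; g_2; q_{21}]$: unit gravity
directions in the two sensor frames and the unit relative quaternion. The
model rests on two assumptions:

* gravity is the only persistent component of the accelerometer signal —
  the *true* (body) acceleration $\tilde a$ follows a first-order
  autoregression $\tilde a_k = c\,\tilde a_{k-1} + \epsilon_k$;
* the magnetic field, whatever its direction and disturbances, is the
  *same* field at both sensors (they sit close together on one body), so
  it informs the relative orientation even when it would mislead a
  world-referenced filter.

**Time update.** Gravity obeys $\dot g_i = -\omega_i \times g_i$ and the
relative quaternion $\dot q_{21} = \tfrac12 q_{21} \otimes (0,
\omega_{diff})$ with $\omega_{diff} = \omega_2 - R_{21}^T \omega_1$. The
covariance is propagated with the first-order Jacobians of these equations
and gyro-driven process noise. The state *mean*, however, is propagated
with exact per-step rotations: each sensor's step rotation vector is formed
by trapezoidal averaging of the two adjacent gyro samples plus a two-sample
coning correction, and the relative quaternion update factorizes exactly as
$q_{21} \leftarrow E_1^* \otimes q_{21} \otimes E_2$ over the per-sensor
step rotations. This matters: with plain first-order Euler stepping at
128 Hz, noiseless strap-down integration alone drifts by several degrees
per minute, which would dominate every other error source the filter is
designed to remove. With the exact factorized step the 60 s prediction-only
error stays below one degree (the strap-down limit), so the measurement
model — not the integrator — determines accuracy.

**Measurements.** The gravity measurement is $\zeta_g = a_k - c \tilde
a_{k-1}$ observed through $H_g = G I_3$. The quaternion measurement aligns
the two gravity estimates by a shortest-arc rotation, then aligns the
gravity-orthogonal (horizontal) magnetometer components by a rotation about
the shared gravity direction; the composition is a direct measurement of
$q_{21}$ with $H_q = I_4$. Its noise is scaled by the current true
acceleration magnitudes, $M_q = \mu (\|\tilde a_1\|^2 + \|\tilde
a_2\|^2) I_4$, so the magnetic/gravity measurement is discounted exactly
when the body accelerates and the gravity estimates are least reliable.
Because gravity alignment is ambiguous when the two gravity estimates are
antiparallel, that case uses a 180-degree flip about an arbitrary
perpendicular axis; the heading stage absorbs the choice, so the composed
measurement is continuous there.

**Parameters** (defaults in `kf_params()`):

| parameter | default | units | role |
|---|---|---|---|
| `sigma_w` | 1e-3 | rad/s | gyro noise standard deviation; squared in the process noise |
| `sigma_a` | 6e-3 | (m/s^2)^2 | accelerometer noise variance; gravity measurement floor |
| `c` | 0.003 | – | AR(1) constant of the true-acceleration model |
| `n_ma` | 64 | samples | window of the moving-average term in the gravity noise |
| `mu` | 5e-8 | – | quaternion measurement noise factor |
| `g` | 9.81 | m/s^2 | gravitational acceleration |

A note on the noise constants: `sigma_w` enters the process-noise formulas
squared (it is a standard deviation), while `sigma_a` is used directly in
the measurement covariance (it is a variance). This asymmetric convention
is deliberate. It is the only reading of the two constants under which the
filter's gains are self-consistent — the gravity update then corrects
slowly enough not to chase periodic body acceleration, while the
quaternion measurement retains enough authority to suppress integration
drift — and it matches the nominal accelerometer noise level of the class
of sensors the defaults describe ($0.08^2 \approx 6.4\times10^{-3}$).
Treating both constants as variances, or both as standard deviations,
degrades noiseless tracking from about one degree RMS to 4–12 degrees RMS
on the simulated walking task.

Other unstated details are resolved as follows: initialization averages the
first `n_ma` accelerometer and magnetometer samples (one AR window,
0.5 s at 128 Hz) and evaluates the quaternion measurement on them;
$P_0 = 10^{-2} I_{10}$ (small, because initialization is itself a
measurement); state norms are restored after every time and measurement
update, while the Kalman algebra runs on the unnormalized state; the
measurement quaternion's sign is flipped to the hemisphere of the predicted
quaternion before the innovation is formed; the moving-average window grows
from 1 to `n_ma` during warm-up; and a $10^{-12}$ ridge keeps the
quaternion innovation covariance invertible in the noiseless-static corner
where both $P_q$ and $M_q$ collapse to zero. Since the printed form of the
quaternion process covariance is not positive semidefinite, the standard
first-order mapping of gyro noise onto the quaternion tangent space,
$Q_q = \tfrac{\Delta t^2}{2} \sigma_\omega^2 (I_4 - qq^T)$, is used.

Because all system matrices are block-diagonal over $(g_1, g_2, q_{21})$,
the filter decouples into three blocks that interact only through the
nonlinear constructions ($\omega_{diff}$ uses $q_{21}$; the quaternion
measurement uses $\hat g_i$; $M_q$ uses $\tilde a_i$). The implementation
runs the blocks separately — algebraically identical to the joint 10-state
filter and several times faster — and assembles the full $10\times10$
covariance on request.

## Functional joint centers

For two segments sharing a ball joint, the joint-center acceleration
computed from either sensor must agree up to the frames' relative rotation:
$$a_1 - (\,[\omega_1]_\times^2 + [\dot\omega_1]_\times) r_1 =
  R_{21}\,\bigl(a_2 - ([\omega_2]_\times^2 + [\dot\omega_2]_\times)
  r_2\bigr),$$
where $r_i$ runs from the joint center to sensor $i$'s origin in that
sensor's frame. Gravity cancels (it enters both accelerometers as the same
world vector), so raw specific force can be used directly. Stacking at
least 1500 samples — those with the largest summed angular velocity norms,
ties broken by earlier index — gives an overdetermined linear system solved
by QR least squares. The observations may be scattered; the solution is
order-free. A condition number above $10^8$ raises a degenerate-motion
error: single-axis motion leaves the component of the centers along the
rotation axis unconstrained.

The knee is quasi-1D, so its center estimate slides along the flexion axis.
The axis is found in both sensor frames by minimizing
$\sum_k (\|\omega_1 \times j_1\| - \|\omega_2 \times j_2\|)^2$ with each
axis parameterized by spherical angles (unit norm by construction) and a
BFGS local optimizer started from a deterministic set (the four diagonal
directions of the upper hemisphere applied to both axes, the principal
angular-velocity direction of each sensor, and the three coordinate axes);
the best local optimum is kept, and axis signs are disambiguated by
requiring the two projected angular velocities to correlate positively.
The center correction
$r_i = \hat r_i - j_i\,(\hat r_1 \cdot j_1 + \hat r_2 \cdot j_2)/2$
moves the estimate to the perpendicular foot point nearest the sensors —
the corrected offsets satisfy $r_1 \cdot j_1 + r_2 \cdot j_2 = 0$ exactly.
Note the foot point is the *identifiable* center, not the anatomical one:
any common mediolateral offset of the two sensors from the joint axis
plane reappears as a small constant tilt of the thigh long axis. With
sensors clipped near the segment midline the tilt is a fraction of a
degree; strongly lateral mountings make it a visible but constant AA/IER
offset.

## Anatomical frames and angles

The pelvis fixed axis $e_1$ is the unit vector from the left to the right
hip center (ISB pelvis Z); each thigh fixed axis $e_3$ is the unit vector
from the knee center to the hip center (ISB thigh y). During the most
still window of the static trial (found by an exhaustive scan minimizing
the summed variance of the gyro and accelerometer norm signals; 1 s
default), the thigh axes are rotated into the pelvis-sensor frame with the
SSRO quaternion averaged over the window, and per side $e_2 = e_3 \times
e_1$. The pelvis frame takes $Z = e_1$, $X$ = normalized mean of the two
$e_2$, $Y = Z \times X$; each thigh frame takes $y = e_3$, $x$ = that
side's $e_2$ rotated back into the thigh-sensor frame, $z = x \times y$.
Cross products are re-orthogonalized (estimated axes are not exactly
perpendicular), and a left-handed frame raises an error rather than being
silently flipped, since it indicates a left/right labeling mistake. With a
single instrumented side the pelvis $X$ uses that side's $e_2$ alone, but
the inter-hip axis still requires both hip centers, so the full pipeline is
bilateral.

Angles follow the joint coordinate system: $e_1$ = pelvis Z, $e_3$ = thigh
y, floating axis $e_2 = e_3 \times e_1$. FE is the signed angle from
pelvis X to $e_2$ about Z; IER the signed angle from thigh x to $e_2$
about y with the side-dependent sign; AA is $\mp\pi/2 \pm \arccos(e_1
\cdot e_3)$ by side (the two branches are exact mirrors — the
implementation treats the printed left branch as $+\pi/2 - \arccos$, its
mirror-symmetric form). `jcs_rotation()` provides the exact forward
construction (intrinsic Z, then X with the side's AA sign, then Y with the
side's IER sign), and the extraction inverts it to $10^{-6}$ degrees away
from the $|AA| = 90^\circ$ gimbal pose, where a singular-pose error is
raised. Angle traces are reported at the sensor rate; `resample_trace()`
linearly interpolates extracted angles (not orientations) when a common
comparison rate is needed.

## Agreement metrics

`wrap_difference()` maps angle differences into $(-180, 180]$ (a raw
difference of 350 degrees is really $-10$); `angle_rmse()` is the root mean
*squared* wrapped difference; `agreement_regression()` regresses the
estimate on the reference (slope = tracking, intercept = bias);
`range_of_motion()` is max minus min, excluding the first 10 s of trials
strictly longer than 30 s so start-up transients cannot inflate the range;
`drift_slope()` is the least-squares slope of the wrapped error over time
(wrapped, for consistency with the RMSE convention), with
`drift_wilcoxon()` for testing per-subject drift distributions against
zero (two-sided, exact up to n = 25).

## The simulator

`simulate_ball_joint()`, `simulate_hinge_joint()` and
`simulate_protocol()` forward-generate exactly what the estimators assume:
rigid segments joined at ball or hinge joints, sensors at fixed offsets
with arbitrary mounting rotations, gravity, a shared homogeneous magnetic
field (unit magnitude, 60-degree downward inclination by default — any
non-vertical field works), and additive white noise (defaults: gyro
0.005 rad/s, accel 0.08 m/s^2, mag 0.01 field units — chosen as realistic
for consumer-grade MEMS parts, stated here as the package's own test
conditions). Angular velocities and accelerations are derived from the
orientation and position profiles by 5-point Richardson stencils with a
step of $10^{-4}$ s — far below the sample interval — so the pre-noise
channels satisfy the ball-joint acceleration identity to better than
$10^{-6}$ m/s^2 and the ground truth carries no sample-rate
discretization error. Profiles must be at least twice continuously
differentiable: a kink in an angle trajectory is an impulsive acceleration,
which is why `smooth_ramp()` (a C2 quintic) is provided for trial onsets.

`simulate_protocol()` reproduces the study structure the pipeline expects:
30 s static standing; a ~55 s star-like calibration with large, slow,
multi-plane hip excursions (FE ±40° at 0.20 Hz, AA ±25° at 0.34 Hz, IER
±20° at 0.26 Hz), knee flexion 30±25°, and a deliberate trunk sway
(±15–18° at 0.28–0.40 Hz) — without pelvis motion the pelvis-side rows of
the joint-center system are noise-dominated and the lumbar offset estimate
degrades; and 60 s of walking-like motion (FE-dominant 1 Hz sinusoids with
smaller AA/IER components, pelvis sway, vertical bob). Shank sensors are
generated for the star trial only, mirroring their temporary role for
knee-center estimation. Mountings are random unit quaternions per sensor,
constant across trials.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: soft-tissue artefact (sensors ride on skin,
not bone), gyro bias and scale-factor error, magnetic field *gradients*
between the two sensors (the shared-field assumption is exact in
simulation; indoor environments violate it to a degree), non-rigid joints,
and marker-based reference noise. Accuracy numbers from the synthetic
protocol are accordingly upper bounds on real-world performance.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run the filter on 60 s trials
at 128 Hz (7680 samples), joint-center estimation on 1500 high-motion
observations from ~50 s calibration trials, and three full protocol
pipelines; these sizes mirror the study conditions while keeping a full
run in a few minutes on one core. Zero-phase filtering uses a 4th-order
Butterworth applied forward and backward — the field's standard reading of
"zero-phase low-pass" — with odd end-extension and steady-state
initialization so a constant signal is reproduced exactly. Central
differences fall back to one-sided first-order differences at the end
points (end points are never calibration-critical). Quaternions are
scalar-first, canonicalized to a non-negative scalar part; all estimators
are exactly equivariant under sensor re-mounting, which is the mechanism
behind the placement-robustness property the pipeline tests assert.

## Known limitations

* The gravity measurement cannot separate gravity from body acceleration
  that persists at time scales beyond the correction pole; long sustained
  accelerations (vehicle riding, prolonged leaning) will bias the gravity
  estimates of both sensors.
* Gyro bias is not a filter state; slowly varying bias appears as drift
  that only the magnetic/gravity measurement can cancel.
* The estimated orientation is exactly invariant to the world magnetic
  field's direction only while the gravity estimates are consistent; during
  dynamics the gravity-estimate error couples weakly to the field
  inclination through the heading alignment (about half a degree at
  walking intensities, vanishing as the gravity error vanishes).
* The anatomical frames are only as good as the functional calibration:
  a calibration trial without genuine 3D hip rotation fails (by design,
  with a degenerate-motion error), and knee-center accuracy depends on the
  knee being exercised during it.
* Hip angles are computed for the hip only; other joints would need their
  own axis conventions.
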