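---
title: "Orientation-invariant activity recognition from a pocket-worn IMU: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation-invariant activity recognition from a pocket-worn IMU: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quathar)
```

## The problem

A smartphone carried loosely in a pants pocket records accelerometer and
gyroscope data in whatever orientation it happens to sit, and that
orientation differs between people, between days, and drifts within a
recording. Classical activity-recognition features assume a known device
axis — most damagingly the inclination angle used to separate standing
from sitting/lying, which reads the gravity component along one fixed
sensor axis. Remount the device a quarter turn and that feature swings by
90°, collapsing exactly the distinction (sedentary vs upright) that
matters most for health applications.

`quathar` implements an approach that removes the mounting orientation
from the problem instead of trying to standardize it:

1. estimate the device orientation per sample from gyroscope and
   accelerometer (no magnetometer);
2. delete the heading (yaw) component, which carries no postural
   information;
3. detect walking from rotation-invariant signal energies, and **learn the
   device's "upright" orientation on-line** as the running average of its
   orientation during walking — whenever a person walks, their body is
   upright, whatever the phone's pose in the pocket;
4. express posture as the *shortest rotation angle* between the recent
   average orientation and that learned upright reference: near 0 when
   upright, near 90° when sedentary, for any mounting;
5. fuse the vertical component of the gravity-corrected acceleration with
   barometric pressure in a small Kalman filter to sense stair climbing;
6. classify six activities (sedentary, standing, walking, walking
   upstairs, walking downstairs, postural transitions) with a fixed
   hierarchy of five single-threshold CART stumps.

## Conventions

Quaternions are Hamilton, scalar-first, and map sensor-frame coordinates
to global-frame coordinates (`g_v = q (0, s_v) q*`); the global frame is
right-handed with z up. `q` and `-q` encode the same rotation, and every
angle-valued function in the package is insensitive to that sign. In the
reference mounting the device y-axis lies along the thigh, x mediolateral,
z out of the thigh; nothing downstream depends on this except the
classical (non-invariant) inclination feature, which is the point of the
comparison.

## Attitude estimation and heading removal

The per-sample orientation comes from a complementary/adaptive-gain
estimator: strapdown integration of the gyroscope (first-order, step
`1/fs`), corrected toward the accelerometer's gravity direction when the
accelerometer magnitude is within `xi_a = 1 m/s²` of gravity. The
correction weight starts at `c_a = 0.1` per sample, is boosted when the
short-window variance of the accelerometer magnitude (window `n_short`) is
small relative to the long-window variance (`n_long`) — the quasi-static
moments where the accelerometer is trustworthy — smoothed with constant
`c_m = 0.99`, and rate-limited to `xi_xy/fs` radians per sample. Window
lengths are rate-specific (7/49/7 samples at 100 Hz, 3/19/3 at 40 Hz);
gains and thresholds are not. The gravity reference is averaged over
`n_m` samples *in the estimated global frame*: averaging raw accelerometer
vectors in the rotating sensor frame would bias the direction by several
degrees at gait rotation rates. The correction axis is always horizontal,
so the correction never injects yaw. This estimator is a documented
stand-in honouring the published tuning-parameter semantics; it sits
behind `estimate_attitude()` so a different estimator can be substituted
without touching anything downstream.

Heading removal projects the global-frame image of the device x-axis onto
the horizontal plane and rotates it onto global x, giving yaw exactly zero
while preserving pitch and roll. When that projection is shorter than
`1e-6` (device x-axis near vertical) the heading is undefined; the
previous correction is held — not reset to identity — to avoid step
discontinuities, and the sample is flagged.

**A genuine degeneracy.** The heading reference is the device x-axis. If a
mounting puts that axis along the thigh long axis (vertical when standing)
or along the anterior axis (vertical when seated), the horizontal
projection flips direction with every small oscillation through vertical
and the heading-free series alternates between two families a half-turn
apart; the tilt feature is then not invariant for that mounting. This is a
property of the construction, not of the implementation. The packaged
orientation presets (`orientation_presets()`) therefore span the six
remountings that map the device x-axis to ±x — identity, the three
half-turns, and the two quarter-turns about x itself — for which the tilt
feature is invariant in principle and, on synthetic data, in practice to
well under 2° RMS. Quarter-turn remounts about y or z sit in the
degenerate family; a lateral pocket (a y-quarter-turn) is exactly such a
case, which is consistent with the original study observing reduced — not
perfect — robustness of the tilt feature on real recordings.

## Walking gate and the upright reference

A sample is walking when the squared raw gyroscope magnitude exceeds
5 rad²·s⁻² **and** the sliding unbiased variance (0.25 s window) of the
squared accelerometer magnitude exceeds 10 m⁴·s⁻⁴. Both quantities are
rotation invariant, so the flags are bit-identical under any remounting.
(The printed units of these two thresholds are mutually inconsistent in
the source material; the numeric values are applied to the quantities as
defined here.)

The upright reference is the hemisphere-aligned running mean of the most
recent `⌊2.5 fs⌋` *walking-flagged* heading-free orientations — an index
set that need not be contiguous and persists indefinitely across
non-walking gaps. Averaging flips each incoming quaternion's sign to agree
with the running sum before adding; for orientations clustered within a
few degrees this matches eigendecomposition-based averaging to first order
at a fraction of the cost, and it admits an O(1) streaming update that the
test suite holds to its batch recomputation at every index.

Before the first walking sample the upright orientation is unset: tilt
features carry a sentinel, and the classifier defaults such windows to
`standing` (the neutral inactive class) while flagging them. A session
with no walking at all therefore classifies entirely as cold-start
standing — deliberate, conservative behaviour.

## Vertical velocity

Gravity is removed in the sensor frame using the third row of the
orientation matrix scaled by the reference gravity magnitude, the residual
is rotated into the global frame, and its vertical component drives the
prediction step of a two-state (altitude, vertical velocity) extended
Kalman filter. Barometer samples update the filter through the
international barometric formula `p = p0 (1 − z/44330.77)^5.26`; the two
clocks need not be commensurate (updates fire at the nearest preceding IMU
tick; a barometer silence longer than 2 s flags the output degraded).
Defaults: `sigma_acc = 5 m/s²` (mid-range of the `a_m/2 ≤ σ ≤ a_m` rule
with `a_m = 10`), `sigma_bar = 0.05 hPa`, `p0` estimated from the first
second of barometer data so all altitudes are relative. The filtered
vertical velocity is feature 8; the study itself found the simpler
differential pressure (feature 4) better at stair discrimination, and
nothing here hides that — the best-feature search is free to reject f8.

## Features

Eight features per 2.5 s window, stepped 1.25 s (50% overlap), windows
anchored at the first IMU sample, trailing partial windows dropped:

| | feature | units | invariant? |
|--|---------------------------------------------|-----------|-----|
|1| mean squared band-passed (1–20 Hz) gyro magnitude | rad²·s⁻² | yes |
|2| mean inclination of the low-passed accelerometer about the y-axis | rad | **no** |
|3| mean squared high-passed (dynamic) acceleration | m²·s⁻⁴ | yes |
|4| mean climb-signed differential pressure | hPa·s⁻¹ | yes |
|5| mean squared pitch/roll angular velocity, global frame | rad²·s⁻² | yes |
|6| mean shortest-rotation tilt vs learned upright | rad | yes |
|7| change in f6 across one full window (lag N, i.e. two steps) | rad | yes |
|8| mean Kalman-filtered vertical velocity | m·s⁻¹ | yes |

Filter choices (the original filter specifications are not published):
linear-phase FIR throughout, applied with reflection padding and centred
convolution so filtered streams stay aligned with raw streams; gravity
tracker low-pass at 0.3 Hz, order `2 fs`, renormalized to exact unit DC
gain; gyro band-pass 1–20 Hz, order `fs`, with the upper edge capped at
`0.45 fs` (at 40 Hz the nominal 20 Hz edge would sit on Nyquist). The
differential pressure is signed so that *ascent is positive* (the negative
of the raw pressure derivative): this is the convention under which the
published stair decision rules ("downstairs if ΔP ≤ negative threshold,
upstairs beyond a positive threshold") are physically coherent. f7's lag
is one full window (two steps at 50% overlap) and the two leading windows,
which have no predecessor, carry 0 rather than a sentinel so
classification stays total.

## The hierarchical classifier

A fixed tree, one leaf per class: active vs inactive; inactive → standing
vs sedentary; active → walking-group vs postural transition; walking-group
→ downstairs vs rest; rest → level walking vs upstairs. Each node is a
CART stump trained only on the windows whose *true* label reaches it.
Candidate thresholds are midpoints between adjacent distinct sorted
values; the split minimizes Gini impurity with per-window weights
proportional to the inverse frequency of the window's **six-class** label.
Weighting by the six classes rather than the node's two branch groups
matters: postural transitions are rare (a few windows per
sit-stand cycle), and branch-binary weighting would let the active node
sacrifice the entire transition class for a handful of boundary windows —
precisely the imbalance the uniform-priors device exists to prevent.
Impurity ties break toward the smaller threshold.

Configurations: `original` (features 1–4), `new` (5–8), and `best`, where
each node trains a stump on both members of its designated pair (1↔5,
2↔6, 3↔7, 4↔8) and keeps the lower-impurity one. When the two impurities
tie exactly — common on cleanly separable synthetic data — the
quaternion-derived member is preferred: among splits the training data
cannot distinguish, the one that is orientation-robust by construction is
the rational prior, and it is the very reason these features exist.
Margin-based tie-breaking was considered and rejected: on synthetic data
window-boundary artifacts dominate the margins.

Models serialize to flat `key = value` text (`write_hmha()` /
`read_hmha()`), round-tripping to identical classifications.

## Evaluation

`score()` computes the confusion matrix, Cohen's κ, per-class sensitivity
and specificity, and the total class sensitivity (unweighted mean over
classes). `cross_validate()` performs stratified window-wise k-fold
cross-validation (10 folds by default), pools held-out predictions, and
attaches 95% confidence intervals from a class-stratified bootstrap over
windows (2000 resamples, percentile method) — window-level resampling is
the interpretation consistent with the narrow intervals reported in the
original study, whose CI method is unstated. Fold assignment and bootstrap
are deterministic given the seed. `shannon_entropy()` bins a feature into
64 equal-width bins (configurable, range overridable so train and test
share bins) and reports the joint (bin, class) entropy in bits, with
marginal and class-conditional variants exposed because the exact
distribution binned in the original analysis is ambiguous from its
reported values.

One directional claim from the source analysis does not transfer to this
generator and is deliberately not asserted: lower joint entropy for the
global-frame gyro power (f5) than for the band-passed gyro magnitude
(f1). Under exact rigid virtual rotations f1 is itself exactly invariant
(identical per-axis linear filters commute with a fixed rotation, and the
squared norm is rotation-invariant), so the real-data advantage of f5 —
which arises from non-rigid pocket motion and cross-subject variability —
has no synthetic signal. The suite asserts entropy *stability* across
remounts for both members and the robust tilt-pair direction (f6 < f2)
instead.

## The synthetic session generator

No cohort recordings are distributed with the method, so the package
carries a generator that emulates the statistical structure the pipeline
consumes, with full ground truth. It is deliberately minimal
biomechanics — it exists to test the computation, not to model gait:

* **Posture**: a thigh-fixed frame, long axis vertical when upright,
  pitched 90° when sedentary; postural transitions ease the pitch with a
  cosine profile over 2 s and move the hip down/up by 0.45 m.
* **Gait**: a 0.4 rad pitch oscillation at 1.8 Hz *plus a 0.3 rad
  transverse oscillation a quarter-cycle out of phase*. The transverse
  component keeps the raw gyro magnitude above the walking detector's
  5 rad²·s⁻² gate through the pitch zero-crossings, as in real gait where
  thigh rotation is never single-axis; without it a third of each gait
  cycle would drop out of the walking gate.
* **Bounce**: a vertical oscillation at twice the cadence with ~2 m/s²
  peak acceleration — far above the detector's variance gate (the implied
  variance is ~70× threshold) yet small enough that walking's high-pass
  acceleration power stays below the transition class's, as the published
  decision rules require.
* **Transitions**: a corrective pitch tremor (0.04 rad at 8 Hz) during the
  movement phase gives transitions their in-band gyro signature, and a
  damped 5 Hz, 18 m/s² horizontal effort/impact transient at the end of
  the transition (the seat-contact moment) gives them their
  large acceleration signature. The two are temporally disjoint by
  construction, and the impact is purely linear while the tremor is purely
  rotational, so the walking detector's two gates never fire together
  during a transition and the upright reference is never polluted by
  mid-transition orientations.
* **Stairs**: gait plus an altitude ramp at ±0.3 m/s, with pressure
  generated by inverting the same barometric formula the Kalman filter
  observes through.
* **Sensors**: the gyroscope is the exact discrete body rate of the
  generated orientation sequence plus bias (0.005 rad/s) and white noise
  (0.01 rad/s); the accelerometer is the sensor-frame image of gravity
  plus the second derivative of the generated displacement plus noise
  (0.05 m/s²); the barometer adds 0.03 hPa of noise; the mounting
  quaternion wobbles slowly (0.02 rad) to emulate pocket slack. Sessions
  are bit-reproducible functions of the seed.

What passing tests on this generator do **not** show: robustness to real
gait variability (asymmetry, turning, harmonics), soft-tissue and fabric
artefacts, barometric weather drift, device removal from the pocket
mid-recording (explicitly out of scope), or cohort effects. The generator
shows that the pipeline computes what it claims to compute and that the
orientation-invariance mechanism works; absolute performance numbers on it
are not comparable to performance on human recordings.

## Problem sizes and determinism

The packaged test and acceptance workloads use sessions of one to two
minutes (6 000–9 000 IMU samples at 100 Hz) with all six activities,
six remountings of the same session, and a 40/20 Hz replicate — enough for
every window-level effect the method relies on to express itself, while a
full check runs in well under a minute. Every stochastic step (simulation,
fold assignment, bootstrap) is seeded; pipelines are deterministic given
their inputs.

## Known limitations

* The attitude estimator is a documented substitute with the published
  tuning semantics, not a port of the original (unpublished) filter;
  absolute convergence behaviour may differ.
* The heading-removal degeneracy for device-x-vertical mounts is inherent
  to the construction (see above); real pockets that hold the device in
  such poses will degrade the tilt feature.
* Transient linear accelerations whose magnitude passes through the
  gravity band can briefly tilt the attitude estimate (the gate admits
  them); the estimate recovers within seconds once quasi-static data
  returns.
* `cross_validate()` stratifies by window, not subject; with multiple
  subjects in one table, window-wise folds leak subject identity between
  train and test. Subject-wise evaluation should split sessions before
  feature extraction, as the acceptance workloads do.
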