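---
title: "Turning analysis from multi-location IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turning analysis from multi-location IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnkit)
library(dplyr)
```

## The problem

People turn around constantly during everyday walking, and the way they
turn — how long it takes, how sharply the trunk rotates, how many steps
the feet need, whether head, neck and pelvis rotate in sequence or
"en bloc" — carries clinically useful information, particularly for
Parkinson's disease (PD), where turning is slower, more segmented and
more step-wise than in controls. `turnkit` implements a complete
analysis chain for body-worn inertial measurement units (IMUs) at five
locations — head (HD), neck (C7), lower back (L5) and both ankles
(LA/RA), each providing tri-axial accelerometer (g), gyroscope (deg/s)
and magnetometer (Gauss) streams at a nominal 128 Hz:

1. **Orientation**: yaw (rotation about the vertical axis) per location;
2. **Turn detection**: segmentation of the yaw trace into turns;
3. **Feature extraction**: a pinned 425-entry schema of turning
   characteristics;
4. **Classification**: PLS-DA with VIP feature ranking and leave-one-out
   cross-validation (LOO-CV);
5. **Agreement statistics**: ICC(2,1), Spearman's rho, RMSE and
   Bland–Altman limits of agreement for comparing event series
   (e.g. a human rater against the algorithm);
6. **Simulation**: a synthetic session generator with exact ground truth,
   used throughout the test-suite and usable for power studies.

All user-facing functions take and return tibbles, so results compose
with the usual dplyr/ggplot2 verbs; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Yaw estimation

For the upper-body sensors, yaw is the cumulative trapezoidal integral
of the vertical angular velocity after bias compensation. The
compensation step (`compensate_gyro()`) estimates a constant per-axis
gyro bias as the mean over the *stillest* window of the trace — the
window of length `static_window_s` (default 2 s) minimizing the moving
variance of the gyro magnitude — and subtracts it. Walking protocols
that include a standing pause provide such a window naturally; if no
window has variance below `still_var_max` (default 25 deg²/s², i.e. a
5 deg/s SD), the whole-trace median is used instead, with a warning. An
optional zero-phase high-pass (default cutoff 0.02 Hz, off by default)
can additionally remove slow residual drift; with the still-window
estimate and sessions of a few minutes it is not needed. Upper-body yaw
integrates the sensor-frame vertical gyro component (per the sidecar's
axis mapping) rather than a gravity-aligned projection; for sensors worn
approximately upright the two coincide to first order, and this is
recorded here as an assumption.

Ankle sensors rotate sharply during swing, so pure integration drifts;
`fuse_orientation_9dof()` instead runs a two-state Kalman filter (yaw
and gyro bias) that propagates yaw with the gyroscope and corrects it
with the tilt-compensated magnetometer heading, the tilt coming from the
low-passed accelerometer. The contract is a *property*, not a specific
filter: on simulated data the estimate must track a true rotation within
a couple of degrees and hold drift below 5° over a stationary minute.
Any quaternion AHRS filter meeting those bounds could be substituted.
Without a magnetometer the function degrades to bias-compensated
integration (6-DOF) with a warning.

Sign convention: counter-clockwise about the anatomical vertical axis,
viewed from above, is positive; a **left turn therefore has negative
yaw displacement**, and event `direction` is derived from that sign.

## Turn detection

Detection follows a zero-crossing rule on the vertical angular velocity:
a candidate segment is a maximal interval of constant sign. Raw zero
crossings are fragile under sensor noise, so sign determination uses a
deadband (default 5 deg/s, `deadband_dps`); each candidate segment is
then *extended outward to the nearest true zero crossing*, so the
reported boundaries are still those of the literal rule and
`deadband_dps = 0` reproduces it exactly. Each segment carries its yaw
displacement (trapezoidal integral over the segment).

Gradual turns are merged: consecutive same-direction segments, each with
displacement above 10°, separated by less than 0.5 s, become one turn
whose angle is the sum of the sub-angles ("intra-turn duration" is read
as the *gap* between sub-turns). Sub-threshold jitter segments (< 10°)
neither merge nor break a chain — a deliberate reading of an ambiguous
rule, chosen because noise-induced micro-reversals otherwise split
genuine slow turns. Merging is idempotent and the sub-turn angles always
sum exactly to the merged angle.

Accepted turns satisfy per-location thresholds: |angle| ≥ 90° at the
lower back, ≥ 30° at head, neck and ankles, with duration in
[0.5 s, 10 s) (lower bound inclusive, upper exclusive). For each
accepted lower-back turn the ankles are relabelled by role — **inner**
(right ankle for a right turn, left for a left turn) and **outer** — to
remove turn-direction bias from ankle features. Steps are counted per
role inside the lower-back turn window padded by ±0.5 s (ankle rotation
can lag the trunk): every *unmerged* ankle rotation ≥ 30° in the turn's
direction is one step. Step counting deliberately uses unmerged
segments: successive swings of one foot are separated by stance gaps
well under 0.5 s, and gradual-turn merging would collapse them into a
single rotation.

## The 425-feature schema

`feature_manifest()` pins the schema: 109 characteristics per upper-body
location (21 spatiotemporal + 88 signal-based; 327 total) and 49 per
ankle role (9 spatiotemporal + 40 signal-based), for a grand total of
425. The upper-body spatiotemporal set comprises turn/left/right counts;
mean, min, max and variability of turn time and of turn-angle magnitude;
mean and variability of overall angular velocity (angle/duration,
deg/s), of peak angular frequency (max |ω| within the turn, rad/s) and
of the mean angular frequency over a 0.1 s window at the turn start, mid
and end (rad/s). "Variability" is the sample SD across turns — chosen
over the coefficient of variation for unit transparency, since the
quantity is otherwise undefined.

Signal-based characteristics are computed per turn and averaged across
turns. Both acceleration and angular velocity are zero-phase low-pass
filtered (4th-order Butterworth, 20 Hz; forward–backward filtering
preserves event timing), the resultant R = √(VT² + AP² + ML²) is added
as a fourth axis, and per window each axis is linearly detrended before
RMS computation (removing gravity and slow posture drift from the
window). Jerk (Δa/Δt, g/s) and angular acceleration (Δω/Δt, rad/s²) are
central differences of the *filtered but non-detrended* signals: a
derivative is already invariant to the constant offset detrending
removes, whereas detrending a window would also subtract the window's
mean slope and bias the derivative itself (the jerk of a pure
acceleration ramp must equal its slope). The per-ankle signal set is the
RMS blocks (acceleration and angular velocity, 4 axes × 4 phases) plus
overall jerk and angular-acceleration RMS per axis; pinning the ankle
total at 9 + 40 = 49 is what makes 327 + 2×49 = 425 internally
consistent.

Phases (start/mid/end) for signal statistics default to equal thirds of
the turn window; a `"window0.1"` mode using 0.1 s windows (as for the
angular-frequency features) is available via `phase_mode`. Missing
locations yield `NA` features, never silent zeros, and
`build_feature_matrix()` flags all-`NA` columns.

## PLS-DA classification

`fit_plsda()` is a NIPALS PLS1 regression of dummy-coded labels (+1 for
the positive class — PD when present, otherwise the minority class; −1
otherwise) on column-standardized features, used as a discriminant
classifier with a 0 threshold (a score of exactly 0 goes to the control
class, deterministically). The component count is selected with the
cumulated Q² index: at each component count, Q² = 1 − PRESS/SS with
PRESS from leave-one-out refits in which standardization is redone
inside every training fold (no leakage; the alternative of standardizing
once globally was rejected). The retained count is the largest k at
which Q² is still increasing and positive; if no component achieves
Q² > 0 the model falls back to one component and is flagged.
`evaluate_loo()` uses a fixed component count across folds — either
supplied or selected once on the full data; re-running the Q² selection
inside every fold would nest LOO within LOO at cubic cost for little
benefit at these sample sizes, and the fixed-k choice is recorded here.

Feature importance is the standard VIP score,
VIP_j = √(p · Σ_k SSY_k w²_jk / Σ_k SSY_k), whose squared values average
to exactly 1 across features; values above 1 are conventionally read as
highly influential and 0.8–1.0 as moderately influential. A
per-component VIP matrix (√p |w_jk|) is available for screening features
influential in any single component.

## Agreement statistics

`icc_2_1()` implements the two-way random-effects, absolute-agreement,
single-measures intraclass correlation from the ANOVA mean squares:
(MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE)). The test-suite checks
it against an independent sums-of-squares oracle (and `aov()`) to 1e-10.
Limits of agreement follow the Bland–Altman convention: bias ±
1.96·SD of the paired differences (1.96, not 2 — the standard normal
95% band), with the percentage form dividing by the grand mean of the
pairwise averages, which resolves the ambiguity in "percentage of the
mean". `compare_event_series()` matches events 1:1 by nearest start time
within a configurable tolerance (default 2 s) — a rule this package has
to define since matched validation sets need not align index-by-index —
and reports starts and ends separately. `compare_groups()` routes each
feature to Student's t-test (equal variances) or the Mann–Whitney U test
by Shapiro–Wilk normality in both groups (p > 0.05), with no
multiple-testing correction by default (a Benjamini–Hochberg option
exists via `p_adjust`).

## The synthetic session generator

`simulate_session()` emulates intermittent straight walks separated by
~180° turns: standing still, walking bouts, and per-turn minimum-jerk
yaw S-curves. Minimum-jerk profiles have exactly zero angular velocity
and acceleration at their endpoints, which makes the ground-truth turn
boundaries kinematically sharp — the reason this profile was chosen over
a raised cosine. Defaults reflect the emulated protocol: 3 turns
(i.e. four straight walks), turn angle 180 ± 10°, and two presets:

| parameter | control-like | PD-like |
|---|---|---|
| turn duration (s) | 2.5 ± 0.7 | 3.5 ± 1.0 |
| segment lag head→neck→L5 (s) | 0.15 | 0 (en bloc) |
| steps per turn | ~3 | ~5 |
| cadence (Hz) | 1.8 | 1.6 |
| movement acc. amplitude (g) | 0.08 | 0.05 |

Gyro signals carry a constant per-axis bias (drawn U(−1, 1) deg/s unless
fixed) plus Gaussian noise (default SD 1 deg/s); the accelerometer
carries gravity, a double-cadence vertical oscillation that persists
through turns (people step through turns; its amplitude is a group
trait, reduced in the PD-like preset consistently with the reduced
movement amplitude this phenotype shows), and noise (SD 0.02 g); the
magnetometer is a constant field rotated by the local yaw plus noise
(SD 0.005 Gauss). Ankle yaw is step-quantized: each turn's angle is
split into discrete minimum-jerk swings, the outer foot offset by half a
slot, so step counts have exact ground truth. Turn durations, angles,
step counts and per-subject jitter (duration ± 0.25 s, cadence
± 0.1 Hz between subjects in `simulate_cohort()`) all derive from one
seed; two runs with the same seed are bit-identical.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: roll/pitch dynamics at the ankles (gravity
is held nominal), turn-strategy variety (pivot vs step turns), freezing
episodes, magnetic disturbances, soft-tissue artefact, and rater
idiosyncrasies beyond Gaussian boundary jitter. Results on real
recordings depend on those factors; the synthetic suite validates the
*algorithmic* contracts, not clinical performance.

## Numerical choices and degenerate inputs

* Time is 0-based seconds; events are half-open `[start_s, end_s)`.
* Boundary comparisons: ≥ for angle thresholds and the 0.5 s duration
  floor, < for the 10 s ceiling.
* Unit conversions happen only as declared by the session sidecar —
  never guessed; a missing sidecar or a missing L5 file is fatal, a
  missing other location degrades with a warning and `NA` features.
* A turn window shorter than 3 samples is skipped with a warning in
  signal-feature extraction; zero accepted turns yield all-`NA` features
  with `n_turns_used = 0`.
* Constant feature columns are dropped (with a warning) before PLS-DA;
  fold-constant columns inside LOO standardize to 0.
* Zero total variance makes ICC undefined (`NaN` with a warning), as
  does a zero grand mean for LOA%.

## Problem sizes used in the validation suite

The bundled tests and the acceptance script run, per invocation: 50
seeded noisy sessions for boundary-recovery statistics; 100 seeds of
permuted-label LOO-CV (n = 40, 20 noise features) for the chance-level
check; 20 seeds of VIP-recovery cohorts (n = 40, 100 features, 5
informative); a 16-subject simulated cohort for end-to-end LOO accuracy;
and 10,000 null features (n = 20 + 20) for type-I calibration of the
group tests. These sizes give stable statistics (binomial SE ≈ 0.2 % on
the type-I rate, ≈ 1 % on the permutation mean) while keeping a full run
in minutes on a laptop.
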