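---
title: "Synthetic IMU training data for gait kinematics estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic IMU training data for gait kinematics estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsynth)
```

## The problem

Recurrent neural networks can estimate three-dimensional hip and knee
rotations during walking from a few body-worn inertial measurement units
(IMUs), but they are data-hungry, and collecting synchronized optical motion
capture plus IMU data at scale is expensive. `gaitsynth` implements the
alternative: augment existing joint-angle trajectories with cheap numerical
operators, push the augmented kinematics through a rigid-body model of the
left lower limb to obtain *synthetic* IMU signals that are consistent with
the new kinematics by construction, and train bidirectional LSTM
(BiLSTM) sequence-to-sequence models on the enlarged dataset. The package
also provides a fully synthetic multi-subject cohort generator so that the
entire pipeline — augmentation, simulation, training, evaluation, and the
statistical comparison of training-set variants — can be exercised and
tested end to end with known ground truth.

Terminology used throughout: **simulated** IMU data are computed from
source kinematics; **synthetic** IMU data are computed from *augmented*
kinematics that were never measured; **measured-emulated** data are
simulated signals degraded with sensor noise and mounting errors to play
the role of real recordings in experiments.

## Rigid-body model and virtual IMUs

The kinematic chain is a serial left lower limb: pelvis → thigh → shank →
foot. Hip and knee have three rotational degrees of freedom, the ankle is a
hinge; seven joint angles in total, in the fixed column order
`r paste(angle_columns(), collapse = ", ")`. Each segment frame has its
origin at the proximal joint center and its distal joint at `(0, 0, -L)` in
the neutral pose; the earth frame is X forward, Y left, Z up.

Joint rotations are intrinsic Euler sequences about the mediolateral,
anteroposterior and longitudinal axes — (Y, X, Z) of the parent frame —
with per-joint axis signs arranged so that flexion, adduction and internal
rotation are positive in their clinical sense for a left limb. No
convention for the sequence is universal in the literature; this one is
fixed, documented, and self-consistent across the whole pipeline
(`joint_quaternion()` / `joint_angles_from_quaternion()` are exact
inverses, which the test suite verifies to below `1e-8` degrees over a
thousand random poses).

A trial (`kinematic_trial`) stores the time base, the seven angle channels
in degrees, and the pelvis root pose. `forward_kinematics()` composes
quaternions down the chain to give every segment's earth-frame pose, plus
the pose of any rigidly mounted sensor (`sensor_mount`).

Angular velocity is computed by the exact recursion
`omega_child = omega_parent + R_parent * omega_joint`, where the joint term
follows analytically from cubic-spline derivatives of the angle channels
(and of the root quaternion for the pelvis, via `omega = 2 q' q*`). Because
the trial's continuous trajectory is *defined* as its spline interpolant,
this recursion is exact rather than a finite-difference approximation; no
resampling is involved. Point accelerations are the second time-derivative
of a body-fixed point's earth-frame position, evaluated by re-running the
forward kinematics on an internal 1000 Hz grid and differentiating the
position spline twice. Accelerometer channels are *free* accelerations
(gravity excluded) reported in the earth frame, while gyroscope channels
are reported in the sensor's own frame — a deliberate asymmetry that
mirrors how processed research-grade sensor data are commonly compared,
and one to note before comparing against raw commercial IMU output.

An independent finite-difference oracle (`fd_imu_oracle()`: axis-angle
differences of the orientation sequence, 5-point second differences of
position) backs both the test suite and `validate_simulation()`, which
reports per-channel Pearson r and RMSE between the analytic and
finite-difference routes. On generated cohorts all 24 sensor channels agree
with r > 0.999.

## Augmentation operators

Five operators create synthetic kinematics from a source cycle, all sharing
their random draw across the seven angle channels of a trial:

* **Magnitude offset** — one draw from N(0°, 5°) added to every sample of
  every channel.
* **Magnitude warp** — a natural cubic spline through 7 knots drawn from
  N(1, 0.2), placed uniformly over the cycle (endpoints included),
  evaluated at the sample times and multiplied element-wise into every
  channel.
* **Offset + warp** — warp first, then offset (the RNG stream is consumed
  in that order).
* **Time warp** — a spline through 7 N(1, 0.2) knots is evaluated at the n
  sample positions, cumulatively summed and divided by n to give a monotone
  map `tau` of cycle fractions; all channels (and the pelvis pose) are
  re-interpolated at `tau`. The indexing places source sample i at fraction
  i/n, so constant unit knots give the exact identity; `tau` is clamped at
  1 rather than rescaled. The output stays on the original n-sample grid,
  so event timing changes *within* the cycle while the padded-sequence
  bookkeeping downstream is unaffected.
* **Time + magnitude warp** — time warp first, then magnitude warp.

`augment_dataset()` applies all five to every input stride — a 5:1
expansion (3943 strides become 19,715 augmented sets, 3451 become 17,255) —
and tags each output with its method and source. No plausibility filter is
applied; the conservative perturbation scales are the control. Magnitude
operators act on joint angles only; the pelvis root is only ever
time-warped, keeping the rigid-body interpretation intact. Crucially,
synthetic IMU signals are always *regenerated* from the augmented angles
via the forward model (`simulate_cycle_imu()`), never warped directly, so
every input/label pair remains physically consistent.

## The synthetic cohort generator

`generate_cohort()` emulates a lab study: by default 30 subjects × 3
walking speeds (slow 1.3 s, self-selected 1.1 s, fast 0.9 s nominal cycle
duration) × 15 trials × 3 strides ≈ 4050 strides, matching the order of
magnitude of a real multi-speed cohort. Anthropometry is drawn per subject
(thigh N(0.42, 0.02) m, shank N(0.40, 0.02) m, and so on); gait style
varies by smooth per-channel amplitude scaling (±10%), angular offsets and
phase shifts (±3% of the cycle); stride-to-stride variation adds duration
jitter (±3%) and small amplitude/phase perturbations blended with a window
that vanishes at cycle boundaries so strides join smoothly. The gait phase
itself is a C²-continuous natural spline through the cycle boundary times —
a piecewise-linear phase would leave acceleration spikes at every boundary.
All template keypoints are configuration values shaped after normative
adult gait curves; they are *not* measurements, and the generator makes no
attempt to model pathological gait.

**Heel-strike ground truth.** The chain has no ground contact, so the
heel's height minimum falls at mid-stance (~42% of the cycle) rather than
at initial contact. The generator therefore *defines* its stored event as
the per-cycle argmin of heel height computed through the subject's own
chain, and the template was designed so each cycle has exactly one deep
minimum: the loading-response knee flexion bump is kept soft (15°) and
early plantarflexion small (−3°), and each trial is trimmed a quarter-cycle
after the last event so no orphan partial swing remains. The matching
detector (`detect_heel_strikes()`) takes local minima of heel height with a
0.6 s minimum separation — below the shortest generated stride (~0.72 s),
above the ~0.5 s spacing of the secondary stance dip — and keeps only
minima in the lowest 12% of the height range, which rejects the shallow
late-swing dip. Within the generator's parameter space this detector
reproduces the stored events exactly; on real data, where the heel does
strike the ground, both the event definition and these two thresholds
would need revisiting.

**Measured emulation.** `emulate_measured()` degrades clean simulated
traces with per-channel white Gaussian noise (defaults: 0.03 rad/s gyro,
0.2 m/s² accelerometer), one fixed mount-misalignment rotation per trial
(N(0°, 2°) per axis), and optionally an exponentially damped ~10 Hz
oscillation at heel strikes emulating soft-tissue artifact (off by
default). This is a deliberately simple error model: it has no bias
random-walk, no magnetic disturbance, and its soft-tissue term is a single
damped mode. Passing tests on this testbed therefore demonstrates internal
consistency of the pipeline, not performance on real sensors.

## Preprocessing

Measured-role IMU streams can be resampled with cubic interpolation
(`resample_cubic()`, mirroring a 40 → 100 Hz acquisition pipeline; the
simulator produces 100 Hz directly, avoiding a pointless down-up round
trip). All channels — IMU and angle targets alike — pass once through a
zero-phase second-order Butterworth low-pass at 6 Hz. Zero-phase (forward
and backward) application was chosen because the pipeline is offline and
phase lag would misalign inputs and labels; the effective magnitude
response is the square of the single-pass response. `signal::filtfilt`
performs no edge treatment, so `butter_lowpass()` pads with an odd
reflection (8/fc seconds per side), which passes constants to within 1e-9.
At 100 Hz the digital filter attenuates a 20 Hz tone to 0.47% — somewhat
stronger than the 0.81% the analog magnitude formula suggests, as expected
from bilinear frequency warping at 40% of Nyquist; the passband (1 Hz)
matches the analog response within 2%.

Cycles are cut strike-to-strike, rejected if longer than 200 samples, and
packed (`pad_and_pack()`) into the fixed training geometry: a 200 × 24
input (sensor-major order pelvis, thigh, shank, foot; per sensor
accelerometer x, y, z then gyroscope x, y, z), a 200 × 3 target (one
joint's flexion, adduction, rotation), and a trailing-zero validity mask.
Splits are always subject-wise (`make_split()`), and `assemble_variant()`
enforces the leakage guard: synthetic samples derived from a held-out
subject's strides can never enter a training set.

## The BiLSTM models

Two independent models map the 24 IMU channels to the three rotations of
one joint (hip or knee). The architecture is a bidirectional LSTM (hidden
size per direction H), a per-timestep fully connected layer 2H → H with
ReLU, dropout 0.5, and a linear layer H → 3. The tuned full-scale sizes are
one layer with H = 32 (hip) and H = 128 (knee); `tune_hyperparameters()`
reproduces that selection protocol as a grid search under subject-wise
5-fold cross-validation, choosing the minimum mean validation RMSE with
ties broken toward the smaller model. Training uses Adam (learning rate
0.001, beta1 0.9, beta2 0.999 — the conventional default for the third
moment constant, which the protocol we follow leaves unstated), batch size
50, 100 epochs at full scale, and a mean-squared-error loss masked so that
padded timesteps contribute exactly zero gradient (verified against finite
differences); an unmasked mode exists for comparison. The engine is
written in RcppArmadillo with full backpropagation through time; seeding
covers initialization, shuffling and dropout, making training runs
bit-reproducible on a given platform.

Inputs *and* targets are z-scored per channel with statistics from the
training split only (stored in the model; predictions are returned in
degrees). The channels mix units of m/s², rad/s and degrees, and without
normalization the optimizer spends thousands of updates just locating the
target offsets. Whether the original protocol normalized is unknown; this
choice is ours and is applied identically across all training-set variants,
so comparisons between variants are unaffected.

The head's layer sizes (2H → H → 3), the ReLU nonlinearity and the
presence of biases are likewise unspecified upstream and exposed in code
as the package's own choices. A forward-only LSTM ablation flag exists;
reversing the input time axis changes predictions, confirming the model is
genuinely non-causal.

## Evaluation and statistics

`cycle_metrics()` computes, per test cycle and degree of freedom over
unmasked samples: Pearson r, RMSE in degrees, and nRMSE in percent.
nRMSE is normalized by the reference signal's per-cycle range — the
dominant convention in this literature (it also explains why small-range
channels such as internal rotation show large nRMSE). A constant reference
makes nRMSE undefined; such cycles are flagged and excluded from
aggregates. `aggregate_table()` reports mean ± sample SD (n−1) per variant
and DoF plus per-joint averages (the arithmetic mean of the three DoF
means). `manova_tukey()` runs a one-way MANOVA (Wilks' Λ with the F
approximation) on the per-cycle 6-dimensional RMSE vectors with training
variant as the factor — the per-cycle unit of observation is a
configuration choice; a per-subject aggregation can be applied upstream —
followed by per-DoF one-way ANOVA with Tukey HSD contrasts at α = 0.05.
The implementation is calibrated in tests: identical groups give Λ ≈ 1 and
p ≈ 1, groups separated by 10 pooled SDs give p < 0.001, and the
parametric p agrees with a permutation test within Monte-Carlo error.

## The desk-scale experiment

`run_experiment()` wires everything together: generate a cohort, build
measured-emulated and clean pairs, augment the training subjects' strides
5:1, regenerate synthetic IMU signals, train one model per variant
(measured / synthetic / measured+synthetic) and joint, and evaluate on the
held-out subjects' measured-role data. The shipped default scale — 8
subjects (2 held out), 3 speeds × 2 trials × 3 strides (144 measured
strides, 540 synthetic), H = 16, 25 epochs — was chosen so a full
three-variant, two-joint run takes minutes on one CPU core; the problem
sizes are stated here as the package's defaults, and everything scales up
by argument. Under the default noise model the combined training set
consistently improves hip-average RMSE over measured-only training
(roughly 3.2° → 2.2° at this scale, seed-dependent), reproducing the
qualitative finding that motivates the whole approach. Absolute accuracies
at desk scale are not comparable to a full-size study — the cohort is
smaller, the models are smaller, and the "measured" data are an emulation.

For the parameter-recovery check the package uses a 540-cycle noiseless
cohort (10 subjects × 3 speeds × 6 trials × 3 strides), a random 100-cycle
holdout, and a knee model with H = 64 trained 60 epochs; that
configuration reaches a 3-seed median knee flexion RMSE of about 1.6° —
well under the 3° bound the package tests against — while smaller hidden
sizes shrink the margin.

## Numerical choices and degenerate inputs

* Quaternions are kept normalized at every construction; trial validation
  rejects non-unit root quaternions beyond 1e-9.
* Spline interpolation is `stats::splinefun`: "fmm" for signals, "natural"
  for warp knots (the knot spline's behavior between widely spaced knots is
  gentler), "periodic" for gait templates.
* Time-warp maps are clamped at cycle end rather than rescaled; monotone by
  construction for positive knot values.
* Fewer than 2 detected heel strikes yields an empty segmentation with a
  warning, not an error; a flat heel trajectory yields no events.
* Cycles longer than 200 samples are rejected by name. At 100 Hz this
  admits strides up to 2 s, comfortably above the slow-speed template.
* MANOVA falls back to per-DoF ANOVA with a diagnostic if the within-group
  covariance is singular.

## Known limitations

The testbed's realism has sharp edges, all deliberate: no ground contact
(hence the mid-stance event definition), a single-mode soft-tissue model,
no sensor bias drift or magnetometer, no pathological gait, left limb
only, and normative templates rather than measured curves. Results on this
testbed validate the machinery — the rigid-body differentiation, the
operators' distributional contracts, the leakage-free data handling, the
optimization — and the *direction* of the synthetic-data benefit, not
clinical accuracy numbers.
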