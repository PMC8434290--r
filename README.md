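# gaitsynth

Synthetic IMU training data for wearable-sensor gait analysis, and BiLSTM
models that estimate 3-DoF hip and knee rotations from four body-worn
inertial measurement units (pelvis, left thigh, shank, foot).

## The problem

Sequence models that map IMU streams to joint kinematics need far more
paired training data (synchronized motion capture + IMU) than most labs can
collect. `gaitsynth` implements the synthetic-data route around that
bottleneck:

1. **Augment** measured joint-angle cycles with five numerical operators —
   magnitude offset (one draw from N(0°, 5°) per trial), magnitude warp
   (natural cubic spline through 7 knots ~ N(1, 0.2)), their combination,
   time warp (cumulative-sum spline map of the cycle fractions), and time +
   magnitude warp — a 5:1 expansion of the training set.
2. **Simulate** the IMU signals belonging to each augmented trajectory
   through a rigid-body model of the left lower limb (pelvis–thigh–shank–
   foot; 3-DoF hip, 3-DoF knee, hinge ankle). Gyroscopes are the exact
   recursive rigid-body angular velocity rotated into the sensor frame,
   `R_sensor(t)' ω(t)`; accelerometers are free (gravity-less) point
   accelerations in the earth frame from analytic spline differentiation.
   Inputs and labels therefore stay physically consistent — signals are
   regenerated from the warped kinematics, never warped directly.
3. **Train** per-joint BiLSTM sequence-to-sequence models (200 × 24 inputs,
   200 × 3 targets, masked MSE over zero-padded cycles, Adam with lr 0.001,
   β₁ 0.9, β₂ 0.999, dropout 0.5, batch 50) on three training-set variants
   — measured only, synthetic only, measured + synthetic — and compare
   per-cycle RMSE/nRMSE/Pearson-r across variants with a one-way MANOVA
   (Wilks' Λ) and Tukey HSD contrasts.

Because no public dataset accompanies this workflow, the package includes a
fully synthetic multi-speed gait cohort generator (normative templates,
per-subject anthropometry and style, ground-truth heel-strike events, and a
measured-sensor emulation with noise and mount misalignment) so the whole
pipeline runs end to end with known truth. The BiLSTM engine itself is
implemented in RcppArmadillo (full BPTT, seeded and bit-reproducible).

## Worked example

```r
library(gaitsynth)

# a small cohort: 8 subjects, 3 speeds, ground-truth heel strikes
cohort <- generate_cohort(n_subjects = 8, trials_per_speed = 2,
                          strides_per_trial = 3, seed = 1)
cohort
#> gait_cohort: 8 subjects, 48 trials, 144 strides @ 100 Hz

# full ablation at desk scale: augment 5:1, simulate, train, evaluate
ex <- run_experiment(joints = "hip",
                     variants = c("measured", "measured+synthetic"),
                     seed = 1)
ex
#> gait_experiment: 108 measured + 540 synthetic training cycles, 36 test cycles
#>              variant         dof rmse_mean    r_mean
#>             measured hip_average  3.247834 0.9641226
#>   measured+synthetic hip_average  2.194131 0.9897331
#> MANOVA p = 1.4e-33
```

Those two numbers are the headline comparison: hip-joint RMSE averaged over
flexion/adduction/rotation on held-out subjects, for a model trained on
measured-emulated data alone versus the same measured data plus the 5:1
synthetic expansion. Adding synthetic data cuts the error by roughly a
third at this scale (exact values vary with the seed) while the Pearson
correlation rises — the direction that motivates synthetic-data training.
`ex$records` holds the per-cycle metrics, `ex$table` the full aggregate
table, and `ex$stats` the MANOVA/Tukey comparison when three variants and
both joints are run.

The simulation itself can be checked against an independent
finite-difference oracle at any time:

```r
rep <- validate_simulation(cohort, n_trials = 3)  # 24 rows: sensor x channel
min(rep$r)
#> [1] 0.9999589
```

## Package layout

| Area | Functions |
| --- | --- |
| Rigid-body chain | `limb_chain`, `sensor_mount`, `forward_kinematics`, `body_angular_velocity`, `point_acceleration`, `heel_trajectory` |
| Virtual IMUs | `simulate_imu`, `emulate_measured`, `fd_imu_oracle`, `write_imu_csv` |
| Augmentation | `magnitude_offset`, `magnitude_warp`, `offset_and_warp`, `time_warp`, `time_and_magnitude_warp`, `augment_dataset` |
| Preprocessing | `resample_cubic`, `butter_lowpass`, `detect_heel_strikes`, `segment_cycles`, `pad_and_pack`, `make_split`, `assemble_variant` |
| Cohort generator | `gait_template`, `subject_spec`, `generate_cohort`, `build_paired_dataset`, `simulate_cycle_imu` |
| Networks | `bilstm_config`, `build_model`, `train_bilstm`, `predict_bilstm`, `tune_hyperparameters`, `make_folds` |
| Evaluation | `cycle_metrics`, `aggregate_table`, `manova_tukey`, `run_experiment`, `validate_simulation` |
| Workflow | `validate_config`, `run_pipeline`, `read_mot`/`write_mot`, `read_chain_config` |

The methods vignette (`vignettes/synthetic-imu-gait.Rmd`) documents the
model conventions, the augmentation contracts, the generator's design and
its limitations, and every numerical choice.
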