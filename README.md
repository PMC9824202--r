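# skatekin

Lower-limb skating kinematics from wearable inertial sensors.

Hockey-skating performance assessment traditionally needs a motion-capture
lab. This package implements the wearable alternative for R users in
biomechanics and sports science: it estimates 3D hip, knee and ankle joint
angles of a skating stride from four body-worn IMUs (pelvis, thigh, shank,
skate), validates them against a marker-based reference, and asks whether
joint-angle features known to separate high- from low-calibre skaters
actually do so — with a fully synthetic, ground-truth-bearing cohort
generator so that every stage is testable without recorded data.

## The method

1. **Orientation estimation.** Raw gyro/accel/mag channels are low-pass
   filtered (4th-order Butterworth, 15 Hz, zero-phase) and fused into sensor
   orientations `q(t)` by a complementary filter: strapdown quaternion
   integration of the gyroscope with per-sample proportional corrections
   toward gravity (accelerometer, gated by an acceleration-magnitude trust
   band) and the magnetic field (magnetometer, yaw-only).
2. **Calibration.** A still standing window gives the constant rotations
   sensor → plate (from plate markers) and plate → body (from anatomical
   landmarks, Cappozzo-style recipes), hence sensor → body; composing it
   with the fused stream yields segment orientations.
3. **Joint angles.** The relative rotation of adjacent segments is
   decomposed in the Grood–Suntay joint coordinate system:
   `R_prox^T R_dist = R_z(flexion) R_x(adduction) R_y(rotation)`
   with flexion about the proximal mediolateral axis, rotation about the
   distal longitudinal axis, adduction about the floating axis.
4. **Validation.** Per-trial RMS error between IMU-based and marker-based
   angles per joint and axis, averaged over each participant's trials, then
   summarized as cohort boxplot statistics.
5. **Calibre classification.** Twelve stride features (angle values at
   initial contact / push-off, ranges, CoM-proxy dispersions) are screened
   by a two-treatment Friedman rank test over the five trial blocks
   (p ≤ 0.05); selected features (or the first three principal components)
   feed a subject-wise cross-validated KNN (k = 1…15, 12 repeats × 3
   held-out participants) reporting sensitivity, specificity, accuracy and
   precision.

## Worked example

Generate a synthetic 12-participant cohort (6 high-, 6 low-calibre, five
trials each) with the default calibre effects injected into three features,
screen the features, and cross-validate the classifier:

```r
library(skatekin)

co  <- generate_cohort(seed = 1, signals = FALSE)
sel <- select_features(co$features)
round(sel$p, 3)
#>              dorsiflexion_range  ankle_adduction_at_push_off_end
#>                           0.025                            0.655
#>  hip_flexion_at_initial_contact        hip_adduction_at_push_off
#>                           0.655                            0.025
#> hip_adduction_at_initial_contact        dorsiflexion_at_push_off
#>                           0.655                            0.655
#>        knee_flexion_at_push_off              hip_flexion_average
#>                           0.025                            0.655
#>                      com_ml_iqr                     com_ml_range
#>                           0.655                            0.655
#>                com_sagittal_iqr               com_sagittal_range
#>                           0.655                            0.655
```

Exactly the three features carrying injected group effects reach the
discrete two-treatment Friedman significance atom (p = 0.025: one group
ahead in all five trial blocks); every null feature sits on a larger atom.
The selected features separate the synthetic groups cleanly:

```r
res <- run_classification(co$features, seed = 1)
res$metrics[c(1, 3, 5), ]
#>   k sensitivity specificity accuracy precision
#> 1 1         100         100      100       100
#> 3 3         100         100      100       100
#> 5 5         100         100      100       100
```

(The generator's default effects are separable by construction; real
cohorts are not — see the methods vignette.)

The full signal-level pipeline runs the same way from CSV files on disk
(`write_cohort()` / `run_pipeline()`), or via the thin CLI wrapper:

```sh
Rscript inst/cli/skatekin.R simulate --out data/ --seed 1
Rscript inst/cli/skatekin.R all --data data/ --pca off --seed 1
```

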