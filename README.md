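# stackpose

Full-body human pose estimation from only **five inertial sensors** (pelvis,
both lower arms, both lower legs), for biomechanists and movement scientists
who want dense motion capture without instrumenting all 23 body segments.

Sparse-sensor pose estimation exploits the redundancy of human movement: the
orientations of a few distal segments, expressed relative to the pelvis,
carry enough information to reconstruct the remaining segment orientations.
`stackpose` implements and compares two learned estimators over the same
inputs:

- **SINN** (stacked-input neural network): a shallow fully-connected
  regressor fed a *stacked input vector* — the pelvis-relative features of
  `P` past, the current, and `F` future samples, spaced `I` frames apart at
  sampling rate `f_s`. The stacked input length is `SIL = P + 1 + F`, the
  inter-sample spacing `Δt = I / f_s`, and using future samples costs an
  acquisition delay of `F · I / f_s` seconds. Temporal coherence is learned
  from the window instead of being built into the architecture.
- **RNN**: a bidirectional LSTM baseline consuming the same window as a
  `D × SIL` sequence, with explicit recurrent temporal modelling.

Both are trained separately for the upper body (12 segments, 48 quaternion
outputs, from the two forearm sensors) and the lower body (6 segments,
24 outputs, from the two lower-leg sensors); the five measured segments pass
through, giving complete 23-segment poses. Features are pelvis-relative
orientation quaternions (8 per frame) optionally extended with
pelvis-relative sensor accelerations (+6): sensor accelerations are rotated
to the global frame, the pelvis acceleration is subtracted (cancelling
gravity and common-mode motion), and the result is rotated into the pelvis
frame, making every feature invariant to the body's global orientation.

Evaluation follows standard motion-capture practice: **mean joint position
error** (Euclidean distance of the 23 forward-kinematics joint positions,
averaged per frame, on an anthropometric skeleton scaled by stature) and
**joint jerk error** (Euclidean norm of the difference of third position
derivatives, a smoothness measure), under subject-wise k-fold
cross-validation so test subjects are never seen in training.

A built-in synthetic generator produces multi-subject, multi-activity
datasets (cyclic gait, high-dynamics sports, low-dynamics daily activities)
with simulated accelerometer readings, so the whole pipeline runs with no
external data. A plain-text motion format and a read-only BVH importer
connect to real recordings.

## Worked example

```r
library(stackpose)

cfg <- synthetic_config(n_subjects = 3,
  trials = data.frame(activity = "gait", duration_s = 30), seed = 7)
dataset <- generate_dataset(cfg)
dataset[[1]]
#> <motion_sequence> subject S1, activity gait: 1800 frames @ 60 Hz (30.0 s), with accelerations

wcfg <- window_config(P = 2, F_ = 2, I = 2, fs = 60)
wcfg
#> <window_config> P=2 F=2 I=2 fs=60 Hz | SIL=5, dt=0.0333 s, delay=66.7 ms

cv <- subject_wise_cv(dataset, wcfg, seed = 7)
cv
#> <cv_result> SINN, 3 folds | position 0.0129 (sd 0.0014) m [baseline 0.0612 m] | jerk 630.9 (sd 70.0) m/s^3
#>   fold S1   position 0.0113 m, jerk    710.7 m/s^3 (baseline 0.0611 m)
#>   fold S2   position 0.0138 m, jerk    602.2 m/s^3 (baseline 0.0595 m)
#>   fold S3   position 0.0135 m, jerk    579.9 m/s^3 (baseline 0.0631 m)
```

Reading the output: with a five-sample window (two past and two future
samples, two frames apart at 60 Hz — a 67 ms acquisition delay), the stacked
network reconstructs held-out subjects' full-body poses with a mean joint
position error of ~1.3 cm on this synthetic gait set, versus ~6.1 cm for the
constant-mean-pose baseline; the jerk column quantifies the smoothness of
the reconstruction. `subject_wise_cv(..., architecture = "rnn")` runs the
recurrent baseline, `use_accel = TRUE` adds acceleration features, and
`config_sweep()` tabulates errors over a grid of `(P, F, I)` window
configurations.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/stackpose.R delay --P 2 --F 2 --I 2 --fs 60
# delay: 66.7 ms (67 ms) for P=2 F=2 I=2 fs=60
Rscript inst/cli/stackpose.R simulate --out-dir data --n-subjects 6 --seed 1
Rscript inst/cli/stackpose.R evaluate --data-dir data --P 2 --F 2 --I 2
```

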