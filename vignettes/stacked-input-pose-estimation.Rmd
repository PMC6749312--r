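---
title: "Stacked-input pose estimation from five inertial sensors: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked-input pose estimation from five inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

A full-body pose is one time sample of the body configuration, represented
as orientation quaternions of 23 rigid body segments. Dense inertial motion
capture instruments every segment; `stackpose` instead estimates the full
pose from five sensors on the pelvis, the two lower arms and the two lower
legs. This is possible because human poses are highly redundant — far more
so once all orientations are expressed *relative to the pelvis*, which
removes the global heading and tilt of the body from both the inputs and
the outputs.

Two body halves are estimated by separate networks: the two forearm
orientations predict the 12 upper-body segments (48 quaternion components)
and the two lower-leg orientations predict the 6 lower-body segments (24
components). Splitting halves the learning problem for a small dataset and
matches the anatomical coupling of the limbs to their own body half. The
five measured segments pass through unchanged, so an assembled pose always
contains 5 + 12 + 6 = 23 segments, with the pelvis fixed to the identity.

## Input features

Each frame contributes 8 orientation features: the left and right limb
quaternions relative to the pelvis (left before right, a fixed convention
that must simply be consistent between training and inference).
Quaternions double-cover rotations (q and −q are the same rotation), so all
feature and target sequences are sign-canonicalized along time (consecutive
samples are forced to non-negative dot products); without this, component
regression is corrupted by arbitrary sign flips.

Optionally, 6 acceleration features are appended. The accelerometer model
is *specific force*: a sensor at rest reads the gravity reaction, rotated
into its own frame. Features are computed by rotating each sensor's reading
to the global frame, subtracting the pelvis sensor's global reading, and
rotating the difference into the pelvis frame. Under the specific-force
model this subtraction cancels gravity *exactly*, and any common-mode
acceleration of the whole body cancels with it; the tests assert both
properties to machine precision, along with exact invariance of every
feature under arbitrary global rotations of the body. Sensor frames are
taken to coincide with segment frames (no mounting misalignment), as is the
case when orientations come from a calibrated motion-capture pipeline.

## Stacked windows

One training or evaluation example pairs the features at sample offsets
`{-P·I, …, -I, 0, +I, …, +F·I}` around a centre frame with the pose target
at the centre. `P` and `F` count past and future samples, `I` is the
inter-sample interval in frames, `SIL = P + 1 + F` the stacked input
length, and `Δt = I/f_s` the spacing in seconds. The shallow network (SINN)
receives the window flattened frame-by-frame, oldest first (`8·SIL`
inputs); the recurrent baseline receives the identical data as an `8 × SIL`
sequence. Waiting for `F` future samples delays the output by `F·I/f_s`
seconds — 67 ms for the default `P = F = I = 2` at 60 Hz — which is the
irreducible, hardware-independent part of the latency.

Boundary frames lacking full context are dropped rather than padded:
padding would fabricate sensor data. Down-sampling (240 Hz recordings to
the 60 Hz working rate, factor 4) is plain decimation without prior
low-pass filtering; quaternion series cannot be filtered componentwise
without leaving the unit sphere, and adjacent 240 Hz poses are nearly
identical so decimation loses little.

## Networks and training

* **SINN**: fully-connected, two hidden layers of 256 rectified units
  (configurable), linear output.
* **RNN**: two bidirectional LSTM layers of 128 memory cells with dropout
  0.2 between them; a linear head reads the hidden states at the window's
  centre step.

Both minimize mean squared error over raw quaternion components with Adam
(learning rate 1e-3, batch 128), early stopping with patience 10 on a
validation split (one training subject when several are available,
otherwise a random 10% of samples), and a default epoch cap of 30 chosen
for desk-scale datasets. Component regression with post-hoc renormalization
of each output 4-tuple to a unit quaternion is used instead of a geodesic
loss; a zero-norm raw output (possible only for a degenerate network) is
replaced by the identity with a warning. One integer seed drives weight
initialization, batch order, dropout and the validation split, making
training bit-reproducible; the implementation is pure R, so there is no
backend nondeterminism.

Input normalization deserves a note. Features are mean-centred, and each
physical block (orientation components; accelerations) is scaled by one
pooled standard deviation relative to the orientation block, never
amplifying any column. Per-column standardization — the usual default — is
deliberately avoided: near-constant quaternion components (w ≈ 1) would
have their measurement noise amplified to unit variance, which measurably
destroys both optimization and cross-subject generalization, and
acceleration channels (tens of m/s²) would otherwise dominate the early
epochs of training. A small decoupled weight decay (1e-4, weights only)
regularizes the SINN towards subject-invariant structure.

The default SINN (≈ 8×10⁴ parameters for the lower body) is several times
smaller than the default RNN (≈ 5×10⁵); the package asserts the ordering,
not a specific ratio.

## Skeleton and metrics

Joint position error requires a concrete skeleton. The package uses a
23-segment tree rooted at the pelvis with offsets from a fixed table of
anthropometric segment-length proportions scaled linearly by stature
(head-to-toe chain ≈ 1.09 × stature). Absolute errors therefore depend on
this proportion table, but method comparisons do not. Forward kinematics
places each segment origin at its parent's origin plus the parent's
rotation applied to the offset, in the pelvis frame with the pelvis at the
origin, so position error is invariant to global body orientation and to
quaternion signs.

* **Mean joint position error** (m): per frame, the mean over the 23 joints
  of the Euclidean distance between ground-truth and estimated joint
  positions.
* **Joint jerk error** (m/s³): per interior frame, the mean over joints of
  the norm of the difference of third position derivatives. Jerk is
  computed with the single 5-point central stencil
  `[p(t+2h) − 2p(t+h) + 2p(t−h) − p(t−2h)]/(2h³)`, `h = 1/f_s` at the
  60 Hz working rate, rather than three successive first differences: the
  stencil has a defined accuracy order (exact on cubics, O(h²) otherwise),
  which the tests verify against analytic derivatives. The jerk series is
  4 frames shorter than the position series.

Cross-validation is subject-wise: each fold holds out one subject entirely,
trains upper and lower networks on the rest, and evaluates on the held-out
subject, so reported errors measure generalization across people. A
constant-mean-pose baseline (training-set mean target, renormalized) is
evaluated alongside as the floor any useful model must beat.

## The synthetic study conditions

The generator emulates the structure of a six-subject inertial
motion-capture study: per subject, trials from three activity classes at
240 Hz down-sampled to 60 Hz. Joint angles are sums of two harmonics of a
per-trial fundamental frequency plus smooth band-limited noise, composed
down the skeleton tree; the pelvis follows a class-dependent global
trajectory (forward progression with vertical bobbing for gait, smooth
jumps for sports, near-stationary sway for daily activities) from which
accelerometer readings are simulated as specific force via second central
differences of the sensor positions. Class parameters encode the intended
dynamics ordering — sports ≈ 1.6× gait's excursion amplitude at ≈ 1.6× its
fundamental frequency, daily activities below half of gait's frequency —
so mean absolute jerk orders sports > gait > ADL by construction.

Subjects differ systematically: per-joint amplitude habits (±15%) and
per-joint-pair phase habits drawn once per subject, plus stature in
[1.60, 1.90] m. Phase habits are shared across body sides so that
contralateral anti-phase relations (left/right legs in opposition, arms
against ipsilateral legs) remain exact within a subject. Limb joints are
kept close to a *pure single harmonic*: a single sensor snapshot then
leaves the movement phase two-fold ambiguous (ascending vs descending limb),
which is precisely the ambiguity that temporal context in the stacked
window resolves — the structural assumption that motivates windowed inputs
in the first place. Axial joints carry richer harmonic content.

Measurement noise is attached after the clean kinematics: white
small-rotation noise of 0.1° on every delivered orientation and 0.15 m/s²
on accelerations. These values reflect fused motion-capture output, which
is smooth with sub-degree accuracy; substantially larger white orientation
noise would make the *ground truth's* jerk dominate the jerk-error metric
and mask differences between estimators.

What the generator does **not** model: ground contact and impacts, soft
tissue artefacts, sensor-to-segment misalignment, magnetometer disturbance,
non-stationary movement (transitions, aperiodic tasks), and realistic
inter-subject anthropometric correlations. Passing tests on this data show
that the pipeline recovers the structure it assumes (phase-coherent,
pelvis-relative redundancy); they do not certify accuracy on real
recordings, for which the text motion format and BVH import provide entry
points.

## Numerical and degenerate-input choices

* Quaternions are Hamilton, scalar-first, right-handed; orientations map
  body-frame to reference-frame coordinates. Unit norm is enforced within
  1e-6 at rotation time; hemisphere canonicalization prefers w ≥ 0 with
  ties broken by the first nonzero component.
* Sign-continuity canonicalization treats a zero dot product between
  consecutive samples as "keep the current sign".
* Windows shorter than the required span produce an empty sample set with
  a warning, not an error, so sweeps over long windows degrade gracefully.
* Motion files store 17 significant digits (bit-exact round trip); readers
  are strict by default and only renormalize near-unit quaternions under an
  explicit lenient flag.
* Training aborts with a named epoch on non-finite loss rather than
  returning a silently broken model.

## Problem sizes used in the shipped checks

The test suite and examples run entirely on generated data at desk scale,
chosen as the smallest sizes at which the statistical claims are stable:
six subjects × 60 s of gait for the cross-validated recovery check
(every fold's mean joint position error under half the mean-pose
baseline's), three seeds × three subjects × 30 s for the window-length
trend on jerk, and three seeds × six subjects × 30 s of the sports class
for the acceleration-feature trend on position error (asserted within a
10% stochastic band, seed-averaged). The recurrent baseline, being ~10×
slower to train in pure R, is exercised on smaller fixtures; its jerk
advantage over the SINN is asserted within a 20% band on a one-fold gait
comparison.

## Known limitations

* The anthropometric proportion table is fixed and simplified; per-subject
  segment-length ratios are not varied independently of stature.
* The RNN reads out only the centre step of its output sequence; streaming
  operation (reusing recurrent state across sliding windows) is not
  implemented.
* No geodesic/rotational loss; component MSE slightly favours small-angle
  accuracy over large rotations.
* Wall-clock latency of inference is hardware- and implementation-specific
  and is deliberately out of scope; only the acquisition delay `F·I/f_s`
  is reported.
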