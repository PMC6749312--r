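# Synthetic multi-subject motion generator.  Joint angles are sums of
# harmonics of a per-trial fundamental frequency, with subject-specific
# amplitude/phase draws, composed down the skeleton tree into global segment
# orientations; a class-dependent global pelvis trajectory makes simulated
# accelerometer readings informative.  Three activity classes emulate the
# structure of an inertial motion-capture protocol: cyclic gait, high-
# dynamics sports, low-dynamics activities of daily living (ADL).

# per-segment oscillation recipe: primary axis, base amplitude (rad), phase
# offset (rad, contralateral limbs are anti-phase; arms anti-phase with the
# ipsilateral leg), constant mean angle giving a natural standing posture,
# and second-harmonic content.  Limb motion is kept close to a pure single
# harmonic: a single sensor snapshot then leaves the movement phase
# two-fold ambiguous (ascending vs descending), which is exactly the
# ambiguity that temporal context in the input window must resolve — the
# redundancy structure the estimation method assumes.  Axial (spine/neck)
# joints carry richer harmonic content.
.JOINT_MOTION <- local({
  m <- rbind(
    L5            = c(0.05,  0.0,      0.00, 0.30),
    L3            = c(0.05,  0.0,      0.00, 0.30),
    T12           = c(0.04,  1.5708,   0.00, 0.30),
    T8            = c(0.04,  0.0,      0.00, 0.30),
    Neck          = c(0.06,  1.5708,   0.00, 0.30),
    Head          = c(0.06,  3.1416,   0.00, 0.30),
    RightShoulder = c(0.06,  3.1416,   0.00, 0.20),
    RightUpperArm = c(0.40,  3.1416,   0.10, 0.08),
    RightForearm  = c(0.45,  1.5708,   0.40, 0.08),
    RightHand     = c(0.10,  3.1416,   0.00, 0.08),
    LeftShoulder  = c(0.06,  0.0,      0.00, 0.20),
    LeftUpperArm  = c(0.40,  0.0,      0.10, 0.08),
    LeftForearm   = c(0.45, -1.5708,   0.40, 0.08),
    LeftHand      = c(0.10,  0.0,      0.00, 0.08),
    RightUpperLeg = c(0.45,  0.0,     -0.10, 0.08),
    RightLowerLeg = c(0.55, -1.5708,  -0.30, 0.08),
    RightFoot     = c(0.25,  3.1416,   0.00, 0.08),
    RightToe      = c(0.08,  3.1416,   0.00, 0.08),
    LeftUpperLeg  = c(0.45,  3.1416,  -0.10, 0.08),
    LeftLowerLeg  = c(0.55,  1.5708,  -0.30, 0.08),
    LeftFoot      = c(0.25,  0.0,      0.00, 0.08),
    LeftToe       = c(0.08,  0.0,      0.00, 0.08))
  colnames(m) <- c("amp", "phase", "mean", "harm2")
  axis1 <- stats::setNames(rep("y", nrow(m)), rownames(m))
  axis1[c("L5", "L3", "T8", "RightShoulder", "LeftShoulder")] <- "z"
  list(table = m, axis1 = axis1)
})

# joints share the subject's phase habit across body sides, so contralateral
# anti-phase relations stay exact for a subject
.joint_base_name <- function(seg) sub("^(Left|Right)", "", seg)

.AXES <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))

.default_class_params <- function() list(
  gait   = list(f0_range = c(0.8, 1.2),  amp_scale = 1.0,
                noise_amp = 0.02, noise_bw = 1.0, speed = 1.2,
                bob_amp = 0.030, jump_amp = 0.00, yaw_amp = 0.08),
  sports = list(f0_range = c(1.3, 1.9),  amp_scale = 1.6,
                noise_amp = 0.03, noise_bw = 1.5, speed = 0.3,
                bob_amp = 0.020, jump_amp = 0.12, yaw_amp = 0.15),
  adl    = list(f0_range = c(0.20, 0.35), amp_scale = 0.7,
                noise_amp = 0.02, noise_bw = 0.5, speed = 0.0,
                bob_amp = 0.005, jump_amp = 0.00, yaw_amp = 0.03))

#' Configuration for the synthetic motion generator
#'
#' Defaults emulate a six-subject inertial motion-capture study: three
#' activity classes of differing dynamics, recorded at 240 Hz and
#' down-sampled by a factor of four to 60 Hz.
#'
#' @param n_subjects Number of subjects.
#' @param trials Data frame with columns `activity`
#'   (`"gait"`/`"sports"`/`"adl"`) and `duration_s`.
#' @param fs_raw Raw sampling frequency (Hz).
#' @param downsample_factor Integer decimation factor for the delivered
#'   dataset.
#' @param stature_range Subject stature range (metres).
#' @param class_params Per-class motion parameters: fundamental frequency
#'   range (Hz), joint-excursion amplitude scale, smooth-noise amplitude
#'   (rad) and bandwidth (Hz), pelvis speed (m/s), vertical bob/jump
#'   amplitudes (m), pelvis yaw amplitude (rad).  See
#'   `stackpose:::.default_class_params()` for defaults.
#' @param orientation_noise_deg Std of white small-rotation measurement
#'   noise applied to every delivered segment orientation (degrees).
#' @param accel_noise Std of white accelerometer noise (m/s^2).
#' @param seed Master seed; all draws derive from it.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 6L,
                             trials = data.frame(
                               activity = c("gait", "sports", "adl"),
                               duration_s = 60),
                             fs_raw = 240, downsample_factor = 4L,
                             stature_range = c(1.60, 1.90),
                             class_params = .default_class_params(),
                             orientation_noise_deg = 0.1,
                             accel_noise = 0.15,
                             seed = 1L) {
  stopifnot(n_subjects >= 1L, nrow(trials) >= 1L,
            all(trials$activity %in% names(class_params)),
            fs_raw > 0, downsample_factor >= 1L,
            length(stature_range) == 2L, stature_range[1] <= stature_range[2])
  structure(list(n_subjects = as.integer(n_subjects), trials = trials,
                 fs_raw = fs_raw, downsample_factor = as.integer(downsample_factor),
                 stature_range = stature_range, class_params = class_params,
                 orientation_noise_deg = orientation_noise_deg,
                 accel_noise = accel_noise, seed = as.integer(seed)),
            class = "synthetic_config")
}

.subject_seed <- function(cfg, subject_index)
  (cfg$seed * 10007L + subject_index * 257L) %% .Machine$integer.max

# subject-level latent draws: stature and per-joint amplitude/phase habits;
# amplitude habits are per joint, phase habits are per joint *pair* so that
# left/right anti-phase relations remain exact within a subject
.draw_subject <- function(cfg, subject_index) {
  set.seed(.subject_seed(cfg, subject_index))
  segs <- rownames(.JOINT_MOTION$table)
  bases <- unique(.joint_base_name(segs))
  base_jitter <- stats::setNames(stats::rnorm(length(bases), 0, 0.08), bases)
  list(
    stature = stats::runif(1, cfg$stature_range[1], cfg$stature_range[2]),
    amp_factor = stats::setNames(stats::runif(length(segs), 0.85, 1.15), segs),
    phase_jitter = stats::setNames(base_jitter[.joint_base_name(segs)], segs),
    harm2_phase = stats::runif(1, 0, 2 * pi),
    heading = stats::runif(1, 0, 2 * pi))
}

# smooth band-limited noise: sum of 3 random sinusoids (infinitely
# differentiable, unlike white noise)
.smooth_noise <- function(t, amp, bw) {
  if (amp <= 0) return(numeric(length(t)))
  out <- numeric(length(t))
  for (k in 1:3) {
    f <- stats::runif(1, 0.05, bw)
    out <- out + amp * stats::runif(1, 0.5, 1) * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  }
  out / sqrt(3)
}

# one clean trial at the raw rate: global orientations + pelvis trajectory
.generate_trial <- function(cfg, subj, subject_index, activity, duration_s,
                            trial_index) {
  cp <- cfg$class_params[[activity]]
  set.seed((.subject_seed(cfg, subject_index) + trial_index * 7919L) %%
             .Machine$integer.max)
  fs <- cfg$fs_raw
  n <- max(5L, round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  f0 <- stats::runif(1, cp$f0_range[1], cp$f0_range[2])
  tab <- .JOINT_MOTION$table

  # local joint rotations, composed down the tree into global orientations
  quats <- array(NA_real_, dim = c(n, 23L, 4L),
                 dimnames = list(NULL, SEGMENT_NAMES, c("w", "x", "y", "z")))
  # pelvis global orientation: heading + small yaw/pitch/roll oscillation
  yaw <- subj$heading + cp$yaw_amp * sin(2 * pi * f0 * t) +
    .smooth_noise(t, cp$noise_amp, cp$noise_bw)
  pitch <- 0.5 * cp$yaw_amp * sin(2 * pi * f0 * t + 1.0)
  roll <- 0.3 * cp$yaw_amp * sin(2 * pi * f0 * t + 2.0)
  qp <- quat_multiply(quat_multiply(quat_from_axis_angle(.AXES$z, yaw),
                                    quat_from_axis_angle(.AXES$y, pitch)),
                      quat_from_axis_angle(.AXES$x, roll))
  quats[, "Pelvis", ] <- qp
  for (seg in SEGMENT_NAMES[-1]) {
    A <- cp$amp_scale * subj$amp_factor[[seg]] * tab[seg, "amp"]
    ph <- tab[seg, "phase"] + subj$phase_jitter[[seg]]
    theta1 <- tab[seg, "mean"] +
      A * (sin(2 * pi * f0 * t + ph) +
             tab[seg, "harm2"] * sin(4 * pi * f0 * t + 2 * ph + subj$harm2_phase)) +
      .smooth_noise(t, cp$noise_amp, cp$noise_bw)
    ax1 <- .JOINT_MOTION$axis1[[seg]]
    ax2 <- if (ax1 == "x") "z" else "x"
    # secondary axis in phase with the primary one: adds 3D richness to the
    # rotation without leaking extra phase information into a snapshot
    theta2 <- 0.15 * A * sin(2 * pi * f0 * t + ph)
    q_local <- quat_multiply(quat_from_axis_angle(.AXES[[ax1]], theta1),
                             quat_from_axis_angle(.AXES[[ax2]], theta2))
    parent <- .SEGMENT_PARENT[[seg]]
    quats[, seg, ] <- quat_multiply(quats[, parent, ], q_local)
  }

  # global pelvis trajectory (class-dependent dynamics)
  z0 <- 0.53 * subj$stature
  fwd <- c(cos(subj$heading), sin(subj$heading))
  amp <- cp$amp_scale
  pos <- cbind(
    cp$speed * t * fwd[1] + 0.2 * cp$jump_amp * sin(pi * f0 * t),
    cp$speed * t * fwd[2] + 0.02 * amp * sin(2 * pi * f0 * t),
    z0 + cp$bob_amp * sin(4 * pi * f0 * t) +
      cp$jump_amp * (1 - cos(2 * pi * f0 * t)) / 2)

  seq_ <- motion_sequence(quats, fs = fs, subject_id = sprintf("S%d", subject_index),
                          activity = activity, stature_m = subj$stature,
                          pelvis_position = pos)
  skel <- default_skeleton(subj$stature)
  seq_$accelerations <- simulate_sensor_accelerations(seq_, skel)
  seq_
}

#' Generate all trials of one subject (clean, raw rate)
#'
#' Deterministic given `(cfg$seed, subject_index)`: repeated calls return
#' bit-identical sequences.  Output is the clean (noise-free) kinematics at
#' the raw sampling rate, with simulated sensor accelerations attached;
#' [generate_dataset()] down-samples and adds measurement noise.
#'
#' @param cfg A `synthetic_config`.
#' @param subject_index Subject number (1-based).
#' @return List of `motion_sequence` objects, one per configured trial.
#' @export
generate_subject <- function(cfg, subject_index) {
  stopifnot(inherits(cfg, "synthetic_config"))
  subj <- .draw_subject(cfg, subject_index)
  lapply(seq_len(nrow(cfg$trials)), function(ti)
    .generate_trial(cfg, subj, subject_index,
                    as.character(cfg$trials$activity[ti]),
                    cfg$trials$duration_s[ti], ti))
}

#' Simulate accelerometer readings from clean kinematics
#'
#' For each of the five sensor segments, computes the global acceleration of
#' the segment origin (second central difference of the global position,
#' obtained from the pelvis trajectory plus forward kinematics), subtracts
#' gravity `(0, 0, -9.81)` m/s^2, and rotates into the sensor frame — i.e.
#' the specific force a real accelerometer measures.  End frames are padded
#' by repetition.
#'
#' @param seq A `motion_sequence` with all 23 segments and a
#'   `pelvis_position` trajectory (>= 5 frames).
#' @param skel The subject's `skeleton` (defaults to the sequence stature).
#' @return An `n x 5 x 3` array of sensor-frame specific force (m/s^2).
#' @export
simulate_sensor_accelerations <- function(seq, skel = NULL) {
  if (seq$n_frames < 5L)
    stop("need at least 5 frames to simulate accelerations")
  if (is.null(seq$pelvis_position))
    stop("sequence has no global pelvis trajectory")
  if (is.null(skel)) skel <- default_skeleton(seq$stature_m)
  n <- seq$n_frames
  fs <- seq$fs
  g <- c(0, 0, -9.81)
  rel <- pelvis_relative_orientations(seq, SEGMENT_NAMES)
  pos_rel <- fk_sequence(skel, rel)
  qp <- quat_normalize(.seq_quats(seq, "Pelvis"))
  out <- array(NA_real_, dim = c(n, 5L, 3L),
               dimnames = list(NULL, INPUT_SEGMENTS, c("ax", "ay", "az")))
  for (s in INPUT_SEGMENTS) {
    p_global <- seq$pelvis_position + quat_rotate(qp, pos_rel[, s, ])
    acc <- matrix(0, n, 3L)
    idx <- 2:(n - 1L)
    acc[idx, ] <- (p_global[idx + 1L, ] - 2 * p_global[idx, ] +
                     p_global[idx - 1L, ]) * fs^2
    acc[1L, ] <- acc[2L, ]
    acc[n, ] <- acc[n - 1L, ]
    qi <- quat_normalize(.seq_quats(seq, s))
    out[, s, ] <- quat_rotate(quat_conjugate(qi),
                              sweep(acc, 2, g, "-"))
  }
  out
}

#' Generate the full synthetic dataset
#'
#' All subjects and trials, down-sampled by `cfg$downsample_factor`, with
#' orientation measurement noise (small random rotations) and accelerometer
#' noise attached after the clean kinematics.  A manifest of seeds and
#' parameters is attached as an attribute.
#'
#' @param cfg A `synthetic_config`.
#' @return A list of `motion_sequence` objects with attribute `manifest`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  out <- list()
  statures <- numeric(0)
  for (si in seq_len(cfg$n_subjects)) {
    trials <- generate_subject(cfg, si)
    set.seed((.subject_seed(cfg, si) + 13L) %% .Machine$integer.max)
    for (seq_ in trials) {
      ds <- downsample_sequence(seq_, cfg$downsample_factor)
      ds <- .add_measurement_noise(ds, cfg$orientation_noise_deg, cfg$accel_noise)
      out[[length(out) + 1L]] <- ds
    }
    statures <- c(statures, trials[[1]]$stature_m)
  }
  attr(out, "manifest") <- list(
    generator = "stackpose-synthetic", seed = cfg$seed,
    n_subjects = cfg$n_subjects, trials = cfg$trials,
    fs = cfg$fs_raw / cfg$downsample_factor,
    orientation_noise_deg = cfg$orientation_noise_deg,
    accel_noise = cfg$accel_noise, statures = statures)
  out
}

.add_measurement_noise <- function(seq, orientation_noise_deg, accel_noise) {
  n <- seq$n_frames
  if (orientation_noise_deg > 0) {
    sd_rad <- orientation_noise_deg * pi / 180
    for (s in dimnames(seq$orientations)[[2]]) {
      ang <- stats::rnorm(n, 0, sd_rad)
      ax <- matrix(stats::rnorm(3L * n), n, 3L)
      ax <- ax / sqrt(rowSums(ax^2))
      nq <- cbind(cos(ang / 2), ax * sin(ang / 2))
      q <- .seq_quats(seq, s)
      seq$orientations[, s, ] <- quat_multiply(q, nq)
    }
  }
  if (!is.null(seq$accelerations) && accel_noise > 0) {
    seq$accelerations <- seq$accelerations +
      array(stats::rnorm(length(seq$accelerations), 0, accel_noise),
            dim = dim(seq$accelerations))
  }
  seq
}
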