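# Synthetic generator: determinism, gait structure, accelerometer model,
# dataset shapes and the dynamics ordering of the activity classes.

static_config <- function(seed = 1L) {
  synthetic_config(
    n_subjects = 1L,
    trials = data.frame(activity = "gait", duration_s = 2),
    class_params = list(gait = list(
      f0_range = c(1, 1), amp_scale = 0, noise_amp = 0, noise_bw = 1,
      speed = 0, bob_amp = 0, jump_amp = 0, yaw_amp = 0)),
    orientation_noise_deg = 0, accel_noise = 0, seed = seed)
}

test_that("generation is deterministic and subjects differ", {
  cfg <- synthetic_config(n_subjects = 2,
                          trials = data.frame(activity = "gait", duration_s = 3),
                          seed = 5)
  a <- generate_subject(cfg, 1L)
  b <- generate_subject(cfg, 1L)
  expect_identical(a, b)
  other <- generate_subject(cfg, 2L)
  expect_false(isTRUE(all.equal(a[[1]]$orientations, other[[1]]$orientations)))
  expect_false(a[[1]]$stature_m == other[[1]]$stature_m)
})

test_that("gait lower legs move in anti-phase", {
  cfg <- synthetic_config(n_subjects = 1,
                          trials = data.frame(activity = "gait", duration_s = 20),
                          orientation_noise_deg = 0, seed = 8)
  ds <- generate_dataset(cfg)
  rel <- pelvis_relative_orientations(ds[[1]], c("LeftLowerLeg", "RightLowerLeg"))
  # use the dominant quaternion component series of each side
  l <- rel[, 1, 3] - mean(rel[, 1, 3])
  r <- rel[, 2, 3] - mean(rel[, 2, 3])
  cc <- stats::ccf(l, r, lag.max = 90, plot = FALSE)
  lag_at_peak <- cc$lag[which.max(abs(cc$acf))]
  # anti-phase: extreme correlation at lag ~ half the fundamental period,
  # or a strong negative correlation at lag 0
  peak0 <- cc$acf[cc$lag == 0]
  expect_lt(peak0, -0.5)
  expect_true(abs(lag_at_peak) <= 45)
})

test_that("zero excursion and zero noise give a constant standing pose", {
  ds <- generate_dataset(static_config())
  seq_ <- ds[[1]]
  rel <- pose_array(seq_)
  for (s in SEGMENT_NAMES) {
    rng <- apply(rel[, s, ], 2, function(x) diff(range(x)))
    expect_lt(max(rng), 1e-9)
  }
})

test_that("simulated accelerometers read the gravity reaction when static", {
  ds <- generate_dataset(static_config())
  seq_ <- ds[[1]]
  for (s in INPUT_SEGMENTS) {
    qi <- seq_$orientations[1, s, ]
    expected <- quat_rotate(quat_conjugate(qi), c(0, 0, 9.81))
    for (k in 1:3)
      expect_equal(unname(seq_$accelerations[5, s, k]), unname(expected[k]),
                   tolerance = 1e-6)
  }
  # closing the loop through the feature pipeline gives exact zeros
  for (limb in c("upper", "lower"))
    expect_lt(max(abs(acceleration_features(seq_, limb))), 1e-9)
})

test_that("common-mode pelvis acceleration cancels out of the features", {
  # rigid body: constant orientations, pelvis accelerating at constant a
  n <- 60L
  q <- array(NA_real_, dim = c(n, 23L, 4L),
             dimnames = list(NULL, SEGMENT_NAMES, c("w", "x", "y", "z")))
  set.seed(9)
  for (s in SEGMENT_NAMES) {
    qs <- random_unit_quat()
    q[, s, ] <- matrix(qs, n, 4, byrow = TRUE)
  }
  t <- (0:(n - 1)) / 60
  a_const <- c(0.7, -0.3, 0.2)
  pos <- cbind(0.5 * a_const[1] * t^2, 0.5 * a_const[2] * t^2,
               1 + 0.5 * a_const[3] * t^2)
  seq_ <- motion_sequence(q, fs = 60, pelvis_position = pos)
  seq_$accelerations <- simulate_sensor_accelerations(seq_)
  for (limb in c("upper", "lower"))
    expect_lt(max(abs(acceleration_features(seq_, limb))), 1e-6)
  expect_error(simulate_sensor_accelerations(
    motion_sequence(q[1:4, , , drop = FALSE], fs = 60,
                    pelvis_position = pos[1:4, ])), "5 frames")
})

test_that("datasets have the configured shape and noise-free limit", {
  cfg <- synthetic_config(n_subjects = 2,
                          trials = data.frame(activity = "gait", duration_s = 10),
                          seed = 12)
  ds <- generate_dataset(cfg)
  expect_length(ds, 2L)
  for (s in ds) {
    expect_equal(s$n_frames, 600L)   # 10 s x 60 Hz after 240 -> 60 down-sampling
    expect_equal(s$fs, 60)
    nrm <- sqrt(apply(s$orientations^2, c(1, 2), sum))
    expect_equal(max(abs(nrm - 1)), 0, tolerance = 1e-9)
    expect_equal(dim(s$accelerations), c(600L, 5L, 3L))
  }
  expect_identical(attr(ds, "manifest")$seed, 12L)

  # with noise off, the delivered data equal the down-sampled clean data
  cfg0 <- synthetic_config(n_subjects = 1,
                           trials = data.frame(activity = "gait", duration_s = 5),
                           orientation_noise_deg = 0, accel_noise = 0, seed = 12)
  clean <- downsample_sequence(generate_subject(cfg0, 1L)[[1]], 4L)
  delivered <- generate_dataset(cfg0)[[1]]
  expect_equal(delivered$orientations, clean$orientations)
  expect_equal(delivered$accelerations, clean$accelerations)
})

test_that("activity classes order by dynamics: sports > gait > adl", {
  mean_abs_jerk <- function(activity) {
    cfg <- synthetic_config(
      n_subjects = 1L, trials = data.frame(activity = activity, duration_s = 15),
      orientation_noise_deg = 0, seed = 21)
    seq_ <- generate_dataset(cfg)[[1]]
    skel <- default_skeleton(seq_$stature_m)
    pos <- fk_sequence(skel, pose_array(seq_))
    mean(abs(vapply(seq_len(23L),
                    function(s) mean(abs(jerk(pos[, s, ], seq_$fs))),
                    numeric(1))))
  }
  j_gait <- mean_abs_jerk("gait")
  j_sports <- mean_abs_jerk("sports")
  j_adl <- mean_abs_jerk("adl")
  expect_gt(j_sports, j_gait)
  expect_gt(j_gait, j_adl)
})
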