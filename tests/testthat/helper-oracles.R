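# Independent oracles used across tests: rotation matrices built directly
# from axis-angle (Rodrigues) or from quaternion components, matrix-chain
# forward kinematics, and brute-force window enumeration.  These never call
# the package's quaternion pipeline beyond reading plain numbers.

# Rodrigues rotation matrix from axis + angle
oracle_axis_angle_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotation matrix from quaternion components (standard closed form,
# written out independently of the package)
oracle_quat_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    nrow = 3, byrow = TRUE)
}

# matrix-chain forward kinematics over the package's skeleton tree
oracle_fk <- function(skel, pose) {
  pos <- matrix(0, 23, 3, dimnames = list(SEGMENT_NAMES, NULL))
  for (seg in SEGMENT_NAMES[-1]) {
    parent <- skel$parent[[seg]]
    R <- oracle_quat_matrix(pose[parent, ])
    pos[seg, ] <- pos[parent, ] + drop(R %*% skel$offsets[seg, ])
  }
  pos
}

# brute-force enumeration of valid window centres
oracle_window_count <- function(n, P, F_, I) {
  count <- 0L
  for (i in seq_len(n)) {
    past <- i - (1:P) * I
    fut <- i + seq_len(F_) * I
    if (P == 0L) past <- integer(0)
    if (F_ == 0L) fut <- integer(0)
    if (all(past >= 1L) && all(fut <= n)) count <- count + 1L
  }
  count
}

random_unit_quat <- function(n = 1L) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  if (n == 1L) drop(q) else q
}

# random pelvis-relative pose (pelvis = identity)
random_pose <- function() {
  pose <- random_unit_quat(23L)
  rownames(pose) <- SEGMENT_NAMES
  colnames(pose) <- c("w", "x", "y", "z")
  pose["Pelvis", ] <- c(1, 0, 0, 0)
  pose
}

# minimal valid motion sequence with all 23 segments
make_sequence <- function(n = 20L, fs = 60, subject = "S1", activity = "gait",
                          seed = 1L, accelerations = FALSE) {
  set.seed(seed)
  q <- array(NA_real_, dim = c(n, 23L, 4L),
             dimnames = list(NULL, SEGMENT_NAMES, c("w", "x", "y", "z")))
  for (s in SEGMENT_NAMES) {
    # smooth random orientation path: slerp-free small-angle walk
    ang <- cumsum(stats::rnorm(n, 0, 0.02)) + stats::runif(1, -0.5, 0.5)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    q[, s, ] <- cbind(cos(ang / 2), outer(sin(ang / 2), ax))
  }
  acc <- NULL
  if (accelerations) {
    acc <- array(stats::rnorm(n * 5 * 3), dim = c(n, 5L, 3L),
                 dimnames = list(NULL, INPUT_SEGMENTS, c("ax", "ay", "az")))
  }
  motion_sequence(q, fs = fs, subject_id = subject, activity = activity,
                  stature_m = 1.75, accelerations = acc)
}

# small synthetic gait dataset shared by model/evaluation tests (built once)
tiny_gait_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        n_subjects = 3L,
        trials = data.frame(activity = "gait", duration_s = 15),
        seed = 42L)
      cache <<- generate_dataset(cfg)
    }
    cache
  }
})
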