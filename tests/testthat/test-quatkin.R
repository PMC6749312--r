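# Quaternion algebra and forward kinematics against rotation-matrix oracles.

test_that("Hamilton product: identity, inverse, and matrix-composition oracle", {
  set.seed(1)
  id <- quat_identity()
  q <- random_unit_quat()
  expect_equal(quat_multiply(id, q), q, ignore_attr = TRUE)
  expect_equal(quat_multiply(q, quat_conjugate(q)), id,
               tolerance = 1e-12, ignore_attr = TRUE)

  # 90 deg about z then 90 deg about x maps (1,0,0) to (0,0,1)
  qz <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  qx <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  composed <- quat_multiply(qx, qz)
  expect_equal(unname(quat_rotate(composed, c(1, 0, 0))), c(0, 0, 1),
               tolerance = 1e-12)
  Rz <- oracle_axis_angle_matrix(c(0, 0, 1), pi / 2)
  Rx <- oracle_axis_angle_matrix(c(1, 0, 0), pi / 2)
  expect_equal(drop((Rx %*% Rz) %*% c(1, 0, 0)), c(0, 0, 1), tolerance = 1e-12)

  # rotation-group homomorphism on random pairs
  for (i in 1:100) {
    a <- random_unit_quat(); b <- random_unit_quat()
    expect_equal(quat_to_matrix(quat_multiply(a, b)),
                 oracle_quat_matrix(a) %*% oracle_quat_matrix(b),
                 tolerance = 1e-9)
  }
})

test_that("conjugation is an involution and inverts rotations", {
  set.seed(2)
  expect_equal(quat_conjugate(quat_identity()), quat_identity(),
               ignore_attr = TRUE)
  for (i in 1:100) {
    q <- random_unit_quat()
    v <- stats::rnorm(3)
    expect_equal(quat_conjugate(quat_conjugate(q)), q, ignore_attr = TRUE)
    expect_equal(unname(quat_rotate(quat_conjugate(q), quat_rotate(q, v))), v,
                 tolerance = 1e-12)
  }
})

test_that("vector rotation matches the matrix oracle and preserves norms", {
  set.seed(3)
  expect_equal(unname(quat_rotate(quat_identity(), c(1, 2, 3))), c(1, 2, 3))
  half_turn_z <- quat_from_axis_angle(c(0, 0, 1), pi)
  expect_equal(unname(quat_rotate(half_turn_z, c(1, 0, 0))), c(-1, 0, 0),
               tolerance = 1e-12)
  for (i in 1:100) {
    q <- random_unit_quat(); v <- stats::rnorm(3)
    got <- quat_rotate(q, v)
    expect_equal(unname(got), drop(oracle_quat_matrix(q) %*% v),
                 tolerance = 1e-9)
    expect_equal(sum(got^2), sum(v^2), tolerance = 1e-9)
  }
  expect_error(quat_rotate(c(2, 0, 0, 0), c(1, 0, 0)), "unit-norm")
  expect_error(quat_multiply(c(NA, 0, 0, 1), quat_identity()), "non-finite")
})

test_that("relative orientation is canonical and left-invariant", {
  set.seed(4)
  q <- random_unit_quat()
  expect_equal(quat_relative(q, q), quat_identity(),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(quat_relative(quat_identity(), q), quat_canonical(q),
               ignore_attr = TRUE)
  for (i in 1:100) {
    g <- random_unit_quat(); ref <- random_unit_quat(); q <- random_unit_quat()
    expect_equal(
      quat_relative(quat_multiply(g, ref), quat_multiply(g, q)),
      quat_relative(ref, q), tolerance = 1e-9)
  }
})

test_that("hemisphere canonicalization and temporal sign continuity", {
  q <- c(0.5, 0.5, 0.5, 0.5)
  expect_equal(quat_canonical(-q), q, ignore_attr = TRUE)
  # w == 0 tie broken by the first nonzero component
  expect_equal(unname(quat_canonical(c(0, -1, 0, 0))), c(0, 1, 0, 0))

  qs <- rbind(q, -q, q)
  out <- quat_canonicalize_sequence(qs)
  expect_equal(unname(out), matrix(rep(q, 3), 3, byrow = TRUE))

  # already-continuous sequences pass through unchanged
  set.seed(5)
  ang <- seq(0, 1, length.out = 10)
  smooth <- quat_from_axis_angle(c(0, 1, 0), ang)
  expect_equal(quat_canonicalize_sequence(smooth), smooth)

  # random sequences with random sign flips: non-negative consecutive dots
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    base <- quat_from_axis_angle(stats::rnorm(3), cumsum(stats::runif(n, 0, 0.4)))
    flipped <- base * sample(c(-1, 1), n, replace = TRUE)
    out <- quat_canonicalize_sequence(flipped)
    dots <- rowSums(out[-1, , drop = FALSE] * out[-n, , drop = FALSE])
    expect_true(all(dots >= 0))
    expect_true(all(abs(abs(rowSums(out * base)) - 1) < 1e-9))  # same rotation
  }
})

test_that("forward kinematics matches the matrix-chain oracle", {
  skel <- default_skeleton(1.75)
  set.seed(6)
  # identity pose: positions are cumulative offset sums along each chain
  pose_id <- matrix(rep(c(1, 0, 0, 0), each = 23), 23, 4,
                    dimnames = list(SEGMENT_NAMES, c("w", "x", "y", "z")))
  pos <- forward_kinematics(skel, pose_id)
  expect_equal(unname(pos["RightLowerLeg", ]),
               unname(skel$offsets["RightUpperLeg", ] + skel$offsets["RightLowerLeg", ]))
  expect_equal(unname(pos["Head", ]),
               unname(colSums(skel$offsets[c("L5", "L3", "T12", "T8", "Neck", "Head"), ])))

  # rotating the right hip 90 deg about x swings the knee to +y
  pose <- pose_id
  pose["RightUpperLeg", ] <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  pos2 <- forward_kinematics(skel, pose)
  l_shank <- abs(skel$offsets["RightLowerLeg", "z"])
  expect_equal(unname(pos2["RightLowerLeg", ] - pos2["RightUpperLeg", ]),
               c(0, l_shank, 0), tolerance = 1e-12)

  for (i in 1:200) {
    pose <- random_pose()
    expect_equal(unname(forward_kinematics(skel, pose)),
                 unname(oracle_fk(skel, pose)), tolerance = 1e-9)
  }
  # missing segment is a schema error
  expect_error(forward_kinematics(skel, pose_id[-2, ]), "missing segments")
})

test_that("forward kinematics preserves segment lengths and quaternion sign", {
  skel <- default_skeleton(1.8)
  set.seed(7)
  n <- 1000L
  quats <- array(random_unit_quat(23L * n), dim = c(n, 23L, 4L),
                 dimnames = list(NULL, SEGMENT_NAMES, NULL))
  pos <- fk_sequence(skel, quats)
  for (seg in SEGMENT_NAMES[-1]) {
    parent <- skel$parent[[seg]]
    d <- pos[, seg, ] - pos[, parent, ]
    expect_equal(sqrt(rowSums(d^2)),
                 rep(sqrt(sum(skel$offsets[seg, ]^2)), n), tolerance = 1e-9)
  }
  # q and -q describe the same rotation
  flipped <- quats * -1
  expect_equal(fk_sequence(skel, flipped), pos, tolerance = 1e-12)
})

test_that("default skeleton is anthropometrically consistent and scales linearly", {
  skel <- default_skeleton(1.80)
  expect_length(skel$segments, 23L)
  expect_setequal(c(skel$input_segments, skel$upper_output_segments,
                    skel$lower_output_segments), SEGMENT_NAMES)
  expect_length(skel$input_segments, 5L)
  expect_length(skel$upper_output_segments, 12L)
  expect_length(skel$lower_output_segments, 6L)
  # tree rooted at the pelvis
  expect_true(is.na(skel$parent[["Pelvis"]]))
  for (seg in SEGMENT_NAMES[-1]) {
    hops <- 0L; cur <- seg
    while (!is.na(skel$parent[[cur]]) && hops < 30L) {
      cur <- skel$parent[[cur]]; hops <- hops + 1L
    }
    expect_identical(cur, "Pelvis")
    expect_gt(sum(skel$offsets[seg, ]^2), 0)
  }
  chain <- skeleton_chain_length(skel)
  expect_gt(chain, 0.9 * 1.80)
  expect_lt(chain, 1.1 * 1.80)

  expect_equal(default_skeleton(1.8)$offsets, default_skeleton(1.6)$offsets * 1.8 / 1.6)
  expect_error(default_skeleton(0.9), "stature")
  expect_error(default_skeleton(2.6), "stature")
})
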