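# 23-segment biomechanical skeleton: tree rooted at the pelvis, with segment
# offsets (the position of a segment's proximal joint in its parent's local
# frame) taken from an anthropometric proportion table scaled by stature.
# Frames are right-handed: x forward, y left, z up.

#' Canonical segment names
#'
#' The 23 body segments, in the fixed canonical order used throughout the
#' package (parents always precede their children).
#' @format Character vector of length 23.
#' @export
SEGMENT_NAMES <- c(
  "Pelvis", "L5", "L3", "T12", "T8", "Neck", "Head",
  "RightShoulder", "RightUpperArm", "RightForearm", "RightHand",
  "LeftShoulder", "LeftUpperArm", "LeftForearm", "LeftHand",
  "RightUpperLeg", "RightLowerLeg", "RightFoot", "RightToe",
  "LeftUpperLeg", "LeftLowerLeg", "LeftFoot", "LeftToe")

#' The five sensor-bearing segments
#' @format Character vector of length 5.
#' @export
INPUT_SEGMENTS <- c("Pelvis", "LeftForearm", "RightForearm",
                    "LeftLowerLeg", "RightLowerLeg")

#' Upper-body output segments (12, estimated from the forearm sensors)
#' @format Character vector of length 12.
#' @export
UPPER_OUTPUT_SEGMENTS <- c("L5", "L3", "T12", "T8", "Neck", "Head",
                           "RightShoulder", "RightUpperArm", "RightHand",
                           "LeftShoulder", "LeftUpperArm", "LeftHand")

#' Lower-body output segments (6, estimated from the lower-leg sensors)
#' @format Character vector of length 6.
#' @export
LOWER_OUTPUT_SEGMENTS <- c("RightUpperLeg", "RightFoot", "RightToe",
                           "LeftUpperLeg", "LeftFoot", "LeftToe")

.SEGMENT_PARENT <- c(
  Pelvis = NA, L5 = "Pelvis", L3 = "L5", T12 = "L3", T8 = "T12",
  Neck = "T8", Head = "Neck",
  RightShoulder = "T8", RightUpperArm = "RightShoulder",
  RightForearm = "RightUpperArm", RightHand = "RightForearm",
  LeftShoulder = "T8", LeftUpperArm = "LeftShoulder",
  LeftForearm = "LeftUpperArm", LeftHand = "LeftForearm",
  RightUpperLeg = "Pelvis", RightLowerLeg = "RightUpperLeg",
  RightFoot = "RightLowerLeg", RightToe = "RightFoot",
  LeftUpperLeg = "Pelvis", LeftLowerLeg = "LeftUpperLeg",
  LeftFoot = "LeftLowerLeg", LeftToe = "LeftFoot")

# joint offsets as fractions of stature (x forward, y left, z up)
.OFFSET_FRACTIONS <- matrix(c(
  # x       y       z
  0.000,  0.000,  0.000,   # Pelvis (root)
  0.000,  0.000,  0.060,   # L5
  0.000,  0.000,  0.060,   # L3
  0.000,  0.000,  0.060,   # T12
  0.000,  0.000,  0.075,   # T8
  0.000,  0.000,  0.075,   # Neck
  0.000,  0.000,  0.045,   # Head
  0.000, -0.105,  0.045,   # RightShoulder
  0.000, -0.085,  0.000,   # RightUpperArm
  0.000,  0.000, -0.186,   # RightForearm (elbow)
  0.000,  0.000, -0.146,   # RightHand (wrist)
  0.000,  0.105,  0.045,   # LeftShoulder
  0.000,  0.085,  0.000,   # LeftUpperArm
  0.000,  0.000, -0.186,   # LeftForearm
  0.000,  0.000, -0.146,   # LeftHand
  0.000, -0.092, -0.030,   # RightUpperLeg (hip)
  0.000,  0.000, -0.245,   # RightLowerLeg (knee)
  0.000,  0.000, -0.246,   # RightFoot (ankle)
  0.120,  0.000, -0.035,   # RightToe
  0.000,  0.092, -0.030,   # LeftUpperLeg
  0.000,  0.000, -0.245,   # LeftLowerLeg
  0.000,  0.000, -0.246,   # LeftFoot
  0.120,  0.000, -0.035),  # LeftToe
  ncol = 3L, byrow = TRUE,
  dimnames = list(SEGMENT_NAMES, c("x", "y", "z")))

#' Build the default 23-segment skeleton for a given stature
#'
#' Offsets come from a fixed table of segment-length proportions scaled
#' linearly by stature, giving a concrete (if simplified) anthropometric
#' model for forward kinematics and joint-position metrics.
#'
#' @param stature_m Standing height in metres, in `[1.0, 2.5]`.
#' @return An object of class `skeleton`: list with `segments`, `parent`
#'   (named character), `offsets` (23 x 3 matrix, metres), `input_segments`,
#'   `upper_output_segments`, `lower_output_segments`, `stature_m`.
#' @export
default_skeleton <- function(stature_m = 1.75) {
  if (!is.finite(stature_m) || stature_m < 1.0 || stature_m > 2.5)
    stop("'stature_m' must be in [1.0, 2.5] metres")
  structure(list(
    segments = SEGMENT_NAMES,
    parent = .SEGMENT_PARENT,
    offsets = .OFFSET_FRACTIONS * stature_m,
    input_segments = INPUT_SEGMENTS,
    upper_output_segments = UPPER_OUTPUT_SEGMENTS,
    lower_output_segments = LOWER_OUTPUT_SEGMENTS,
    stature_m = stature_m), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d segments, stature %.2f m\n",
              length(x$segments), x$stature_m))
  invisible(x)
}

.check_pose <- function(pose) {
  if (is.null(dim(pose)) || ncol(pose) != 4L)
    stop("a pose must be a (segments x 4) quaternion matrix")
  if (is.null(rownames(pose)) || !all(SEGMENT_NAMES %in% rownames(pose)))
    stop("pose is missing segments: ",
         paste(setdiff(SEGMENT_NAMES, rownames(pose)), collapse = ", "))
  pose[SEGMENT_NAMES, , drop = FALSE]
}

#' Forward kinematics for one pose
#'
#' Computes the 23 joint (segment-origin) positions in the pelvis frame,
#' pelvis at the origin: `position(seg) = position(parent) +
#' rotate(orientation(parent), offset(seg))`.  Orientations are the
#' pelvis-relative segment orientations (pelvis row = identity); the result
#' is therefore invariant to global body orientation and to quaternion sign.
#'
#' @param skel A `skeleton`.
#' @param pose A 23 x 4 quaternion matrix with segment rownames.
#' @return A 23 x 3 matrix of joint positions (metres) in the pelvis frame.
#' @export
forward_kinematics <- function(skel, pose) {
  pose <- .check_pose(pose)
  qs <- array(pose, dim = c(1L, 23L, 4L))
  drop_third <- fk_sequence(skel, qs)
  pos <- matrix(drop_third, nrow = 23L, ncol = 3L,
                dimnames = list(SEGMENT_NAMES, c("x", "y", "z")), byrow = FALSE)
  pos
}

#' Forward kinematics over a pose sequence
#'
#' Vectorised forward kinematics: one call per segment rather than per frame.
#'
#' @param skel A `skeleton`.
#' @param quats An `n x 23 x 4` array of pelvis-relative orientations
#'   (segment order `SEGMENT_NAMES` along the second dimension).
#' @return An `n x 23 x 3` array of joint positions in the pelvis frame.
#' @export
fk_sequence <- function(skel, quats) {
  d <- dim(quats)
  if (length(d) != 3L || d[2] != 23L || d[3] != 4L)
    stop("'quats' must be an n x 23 x 4 array")
  n <- d[1]
  pos <- array(0, dim = c(n, 23L, 3L),
               dimnames = list(NULL, SEGMENT_NAMES, c("x", "y", "z")))
  idx <- stats::setNames(seq_along(SEGMENT_NAMES), SEGMENT_NAMES)
  for (si in 2:23) {
    seg <- SEGMENT_NAMES[si]
    pi_ <- idx[[skel$parent[[seg]]]]
    qp <- quats[, pi_, , drop = TRUE]
    if (n == 1L) qp <- matrix(qp, nrow = 1L)
    off <- skel$offsets[seg, ]
    pos[, si, ] <- pos[, pi_, ] +
      quat_rotate(quat_normalize(qp), matrix(off, nrow = 1L))
  }
  pos
}

#' Total chain length of the skeleton from head to toe
#'
#' Sum of offset lengths along the head-to-pelvis-to-toe kinematic chain;
#' a consistency check on the proportion table (close to the stature).
#'
#' @param skel A `skeleton`.
#' @return Chain length in metres.
#' @export
skeleton_chain_length <- function(skel) {
  chain <- c("Head", "Neck", "T8", "T12", "L3", "L5",
             "RightUpperLeg", "RightLowerLeg", "RightFoot", "RightToe")
  sum(sqrt(rowSums(skel$offsets[chain, , drop = FALSE]^2)))
}
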