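# Input feature engineering: the five sensor segments' global orientations
# (and optionally their sensor-frame accelerations) are reduced to
# pelvis-relative quantities, which makes every feature invariant to the
# orientation of the body with respect to the world.

.limb_segments <- function(limb_pair) {
  switch(match.arg(limb_pair, c("upper", "lower")),
         upper = c("LeftForearm", "RightForearm"),
         lower = c("LeftLowerLeg", "RightLowerLeg"))
}

#' Pelvis-relative orientation features
#'
#' For the chosen limb pair (forearms for the upper body, lower legs for the
#' lower body) returns the two limb orientations expressed relative to the
#' pelvis as unit quaternions: 8 feature columns per frame, left limb first.
#'
#' @param seq A `motion_sequence` containing at least the 5 sensor segments.
#' @param limb_pair `"upper"` (forearms) or `"lower"` (lower legs).
#' @return An `n x 8` matrix, columns `<Segment>.<w|x|y|z>`.
#' @export
orientation_features <- function(seq, limb_pair = c("upper", "lower")) {
  segs <- .limb_segments(limb_pair)
  rel <- pelvis_relative_orientations(seq, segs)
  left <- matrix(rel[, 1, ], nrow = seq$n_frames)
  right <- matrix(rel[, 2, ], nrow = seq$n_frames)
  out <- cbind(left, right)
  colnames(out) <- c(paste0(segs[1], ".", c("w", "x", "y", "z")),
                     paste0(segs[2], ".", c("w", "x", "y", "z")))
  out
}

#' Pelvis-relative acceleration features
#'
#' Implements the acceleration processing pipeline: each sensor's measured
#' specific force is rotated to the global frame using the sensor's
#' orientation, the pelvis sensor's global acceleration is subtracted (which
#' cancels gravity and any common-mode acceleration), and the difference is
#' rotated into the pelvis frame.
#'
#' @param seq A `motion_sequence` whose `accelerations` field is present.
#' @param limb_pair `"upper"` or `"lower"`.
#' @return An `n x 6` matrix (m/s^2), columns `<Segment>.a<x|y|z>`, left
#'   limb first.
#' @export
acceleration_features <- function(seq, limb_pair = c("upper", "lower")) {
  if (is.null(seq$accelerations))
    stop("sequence has no accelerations; record or simulate them first")
  segs <- .limb_segments(limb_pair)
  qp <- quat_normalize(.seq_quats(seq, "Pelvis"))
  a_p_global <- quat_rotate(qp, .seq_accel(seq, "Pelvis"))
  cp <- quat_conjugate(qp)
  cols <- list()
  for (s in segs) {
    qi <- quat_normalize(.seq_quats(seq, s))
    a_global <- quat_rotate(qi, .seq_accel(seq, s))
    cols[[s]] <- quat_rotate(cp, a_global - a_p_global)
  }
  out <- do.call(cbind, cols)
  colnames(out) <- c(paste0(segs[1], ".a", c("x", "y", "z")),
                     paste0(segs[2], ".a", c("x", "y", "z")))
  out
}

.seq_accel <- function(seq, segment) {
  a <- seq$accelerations[, segment, , drop = TRUE]
  if (seq$n_frames == 1L) a <- matrix(a, nrow = 1L)
  a
}

#' Build the per-frame feature matrix for one body half
#'
#' Assembles the 8 orientation features (and optionally the 6 acceleration
#' features) for every frame of a sequence.  Orientation features are sign-
#' canonicalized as a temporal sequence so components are continuous in time.
#'
#' @param seq A `motion_sequence`.
#' @param limb_pair `"upper"` or `"lower"`.
#' @param use_accel Include acceleration features? Requires the sequence to
#'   carry accelerations.
#' @return An `n x D` matrix, `D = 8` or `14`, with attribute `fs`.
#' @export
build_feature_sequence <- function(seq, limb_pair = c("upper", "lower"),
                                   use_accel = FALSE) {
  feats <- orientation_features(seq, limb_pair)
  if (use_accel)
    feats <- cbind(feats, acceleration_features(seq, limb_pair))
  attr(feats, "fs") <- seq$fs
  feats
}
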