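# MotionSequence: per-subject, per-trial time series of global segment
# orientations (all 23 segments for ground-truth data, or at least the five
# sensor segments for sensor-only data), optional sensor-frame accelerations
# for the five sensor segments, and an optional global pelvis trajectory.

#' Construct a motion sequence
#'
#' @param orientations `n x k x 4` array of unit quaternions in a common
#'   global frame; the second dimension must carry segment dimnames covering
#'   at least the five sensor segments (`INPUT_SEGMENTS`).
#' @param fs Sampling frequency in Hz (> 0).
#' @param subject_id Subject identifier (character).
#' @param activity Activity label, e.g. `"gait"`, `"sports"`, `"adl"`.
#' @param stature_m Subject stature in metres.
#' @param accelerations Optional `n x 5 x 3` array of sensor-frame specific
#'   force (m/s^2), second dimension named by `INPUT_SEGMENTS`.
#' @param pelvis_position Optional `n x 3` matrix: global pelvis trajectory
#'   in metres (used when simulating accelerometer readings).
#' @return An object of class `motion_sequence`.
#' @export
motion_sequence <- function(orientations, fs, subject_id = "S1",
                            activity = "unknown", stature_m = 1.75,
                            accelerations = NULL, pelvis_position = NULL) {
  d <- dim(orientations)
  if (length(d) != 3L || d[3] != 4L)
    stop("'orientations' must be an n x segments x 4 array")
  segs <- dimnames(orientations)[[2]]
  if (is.null(segs) || !all(INPUT_SEGMENTS %in% segs))
    stop("'orientations' must carry segment dimnames including the 5 sensor segments")
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be a positive frequency (Hz)")
  n <- d[1]
  if (!is.null(accelerations)) {
    da <- dim(accelerations)
    if (length(da) != 3L || da[1] != n || da[3] != 3L)
      stop("'accelerations' must be an n x 5 x 3 array aligned with the frames")
    asegs <- dimnames(accelerations)[[2]]
    if (is.null(asegs) || !setequal(asegs, INPUT_SEGMENTS))
      stop("'accelerations' must be named by the 5 sensor segments")
    accelerations <- accelerations[, INPUT_SEGMENTS, , drop = FALSE]
  }
  if (!is.null(pelvis_position)) {
    if (!is.matrix(pelvis_position) || nrow(pelvis_position) != n ||
        ncol(pelvis_position) != 3L)
      stop("'pelvis_position' must be an n x 3 matrix")
  }
  structure(list(orientations = orientations, accelerations = accelerations,
                 pelvis_position = pelvis_position, fs = fs,
                 subject_id = as.character(subject_id),
                 activity = as.character(activity),
                 stature_m = stature_m, n_frames = n),
            class = "motion_sequence")
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat(sprintf(
    "<motion_sequence> subject %s, activity %s: %d frames @ %g Hz (%.1f s)%s\n",
    x$subject_id, x$activity, x$n_frames, x$fs, x$n_frames / x$fs,
    if (is.null(x$accelerations)) "" else ", with accelerations"))
  invisible(x)
}

#' Number of frames
#' @param seq A `motion_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) seq$n_frames

.seq_quats <- function(seq, segment) {
  q <- seq$orientations[, segment, , drop = TRUE]
  if (seq$n_frames == 1L) q <- matrix(q, nrow = 1L)
  q
}

#' Pelvis-relative orientations for a set of segments
#'
#' For each requested segment, computes `conj(q_pelvis) * q_segment` and
#' repairs quaternion sign continuity over time.
#'
#' @param seq A `motion_sequence`.
#' @param segments Character vector of segment names.
#' @return An `n x length(segments) x 4` array of canonical pelvis-relative
#'   quaternions (pelvis itself maps to the identity).
#' @export
pelvis_relative_orientations <- function(seq, segments = SEGMENT_NAMES) {
  avail <- dimnames(seq$orientations)[[2]]
  missing <- setdiff(segments, avail)
  if (length(missing))
    stop("sequence is missing segments: ", paste(missing, collapse = ", "))
  qp <- quat_normalize(.seq_quats(seq, "Pelvis"))
  out <- array(NA_real_, dim = c(seq$n_frames, length(segments), 4L),
               dimnames = list(NULL, segments, c("w", "x", "y", "z")))
  cp <- quat_conjugate(qp)
  for (s in segments) {
    if (s == "Pelvis") {
      out[, s, ] <- quat_identity(seq$n_frames)
    } else {
      rel <- quat_multiply(cp, quat_normalize(.seq_quats(seq, s)))
      out[, s, ] <- quat_canonicalize_sequence(rel)
    }
  }
  out
}

#' Ground-truth pose target matrix for one body half
#'
#' Flattens the pelvis-relative orientations of the output segments of a
#' body half into the regression target matrix: 4 columns (w, x, y, z) per
#' segment, 48 columns for the upper body, 24 for the lower body.
#'
#' @param seq A `motion_sequence` containing all 23 segments.
#' @param body_half `"upper"` or `"lower"`.
#' @return An `n x (4 * n_segments)` numeric matrix with named columns.
#' @export
pose_targets <- function(seq, body_half = c("upper", "lower")) {
  body_half <- match.arg(body_half)
  segs <- if (body_half == "upper") UPPER_OUTPUT_SEGMENTS else LOWER_OUTPUT_SEGMENTS
  rel <- pelvis_relative_orientations(seq, segs)
  out <- matrix(NA_real_, nrow = seq$n_frames, ncol = 4L * length(segs))
  cn <- character(0)
  for (i in seq_along(segs)) {
    out[, (4 * i - 3):(4 * i)] <- rel[, i, ]
    cn <- c(cn, paste0(segs[i], ".", c("w", "x", "y", "z")))
  }
  colnames(out) <- cn
  out
}

#' Full pelvis-relative pose array for a sequence
#'
#' @param seq A `motion_sequence` with all 23 segments.
#' @return An `n x 23 x 4` array (canonical, pelvis = identity).
#' @export
pose_array <- function(seq) pelvis_relative_orientations(seq, SEGMENT_NAMES)
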