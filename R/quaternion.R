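# Quaternion algebra: Hamilton convention, scalar-first (w, x, y, z),
# right-handed frames.  A quaternion q gives the orientation of a body
# (segment/sensor) frame in a reference frame, so quat_rotate(q, v) maps
# body-frame coordinates to reference-frame coordinates.
#
# All operations accept either a length-4 numeric vector or an n x 4 matrix
# (one quaternion per row) and are vectorised over rows.

.quat_mat <- function(q, arg = "q") {
  if (is.null(dim(q))) {
    if (length(q) != 4L)
      stop(sprintf("'%s' must have 4 components (w, x, y, z)", arg))
    q <- matrix(q, nrow = 1L)
  }
  if (ncol(q) != 4L)
    stop(sprintf("'%s' must have 4 columns (w, x, y, z)", arg))
  if (!all(is.finite(q)))
    stop(sprintf("'%s' contains non-finite values", arg))
  q
}

# return in the same shape the caller used
.quat_shape <- function(res, template) {
  if (is.null(dim(template)) && nrow(res) == 1L) drop(res) else res
}

#' Identity quaternion(s)
#'
#' @param n Number of identity quaternions to return.
#' @return A length-4 vector if `n == 1`, otherwise an `n x 4` matrix.
#' @export
quat_identity <- function(n = 1L) {
  q <- cbind(w = rep(1, n), x = 0, y = 0, z = 0)
  if (n == 1L) drop(q) else q
}

#' Normalize quaternions to unit norm
#'
#' @param q Quaternion(s): length-4 vector or `n x 4` matrix.
#' @return Unit quaternion(s) in the same shape.
#' @export
quat_normalize <- function(q) {
  qm <- .quat_mat(q)
  nrm <- sqrt(rowSums(qm^2))
  if (any(nrm == 0)) stop("cannot normalize a zero quaternion")
  .quat_shape(qm / nrm, q)
}

#' Hamilton product of quaternions
#'
#' Composes two rotations: if `a` maps frame B to frame A and `b` maps
#' frame C to frame B, then `quat_multiply(a, b)` maps frame C to frame A.
#' Row-wise with recycling of a single quaternion against a matrix.
#'
#' @param a,b Quaternions (length-4 vectors or `n x 4` matrices).
#' @return The product(s), same shape conventions as the inputs.
#' @export
quat_multiply <- function(a, b) {
  am <- .quat_mat(a, "a"); bm <- .quat_mat(b, "b")
  n <- max(nrow(am), nrow(bm))
  if (nrow(am) == 1L && n > 1L) am <- am[rep(1L, n), , drop = FALSE]
  if (nrow(bm) == 1L && n > 1L) bm <- bm[rep(1L, n), , drop = FALSE]
  if (nrow(am) != nrow(bm))
    stop("'a' and 'b' must have the same number of rows (or one row)")
  w <- am[, 1] * bm[, 1] - am[, 2] * bm[, 2] - am[, 3] * bm[, 3] - am[, 4] * bm[, 4]
  x <- am[, 1] * bm[, 2] + am[, 2] * bm[, 1] + am[, 3] * bm[, 4] - am[, 4] * bm[, 3]
  y <- am[, 1] * bm[, 3] - am[, 2] * bm[, 4] + am[, 3] * bm[, 1] + am[, 4] * bm[, 2]
  z <- am[, 1] * bm[, 4] + am[, 2] * bm[, 3] - am[, 3] * bm[, 2] + am[, 4] * bm[, 1]
  res <- cbind(w = w, x = x, y = y, z = z)
  template <- if (is.null(dim(a)) && is.null(dim(b))) numeric(4) else matrix(0)
  .quat_shape(res, template)
}

#' Quaternion conjugate
#'
#' For unit quaternions the conjugate is the inverse rotation.
#'
#' @param q Quaternion(s).
#' @return `(w, -x, -y, -z)`, same shape.
#' @export
quat_conjugate <- function(q) {
  qm <- .quat_mat(q)
  .quat_shape(cbind(w = qm[, 1], x = -qm[, 2], y = -qm[, 3], z = -qm[, 4]), q)
}

#' Rotate 3-vectors by quaternions
#'
#' Applies the rotation encoded by unit quaternion(s) `q` to vector(s) `v`,
#' i.e. maps body-frame coordinates to the reference frame.
#'
#' @param q Unit quaternion(s) (length-4 or `n x 4`).
#' @param v 3-vector(s) (length-3 or `n x 3`).
#' @param tol Unit-norm tolerance; deviations beyond it are an error.
#' @return Rotated vector(s), same shape conventions as `v`.
#' @export
quat_rotate <- function(q, v, tol = 1e-6) {
  qm <- .quat_mat(q)
  if (is.null(dim(v))) {
    if (length(v) != 3L) stop("'v' must have 3 components")
    vm <- matrix(v, nrow = 1L)
  } else vm <- v
  if (ncol(vm) != 3L) stop("'v' must have 3 columns")
  if (!all(is.finite(vm))) stop("'v' contains non-finite values")
  nrm <- rowSums(qm^2)
  if (any(abs(nrm - 1) > 2 * tol))
    stop("'q' must be unit-norm (use quat_normalize first)")
  n <- max(nrow(qm), nrow(vm))
  if (nrow(qm) == 1L && n > 1L) qm <- qm[rep(1L, n), , drop = FALSE]
  if (nrow(vm) == 1L && n > 1L) vm <- vm[rep(1L, n), , drop = FALSE]
  if (nrow(qm) != nrow(vm))
    stop("'q' and 'v' must have the same number of rows (or one row)")
  w <- qm[, 1]; u <- qm[, 2:4, drop = FALSE]
  # v' = v + 2 w (u x v) + 2 u x (u x v)
  cross <- function(a, b) cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1])
  uv <- cross(u, vm)
  res <- vm + 2 * w * uv + 2 * cross(u, uv)
  colnames(res) <- c("x", "y", "z")
  if (is.null(dim(v)) && nrow(res) == 1L) drop(res) else res
}

#' Relative orientation with respect to a reference
#'
#' Expresses `q` in the frame of `reference`:
#' `conj(reference) * q`, canonicalized to the `w >= 0` hemisphere.
#' Used to make all segment orientations pelvis-relative.
#'
#' @param reference,q Unit quaternion(s).
#' @param tol Unit-norm tolerance.
#' @return Canonical relative quaternion(s).
#' @export
quat_relative <- function(reference, q, tol = 1e-6) {
  rm_ <- .quat_mat(reference, "reference"); qm <- .quat_mat(q)
  if (any(abs(rowSums(rm_^2) - 1) > 2 * tol) || any(abs(rowSums(qm^2) - 1) > 2 * tol))
    stop("'reference' and 'q' must be unit-norm")
  quat_canonical(quat_multiply(quat_conjugate(reference), q))
}

#' Canonicalize to the non-negative hemisphere
#'
#' Flips the sign of any quaternion with `w < 0`; a tie at `w == 0` is broken
#' by requiring the first nonzero of `(x, y, z)` to be non-negative.  The
#' rotation represented is unchanged (q and -q are the same rotation).
#'
#' @param q Quaternion(s).
#' @return Hemisphere-canonical quaternion(s), same shape.
#' @export
quat_canonical <- function(q) {
  qm <- .quat_mat(q)
  s <- sign(qm[, 1])
  z1 <- s == 0
  if (any(z1)) {
    s[z1] <- sign(qm[z1, 2])
    z2 <- s == 0
    if (any(z2)) {
      s[z2] <- sign(qm[z2, 3])
      z3 <- s == 0
      if (any(z3)) s[z3] <- sign(qm[z3, 4])
    }
  }
  s[s == 0] <- 1
  .quat_shape(qm * s, q)
}

#' Temporal sign-continuity canonicalization
#'
#' Resolves the q/-q double cover along a time-ordered quaternion sequence so
#' that consecutive samples have a non-negative dot product, making the
#' component series continuous in time (required before stacking windows or
#' regressing on components).  The first sample is placed on the `w >= 0`
#' hemisphere.
#'
#' @param qs Time-ordered quaternions as an `n x 4` matrix (or length-4
#'   vector for a single sample).
#' @return The sign-repaired sequence, same shape; each row equals its input
#'   up to sign.
#' @export
quat_canonicalize_sequence <- function(qs) {
  if (is.null(dim(qs)) && length(qs) == 0L) return(qs)
  qm <- .quat_mat(qs, "qs")
  n <- nrow(qm)
  if (n == 0L) return(qs)
  d <- rowSums(qm[-1L, , drop = FALSE] * qm[-n, , drop = FALSE])
  flip <- cumprod(c(1, ifelse(d < 0, -1, 1)))
  out <- qm * flip
  # one global sign so the first sample is hemisphere-canonical
  first <- quat_canonical(out[1L, ])
  if (any(first != out[1L, ])) out <- -out
  .quat_shape(out, qs)
}

#' Quaternion from axis and angle
#'
#' @param axis A 3-vector (normalized internally).
#' @param angle Rotation angle(s) in radians; vectorised.
#' @return A unit quaternion (length-4) or `n x 4` matrix for vector `angle`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  if (length(axis) != 3L || !all(is.finite(axis)))
    stop("'axis' must be a finite 3-vector")
  a <- axis / sqrt(sum(axis^2))
  res <- cbind(w = cos(angle / 2),
               x = a[1] * sin(angle / 2),
               y = a[2] * sin(angle / 2),
               z = a[3] * sin(angle / 2))
  if (length(angle) == 1L) drop(res) else res
}

#' Rotation matrix from a unit quaternion
#'
#' @param q A single unit quaternion.
#' @return The corresponding 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- .quat_mat(q)
  if (nrow(q) != 1L) stop("quat_to_matrix expects a single quaternion")
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3L, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#'
#' Shepperd's method: picks the numerically largest of the four candidate
#' pivots; result is hemisphere-canonical.
#'
#' @param R A 3x3 rotation matrix.
#' @return A unit quaternion (length-4 vector).
#' @export
quat_from_matrix <- function(R) {
  if (!is.matrix(R) || any(dim(R) != 3L) || !all(is.finite(R)))
    stop("'R' must be a finite 3x3 matrix")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  cand <- c(tr, R[1, 1], R[2, 2], R[3, 3])
  i <- which.max(cand)
  if (i == 1L) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (i == 2L) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (i == 3L) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  names(q) <- c("w", "x", "y", "z")
  quat_canonical(quat_normalize(q))
}
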