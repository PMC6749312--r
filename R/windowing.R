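# Stacked time-window construction.  One training/evaluation example pairs
# the features at sample offsets {-P*I, ..., -I, 0, +I, ..., +F*I} around a
# centre frame with the full-body pose target at the centre frame.  P past
# and F future samples at inter-sample interval I (frames) give a stacked
# input length SIL = P + 1 + F; using future samples incurs an acquisition
# delay of F*I/fs seconds.

#' Window configuration
#'
#' @param P Number of past samples (>= 0).
#' @param F_ Number of future samples (>= 0).
#' @param I Inter-sample interval in frames (>= 1).
#' @param fs Sampling frequency in Hz.
#' @return A `window_config`: list with `P`, `F`, `I`, `fs` and the derived
#'   `dt = I/fs` (s), `SIL = P + 1 + F`, and `delay_s = F*I/fs` (s).
#' @export
window_config <- function(P = 2L, F_ = 2L, I = 2L, fs = 60) {
  P <- as.integer(P); F_ <- as.integer(F_); I <- as.integer(I)
  if (is.na(P) || P < 0L) stop("'P' must be a non-negative integer")
  if (is.na(F_) || F_ < 0L) stop("'F' must be a non-negative integer")
  if (is.na(I) || I < 1L) stop("'I' must be a positive integer")
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be a positive frequency (Hz)")
  structure(list(P = P, F = F_, I = I, fs = fs,
                 dt = I / fs, SIL = P + 1L + F_,
                 delay_s = F_ * I / fs),
            class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf(
    "<window_config> P=%d F=%d I=%d fs=%g Hz | SIL=%d, dt=%.4f s, delay=%.1f ms\n",
    x$P, x$F, x$I, x$fs, x$SIL, x$dt, 1000 * x$delay_s))
  invisible(x)
}

#' Acquisition delay of a window configuration
#'
#' The delay introduced by waiting for future sensor samples: `F * I / fs`
#' seconds.  This is the data-acquisition part of the total output delay
#' (computation time comes on top and is hardware-dependent).
#'
#' @param cfg A `window_config`.
#' @return Delay in seconds.
#' @export
delay_seconds <- function(cfg) {
  stopifnot(inherits(cfg, "window_config"))
  cfg$F * cfg$I / cfg$fs
}

#' Down-sample a motion sequence by plain decimation
#'
#' Keeps every `factor`-th frame starting at index 1 (sample 0); no
#' filtering is applied.  Applies to orientations, accelerations and the
#' pelvis trajectory alike; the sampling frequency becomes `fs / factor`.
#'
#' @param seq A `motion_sequence`.
#' @param factor Integer decimation factor (>= 1).
#' @return The decimated `motion_sequence`.
#' @export
downsample_sequence <- function(seq, factor = 4L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be a positive integer")
  if (factor == 1L) return(seq)
  keep <- seq.int(1L, seq$n_frames, by = factor)
  motion_sequence(
    orientations = seq$orientations[keep, , , drop = FALSE],
    fs = seq$fs / factor,
    subject_id = seq$subject_id, activity = seq$activity,
    stature_m = seq$stature_m,
    accelerations = if (is.null(seq$accelerations)) NULL else
      seq$accelerations[keep, , , drop = FALSE],
    pelvis_position = if (is.null(seq$pelvis_position)) NULL else
      seq$pelvis_position[keep, , drop = FALSE])
}

#' Build stacked window samples from a feature sequence
#'
#' Every frame with full past/future context becomes one sample; boundary
#' frames lacking context are dropped (no padding).  The stacked input row
#' is the frame-by-frame concatenation of the window's feature vectors,
#' oldest frame first, i.e. the column-major flattening of the `D x SIL`
#' input matrix consumed by the recurrent model.
#'
#' @param features `n x D` feature matrix (see [build_feature_sequence()]).
#' @param targets `n x K` aligned target matrix (see [pose_targets()]).
#' @param cfg A `window_config`.
#' @param subject_id,activity Metadata attached to every sample.
#' @return A `window_set`: list with `X` (`m x D*SIL`), `Y` (`m x K`),
#'   `centre` (1-based centre frame indices), `subject`, `activity`
#'   (length-`m` vectors), `D`, `SIL`, `cfg`.  `m = n - (P+F)*I` (0 if the
#'   sequence is too short, with a warning).
#' @export
build_windows <- function(features, targets, cfg, subject_id = "S1",
                          activity = "unknown") {
  stopifnot(inherits(cfg, "window_config"))
  if (!is.matrix(features)) stop("'features' must be a matrix")
  if (!is.matrix(targets)) stop("'targets' must be a matrix")
  n <- nrow(features)
  if (nrow(targets) != n)
    stop("'features' and 'targets' must be aligned (same number of rows)")
  D <- ncol(features)
  span <- (cfg$P + cfg$F) * cfg$I
  offs <- seq.int(-cfg$P, cfg$F) * cfg$I
  m <- n - span
  if (m <= 0L) {
    warning(sprintf("sequence of %d frames too short for window span %d; no samples",
                    n, span))
    return(structure(list(
      X = matrix(numeric(0), nrow = 0L, ncol = D * cfg$SIL),
      Y = targets[0, , drop = FALSE], centre = integer(0),
      subject = character(0), activity = character(0),
      D = D, SIL = cfg$SIL, cfg = cfg), class = "window_set"))
  }
  centre <- seq.int(cfg$P * cfg$I + 1L, n - cfg$F * cfg$I)
  X <- matrix(NA_real_, nrow = m, ncol = D * cfg$SIL)
  for (j in seq_along(offs)) {
    X[, ((j - 1L) * D + 1L):(j * D)] <- features[centre + offs[j], , drop = FALSE]
  }
  colnames(X) <- paste0(rep(colnames(features), times = cfg$SIL),
                        "@", rep(offs, each = D))
  structure(list(X = X, Y = targets[centre, , drop = FALSE], centre = centre,
                 subject = rep(as.character(subject_id), m),
                 activity = rep(as.character(activity), m),
                 D = D, SIL = cfg$SIL, cfg = cfg),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d samples, D=%d, SIL=%d (input %d), targets %d\n",
              nrow(x$X), x$D, x$SIL, ncol(x$X), ncol(x$Y)))
  invisible(x)
}

#' Unstack one stacked input row to the D x SIL input matrix
#'
#' @param x_row A stacked input vector of length `D * SIL`.
#' @param D Per-frame feature dimensionality.
#' @param SIL Stacked input length.
#' @return A `D x SIL` matrix, oldest frame in column 1.
#' @export
unstack_input <- function(x_row, D, SIL) {
  if (length(x_row) != D * SIL) stop("input length must equal D * SIL")
  matrix(x_row, nrow = D, ncol = SIL)
}

#' Concatenate window sets
#'
#' @param sets A list of `window_set` objects with identical `D` and `SIL`.
#' @return One combined `window_set`.
#' @export
bind_window_sets <- function(sets) {
  sets <- Filter(function(s) nrow(s$X) > 0L, sets)
  if (!length(sets)) stop("no non-empty window sets to combine")
  D <- sets[[1]]$D; SIL <- sets[[1]]$SIL
  for (s in sets) if (s$D != D || s$SIL != SIL)
    stop("window sets have inconsistent dimensions")
  structure(list(
    X = do.call(rbind, lapply(sets, `[[`, "X")),
    Y = do.call(rbind, lapply(sets, `[[`, "Y")),
    centre = unlist(lapply(sets, `[[`, "centre")),
    subject = unlist(lapply(sets, `[[`, "subject")),
    activity = unlist(lapply(sets, `[[`, "activity")),
    D = D, SIL = SIL, cfg = sets[[1]]$cfg), class = "window_set")
}

#' Enumerate window configurations over a grid
#'
#' For each stacked input length, all `(P, F)` splits with `P + 1 + F = SIL`
#' are crossed with each interval, in deterministic order (ascending SIL,
#' then P, then I).
#'
#' @param SILs Positive integer vector of stacked input lengths.
#' @param Is Positive integer vector of sample intervals.
#' @param fs Sampling frequency for the resulting configurations.
#' @return A data.frame with columns `SIL`, `P`, `F`, `I` and a list column
#'   `cfg` of `window_config` objects.
#' @export
enumerate_configs <- function(SILs, Is, fs = 60) {
  SILs <- sort(unique(as.integer(SILs))); Is <- sort(unique(as.integer(Is)))
  if (any(SILs < 1L)) stop("'SILs' must be positive")
  if (any(Is < 1L)) stop("'Is' must be positive")
  rows <- list()
  for (sil in SILs) for (P in 0:(sil - 1L)) for (I in Is) {
    rows[[length(rows) + 1L]] <-
      data.frame(SIL = sil, P = P, F = sil - 1L - P, I = I)
  }
  out <- do.call(rbind, rows)
  out$cfg <- lapply(seq_len(nrow(out)), function(i)
    window_config(out$P[i], out$F[i], out$I[i], fs))
  out
}
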