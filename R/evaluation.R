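# Evaluation metrics: mean joint position error via forward kinematics and
# joint jerk error via third differentiation of the joint-position series,
# aggregated under subject-wise k-fold cross-validation.

#' Mean joint position error between two poses (or pose sequences)
#'
#' Forward kinematics is run on the ground-truth and estimated poses (both
#' pelvis-relative, pelvis at the origin) and the Euclidean distances of the
#' 23 joint positions are averaged per frame.  Invariant to global body
#' orientation and quaternion sign.
#'
#' @param skel A `skeleton`.
#' @param truth,estimate 23 x 4 pose matrices (one frame) or `n x 23 x 4`
#'   pose arrays.
#' @return Per-frame mean joint position error(s), metres.
#' @export
joint_position_error <- function(skel, truth, estimate) {
  truth <- .as_pose_array(truth)
  estimate <- .as_pose_array(estimate)
  if (!identical(dim(truth), dim(estimate)))
    stop("'truth' and 'estimate' must have the same dimensions")
  pt <- fk_sequence(skel, truth)
  pe <- fk_sequence(skel, estimate)
  d2 <- (pt - pe)^2
  dist <- sqrt(d2[, , 1] + d2[, , 2] + d2[, , 3])
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = 1L)
  rowMeans(dist)
}

.as_pose_array <- function(pose) {
  if (is.matrix(pose)) {
    pose <- .check_pose(pose)
    array(pose, dim = c(1L, 23L, 4L),
          dimnames = list(NULL, SEGMENT_NAMES, c("w", "x", "y", "z")))
  } else if (length(dim(pose)) == 3L) {
    if (dim(pose)[2] != 23L || dim(pose)[3] != 4L)
      stop("pose array must be n x 23 x 4")
    pose
  } else stop("pose must be a 23 x 4 matrix or an n x 23 x 4 array")
}

#' Jerk of a position time series
#'
#' Third time derivative by the 5-point central stencil
#' `[p(t+2h) - 2 p(t+h) + 2 p(t-h) - p(t-2h)] / (2 h^3)` with `h = 1/fs`;
#' exact for cubic trajectories, accuracy order O(h^2).  The output loses
#' two frames at each end.
#'
#' @param positions `n x 3` matrix of positions (metres), `n >= 5`.
#' @param fs Sampling frequency (Hz).
#' @return `(n - 4) x 3` matrix of jerk (m/s^3), row `t` corresponding to
#'   input frame `t + 2`.
#' @export
jerk <- function(positions, fs) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1L)
  n <- nrow(positions)
  if (n < 5L) stop("jerk needs at least 5 frames")
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be a positive frequency")
  h <- 1 / fs
  idx <- 3:(n - 2L)
  (positions[idx + 2L, , drop = FALSE] - 2 * positions[idx + 1L, , drop = FALSE] +
     2 * positions[idx - 1L, , drop = FALSE] - positions[idx - 2L, , drop = FALSE]) /
    (2 * h^3)
}

#' Joint jerk error between two pose sequences
#'
#' Runs forward kinematics on both sequences, differentiates every joint's
#' position series three times (5-point stencil), and averages over the 23
#' joints the Euclidean norm of the jerk difference per interior frame.
#'
#' @param skel A `skeleton`.
#' @param truth_seq,estimate_seq `n x 23 x 4` pose arrays, `n >= 5`.
#' @param fs Sampling frequency (Hz).
#' @return Length `n - 4` vector of mean joint jerk errors (m/s^3).
#' @export
joint_jerk_error <- function(skel, truth_seq, estimate_seq, fs) {
  truth_seq <- .as_pose_array(truth_seq)
  estimate_seq <- .as_pose_array(estimate_seq)
  if (!identical(dim(truth_seq), dim(estimate_seq)))
    stop("sequences must have the same dimensions")
  n <- dim(truth_seq)[1]
  if (n < 5L) stop("jerk error needs at least 5 frames")
  pt <- fk_sequence(skel, truth_seq)
  pe <- fk_sequence(skel, estimate_seq)
  err <- matrix(0, n - 4L, 23L)
  for (s in seq_len(23L)) {
    jd <- jerk(pt[, s, ], fs) - jerk(pe[, s, ], fs)
    err[, s] <- sqrt(rowSums(jd^2))
  }
  rowMeans(err)
}

#' Constant-mean-pose baseline predictor
#'
#' The naive reference model: predict, for every test frame, the per-
#' component mean of the training targets renormalized to unit quaternions.
#' Learned models must beat this floor for the claim of exploiting motion
#' redundancy to hold.
#'
#' @param train_targets `m x 4k` training target matrix.
#' @return A length `4k` mean pose vector (unit quaternions per segment).
#' @export
mean_pose_baseline <- function(train_targets) {
  drop(renormalize_pose_matrix(matrix(colMeans(train_targets), nrow = 1L)))
}

## ---- cross-validation ---------------------------------------------------

.dataset_subjects <- function(dataset) {
  vapply(dataset, function(s) s$subject_id, character(1))
}

# windows + metadata for all sequences of the given subjects
.subject_windows <- function(dataset, subjects, cfg, body_half, use_accel) {
  sets <- list()
  for (seq_ in dataset) {
    if (!(seq_$subject_id %in% subjects)) next
    feats <- build_feature_sequence(seq_, body_half, use_accel = use_accel)
    targs <- pose_targets(seq_, body_half)
    sets[[length(sets) + 1L]] <-
      build_windows(feats, targs, cfg, seq_$subject_id, seq_$activity)
  }
  bind_window_sets(sets)
}

# evaluate trained upper+lower models on one held-out sequence
.evaluate_sequence <- function(seq_, models, cfg, use_accel, skel) {
  wu <- build_windows(build_feature_sequence(seq_, "upper", use_accel),
                      pose_targets(seq_, "upper"), cfg,
                      seq_$subject_id, seq_$activity)
  wl <- build_windows(build_feature_sequence(seq_, "lower", use_accel),
                      pose_targets(seq_, "lower"), cfg,
                      seq_$subject_id, seq_$activity)
  if (nrow(wu$X) == 0L) return(NULL)
  up <- predict(models$upper, wu)
  lo <- predict(models$lower, wl)
  rel <- pelvis_relative_orientations(seq_, INPUT_SEGMENTS)
  inputs <- rel[wu$centre, , , drop = FALSE]
  est <- assemble_pose_sequence(up, lo, inputs)
  truth <- pose_array(seq_)[wu$centre, , , drop = FALSE]

  # baselines: constant mean training pose for both halves
  base_est <- assemble_pose_sequence(
    matrix(models$baseline_upper, nrow(up), 48L, byrow = TRUE),
    matrix(models$baseline_lower, nrow(lo), 24L, byrow = TRUE),
    inputs)

  pos_err <- joint_position_error(skel, truth, est)
  base_pos_err <- joint_position_error(skel, truth, base_est)
  n <- length(pos_err)
  jerk_err <- if (n >= 5L) joint_jerk_error(skel, truth, est, seq_$fs) else numeric(0)
  list(activity = seq_$activity, pos_err = pos_err, jerk_err = jerk_err,
       base_pos_err = base_pos_err)
}

#' Subject-wise k-fold cross-validation of the pose estimators
#'
#' For each subject in turn, trains upper- and lower-body networks on all
#' remaining subjects and evaluates mean joint position error and joint
#' jerk error on the held-out subject's sequences.  A constant-mean-pose
#' baseline (training-set mean target) is evaluated alongside.
#'
#' @param dataset List of `motion_sequence` objects (>= 2 subjects).
#' @param cfg A `window_config`.
#' @param use_accel Include acceleration features?
#' @param architecture `"sinn"` or `"rnn"`.
#' @param seed Integer seed (training seeds are derived per fold).
#' @param max_folds Optionally evaluate only the first `max_folds` folds
#'   (all folds by default).
#' @param ... Overrides passed to [model_spec()] (e.g. `max_epochs`,
#'   `hidden`).
#' @return A `cv_result`: list with per-fold results (`folds`), pooled
#'   summary (`pooled`), per-activity medians (`activity_medians`) and the
#'   configuration used.
#' @export
subject_wise_cv <- function(dataset, cfg, use_accel = FALSE,
                            architecture = c("sinn", "rnn"),
                            seed = 1L, max_folds = NULL, ...) {
  architecture <- match.arg(architecture)
  stopifnot(inherits(cfg, "window_config"))
  subjects <- unique(.dataset_subjects(dataset))
  has_data <- vapply(subjects, function(s) {
    any(vapply(dataset, function(q)
      q$subject_id == s && q$n_frames > 0L, logical(1)))
  }, logical(1))
  if (any(!has_data)) {
    warning("excluding subjects with no data: ",
            paste(subjects[!has_data], collapse = ", "))
    subjects <- subjects[has_data]
  }
  if (length(subjects) < 2L) stop("subject-wise CV needs at least 2 subjects")
  k <- length(subjects)
  eval_folds <- if (is.null(max_folds)) seq_len(k) else seq_len(min(max_folds, k))
  D <- if (use_accel) 14L else 8L

  folds <- list()
  for (fi in eval_folds) {
    test_subject <- subjects[fi]
    train_subjects <- setdiff(subjects, test_subject)
    fold_seed <- (seed * 131L + fi * 7L) %% .Machine$integer.max
    models <- list()
    for (half in c("upper", "lower")) {
      ws <- .subject_windows(dataset, train_subjects, cfg, half, use_accel)
      spec <- model_spec(body_half = half, architecture = architecture,
                         D = D, SIL = cfg$SIL, seed = fold_seed, ...)
      models[[half]] <- if (architecture == "sinn") train_sinn(ws, spec)
                        else train_rnn(ws, spec)
      models[[paste0("baseline_", half)]] <- mean_pose_baseline(ws$Y)
    }
    pos <- numeric(0); jrk <- numeric(0); base <- numeric(0)
    act_pos <- list(); act_jrk <- list()
    for (seq_ in dataset) {
      if (seq_$subject_id != test_subject) next
      skel <- default_skeleton(seq_$stature_m)
      ev <- .evaluate_sequence(seq_, models, cfg, use_accel, skel)
      if (is.null(ev)) next
      pos <- c(pos, ev$pos_err); jrk <- c(jrk, ev$jerk_err)
      base <- c(base, ev$base_pos_err)
      act_pos[[ev$activity]] <- c(act_pos[[ev$activity]], ev$pos_err)
      act_jrk[[ev$activity]] <- c(act_jrk[[ev$activity]], ev$jerk_err)
    }
    folds[[fi]] <- list(
      test_subject = test_subject,
      n_frames = length(pos),
      mean_position_error = mean(pos), sd_position_error = stats::sd(pos),
      mean_jerk_error = mean(jrk), sd_jerk_error = stats::sd(jrk),
      baseline_position_error = mean(base),
      activity_position = act_pos, activity_jerk = act_jrk,
      models = list(upper_epochs = models$upper$best_epoch,
                    lower_epochs = models$lower$best_epoch))
  }
  pos_means <- vapply(folds, `[[`, numeric(1), "mean_position_error")
  jerk_means <- vapply(folds, `[[`, numeric(1), "mean_jerk_error")
  base_means <- vapply(folds, `[[`, numeric(1), "baseline_position_error")
  all_act <- unique(unlist(lapply(folds, function(f) names(f$activity_position))))
  activity_medians <- data.frame(
    activity = all_act,
    median_position_error = vapply(all_act, function(a)
      stats::median(unlist(lapply(folds, function(f) f$activity_position[[a]]))),
      numeric(1)),
    median_jerk_error = vapply(all_act, function(a)
      stats::median(unlist(lapply(folds, function(f) f$activity_jerk[[a]]))),
      numeric(1)),
    row.names = NULL)
  structure(list(
    folds = folds,
    pooled = list(
      mean_position_error = mean(pos_means), sd_position_error = stats::sd(pos_means),
      mean_jerk_error = mean(jerk_means), sd_jerk_error = stats::sd(jerk_means),
      baseline_position_error = mean(base_means)),
    activity_medians = activity_medians,
    config = list(cfg = cfg, use_accel = use_accel,
                  architecture = architecture, seed = seed)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s, %d folds | position %.4f (sd %.4f) m [baseline %.4f m] | jerk %.1f (sd %.1f) m/s^3\n",
    toupper(x$config$architecture), length(x$folds),
    x$pooled$mean_position_error, x$pooled$sd_position_error,
    x$pooled$baseline_position_error,
    x$pooled$mean_jerk_error, x$pooled$sd_jerk_error))
  for (f in x$folds)
    cat(sprintf("  fold %-4s position %.4f m, jerk %8.1f m/s^3 (baseline %.4f m)\n",
                f$test_subject, f$mean_position_error, f$mean_jerk_error,
                f$baseline_position_error))
  invisible(x)
}

#' Sweep window configurations (and feature flags) over the dataset
#'
#' Runs [subject_wise_cv()] for every window configuration crossed with
#' every acceleration-feature flag and tabulates pooled errors; reproduces
#' the structure of a time-window configuration study.
#'
#' @param dataset List of `motion_sequence` objects.
#' @param configs A data.frame from [enumerate_configs()] (or a list of
#'   `window_config`s).
#' @param use_accel Logical vector of feature flags to cross with configs.
#' @param architecture `"sinn"` or `"rnn"`.
#' @param seed Seed forwarded to each CV run.
#' @param ... Passed to [subject_wise_cv()].
#' @return A data.frame, one row per (config, flag): `P`, `F`, `I`, `SIL`,
#'   `use_accel`, pooled position/jerk means and sds, baseline error.
#' @export
config_sweep <- function(dataset, configs, use_accel = FALSE,
                         architecture = "sinn", seed = 1L, ...) {
  cfgs <- if (is.data.frame(configs)) configs$cfg else configs
  rows <- list()
  for (ci in seq_along(cfgs)) for (ua in use_accel) {
    cfg <- cfgs[[ci]]
    cv <- subject_wise_cv(dataset, cfg, use_accel = ua,
                          architecture = architecture, seed = seed, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      P = cfg$P, F = cfg$F, I = cfg$I, SIL = cfg$SIL, use_accel = ua,
      architecture = architecture,
      position_mean = cv$pooled$mean_position_error,
      position_sd = cv$pooled$sd_position_error,
      jerk_mean = cv$pooled$mean_jerk_error,
      jerk_sd = cv$pooled$sd_jerk_error,
      baseline_position = cv$pooled$baseline_position_error)
  }
  do.call(rbind, rows)
}
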