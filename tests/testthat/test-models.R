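# SINN and RNN training contracts: degenerate regression, determinism,
# output normalization, capacity ordering, leakage-freedom, learning sanity.

# a static-pose trial: near-constant features, exactly constant targets
make_constant_target_windows <- function(m = 300L, D = 8L, K = 24L, seed = 31L) {
  set.seed(seed)
  centre <- stats::rnorm(D, sd = 0.5)
  feats <- matrix(stats::rnorm(m * D, sd = 0.02), m, D,
                  dimnames = list(NULL, paste0("f", seq_len(D)))) +
    matrix(centre, m, D, byrow = TRUE)
  const <- quat_normalize(c(0.8, 0.4, 0.2, 0.1))
  targs <- matrix(rep(const, K / 4), m, K, byrow = TRUE)
  build_windows(feats, targs, window_config(0, 0, 1, 60),
                subject_id = "S1", activity = "test")
}

test_that("SINN converges to a constant target and is seed-deterministic", {
  ws <- make_constant_target_windows()
  spec <- model_spec("lower", "sinn", D = 8, SIL = 1, hidden = c(32, 32),
                     learning_rate = 1e-2, max_epochs = 200, seed = 9)
  m1 <- train_sinn(ws, spec)
  pred <- predict_sinn(m1, ws$X[1:20, ])
  const <- quat_normalize(c(0.8, 0.4, 0.2, 0.1))
  expect_lt(max(abs(sweep(pred, 2, rep(const, 6)))), 1e-2)
  # training loss decreases from the first epoch to the best epoch
  expect_lt(m1$history$train_loss[m1$best_epoch], m1$history$train_loss[1])

  m2 <- train_sinn(ws, spec)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("prediction renormalization yields proper unit quaternions", {
  ws <- make_constant_target_windows(m = 200L)
  spec <- model_spec("lower", "sinn", D = 8, SIL = 1, hidden = c(16),
                     max_epochs = 5, seed = 2)
  m <- train_sinn(ws, spec)
  pred <- predict_sinn(m, ws$X)
  for (i in 1:6) {
    nrm <- sqrt(rowSums(pred[, (4 * i - 3):(4 * i)]^2))
    expect_equal(nrm, rep(1, nrow(pred)), tolerance = 1e-9)
  }
  # renormalization is idempotent and rescales raw outputs
  expect_equal(renormalize_pose_matrix(pred), pred, tolerance = 1e-12)
  raw <- matrix(c(2, 0, 0, 0), 1, 4)
  expect_equal(unname(renormalize_pose_matrix(raw)), matrix(c(1, 0, 0, 0), 1))
  expect_warning(out <- renormalize_pose_matrix(matrix(0, 1, 4)), "zero-norm")
  expect_equal(unname(out), matrix(c(1, 0, 0, 0), 1))
  # dimension mismatches are schema errors
  expect_error(predict_sinn(m, matrix(0, 2, 5)), "input length")
  expect_error(train_sinn(make_constant_target_windows(K = 48), spec),
               "dimension mismatch")
})

test_that("RNN fits a constant target and exceeds the SINN in capacity", {
  ws <- make_constant_target_windows(m = 240L, seed = 33L)
  # widen to SIL 3 for a genuine sequence input
  set.seed(33)
  feats <- matrix(stats::rnorm(260 * 8, sd = 0.02), 260, 8,
                  dimnames = list(NULL, paste0("f", 1:8)))
  const <- quat_normalize(c(0.8, 0.4, 0.2, 0.1))
  targs <- matrix(rep(const, 6), 260, 24, byrow = TRUE)
  ws <- build_windows(feats, targs, window_config(1, 1, 1, 60), "S1", "test")
  spec <- model_spec("lower", "rnn", D = 8, SIL = 3, rnn_units = c(16, 16),
                     learning_rate = 1e-2, max_epochs = 120, seed = 5)
  m <- train_rnn(ws, spec)
  pred <- predict_rnn(m, ws$X[1:10, ])
  expect_lt(max(abs(sweep(pred, 2, rep(const, 6)))), 1e-2)

  # default specs: the shallow stacked-input net has strictly fewer
  # trainable parameters than the recurrent baseline
  for (half in c("upper", "lower")) {
    n_sinn <- count_parameters(model_spec(half, "sinn", D = 8, SIL = 5))
    n_rnn <- count_parameters(model_spec(half, "rnn", D = 8, SIL = 5))
    expect_lt(n_sinn, n_rnn)
  }
})

test_that("training statistics never depend on the held-out subject", {
  ds <- tiny_gait_dataset()
  cfg <- window_config(2, 2, 2, 60)
  # corrupt the third subject's data; folds evaluated on other subjects
  # must train identically since the held-out subject is excluded entirely
  ds2 <- ds
  set.seed(77)
  ds2[[3]]$orientations <- array(random_unit_quat(ds[[3]]$n_frames * 23L),
                                 dim = dim(ds[[3]]$orientations),
                                 dimnames = dimnames(ds[[3]]$orientations))
  train_fold3 <- function(dataset) {
    subjects <- setdiff(unique(sapply(dataset, `[[`, "subject_id")), "S3")
    sets <- lapply(dataset[sapply(dataset, `[[`, "subject_id") %in% subjects],
                   function(s) build_windows(
                     build_feature_sequence(s, "lower"), pose_targets(s, "lower"),
                     cfg, s$subject_id, s$activity))
    train_sinn(bind_window_sets(sets),
               model_spec("lower", "sinn", D = 8, SIL = 5, hidden = c(32, 32),
                          max_epochs = 4, seed = 1))
  }
  m1 <- train_fold3(ds)
  m2 <- train_fold3(ds2)
  expect_identical(m1$norm, m2$norm)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("held-out error approaches the noise floor on an affine task", {
  # targets are small rotations whose angle is an affine function of the
  # inputs plus Gaussian noise: a solvable regression with a known floor
  set.seed(41)
  n <- 3000L
  D <- 8L
  feats <- matrix(stats::rnorm(n * D, sd = 0.5), n, D,
                  dimnames = list(NULL, paste0("f", 1:D)))
  wvec <- stats::rnorm(D, sd = 0.2)
  sigma <- 0.02
  angle <- drop(feats %*% wvec) + stats::rnorm(n, 0, sigma)
  targs <- do.call(cbind, rep(list(cbind(cos(angle / 2), sin(angle / 2), 0, 0)), 6))
  ws <- build_windows(feats, targs, window_config(0, 0, 1, 60), "S1", "affine")
  tr <- 1:2400; te <- 2401:3000
  wtr <- ws; wtr$X <- ws$X[tr, ]; wtr$Y <- ws$Y[tr, ]
  wtr$subject <- ws$subject[tr]; wtr$activity <- ws$activity[tr]
  wtr$centre <- ws$centre[tr]
  m <- train_sinn(wtr, model_spec("lower", "sinn", D = D, SIL = 1,
                                  hidden = c(64, 64), learning_rate = 3e-3,
                                  max_epochs = 200, patience = 25, seed = 3))
  pred <- predict_sinn(m, ws$X[te, ])
  # recovered angle error vs the irreducible noise sigma
  ang_hat <- 2 * atan2(pred[, 2], pred[, 1])
  resid <- ang_hat - drop(feats[te, ] %*% wvec)
  expect_lt(stats::sd(resid), sigma + 3 * sigma / sqrt(2 * length(te)) + 0.01)
})

test_that("full poses assemble from both halves with input pass-through", {
  set.seed(51)
  upper <- renormalize_pose_matrix(matrix(stats::rnorm(48), 1))
  lower <- renormalize_pose_matrix(matrix(stats::rnorm(24), 1))
  inputs <- random_unit_quat(5L)
  rownames(inputs) <- INPUT_SEGMENTS
  inputs["Pelvis", ] <- c(1, 0, 0, 0)
  pose <- assemble_full_pose(upper, lower, inputs)
  expect_equal(dim(pose), c(23L, 4L))
  expect_setequal(rownames(pose), SEGMENT_NAMES)
  expect_equal(unname(pose["Pelvis", ]), c(1, 0, 0, 0))
  # measured limb inputs pass through bit-identically
  for (s in setdiff(INPUT_SEGMENTS, "Pelvis"))
    expect_identical(unname(pose[s, ]), unname(inputs[s, ]))
  expect_identical(unname(pose["Head", ]), unname(upper[1, 21:24]))

  # perfect predictions reproduce the ground-truth pose
  truth <- random_pose()
  up <- matrix(t(truth[UPPER_OUTPUT_SEGMENTS, ]), 1)
  lo <- matrix(t(truth[LOWER_OUTPUT_SEGMENTS, ]), 1)
  rebuilt <- assemble_full_pose(up, lo, truth[INPUT_SEGMENTS, ])
  expect_equal(rebuilt[SEGMENT_NAMES, ], truth[SEGMENT_NAMES, ])

  expect_error(assemble_full_pose(upper[, 1:40], lower, inputs), "48")
  expect_error(assemble_full_pose(upper, lower, inputs[1:4, ]), "5 x 4")
})

test_that("models serialize to JSON and restore identical predictions", {
  ws <- make_constant_target_windows(m = 150L)
  spec <- model_spec("lower", "sinn", D = 8, SIL = 1, hidden = c(16),
                     max_epochs = 4, seed = 8)
  m <- train_sinn(ws, spec)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict_sinn(m2, ws$X[1:5, ]), predict_sinn(m, ws$X[1:5, ]))
  expect_equal(m2$n_params, m$n_params)
  expect_error(load_model(ws_path <- {
    p <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(container = "other"), p); p
  }), "not a stackpose model")
})
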