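# The two regressors that map stacked sensor windows to pelvis-relative
# segment orientation quaternions: a shallow fully-connected stacked-input
# network (SINN) fed the flattened D*SIL window, and a bidirectional LSTM
# baseline (RNN) fed the same window as a D x SIL sequence.  Separate
# networks are trained for the upper body (48 outputs = 12 segments x 4)
# and the lower body (24 outputs = 6 segments x 4).  Both are trained with
# minibatch Adam on mean squared error over raw quaternion components;
# predictions are renormalized to unit quaternions afterwards.

#' Model specification
#'
#' @param body_half `"upper"` (48 outputs) or `"lower"` (24 outputs).
#' @param architecture `"sinn"` (shallow fully-connected stacked-input
#'   network) or `"rnn"` (bidirectional LSTM).
#' @param D Per-frame feature dimensionality (8 orientation-only, 14 with
#'   accelerations).
#' @param SIL Stacked input length of the window configuration.
#' @param hidden Hidden fully-connected layer sizes (SINN).
#' @param rnn_units Memory cells per bidirectional recurrent layer (RNN).
#' @param dropout Dropout rate between recurrent layers (RNN only).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param weight_decay Decoupled L2 weight decay applied to weight matrices
#'   (not biases) at each Adam step; regularizes the SINN towards
#'   subject-invariant structure.
#' @param seed Integer seed controlling weight init, batch order, dropout
#'   and the validation split.
#' @return A `model_spec` object.
#' @export
model_spec <- function(body_half = c("upper", "lower"),
                       architecture = c("sinn", "rnn"),
                       D = 8L, SIL = 5L,
                       hidden = c(256L, 256L),
                       rnn_units = c(128L, 128L),
                       dropout = 0.2,
                       learning_rate = 1e-3,
                       batch_size = 128L,
                       max_epochs = 30L,
                       patience = 10L,
                       weight_decay = 1e-4,
                       seed = 1L) {
  body_half <- match.arg(body_half)
  architecture <- match.arg(architecture)
  output_dim <- if (body_half == "upper") 48L else 24L
  structure(list(body_half = body_half, architecture = architecture,
                 D = as.integer(D), SIL = as.integer(SIL),
                 input_dim = as.integer(D * SIL),
                 output_dim = output_dim,
                 hidden = as.integer(hidden),
                 rnn_units = as.integer(rnn_units),
                 dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  arch <- if (x$architecture == "sinn")
    sprintf("SINN hidden [%s]", paste(x$hidden, collapse = ", "))
  else
    sprintf("bi-LSTM units [%s], dropout %g", paste(x$rnn_units, collapse = ", "),
            x$dropout)
  cat(sprintf("<model_spec> %s body, %s: input %d (D=%d x SIL=%d) -> %d outputs\n",
              x$body_half, arch, x$input_dim, x$D, x$SIL, x$output_dim))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- parameter store helpers -------------------------------------------

.n_params <- function(params) sum(vapply(params, length, integer(1)))

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_update <- function(params, grads, state, lr, weight_decay = 0,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    # decoupled weight decay on weight matrices only
    if (weight_decay > 0 && !is.null(dim(params[[nm]])))
      step <- step + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# Centre every column; bring every physical feature block (orientation
# components vs accelerations) to a common pooled scale, relative to the
# orientation block, without ever amplifying a column.  Quaternion
# components are dimensionless and O(1) and are fed raw; accelerations
# (m/s^2, reaching tens) are scaled down to the orientation block's pooled
# spread so no block dominates the fit.  Per-column standardization is
# deliberately avoided: near-constant quaternion components (e.g. w close
# to 1) would have their measurement noise amplified to unit variance,
# which destroys both optimization and cross-subject generalization.
.standardize_fit <- function(X, blocks = NULL) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_)] <- 0
  if (is.null(blocks)) blocks <- rep(1L, ncol(X))
  ref <- sqrt(mean(sd_[blocks == blocks[1]]^2))
  if (!is.finite(ref) || ref < 1e-12) ref <- 1
  scale_ <- numeric(ncol(X))
  for (b in unique(blocks)) {
    sel <- blocks == b
    s <- sqrt(mean(sd_[sel]^2))
    scale_[sel] <- if (is.finite(s)) max(s / ref, 1) else 1
  }
  list(mu = mu, sd = scale_)
}

# block label per stacked column: per frame, the first 8 features are
# quaternion components, any remainder are acceleration components
.feature_blocks <- function(D, SIL) {
  per_frame <- c(rep(1L, min(8L, D)), rep(2L, max(0L, D - 8L)))
  rep(per_frame, SIL)
}

.standardize_apply <- function(X, norm) {
  sweep(sweep(X, 2, norm$mu, "-"), 2, norm$sd, "/")
}

## ---- SINN (shallow fully-connected network) ----------------------------

.mlp_init <- function(input_dim, hidden, output_dim) {
  sizes <- c(input_dim, hidden, output_dim)
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    params[[paste0("W", l)]] <-
      matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
             nrow = fan_in)
    params[[paste0("b", l)]] <- numeric(sizes[l + 1L])
  }
  params
}

.mlp_forward <- function(params, X) {
  L <- length(params) / 2L
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% params[[paste0("W", l)]]
    Z <- Z + matrix(params[[paste0("b", l)]], nrow(Z), ncol(Z), byrow = TRUE)
    acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z   # ReLU hidden, linear out
  }
  acts
}

.mlp_backward <- function(params, acts, dOut) {
  L <- length(params) / 2L
  grads <- params
  delta <- dOut
  for (l in rev(seq_len(L))) {
    grads[[paste0("W", l)]] <- crossprod(acts[[l]], delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(params[[paste0("W", l)]])
      delta <- delta * (acts[[l]] > 0)
    }
  }
  grads
}

.mlp_loss <- function(params, X, Y) {
  pred <- .mlp_forward(params, X)[[length(params) / 2L + 1L]]
  mean((pred - Y)^2)
}

## ---- shared training loop ----------------------------------------------

.train_split <- function(subject, m, seed) {
  subs <- unique(subject)
  if (length(subs) >= 2L) {
    val_subject <- sample(subs, 1L)
    list(val_idx = which(subject == val_subject), val_subject = val_subject)
  } else {
    list(val_idx = sample.int(m, max(1L, floor(0.1 * m))), val_subject = NA_character_)
  }
}

.check_window_set <- function(windows, spec) {
  if (!inherits(windows, "window_set")) stop("'windows' must be a window_set")
  if (ncol(windows$X) != spec$input_dim)
    stop(sprintf("input dimension mismatch: windows have %d columns, spec expects %d",
                 ncol(windows$X), spec$input_dim))
  if (ncol(windows$Y) != spec$output_dim)
    stop(sprintf("target dimension mismatch: windows have %d columns, spec expects %d (%s body)",
                 ncol(windows$Y), spec$output_dim, spec$body_half))
  if (windows$D != spec$D || windows$SIL != spec$SIL)
    stop("window D/SIL do not match the model spec")
  invisible(TRUE)
}

.run_training <- function(spec, X, Y, subject,
                          forward_loss, batch_grads, init_params) {
  set.seed(spec$seed)
  m <- nrow(X)
  split <- .train_split(subject, m, spec$seed)
  tr_idx <- setdiff(seq_len(m), split$val_idx)
  norm <- .standardize_fit(X[tr_idx, , drop = FALSE],
                           .feature_blocks(spec$D, spec$SIL))
  Xs <- .standardize_apply(X, norm)
  Xtr <- Xs[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xval <- Xs[split$val_idx, , drop = FALSE]; Yval <- Y[split$val_idx, , drop = FALSE]

  params <- init_params()
  state <- .adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  wait <- 0L
  ntr <- nrow(Xtr)
  bs <- min(spec$batch_size, ntr)
  for (epoch in seq_len(spec$max_epochs)) {
    perm <- sample.int(ntr)
    batch_losses <- numeric(0)
    for (start in seq.int(1L, ntr, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, ntr)]
      bg <- batch_grads(params, Xtr[idx, , drop = FALSE], Ytr[idx, , drop = FALSE])
      if (!is.finite(bg$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      batch_losses <- c(batch_losses, bg$loss)
      upd <- .adam_update(params, bg$grads, state, spec$learning_rate,
                          weight_decay = spec$weight_decay %||% 0)
      params <- upd$params; state <- upd$state
    }
    train_loss <- mean(batch_losses)
    val_loss <- forward_loss(params, Xval, Yval)
    if (!is.finite(val_loss))
      stop(sprintf("training diverged (non-finite validation loss) at epoch %d", epoch))
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss))
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  list(params = best$params, best_epoch = best$epoch, history = history,
       norm = norm, val_subject = split$val_subject)
}

#' Train the stacked-input network (SINN)
#'
#' Fits a shallow fully-connected network mapping the stacked input vector
#' (flattened `D x SIL` window) to the body-half pose target, using
#' minibatch Adam on component-wise mean squared error, per-feature input
#' standardization learned from the training samples, and early stopping on
#' a held-out validation split (one training subject when at least two are
#' present, otherwise a random 10% of samples).  Deterministic given
#' `spec$seed`.
#'
#' @param windows A `window_set` (see [build_windows()]).
#' @param spec A `model_spec` with `architecture = "sinn"`.
#' @return A `trained_model`: spec, learned weights, input normalization
#'   constants, per-epoch `history`, `best_epoch`, `n_params`.
#' @export
train_sinn <- function(windows, spec = NULL) {
  if (is.null(spec))
    stop("supply a model_spec (body_half must be chosen explicitly)")
  if (spec$architecture != "sinn") stop("spec$architecture must be 'sinn'")
  .check_window_set(windows, spec)
  fit <- .run_training(
    spec, windows$X, windows$Y, windows$subject,
    forward_loss = .mlp_loss,
    batch_grads = function(params, Xb, Yb) {
      acts <- .mlp_forward(params, Xb)
      pred <- acts[[length(acts)]]
      err <- pred - Yb
      loss <- mean(err^2)
      dOut <- 2 * err / length(err)
      list(loss = loss, grads = .mlp_backward(params, acts, dOut))
    },
    init_params = function() .mlp_init(spec$input_dim, spec$hidden, spec$output_dim))
  structure(c(fit, list(spec = spec, n_params = .n_params(fit$params),
                        format_version = 1L)),
            class = "trained_model")
}

#' Predict poses with a trained SINN
#'
#' Runs the network and renormalizes each output 4-tuple to a proper unit
#' quaternion; a zero-norm raw output is replaced by the identity quaternion
#' with a warning.
#'
#' @param model A `trained_model` with SINN architecture.
#' @param X Stacked input matrix (`m x D*SIL`) or a `window_set`.
#' @return An `m x output_dim` matrix of unit quaternion components.
#' @export
predict_sinn <- function(model, X) {
  stopifnot(inherits(model, "trained_model"),
            model$spec$architecture == "sinn")
  if (inherits(X, "window_set")) X <- X$X
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$spec$input_dim)
    stop(sprintf("input length %d does not match spec input_dim %d",
                 ncol(X), model$spec$input_dim))
  Xs <- .standardize_apply(X, model$norm)
  raw <- .mlp_forward(model$params, Xs)[[length(model$params) / 2L + 1L]]
  renormalize_pose_matrix(raw)
}

#' Renormalize raw quaternion outputs to unit norm
#'
#' Treats every consecutive group of 4 columns as one quaternion and scales
#' it to unit length; zero-norm quaternions become the identity (with a
#' warning).  Idempotent.
#'
#' @param Y An `m x 4k` matrix of raw quaternion components.
#' @return The renormalized matrix.
#' @export
renormalize_pose_matrix <- function(Y) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  if (ncol(Y) %% 4L != 0L) stop("'Y' must have a multiple of 4 columns")
  warned <- FALSE
  for (i in seq_len(ncol(Y) / 4L)) {
    cols <- (4L * i - 3L):(4L * i)
    block <- Y[, cols, drop = FALSE]
    nrm <- sqrt(rowSums(block^2))
    zero <- nrm == 0
    if (any(zero)) {
      if (!warned) {
        warning("zero-norm quaternion output replaced by identity")
        warned <- TRUE
      }
      block[zero, ] <- matrix(c(1, 0, 0, 0), sum(zero), 4L, byrow = TRUE)
      nrm[zero] <- 1
    }
    Y[, cols] <- block / nrm
  }
  Y
}

## ---- RNN (bidirectional LSTM) ------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

.lstm_init <- function(input_dim, H) {
  fan_in <- input_dim + H
  list(W = matrix(stats::rnorm(fan_in * 4L * H, sd = sqrt(1 / fan_in)),
                  nrow = fan_in),
       b = rep(c(0, 1, 0, 0), each = H))   # forget-gate bias 1
}

.rnn_init <- function(spec) {
  H1 <- spec$rnn_units[1]; H2 <- spec$rnn_units[2]
  p <- list()
  l1f <- .lstm_init(spec$D, H1); l1b <- .lstm_init(spec$D, H1)
  l2f <- .lstm_init(2L * H1, H2); l2b <- .lstm_init(2L * H1, H2)
  p$W1f <- l1f$W; p$b1f <- l1f$b; p$W1b <- l1b$W; p$b1b <- l1b$b
  p$W2f <- l2f$W; p$b2f <- l2f$b; p$W2b <- l2b$W; p$b2b <- l2b$b
  p$Wd <- matrix(stats::rnorm(2L * H2 * spec$output_dim, sd = sqrt(1 / (2 * H2))),
                 nrow = 2L * H2)
  p$bd <- numeric(spec$output_dim)
  p
}

# one LSTM direction over a list of step inputs; returns hidden states and
# the caches needed for backprop
.lstm_forward <- function(Xsteps, W, b, reverse = FALSE) {
  SIL <- length(Xsteps)
  B <- nrow(Xsteps[[1]])
  H <- length(b) / 4L
  order_ <- if (reverse) rev(seq_len(SIL)) else seq_len(SIL)
  h <- vector("list", SIL); cache <- vector("list", SIL)
  h_prev <- matrix(0, B, H); c_prev <- matrix(0, B, H)
  bmat <- matrix(b, B, 4L * H, byrow = TRUE)
  for (t in order_) {
    z <- cbind(Xsteps[[t]], h_prev)
    a <- z %*% W + bmat
    i <- .sigmoid(a[, 1:H, drop = FALSE])
    f <- .sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_t <- f * c_prev + i * g
    tc <- tanh(c_t)
    h_t <- o * tc
    cache[[t]] <- list(z = z, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, tc = tc)
    h[[t]] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  list(h = h, cache = cache, order = order_)
}

# backward pass matching .lstm_forward; dh_steps may be zero matrices for
# steps that receive no gradient directly
.lstm_backward <- function(fwd, W, dh_steps, input_dim) {
  SIL <- length(dh_steps)
  B <- nrow(dh_steps[[1]])
  H <- ncol(dh_steps[[1]])
  dW <- W * 0; db <- numeric(4L * H)
  dX <- vector("list", SIL)
  dh_carry <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(fwd$order)) {
    ca <- fwd$cache[[t]]
    dh <- dh_steps[[t]] + dh_carry
    do_ <- dh * ca$tc
    dc <- dc_next + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g
    df <- dc * ca$c_prev
    dg <- dc * ca$i
    da <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do_ * ca$o * (1 - ca$o))
    dW <- dW + crossprod(ca$z, da)
    db <- db + colSums(da)
    dz <- da %*% t(W)
    dX[[t]] <- dz[, seq_len(input_dim), drop = FALSE]
    dh_carry <- dz[, (input_dim + 1L):(input_dim + H), drop = FALSE]
    dc_next <- dc * ca$f
  }
  list(dX = dX, dW = dW, db = db)
}

.rnn_steps <- function(X, D, SIL) {
  lapply(seq_len(SIL), function(j)
    X[, ((j - 1L) * D + 1L):(j * D), drop = FALSE])
}

# full forward through 2 bidirectional layers + dense head at the centre step
.rnn_forward <- function(params, X, spec, dropout_mask = NULL) {
  steps <- .rnn_steps(X, spec$D, spec$SIL)
  f1 <- .lstm_forward(steps, params$W1f, params$b1f, reverse = FALSE)
  b1 <- .lstm_forward(steps, params$W1b, params$b1b, reverse = TRUE)
  h1 <- lapply(seq_len(spec$SIL), function(t) cbind(f1$h[[t]], b1$h[[t]]))
  if (!is.null(dropout_mask))
    h1 <- lapply(seq_len(spec$SIL), function(t) h1[[t]] * dropout_mask[[t]])
  f2 <- .lstm_forward(h1, params$W2f, params$b2f, reverse = FALSE)
  b2 <- .lstm_forward(h1, params$W2b, params$b2b, reverse = TRUE)
  centre <- .rnn_centre(spec)
  hc <- cbind(f2$h[[centre]], b2$h[[centre]])
  pred <- hc %*% params$Wd +
    matrix(params$bd, nrow(hc), spec$output_dim, byrow = TRUE)
  list(pred = pred, steps = steps, f1 = f1, b1 = b1, h1 = h1,
       f2 = f2, b2 = b2, hc = hc, centre = centre)
}

# centre step of the window: P past frames precede it
.rnn_centre <- function(spec) {
  centre <- attr(spec, "centre_step")
  if (is.null(centre)) (spec$SIL + 1L) %/% 2L else centre
}

.rnn_loss <- function(params, X, Y, spec) {
  if (nrow(X) == 0L) return(NA_real_)
  mean((.rnn_forward(params, X, spec)$pred - Y)^2)
}

.rnn_batch_grads <- function(params, Xb, Yb, spec, train_dropout = TRUE) {
  B <- nrow(Xb)
  H1 <- spec$rnn_units[1]
  mask <- NULL
  if (train_dropout && spec$dropout > 0) {
    keep <- 1 - spec$dropout
    mask <- lapply(seq_len(spec$SIL), function(t)
      matrix(stats::rbinom(B * 2L * H1, 1L, keep) / keep, B, 2L * H1))
  }
  fw <- .rnn_forward(params, Xb, spec, dropout_mask = mask)
  err <- fw$pred - Yb
  loss <- mean(err^2)
  dpred <- 2 * err / length(err)

  grads <- lapply(params, function(p) p * 0)
  grads$Wd <- crossprod(fw$hc, dpred)
  grads$bd <- colSums(dpred)
  dhc <- dpred %*% t(params$Wd)
  H2 <- spec$rnn_units[2]
  zero2 <- matrix(0, B, H2)
  dh2f <- rep(list(zero2), spec$SIL)
  dh2b <- rep(list(zero2), spec$SIL)
  dh2f[[fw$centre]] <- dhc[, seq_len(H2), drop = FALSE]
  dh2b[[fw$centre]] <- dhc[, (H2 + 1L):(2L * H2), drop = FALSE]

  bk2f <- .lstm_backward(fw$f2, params$W2f, dh2f, 2L * H1)
  bk2b <- .lstm_backward(fw$b2, params$W2b, dh2b, 2L * H1)
  grads$W2f <- bk2f$dW; grads$b2f <- bk2f$db
  grads$W2b <- bk2b$dW; grads$b2b <- bk2b$db

  dh1 <- lapply(seq_len(spec$SIL), function(t) bk2f$dX[[t]] + bk2b$dX[[t]])
  if (!is.null(mask))
    dh1 <- lapply(seq_len(spec$SIL), function(t) dh1[[t]] * mask[[t]])
  dh1f <- lapply(dh1, function(d) d[, seq_len(H1), drop = FALSE])
  dh1b <- lapply(dh1, function(d) d[, (H1 + 1L):(2L * H1), drop = FALSE])

  bk1f <- .lstm_backward(fw$f1, params$W1f, dh1f, spec$D)
  bk1b <- .lstm_backward(fw$b1, params$W1b, dh1b, spec$D)
  grads$W1f <- bk1f$dW; grads$b1f <- bk1f$db
  grads$W1b <- bk1b$dW; grads$b1b <- bk1b$db

  list(loss = loss, grads = grads)
}

#' Train the bidirectional recurrent baseline (RNN)
#'
#' Fits a two-layer bidirectional LSTM over the `SIL` window steps (each
#' step the `D` per-frame features), with dropout between the recurrent
#' layers and a linear head read out at the window's centre step (the frame
#' whose pose is the regression target).  Optimization, normalization,
#' validation split and early stopping are identical to [train_sinn()].
#' Deterministic given `spec$seed` (pure R implementation; no backend
#' nondeterminism).
#'
#' @param windows A `window_set`.
#' @param spec A `model_spec` with `architecture = "rnn"`.
#' @return A `trained_model`.
#' @export
train_rnn <- function(windows, spec = NULL) {
  if (is.null(spec)) stop("supply a model_spec")
  if (spec$architecture != "rnn") stop("spec$architecture must be 'rnn'")
  .check_window_set(windows, spec)
  # the centre step position follows the window's P (past frames first)
  attr(spec, "centre_step") <- windows$cfg$P + 1L
  fit <- .run_training(
    spec, windows$X, windows$Y, windows$subject,
    forward_loss = function(params, Xv, Yv) .rnn_loss(params, Xv, Yv, spec),
    batch_grads = function(params, Xb, Yb) .rnn_batch_grads(params, Xb, Yb, spec),
    init_params = function() .rnn_init(spec))
  structure(c(fit, list(spec = spec, n_params = .n_params(fit$params),
                        format_version = 1L)),
            class = "trained_model")
}

#' Predict poses with a trained RNN
#'
#' @param model A `trained_model` with RNN architecture.
#' @param X Stacked input matrix (`m x D*SIL`; unstacked internally to the
#'   `D x SIL` sequence) or a `window_set`.
#' @return An `m x output_dim` matrix of unit quaternion components.
#' @export
predict_rnn <- function(model, X) {
  stopifnot(inherits(model, "trained_model"),
            model$spec$architecture == "rnn")
  if (inherits(X, "window_set")) X <- X$X
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$spec$input_dim)
    stop(sprintf("input length %d does not match spec input_dim %d",
                 ncol(X), model$spec$input_dim))
  Xs <- .standardize_apply(X, model$norm)
  raw <- .rnn_forward(model$params, Xs, model$spec)$pred
  renormalize_pose_matrix(raw)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %s %s body: %d parameters, best epoch %d (val loss %.3g)\n",
    toupper(x$spec$architecture), x$spec$body_half, x$n_params, x$best_epoch,
    min(x$history$val_loss)))
  invisible(x)
}

#' Predict from a trained model (SINN or RNN)
#'
#' @param object A `trained_model`.
#' @param newdata Stacked input matrix or `window_set`.
#' @param ... Unused.
#' @return Matrix of unit quaternion components.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  if (object$spec$architecture == "sinn") predict_sinn(object, newdata)
  else predict_rnn(object, newdata)
}

## ---- pose assembly ------------------------------------------------------

#' Assemble a full 23-segment pose from the two body-half predictions
#'
#' Combines the upper-body prediction (12 segments), the lower-body
#' prediction (6 segments) and the five measured pelvis-relative input
#' orientations into one complete pelvis-relative pose (pelvis = identity;
#' the four measured limb orientations pass through unchanged).
#'
#' @param upper_pred Length-48 vector (or 1 x 48 matrix) of upper-body
#'   quaternion components in `UPPER_OUTPUT_SEGMENTS` order.
#' @param lower_pred Length-24 vector for `LOWER_OUTPUT_SEGMENTS`.
#' @param input_orientations 5 x 4 matrix of measured pelvis-relative unit
#'   quaternions with rownames `INPUT_SEGMENTS`.
#' @return A 23 x 4 pose matrix with rownames `SEGMENT_NAMES`.
#' @export
assemble_full_pose <- function(upper_pred, lower_pred, input_orientations) {
  upper_pred <- if (is.null(dim(upper_pred))) matrix(upper_pred, nrow = 1L) else upper_pred
  lower_pred <- if (is.null(dim(lower_pred))) matrix(lower_pred, nrow = 1L) else lower_pred
  if (ncol(upper_pred) != 48L) stop("'upper_pred' must have 48 components")
  if (ncol(lower_pred) != 24L) stop("'lower_pred' must have 24 components")
  if (!is.matrix(input_orientations) || any(dim(input_orientations) != c(5L, 4L)) ||
      is.null(rownames(input_orientations)) ||
      !setequal(rownames(input_orientations), INPUT_SEGMENTS))
    stop("'input_orientations' must be a 5 x 4 matrix with the sensor segment rownames")
  arr <- assemble_pose_sequence(upper_pred, lower_pred,
                                array(input_orientations[INPUT_SEGMENTS, ],
                                      dim = c(1L, 5L, 4L),
                                      dimnames = list(NULL, INPUT_SEGMENTS, NULL)))
  pose <- matrix(arr[1L, , ], nrow = 23L,
                 dimnames = list(SEGMENT_NAMES, c("w", "x", "y", "z")))
  pose
}

#' Assemble full-pose sequences from body-half prediction matrices
#'
#' @param upper_pred `m x 48` matrix (see [assemble_full_pose()]).
#' @param lower_pred `m x 24` matrix.
#' @param input_orientations `m x 5 x 4` array of measured pelvis-relative
#'   quaternions, second dimension named by `INPUT_SEGMENTS`.
#' @return An `m x 23 x 4` pose array.
#' @export
assemble_pose_sequence <- function(upper_pred, lower_pred, input_orientations) {
  m <- nrow(upper_pred)
  if (nrow(lower_pred) != m || dim(input_orientations)[1] != m)
    stop("prediction and input lengths disagree")
  out <- array(NA_real_, dim = c(m, 23L, 4L),
               dimnames = list(NULL, SEGMENT_NAMES, c("w", "x", "y", "z")))
  out[, "Pelvis", ] <- quat_identity(m)
  for (s in setdiff(INPUT_SEGMENTS, "Pelvis"))
    out[, s, ] <- input_orientations[, s, ]
  for (i in seq_along(UPPER_OUTPUT_SEGMENTS))
    out[, UPPER_OUTPUT_SEGMENTS[i], ] <- upper_pred[, (4L * i - 3L):(4L * i)]
  for (i in seq_along(LOWER_OUTPUT_SEGMENTS))
    out[, LOWER_OUTPUT_SEGMENTS[i], ] <- lower_pred[, (4L * i - 3L):(4L * i)]
  out
}

#' Number of trainable parameters in a model or spec
#'
#' @param x A `trained_model` or `model_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "trained_model")) return(.n_params(x$params))
  if (inherits(x, "model_spec")) {
    params <- if (x$architecture == "sinn")
      .mlp_init(x$input_dim, x$hidden, x$output_dim)
    else .rnn_init(x)
    return(.n_params(params))
  }
  stop("'x' must be a trained_model or model_spec")
}

## ---- serialization ------------------------------------------------------

#' Save a trained model to a versioned JSON container
#'
#' Stores the spec, normalization constants, weights (full precision) and
#' seed; [load_model()] restores an equivalent model.
#'
#' @param model A `trained_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  payload <- list(
    container = "stackpose-model",
    format_version = model$format_version,
    spec = unclass(model$spec),
    centre_step = attr(model$spec, "centre_step"),
    norm = model$norm,
    best_epoch = model$best_epoch,
    history = model$history,
    n_params = model$n_params,
    params = lapply(model$params, function(p)
      list(dim = if (is.null(dim(p))) length(p) else dim(p), data = as.numeric(p))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trained model saved by [save_model()]
#'
#' @param path Path to the JSON container.
#' @return A `trained_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$container, "stackpose-model"))
    stop("not a stackpose model container: ", path)
  if (!identical(as.integer(payload$format_version), 1L))
    stop("unsupported model format version: ", payload$format_version)
  spec <- structure(payload$spec, class = "model_spec")
  spec$hidden <- as.integer(spec$hidden)
  spec$rnn_units <- as.integer(spec$rnn_units)
  if (!is.null(payload$centre_step))
    attr(spec, "centre_step") <- as.integer(payload$centre_step)
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2]) else as.numeric(p$data)
  })
  structure(list(params = params, best_epoch = payload$best_epoch,
                 history = payload$history,
                 norm = list(mu = as.numeric(payload$norm$mu),
                             sd = as.numeric(payload$norm$sd)),
                 val_subject = NA_character_, spec = spec,
                 n_params = payload$n_params, format_version = 1L),
            class = "trained_model")
}
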