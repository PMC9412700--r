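#' Stacked bidirectional LSTM architecture
#'
#' Two stacked bidirectional LSTM layers encode a variable-length velocity
#' trial; layer normalization and a ReLU block follow each recurrent layer.
#' The encoder output (concatenated final forward and backward hidden
#' states of the second layer) feeds a 30-unit rectified hidden layer and a
#' softmax output layer with one neuron per movement class, and the
#' predicted label is the argmax of the class probabilities.
#'
#' @param hidden_units Integer vector of length 2: hidden units per
#'   direction in each recurrent layer (default 100 each).
#' @param dense_units Width of the rectified hidden layer (default 30).
#' @param bidirectional If `FALSE`, drop the backward direction (ablation).
#' @return An `lstm_architecture` list.
#' @export
lstm_architecture <- function(hidden_units = c(100, 100), dense_units = 30,
                              bidirectional = TRUE) {
  stopifnot(length(hidden_units) == 2, all(hidden_units >= 1),
            dense_units >= 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 dense_units = as.integer(dense_units),
                 bidirectional = isTRUE(bidirectional)),
            class = "lstm_architecture")
}

#' LSTM training hyperparameters
#'
#' Defaults follow the fixed training recipe used throughout: 64 epochs,
#' mini-batches of 16 ragged sequences (sorted-by-length bucketing with
#' right-padding and masks), Adam at learning rate 0.001, cross-entropy
#' loss, no early stopping.
#'
#' @param epochs,batch_size,learning_rate Positive training parameters.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @return An `lstm_training_params` list.
#' @export
lstm_training_params <- function(epochs = 64, batch_size = 16,
                                 learning_rate = 0.001, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "lstm_training_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

init_cell <- function(n_in, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1      # forget-gate bias starts open
  list(W = glorot(n_in, 4 * h), U = glorot(h, 4 * h), b = b)
}

#' Build an untrained LSTM classifier
#'
#' Initializes all weights (Glorot-uniform, forget-gate biases at 1) from
#' `seed`. The forward pass maps a time-by-channel input of any length to a
#' probability vector over the classes.
#'
#' @param n_channels Input channels per timestep.
#' @param classes Character vector of class labels (>= 2).
#' @param arch An [lstm_architecture()].
#' @param seed Integer seed for weight initialization.
#' @return A `grip_lstm` model object.
#' @export
build_lstm <- function(n_channels, classes = grip_tasks(),
                       arch = lstm_architecture(), seed = 1L) {
  if (length(classes) < 2) abort("need at least 2 classes")
  h <- arch$hidden_units
  nd <- if (arch$bidirectional) 2L else 1L
  with_preserved_rng(seed, {
    weights <- list(
      layers = list(
        list(dirs = lapply(seq_len(nd), function(d) init_cell(n_channels, h[1])),
             ln = list(g = rep(1, nd * h[1]), b = rep(0, nd * h[1]))),
        list(dirs = lapply(seq_len(nd), function(d) init_cell(nd * h[1], h[2])),
             ln = list(g = rep(1, nd * h[2]), b = rep(0, nd * h[2])))
      ),
      dense = list(
        W1 = glorot(nd * h[2], arch$dense_units), b1 = numeric(arch$dense_units),
        W2 = glorot(arch$dense_units, length(classes)),
        b2 = numeric(length(classes))
      )
    )
    structure(list(weights = weights, arch = arch, classes = classes,
                   n_channels = n_channels, loss_curve = numeric(0)),
              class = "grip_lstm")
  })
}

#' Closed-form and actual parameter counts
#'
#' Each recurrent direction of a layer holds `4 * h * (n_in + h + 1)`
#' weights; layer normalization adds `2 * dim` per normalized vector and
#' the dense head `(in + 1) * out` per layer.
#'
#' @param model A `grip_lstm`.
#' @return Named list with `actual` (summed array lengths) and `formula`
#'   (the closed-form count); the two are equal.
#' @export
lstm_param_count <- function(model) {
  arch <- model$arch
  h <- arch$hidden_units
  nd <- if (arch$bidirectional) 2L else 1L
  K <- length(model$classes)
  formula <- nd * 4 * h[1] * (model$n_channels + h[1] + 1) +
    nd * 4 * h[2] * (nd * h[1] + h[2] + 1) +
    2 * nd * h[1] + 2 * nd * h[2] +
    (nd * h[2] + 1) * arch$dense_units +
    (arch$dense_units + 1) * K
  actual <- as.double(sum(unlist(rapply(model$weights, length, how = "list"),
                                 use.names = FALSE)))
  list(actual = actual, formula = formula)
}

# ---- batched forward / backward -------------------------------------------
#
# Padded batches are held as one stacked matrix of B*T rows in time-major
# blocks (rows (t-1)*B + 1 .. t*B hold timestep t of all B trials), so the
# input projection, layer normalization and weight-gradient accumulation
# each reduce to a single large matrix product over the whole batch; only
# the hidden-state recurrence iterates over timesteps.

# Right-pad a list of Ti x c matrices into a stacked batch.
pad_batch <- function(values) {
  lens <- vapply(values, nrow, integer(1))
  T_max <- max(lens)
  B <- length(values)
  c_in <- ncol(values[[1]])
  X <- matrix(0, B * T_max, c_in)
  mask <- matrix(0, B, T_max)
  for (i in seq_len(B)) {
    X[seq.int(i, by = B, length.out = lens[i]), ] <- values[[i]]
    mask[i, seq_len(lens[i])] <- 1
  }
  list(X = X, mask = mask, lens = lens, B = B, T = T_max)
}

t_rows <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# One direction over the whole padded batch; `ord` is 1:T (forward
# direction) or T:1 (backward direction). Hidden and cell states hold their
# previous value at masked (padded) timesteps, so the final forward state
# equals the state at each trial's last valid sample.
dir_forward <- function(X, mask, wp, ord, hdim, B, want_cache) {
  Tm <- length(ord)
  ZX <- X %*% wp$W
  bmat <- matrix(wp$b, B, 4 * hdim, byrow = TRUE)
  i1 <- 1:hdim; i2 <- hdim + i1; i3 <- 2 * hdim + i1; i4 <- 3 * hdim + i1
  h <- matrix(0, B, hdim)
  cc <- matrix(0, B, hdim)
  Hs <- matrix(0, B * Tm, hdim)            # time-major sequence output
  cache <- if (want_cache) {
    list(I = matrix(0, B * Tm, hdim), F = matrix(0, B * Tm, hdim),
         G = matrix(0, B * Tm, hdim), O = matrix(0, B * Tm, hdim),
         TC = matrix(0, B * Tm, hdim), Cprev = matrix(0, B * Tm, hdim),
         Hprev = matrix(0, B * Tm, hdim), X = X)
  } else NULL
  for (s in seq_len(Tm)) {
    t <- ord[s]
    rows <- t_rows(t, B)
    m <- mask[, t]
    z <- ZX[rows, , drop = FALSE] + h %*% wp$U + bmat
    gi <- sigmoid(z[, i1, drop = FALSE])
    gf <- sigmoid(z[, i2, drop = FALSE])
    gg <- tanh(z[, i3, drop = FALSE])
    go <- sigmoid(z[, i4, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    if (want_cache) {
      srows <- t_rows(s, B)                # caches in processing order
      cache$I[srows, ] <- gi; cache$F[srows, ] <- gf
      cache$G[srows, ] <- gg; cache$O[srows, ] <- go
      cache$TC[srows, ] <- tc; cache$Cprev[srows, ] <- cc
      cache$Hprev[srows, ] <- h
    }
    h <- m * (go * tc) + (1 - m) * h
    cc <- m * c_new + (1 - m) * cc
    Hs[rows, ] <- h
  }
  list(Hs = Hs, final = h, cache = cache)
}

# dh_seq: B*T x h time-major gradient into the sequence output (or NULL);
# dh_final: gradient into the direction's final state (or NULL).
dir_backward <- function(wp, cache, mask, ord, dh_seq, dh_final, hdim, B) {
  Tm <- length(ord)
  tU <- t(wp$U)
  DZ <- matrix(0, B * Tm, 4 * hdim)        # processing order
  dh <- if (is.null(dh_final)) matrix(0, B, hdim) else dh_final
  dc <- matrix(0, B, hdim)
  for (s in rev(seq_len(Tm))) {
    t <- ord[s]
    if (!is.null(dh_seq)) dh <- dh + dh_seq[t_rows(t, B), , drop = FALSE]
    srows <- t_rows(s, B)
    m <- mask[, t]
    gi <- cache$I[srows, , drop = FALSE]
    gf <- cache$F[srows, , drop = FALSE]
    gg <- cache$G[srows, , drop = FALSE]
    go <- cache$O[srows, , drop = FALSE]
    tc <- cache$TC[srows, , drop = FALSE]
    c_prev <- cache$Cprev[srows, , drop = FALSE]
    dh_new <- dh * m
    dh_prev <- dh * (1 - m)
    dc_new <- dc * m
    dc_prev0 <- dc * (1 - m)
    do_ <- dh_new * tc
    dc_new <- dc_new + dh_new * go * (1 - tc^2)
    dz <- cbind((dc_new * gg) * gi * (1 - gi),
                (dc_new * c_prev) * gf * (1 - gf),
                (dc_new * gi) * (1 - gg^2),
                do_ * go * (1 - go))
    DZ[srows, ] <- dz
    dh <- dz %*% tU + dh_prev
    dc <- dc_new * gf + dc_prev0
  }
  # X rows are time-major but dW sums over all steps, so reorder DZ to
  # time-major once for the input/weight products
  if (identical(ord, seq_len(Tm))) {
    DZ_time <- DZ
  } else {
    perm <- as.vector(vapply(ord, t_rows, integer(B), B = B))
    DZ_time <- matrix(0, B * Tm, 4 * hdim)
    DZ_time[perm, ] <- DZ
  }
  list(dW = crossprod(cache$X, DZ_time),
       dU = crossprod(cache$Hprev, DZ),
       db = colSums(DZ),
       dX = DZ_time %*% t(wp$W))
}

ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, g, `*`)
  y <- sweep(y, 2, b, `+`)
  list(y = y, xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, `*`)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

relu <- function(x) pmax(x, 0)

# Full forward pass over one padded batch.
lstm_forward_batch <- function(w, arch, batch, want_cache = FALSE) {
  h <- arch$hidden_units
  nd <- if (arch$bidirectional) 2L else 1L
  Tm <- batch$T
  B <- batch$B
  orders <- list(seq_len(Tm), rev(seq_len(Tm)))[seq_len(nd)]

  # layer 1: sequence output, normalized and rectified per timestep
  l1 <- lapply(seq_len(nd), function(d) {
    dir_forward(batch$X, batch$mask, w$layers[[1]]$dirs[[d]], orders[[d]],
                h[1], B, want_cache)
  })
  seq1_raw <- do.call(cbind, lapply(l1, `[[`, "Hs"))
  ln1 <- ln_forward(seq1_raw, w$layers[[1]]$ln$g, w$layers[[1]]$ln$b)
  seq1 <- relu(ln1$y)

  # layer 2: last-state output
  l2 <- lapply(seq_len(nd), function(d) {
    dir_forward(seq1, batch$mask, w$layers[[2]]$dirs[[d]], orders[[d]],
                h[2], B, want_cache)
  })
  E_raw <- do.call(cbind, lapply(l2, `[[`, "final"))
  ln2 <- ln_forward(E_raw, w$layers[[2]]$ln$g, w$layers[[2]]$ln$b)
  E <- relu(ln2$y)

  Z1 <- sweep(E %*% w$dense$W1, 2, w$dense$b1, `+`)
  A1 <- relu(Z1)
  logits <- sweep(A1 %*% w$dense$W2, 2, w$dense$b2, `+`)
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)

  out <- list(P = P, logits = logits)
  if (want_cache) {
    out$cache <- list(l1 = l1, l2 = l2, ln1 = ln1, ln2 = ln2, E = E,
                      Z1 = Z1, A1 = A1, orders = orders, B = B, Tm = Tm)
  }
  out
}

# Loss and full gradient tree for one batch; y_idx are 1-based class
# indices. Returns mean cross-entropy and gradients shaped like `w`.
lstm_loss_and_grads <- function(w, arch, batch, y_idx) {
  fwd <- lstm_forward_batch(w, arch, batch, want_cache = TRUE)
  ca <- fwd$cache
  B <- ca$B
  h <- arch$hidden_units
  nd <- if (arch$bidirectional) 2L else 1L

  loss <- -mean(log(pmax(fwd$P[cbind(seq_len(B), y_idx)], 1e-12)))
  if (!is.finite(loss)) abort("non-finite training loss; aborting")

  dlogits <- fwd$P
  dlogits[cbind(seq_len(B), y_idx)] <-
    dlogits[cbind(seq_len(B), y_idx)] - 1
  dlogits <- dlogits / B

  g <- list(layers = list(list(dirs = vector("list", nd), ln = NULL),
                          list(dirs = vector("list", nd), ln = NULL)),
            dense = list())
  g$dense$W2 <- crossprod(ca$A1, dlogits)
  g$dense$b2 <- colSums(dlogits)
  dA1 <- dlogits %*% t(w$dense$W2)
  dZ1 <- dA1 * (ca$Z1 > 0)
  g$dense$W1 <- crossprod(ca$E, dZ1)
  g$dense$b1 <- colSums(dZ1)
  dE <- dZ1 %*% t(w$dense$W1)

  dln2y <- dE * (ca$ln2$y > 0)
  bk2 <- ln_backward(dln2y, ca$ln2, w$layers[[2]]$ln$g)
  g$layers[[2]]$ln <- list(g = bk2$dg, b = bk2$db)
  dE_raw <- bk2$dx

  # split into per-direction final-state gradients, then BPTT layer 2
  dseq1 <- matrix(0, B * ca$Tm, nd * h[1])
  for (d in seq_len(nd)) {
    cols <- ((d - 1) * h[2] + 1):(d * h[2])
    bk <- dir_backward(w$layers[[2]]$dirs[[d]], ca$l2[[d]]$cache,
                       batch$mask, ca$orders[[d]], NULL,
                       dE_raw[, cols, drop = FALSE], h[2], B)
    g$layers[[2]]$dirs[[d]] <- list(W = bk$dW, U = bk$dU, b = bk$db)
    dseq1 <- dseq1 + bk$dX
  }

  # back through layer-1 ReLU + layer norm over the whole stack at once
  dy <- dseq1 * (ca$ln1$y > 0)
  bk1 <- ln_backward(dy, ca$ln1, w$layers[[1]]$ln$g)
  g$layers[[1]]$ln <- list(g = bk1$dg, b = bk1$db)

  for (d in seq_len(nd)) {
    cols <- ((d - 1) * h[1] + 1):(d * h[1])
    bk <- dir_backward(w$layers[[1]]$dirs[[d]], ca$l1[[d]]$cache,
                       batch$mask, ca$orders[[d]],
                       bk1$dx[, cols, drop = FALSE], NULL, h[1], B)
    g$layers[[1]]$dirs[[d]] <- list(W = bk$dW, U = bk$dU, b = bk$db)
  }
  list(loss = loss, grads = g)
}

# ---- Adam over the nested weight tree -------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    keys <- names(a)
    for (i in seq_along(a)) {
      key <- if (!is.null(keys) && nzchar(keys[i])) keys[i] else i
      out[[key]] <- tree_map2(f, a[[key]], b[[key]])
    }
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_step <- function(state, w, g, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- tree_map2(function(m, gg) beta1 * m + (1 - beta1) * gg,
                       state$m, g)
  state$v <- tree_map2(function(v, gg) beta2 * v + (1 - beta2) * gg^2,
                       state$v, g)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  state$w <- tree_map2(`-`, w, upd)
  state
}

# ---- training / prediction -------------------------------------------------

#' Train the LSTM classifier
#'
#' Stochastic (seeded) mini-batch training: trials are sorted by length,
#' chunked into batches that are right-padded with masks, and the batch
#' order is reshuffled every epoch. Cross-entropy loss is minimized with
#' Adam for a fixed number of epochs (no early stopping). Padded timesteps
#' never influence a trial's hidden states or gradients.
#'
#' @param values List of time-by-channel velocity matrices (ragged lengths
#'   allowed; fixed-length DTW-aligned trials are accepted identically).
#' @param labels Class label per trial.
#' @param arch An [lstm_architecture()].
#' @param params An [lstm_training_params()].
#' @param classes Class order; defaults to the sorted unique labels.
#' @return A trained `grip_lstm` with a per-epoch `loss_curve`.
#' @export
train_lstm <- function(values, labels, arch = lstm_architecture(),
                       params = lstm_training_params(),
                       classes = NULL) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(unique(labels)) < 2) abort("need at least 2 classes to train")
  ncs <- vapply(values, ncol, integer(1))
  if (any(ncs != ncs[1])) abort("trials must share one channel count")

  model <- build_lstm(ncs[1], classes, arch, seed = params$seed)
  y_idx_all <- match(labels, classes)

  with_preserved_rng(params$seed + 1L, {
    ord <- order(vapply(values, nrow, integer(1)))
    batches_idx <- split(ord, ceiling(seq_along(ord) / params$batch_size))
    batches <- lapply(batches_idx, function(ix) {
      b <- pad_batch(values[ix])
      b$y <- y_idx_all[ix]
      b
    })
    state <- list(w = model$weights, m = tree_zero(model$weights),
                  v = tree_zero(model$weights))
    step <- 0L
    loss_curve <- numeric(params$epochs)
    for (ep in seq_len(params$epochs)) {
      ep_loss <- 0
      for (bi in sample(seq_along(batches))) {
        b <- batches[[bi]]
        lg <- lstm_loss_and_grads(state$w, arch, b, b$y)
        step <- step + 1L
        state <- adam_step(state, state$w, lg$grads, params$learning_rate,
                           step)
        ep_loss <- ep_loss + lg$loss * length(b$y)
      }
      loss_curve[ep] <- ep_loss / length(values)
    }
    model$weights <- state$w
    model$loss_curve <- loss_curve
    model$params <- params
    model
  })
}

#' Predict movement classes with a trained LSTM
#'
#' @param object A `grip_lstm`.
#' @param values List of time-by-channel matrices (any lengths) with the
#'   training channel count.
#' @param batch_size Inference batch size (result is identical to
#'   per-trial inference thanks to masking).
#' @param ... Unused.
#' @return Tibble with `label` and one `prob_<class>` column per class.
#' @export
predict.grip_lstm <- function(object, values, batch_size = 32, ...) {
  ncs <- vapply(values, ncol, integer(1))
  if (any(ncs != object$n_channels)) {
    abort(paste0("channel count ", ncs[which(ncs != object$n_channels)[1]],
                 " does not match model channels ", object$n_channels))
  }
  n <- length(values)
  P <- matrix(NA_real_, n, length(object$classes))
  ord <- order(vapply(values, nrow, integer(1)))
  chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
  for (ix in chunks) {
    b <- pad_batch(values[ix])
    fwd <- lstm_forward_batch(object$weights, object$arch, b)
    P[ix, ] <- fwd$P
  }
  lab <- object$classes[max.col(P, ties.method = "first")]
  out <- tibble::as_tibble(as.data.frame(P))
  names(out) <- paste0("prob_", object$classes)
  dplyr::bind_cols(tibble::tibble(label = lab), out)
}

#' @export
print.grip_lstm <- function(x, ...) {
  pc <- lstm_param_count(x)
  cat("<grip_lstm> stacked ",
      if (x$arch$bidirectional) "bidirectional " else "", "LSTM\n", sep = "")
  cat("  hidden units:", paste(x$arch$hidden_units, collapse = ", "),
      "per direction; dense:", x$arch$dense_units, "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  parameters:", pc$actual,
      if (length(x$loss_curve)) paste0(" (trained ", length(x$loss_curve),
                                       " epochs, final loss ",
                                       signif(x$loss_curve[length(x$loss_curve)], 4), ")")
      else " (untrained)", "\n")
  invisible(x)
}

#' @rdname tidy.grip_cv
#' @method tidy grip_lstm
#' @export
tidy.grip_lstm <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_curve), loss = x$loss_curve)
}

#' @rdname tidy.grip_cv
#' @method glance grip_lstm
#' @export
glance.grip_lstm <- function(x, ...) {
  pc <- lstm_param_count(x)
  tibble::tibble(
    n_parameters = pc$actual,
    n_classes = length(x$classes),
    epochs_trained = length(x$loss_curve),
    final_loss = if (length(x$loss_curve)) x$loss_curve[length(x$loss_curve)]
                 else NA_real_
  )
}

#' Grid search over LSTM hyperparameters
#'
#' Optional utility (not run by any default pipeline): trains one model per
#' row of the expanded grid and reports holdout accuracy.
#'
#' @param values,labels Training trials and labels.
#' @param holdout_values,holdout_labels Evaluation set.
#' @param epochs,batch_size,hidden_units Vectors of candidate values;
#'   `hidden_units` is used for both recurrent layers.
#' @param seed Seed shared by all fits.
#' @return Tibble of configurations and holdout accuracies, best first.
#' @export
lstm_grid_search <- function(values, labels, holdout_values, holdout_labels,
                             epochs = c(32, 64), batch_size = c(16, 32),
                             hidden_units = c(50, 100), seed = 1L) {
  grid <- expand.grid(epochs = epochs, batch_size = batch_size,
                      hidden_units = hidden_units)
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    m <- train_lstm(
      values, labels,
      arch = lstm_architecture(hidden_units = rep(grid$hidden_units[i], 2)),
      params = lstm_training_params(epochs = grid$epochs[i],
                                    batch_size = grid$batch_size[i],
                                    seed = seed)
    )
    pred <- predict(m, holdout_values)
    grid$accuracy[i] <- mean(pred$label == as.character(holdout_labels))
  }
  dplyr::arrange(tibble::as_tibble(grid), dplyr::desc(.data$accuracy))
}
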