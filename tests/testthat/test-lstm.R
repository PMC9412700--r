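small_arch <- function() lstm_architecture(hidden_units = c(6, 5),
                                           dense_units = 7)

test_that("an untrained model outputs a valid probability simplex", {
  m <- build_lstm(4, classes = letters[1:6], arch = small_arch(), seed = 2)
  vals <- lapply(c(9, 3, 12), function(t) random_series(t, 4))
  pred <- predict(m, vals)
  P <- as.matrix(pred[, -1])
  expect_identical(dim(P), c(3L, 6L))
  expect_true(all(P > 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-6)
  # reversing a sequence changes states but not the output shape
  rev_pred <- predict(m, list(vals[[1]][rev(seq_len(9)), ]))
  expect_identical(dim(as.matrix(rev_pred[, -1])), c(1L, 6L))
  expect_error(predict(m, list(random_series(5, 3))), "channel")
})

test_that("parameter count equals the closed-form formula", {
  m <- build_lstm(15, classes = letters[1:6], arch = small_arch())
  pc <- lstm_param_count(m)
  expect_identical(pc$actual, pc$formula)

  # ablating the backward direction removes the predicted amount
  m1 <- build_lstm(15, classes = letters[1:6],
                   arch = lstm_architecture(c(6, 5), 7, bidirectional = FALSE))
  pc1 <- lstm_param_count(m1)
  expect_identical(pc1$actual, pc1$formula)
  h1 <- 6; h2 <- 5
  removed <- 4 * h1 * (15 + h1 + 1) +          # backward cell, layer 1
    4 * h2 * (2 * h1 + h2 + 1) +               # backward cell, layer 2
    (4 * h2 * h1) +                            # forward layer-2 input halves
    2 * h1 + 2 * h2 +                          # layer-norm params
    h2 * 7                                     # dense input halves
  expect_identical(pc$formula - pc1$formula, removed)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  vals <- lapply(c(5, 7, 6, 4), function(t) random_series(t, 3))
  y <- c(1L, 2L, 1L, 2L)
  arch <- lstm_architecture(hidden_units = c(4, 5), dense_units = 6)
  m <- build_lstm(3, classes = c("a", "b"), arch = arch, seed = 3)
  b <- gripdecode:::pad_batch(vals)
  lg <- gripdecode:::lstm_loss_and_grads(m$weights, arch, b, y)
  loss_at <- function(w) {
    P <- gripdecode:::lstm_forward_batch(w, arch, b)$P
    -mean(log(P[cbind(seq_along(y), y)]))
  }
  paths <- list(list("layers", 1, "dirs", 1, "W"),
                list("layers", 1, "dirs", 2, "U"),
                list("layers", 1, "ln", "g"),
                list("layers", 2, "dirs", 1, "W"),
                list("layers", 2, "dirs", 2, "b"),
                list("layers", 2, "ln", "b"),
                list("dense", "W1"), list("dense", "W2"))
  eps <- 1e-6
  for (p in paths) {
    garr <- purrr::pluck(lg$grads, !!!p)
    for (i in sample(length(garr), 3)) {
      wp <- m$weights; purrr::pluck(wp, !!!p)[i] <-
        purrr::pluck(wp, !!!p)[i] + eps
      wm <- m$weights; purrr::pluck(wm, !!!p)[i] <-
        purrr::pluck(wm, !!!p)[i] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_lt(abs(num - garr[i]), 1e-7)
    }
  }
})

test_that("padding inside a batch does not change a trial's prediction", {
  m <- build_lstm(3, classes = letters[1:4], arch = small_arch(), seed = 5)
  set.seed(6)
  vals <- lapply(c(14, 3, 8, 11, 5), function(t) random_series(t, 3))
  batched <- predict(m, vals, batch_size = 5)       # padded together
  single <- dplyr::bind_rows(lapply(vals, function(v) predict(m, list(v))))
  expect_lt(max(abs(as.matrix(batched[, -1]) - as.matrix(single[, -1]))),
            1e-5)
  expect_identical(batched$label, single$label)
})

test_that("training is seeded-deterministic and learns separable data", {
  ds <- tiny_velocity_dataset()
  idx <- which(ds$trials$subject_id == "S01")
  vals <- ds$trials$values[idx]
  labs <- ds$trials$task[idx]
  arch <- lstm_architecture(hidden_units = c(12, 12))
  params <- lstm_training_params(epochs = 40, seed = 4)
  m1 <- train_lstm(vals, labs, arch = arch, params = params,
                   classes = grip_tasks())
  m2 <- train_lstm(vals, labs, arch = arch, params = params,
                   classes = grip_tasks())
  expect_identical(m1$loss_curve, m2$loss_curve)
  expect_lt(abs(m1$loss_curve[40] - m2$loss_curve[40]), 1e-6)
  expect_identical(length(m1$loss_curve), 40L)
  # the loss trend is downward on separable data
  expect_lt(mean(tail(m1$loss_curve, 5)), mean(head(m1$loss_curve, 5)))
  acc <- mean(predict(m1, vals)$label == labs)
  expect_gt(acc, 0.95)
  # tidy/glance accessors
  expect_identical(nrow(tidy(m1)), 40L)
  expect_identical(glance(m1)$epochs_trained, 40L)
})

test_that("fixed-length aligned trials are accepted like ragged ones", {
  ds <- tiny_velocity_dataset()
  idx <- which(ds$trials$subject_id == "S01")
  al <- align_dataset(ds$trials$values[idx])
  labs <- ds$trials$task[idx]
  m <- train_lstm(al$train, labs, arch = small_arch(),
                  params = lstm_training_params(epochs = 3, seed = 7),
                  classes = grip_tasks())
  pred <- predict(m, al$train)
  expect_identical(nrow(pred), length(idx))
})
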