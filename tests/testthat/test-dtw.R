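test_that("identical series give zero distance and the diagonal path", {
  x <- random_series(8, 3)
  al <- dtw_warp(x, x)
  expect_identical(al$distance, 0)
  expect_identical(al$path, cbind(1:8, 1:8))
})

test_that("dtw matches the brute-force recursion on random instances", {
  set.seed(11)
  for (i in 1:80) {
    n <- sample(1:10, 1); m <- sample(1:10, 1); ch <- sample(1:3, 1)
    x <- random_series(n, ch); y <- random_series(m, ch)
    al <- dtw_warp(x, y)
    expect_lt(abs(al$distance - dtw_oracle(x, y)), 1e-9)
    # symmetry
    expect_lt(abs(al$distance - dtw_warp(y, x)$distance), 1e-12)
    # path axioms: endpoints, monotone steps of 1
    p <- al$path
    expect_identical(p[1, ], c(1L, 1L))
    expect_identical(p[nrow(p), ], c(n, m))
    if (nrow(p) > 1) {
      steps <- diff(p)
      expect_true(all(steps >= 0 & steps <= 1))
      expect_true(all(rowSums(steps) >= 1))
    }
    expect_lte(nrow(p), n + m - 1)
    # the returned path attains the returned distance
    cost <- sum(sqrt(rowSums(
      (x[p[, 1], , drop = FALSE] - y[p[, 2], , drop = FALSE])^2)))
    expect_lt(abs(cost - al$distance), 1e-9)
  }
})

test_that("a single-sample series pairs against every sample", {
  y <- c(0.5, 2, -1)
  al <- dtw_warp(3, y)
  expect_equal(al$distance, sum(abs(3 - y)))
  expect_identical(al$path, cbind(c(1L, 1L, 1L), 1:3))
  expect_error(dtw_warp(random_series(4, 2), random_series(4, 3)), "channel")
})

test_that("warp-resampling collapses onto the template time base", {
  # optimal path pairs x1,x2 -> t1 and x3 -> t2; averaging gives (0, 4)
  out <- warp_to_template(c(0, 0, 4), c(0, 4))
  expect_equal(out[, 1], c(0, 4))

  tpl <- random_series(7, 2)
  expect_identical(warp_to_template(tpl, tpl), tpl)

  set.seed(12)
  for (i in 1:100) {
    x <- random_series(sample(2:20, 1), 2)
    tpl2 <- random_series(sample(2:20, 1), 2)
    expect_identical(nrow(warp_to_template(x, tpl2)), nrow(tpl2))
  }
})

test_that("warping synchronizes time-rescaled copies of the template", {
  # a slow and a fast replay of one underlying movement both land close to
  # the template after warp-resampling
  u <- seq(0, 1, length.out = 40)
  base <- cbind(sin(2 * pi * u), cos(4 * pi * u))
  slow <- apply(base, 2, function(col)
    approx(u, col, xout = seq(0, 1, length.out = 73))$y)
  fast <- apply(base, 2, function(col)
    approx(u, col, xout = seq(0, 1, length.out = 26))$y)
  for (v in list(slow, fast)) {
    w <- warp_to_template(v, base)
    expect_lt(mean(sqrt(rowSums((w - base)^2))), 0.12)
  }
})

test_that("template selection follows the pairing score", {
  # identical trials: zero raw distances, degenerate normalization, and the
  # first pairing's first trial is returned
  x <- random_series(6, 2)
  same <- replicate(6, x, simplify = FALSE)
  sel <- select_template(same)
  expect_identical(sel$template_index, 1L)
  expect_true(all(sel$scores$dist == 0))
  expect_equal(sel$scores$score, sel$scores$rho)

  expect_error(select_template(same[1:3]), "at least 4")
  const <- replicate(4, matrix(1, 5, 2), simplify = FALSE)
  expect_error(select_template(const), "constant")
})

test_that("an outlier trial is never selected as template", {
  set.seed(15)
  u <- seq(0, 1, length.out = 30)
  mk <- function(amp = 1) amp * cbind(sin(2 * pi * u), cos(2 * pi * u)) +
    0.05 * random_series(30, 2)
  trials <- replicate(6, mk(), simplify = FALSE)
  trials[[2]] <- mk(amp = 10)              # pairing (2, 5) sees the outlier
  sel <- select_template(trials)
  expect_false(sel$template_index == 2L)

  # independent recomputation of every pairing score
  n <- length(trials)
  half <- floor(n / 2)
  raw <- numeric(half - 1); rho <- numeric(half - 1)
  for (i in seq_len(half - 1)) {
    x <- trials[[i]]; y <- trials[[i + half]]
    raw[i] <- dtw_oracle(x, y)
    p <- dtw_warp(x, y)$path
    rho[i] <- cor(as.vector(x[p[, 1], ]), as.vector(y[p[, 2], ]))
  }
  score <- rho * (1 - raw / max(raw))
  expect_lt(max(abs(score - sel$scores$score)), 1e-9)
  expect_identical(sel$template_index, which.max(score))
})

test_that("odd trial counts use floor(n/2) pairings and may leave one trial out", {
  set.seed(16)
  trials <- replicate(7, random_series(8, 2), simplify = FALSE)
  sel <- select_template(trials)
  expect_identical(nrow(sel$scores), 2L)       # floor(7/2) - 1
  expect_identical(sel$scores$j, sel$scores$i + 3L)
})

test_that("align_dataset fits the template on training trials only", {
  ds <- tiny_velocity_dataset()
  values <- ds$trials$values
  train <- values[1:12]; test <- values[13:18]
  al <- align_dataset(train, test)
  expect_lte(al$template_index, 12L)
  expect_identical(length(al$test), 6L)
  lens <- vapply(c(al$train, al$test), nrow, integer(1))
  expect_true(all(lens == nrow(al$template)))
  ftr <- flatten_features(al$train)
  fte <- flatten_features(al$test)
  expect_identical(ncol(ftr), ncol(fte))
  # empty test set is valid
  al0 <- align_dataset(train)
  expect_identical(al0$test, list())
})
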