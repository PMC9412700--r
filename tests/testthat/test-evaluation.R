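test_that("folds partition the trials under every scheme", {
  ds <- tiny_velocity_dataset()
  n <- nrow(ds$trials)

  loso <- make_folds(ds, cv_spec("loso"))
  expect_identical(nrow(loso), 2L)
  expect_identical(sort(unlist(loso$test)), seq_len(n))
  expect_true(all(vapply(seq_len(nrow(loso)), function(i) {
    length(intersect(loso$train[[i]], loso$test[[i]])) == 0
  }, logical(1))))

  loro <- make_folds(ds, cv_spec("loro"))
  expect_identical(nrow(loro), 4L)          # 2 subjects x 2 runs
  expect_identical(sort(unlist(loro$test)), seq_len(n))
  for (i in seq_len(nrow(loro))) {
    tr <- ds$trials[loro$train[[i]], ]
    te <- ds$trials[loro$test[[i]], ]
    expect_identical(unique(tr$subject_id), unique(te$subject_id))
    expect_false(any(te$run %in% tr$run))
    expect_identical(nrow(te), 18L)         # 6 blocks x 3 repetitions
  }
})

test_that("two-fold splits follow the grouping rules", {
  cfg <- synthetic_config(n_subjects_per_group = 2, runs = 1,
                          trials_per_block = 1, base_duration = 1,
                          sample_rate = 50, seed = 44)
  ds <- generate_dataset(cfg)

  hs <- make_folds(ds, cv_spec("two_fold", split = "hand_size"))
  expect_identical(nrow(hs), 2L)
  sizes <- ds$subjects$hand_size
  med <- stats::median(sizes)
  for (i in 1:2) {
    te_subj <- unique(ds$trials$subject_id[hs$test[[i]]])
    te_sizes <- sizes[match(te_subj, ds$subjects$subject_id)]
    expect_true(all(te_sizes <= med) || all(te_sizes >= med))
  }

  ag <- make_folds(ds, cv_spec("two_fold", split = "age"))
  for (i in 1:2) {
    te_subj <- unique(ds$trials$subject_id[ag$test[[i]]])
    expect_identical(
      length(unique(ds$subjects$age_group[match(te_subj,
                                                ds$subjects$subject_id)])),
      1L)
  }

  mt <- make_folds(ds, cv_spec("two_fold", split = "matched"))
  # each fold holds one of each hand-size-rank pair per age group
  a_subj <- unique(ds$trials$subject_id[mt$test[[1]]])
  expect_identical(length(a_subj), 2L)
  a_groups <- ds$subjects$age_group[match(a_subj, ds$subjects$subject_id)]
  expect_setequal(a_groups, c("young", "old"))

  odd <- ds
  odd$trials <- odd$trials[odd$trials$subject_id != "S01", ]
  odd$subjects <- odd$subjects[odd$subjects$subject_id != "S01", ]
  expect_error(make_folds(odd, cv_spec("two_fold", split = "matched")),
               "even number")
})

test_that("run_cv reports internally consistent metrics", {
  ds <- tiny_velocity_dataset()
  cv <- run_cv(ds, cv_spec("loro", "svm_dtw"))
  expect_identical(sum(cv$confusion), nrow(ds$trials))
  expect_equal(100 * sum(diag(cv$confusion)) / sum(cv$confusion), cv$da)
  expect_identical(unname(rowSums(cv$confusion)),
                   rep(nrow(ds$trials) / 6, 6))
  # balanced classes: sensitivities average to the overall DA
  expect_equal(mean(cv$sensitivity$sensitivity), cv$da, tolerance = 1e-9)
  expect_equal(mean(cv$per_subject$da), cv$da, tolerance = 1e-9)
  expect_equal(cv$se, sd(cv$per_subject$da) / sqrt(2))
  g <- glance(cv)
  expect_identical(g$da, cv$da)
  expect_identical(tidy(cv), cv$sensitivity)
})

test_that("a single-class training fold warns and predicts the majority", {
  ds <- tiny_velocity_dataset()
  one_class <- ds
  keep <- one_class$trials$task == "clothes_peg"
  one_class$trials <- one_class$trials[keep, ]
  w <- capture_warnings(cv <- run_cv(one_class, cv_spec("loro", "svm_dtw")))
  expect_true(any(grepl("single-class", w)))
  expect_identical(cv$da, 100)
})

test_that("the Gram-factor refit path reproduces the full SVM pipeline", {
  ds <- tiny_velocity_dataset()
  tr <- ds$trials
  train <- which(tr$subject_id == "S01")
  test <- which(tr$subject_id == "S02")
  al <- align_dataset(tr$values[train], tr$values[test])
  Ftr <- flatten_features(al$train)
  Fte <- flatten_features(al$test)
  set.seed(31)
  shuffled <- sample(tr$task[train])
  C <- svm_default_C(Ftr)
  m <- train_ovr_svm(Ftr, shuffled, C = C, classes = grip_tasks())
  direct <- predict(m, Fte)$label
  K <- tcrossprod(Ftr)
  eg <- eigen(K, symmetric = TRUE)
  G <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  fast <- gripdecode:::ovr_gram_predict(G, K, Fte %*% t(Ftr), shuffled, C,
                                        grip_tasks(), 1e-6)
  expect_identical(fast, direct)
})

test_that("the DTW+LSTM mode consumes aligned trials with template provenance", {
  ds <- tiny_velocity_dataset()
  spec <- cv_spec("loso", "lstm_dtw",
                  lstm_arch = lstm_architecture(hidden_units = c(6, 6)),
                  lstm_params = lstm_training_params(epochs = 2, seed = 8))
  cv <- run_cv(ds, spec)
  expect_identical(nrow(cv$predictions), nrow(ds$trials))
  expect_true(all(!is.na(cv$folds$template_row)))
  expect_true(all(cv$folds$template_in_train))
  expect_true(all(cv$predictions$predicted %in% grip_tasks()))
})

test_that("permutation draws are seeded and the CI brackets the mean", {
  ds <- tiny_velocity_dataset()
  spec <- cv_spec("loso", "svm_dtw")
  p2a <- permutation_test(ds, spec, n_permutations = 2, seed = 9)
  p2b <- permutation_test(ds, spec, n_permutations = 2, seed = 9)
  expect_identical(p2a$das, p2b$das)
  expect_identical(length(p2a$das), 2L)

  p100 <- permutation_test(ds, spec, n_permutations = 100, seed = 10)
  expect_lte(p100$ci[1], mean(p100$das))
  expect_gte(p100$ci[2], mean(p100$das))
  expect_identical(p100$threshold, p100$ci[2])
  expect_gte(p100$threshold, stats::median(p100$das))
  gl <- glance(p100)
  expect_identical(gl$n_permutations, 100L)
  expect_identical(nrow(tidy(p100)), 100L)
})

test_that("paired condition comparison follows the signed-rank conventions", {
  a <- c(90, 91, 92, 93, 94)
  expect_warning(res <- compare_conditions(a, a), "zero")
  expect_identical(res$p_value, 1)
  expect_identical(res$p_adjusted, 1)

  # all-positive distinct differences, n = 17: the exact two-sided p is
  # 2 / 2^17 (most extreme rank sum)
  set.seed(12)
  b <- runif(17, 80, 95)
  shift <- 2 + (1:17) / 100                 # distinct magnitudes, no ties
  res2 <- compare_conditions(b + shift, b)
  expect_equal(res2$p_value, 2 / 2^17)
  expect_equal(res2$p_adjusted, res2$p_value)
  res3 <- compare_conditions(b + shift, b, n_comparisons = 3)
  expect_equal(res3$p_adjusted, 3 * res2$p_value)
  # adjusted p caps at 1
  set.seed(13)
  x <- rnorm(10); y <- x + rnorm(10, sd = 2)
  res4 <- compare_conditions(x, y, n_comparisons = 1e6)
  expect_lte(res4$p_adjusted, 1)
})

test_that("the sensitivity table mirrors per-class recall", {
  ds <- tiny_velocity_dataset()
  cv <- run_cv(ds, cv_spec("loro", "svm_dtw"))
  tab <- sensitivity_table(list(svm_loro = cv), format = FALSE)
  expect_identical(tab$task, grip_tasks())
  expect_equal(tab$svm_loro_sensitivity, cv$sensitivity$sensitivity)
  fmt <- sensitivity_table(list(svm_loro = cv))
  expect_match(fmt$svm_loro[1], "^\\d+\\.\\d \\(\\d+\\.\\d\\)$")
  # perfect confusion matrix means 100% everywhere
  perfect <- cv
  perfect$sensitivity$sensitivity <- rep(100, 6)
  tab100 <- sensitivity_table(list(x = perfect), format = FALSE)
  expect_true(all(tab100$x_sensitivity == 100))
})

test_that("autoplot methods return ggplot objects", {
  ds <- tiny_velocity_dataset()
  cv <- run_cv(ds, cv_spec("loro", "svm_dtw"))
  expect_s3_class(autoplot(cv), "ggplot")
  pt <- permutation_test(ds, cv_spec("loso", "svm_dtw"),
                         n_permutations = 5, seed = 3)
  expect_s3_class(autoplot(pt, observed_da = cv$da), "ggplot")
  expect_s3_class(plot_trial(ds$trials$values[[1]], 16), "ggplot")
})
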