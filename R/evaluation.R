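#' Cross-validation specification
#'
#' Three regimes: `"loro"` leaves one run out within each subject
#' (within-subject decoding; one fold per subject-run pair, trained on that
#' subject's remaining runs); `"loso"` leaves one subject out
#' (across-subject generalization); `"two_fold"` splits the subjects into
#' two halves by the chosen `split` rule and trains on each half in turn.
#'
#' @param scheme One of `"loro"`, `"loso"`, `"two_fold"`.
#' @param classifier `"svm_dtw"` (DTW alignment + one-vs-rest linear SVM),
#'   `"lstm"` (sequence classifier on raw velocity trials) or `"lstm_dtw"`
#'   (LSTM on DTW-aligned trials).
#' @param split Two-fold split rule: `"matched"` pairs subjects by age group
#'   and hand-size rank and puts one of each pair in each fold;
#'   `"hand_size"` splits small vs large hands at the median;
#'   `"age"` splits young vs old.
#' @param svm_C SVM box constraint (`NULL` = [svm_default_C()] per fold).
#' @param svm_tolerance SVM solver tolerance.
#' @param lstm_arch,lstm_params LSTM configuration, see
#'   [lstm_architecture()] and [lstm_training_params()].
#' @return A `cv_spec` list.
#' @export
cv_spec <- function(scheme = c("loso", "loro", "two_fold"),
                    classifier = c("svm_dtw", "lstm", "lstm_dtw"),
                    split = c("matched", "hand_size", "age"),
                    svm_C = NULL, svm_tolerance = 1e-6,
                    lstm_arch = lstm_architecture(),
                    lstm_params = lstm_training_params()) {
  structure(list(scheme = match.arg(scheme),
                 classifier = match.arg(classifier),
                 split = match.arg(split),
                 svm_C = svm_C, svm_tolerance = svm_tolerance,
                 lstm_arch = lstm_arch, lstm_params = lstm_params),
            class = "cv_spec")
}

#' Build cross-validation folds
#'
#' Returns one row per fold with list columns of trial row indices. The
#' test sets partition the trials: every trial appears in exactly one test
#' fold under every scheme.
#'
#' @param dataset A `glove_dataset`.
#' @param spec A [cv_spec()].
#' @return Tibble with columns `fold`, `subject_id` (NA where not
#'   applicable), `train` and `test` (lists of integer row indices).
#' @export
make_folds <- function(dataset, spec) {
  tr <- dataset$trials
  idx <- seq_len(nrow(tr))
  if (spec$scheme != "loro" && length(unique(tr$subject_id)) < 2) {
    abort("across-subject schemes need at least 2 subjects")
  }
  if (spec$scheme == "loso") {
    subs <- unique(tr$subject_id)
    folds <- purrr::map(subs, function(s) {
      list(test = idx[tr$subject_id == s], train = idx[tr$subject_id != s])
    })
    tibble::tibble(
      fold = seq_along(subs), subject_id = subs,
      train = purrr::map(folds, "train"), test = purrr::map(folds, "test")
    )
  } else if (spec$scheme == "loro") {
    runs_per_subject <- tapply(tr$run, tr$subject_id,
                               function(r) length(unique(r)))
    if (any(runs_per_subject < 2)) {
      abort(paste0("leave-one-run-out needs at least 2 runs per subject; ",
                   "subject ", names(runs_per_subject)[runs_per_subject < 2][1],
                   " has ", min(runs_per_subject)))
    }
    key <- unique(tr[, c("subject_id", "run")])
    folds <- purrr::pmap(key, function(subject_id, run) {
      list(test = idx[tr$subject_id == subject_id & tr$run == run],
           train = idx[tr$subject_id == subject_id & tr$run != run])
    })
    tibble::tibble(
      fold = seq_len(nrow(key)), subject_id = key$subject_id,
      run = key$run,
      train = purrr::map(folds, "train"), test = purrr::map(folds, "test")
    )
  } else {
    groups <- two_fold_groups(dataset, spec$split)
    a <- idx[tr$subject_id %in% groups$a]
    b <- idx[tr$subject_id %in% groups$b]
    tibble::tibble(
      fold = 1:2, subject_id = NA_character_,
      train = list(a, b), test = list(b, a)
    )
  }
}

two_fold_groups <- function(dataset, split) {
  su <- dataset$subjects
  su <- su[su$subject_id %in% unique(dataset$trials$subject_id), ]
  if (split == "age") {
    list(a = su$subject_id[su$age_group == "young"],
         b = su$subject_id[su$age_group == "old"])
  } else if (split == "hand_size") {
    ord <- su$subject_id[order(su$hand_size)]
    half <- floor(length(ord) / 2)
    list(a = ord[seq_len(half)], b = ord[-seq_len(half)])
  } else { # matched: pair by (age group, hand-size rank), alternate folds
    a <- character(0)
    b <- character(0)
    for (gr in unique(su$age_group)) {
      ids <- su$subject_id[su$age_group == gr]
      if (length(ids) %% 2 == 1) {
        abort(paste0("matched split needs an even number of '", gr,
                     "' subjects"))
      }
      ids <- ids[order(su$hand_size[match(ids, su$subject_id)])]
      a <- c(a, ids[seq_along(ids) %% 2 == 1])
      b <- c(b, ids[seq_along(ids) %% 2 == 0])
    }
    list(a = a, b = b)
  }
}

fit_predict_fold <- function(values, labels, train, test, spec) {
  tr_lab <- labels[train]
  if (length(unique(tr_lab)) < 2) {
    warn("single-class training fold: predicting the majority class")
    return(list(pred = rep(tr_lab[1], length(test)), template_row = NA_integer_))
  }
  if (spec$classifier == "svm_dtw") {
    al <- align_dataset(values[train], values[test])
    model <- train_ovr_svm(flatten_features(al$train), tr_lab,
                           C = spec$svm_C, classes = grip_tasks(),
                           tolerance = spec$svm_tolerance)
    pred <- predict(model, flatten_features(al$test))$label
    list(pred = pred, template_row = train[al$template_index])
  } else if (spec$classifier == "lstm") {
    model <- train_lstm(values[train], tr_lab, arch = spec$lstm_arch,
                        params = spec$lstm_params, classes = grip_tasks())
    list(pred = predict(model, values[test])$label,
         template_row = NA_integer_)
  } else { # lstm_dtw: LSTM consumes the DTW-aligned fixed-length trials
    al <- align_dataset(values[train], values[test])
    model <- train_lstm(al$train, tr_lab, arch = spec$lstm_arch,
                        params = spec$lstm_params, classes = grip_tasks())
    list(pred = predict(model, al$test)$label,
         template_row = train[al$template_index])
  }
}

#' Run a cross-validated decoding analysis
#'
#' For every fold the classifier (and, for the DTW pipelines, the template)
#' is fit on the training trials only and evaluated on the held-out trials.
#' Decoding accuracy (DA) is the percentage of test trials whose predicted
#' movement class matches the true class; the standard error is computed
#' across per-subject DAs.
#'
#' @param dataset A velocity-stage `glove_dataset` (see
#'   [preprocess_dataset()]).
#' @param spec A [cv_spec()].
#' @return A `grip_cv` object: `da` (percent), `se`, trial-level
#'   `predictions`, 6x6 `confusion` matrix (rows = true class),
#'   `sensitivity` per class, `per_subject` DAs and per-fold metadata
#'   including DTW template provenance.
#' @export
run_cv <- function(dataset, spec) {
  validate_glove_dataset(dataset)
  tr <- dataset$trials
  if (nrow(tr) == 0) abort("empty dataset")
  values <- tr$values
  labels <- tr$task
  folds <- make_folds(dataset, spec)

  preds <- vector("list", nrow(folds))
  meta <- vector("list", nrow(folds))
  for (i in seq_len(nrow(folds))) {
    fp <- fit_predict_fold(values, labels, folds$train[[i]],
                           folds$test[[i]], spec)
    preds[[i]] <- tibble::tibble(
      row = folds$test[[i]],
      fold = folds$fold[i],
      subject_id = tr$subject_id[folds$test[[i]]],
      run = tr$run[folds$test[[i]]],
      task = labels[folds$test[[i]]],
      predicted = fp$pred
    )
    meta[[i]] <- tibble::tibble(
      fold = folds$fold[i],
      n_train = length(folds$train[[i]]),
      n_test = length(folds$test[[i]]),
      template_row = fp$template_row,
      template_in_train = if (is.na(fp$template_row)) NA else
        fp$template_row %in% folds$train[[i]]
    )
  }
  predictions <- dplyr::bind_rows(preds)
  new_grip_cv(predictions, dplyr::bind_rows(meta), spec)
}

new_grip_cv <- function(predictions, folds_meta, spec) {
  tasks <- grip_tasks()
  conf <- table(factor(predictions$task, levels = tasks),
                factor(predictions$predicted, levels = tasks))
  conf <- matrix(as.integer(conf), nrow = length(tasks),
                 dimnames = list(true = tasks, predicted = tasks))
  da <- 100 * mean(predictions$predicted == predictions$task)

  per_subject <- predictions |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(da = 100 * mean(.data$predicted == .data$task),
                     n = dplyr::n(), .groups = "drop")
  se <- if (nrow(per_subject) > 1) {
    sd(per_subject$da) / sqrt(nrow(per_subject))
  } else NA_real_

  per_subj_class <- predictions |>
    dplyr::group_by(.data$subject_id, .data$task) |>
    dplyr::summarise(sens = 100 * mean(.data$predicted == .data$task),
                     .groups = "drop")
  sensitivity <- per_subj_class |>
    dplyr::group_by(task = factor(.data$task, levels = tasks)) |>
    dplyr::summarise(
      sensitivity = mean(.data$sens),
      se = if (dplyr::n() > 1) sd(.data$sens) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$task) |>
    dplyr::mutate(task = as.character(.data$task))

  structure(list(da = da, se = se, predictions = predictions,
                 confusion = conf, sensitivity = sensitivity,
                 per_subject = per_subject, folds = folds_meta,
                 spec = spec),
            class = "grip_cv")
}

#' @export
print.grip_cv <- function(x, ...) {
  cat("<grip_cv> ", x$spec$classifier, " / ", x$spec$scheme,
      if (x$spec$scheme == "two_fold") paste0(" (", x$spec$split, ")"),
      "\n", sep = "")
  cat(sprintf("  decoding accuracy: %.1f%% (SE %.1f) over %d trials, %d folds\n",
              x$da, x$se, nrow(x$predictions), nrow(x$folds)))
  invisible(x)
}

#' Tidy decoding results
#'
#' `tidy()` returns per-class sensitivities for a `grip_cv`, the permutation
#' DA draws for a `grip_permtest`, per-class weight summaries for an
#' `ovr_svm` and the training loss curve for a `grip_lstm`; `glance()`
#' returns the corresponding one-row summaries.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy grip_cv
#' @export
tidy.grip_cv <- function(x, ...) x$sensitivity

#' @rdname tidy.grip_cv
#' @method glance grip_cv
#' @export
glance.grip_cv <- function(x, ...) {
  tibble::tibble(
    da = x$da, se = x$se, n_trials = nrow(x$predictions),
    n_folds = nrow(x$folds), n_subjects = nrow(x$per_subject),
    scheme = x$spec$scheme, classifier = x$spec$classifier
  )
}

#' Permutation-based chance-level estimation
#'
#' Shuffles the task labels over all trials (preserving the class counts),
#' reruns the full cross-validation on the relabeled data, and records the
#' decoding accuracy; repeated `n_permutations` times. The 2.5th and 97.5th
#' percentiles of the resulting DA distribution form the 95% confidence
#' interval, and the upper bound serves as the significance threshold for
#' observed accuracies. On a balanced six-class design the distribution
#' centers on the theoretical guessing level of 1/6.
#'
#' For the `svm_dtw` pipeline the per-fold template selection, alignment
#' and default box constraint depend only on the signals, not the labels,
#' so they are computed once per fold and reused across permutations; the
#' SVM itself is refit for every permutation. This is mathematically
#' identical to rerunning the whole pipeline per permutation.
#'
#' @param dataset A velocity-stage `glove_dataset`.
#' @param spec A [cv_spec()].
#' @param n_permutations Number of label shuffles (1000 for publication-
#'   grade thresholds; small values are fine for smoke tests).
#' @param seed Integer seed for the shuffles.
#' @return A `grip_permtest`: the DA distribution `das`, percentile `ci`,
#'   significance `threshold` and metadata.
#' @export
permutation_test <- function(dataset, spec, n_permutations = 1000,
                             seed = 1L) {
  validate_glove_dataset(dataset)
  stopifnot(n_permutations >= 1)
  tr <- dataset$trials
  labels <- tr$task
  values <- tr$values
  folds <- make_folds(dataset, spec)

  das <- with_preserved_rng(seed, {
    if (spec$classifier == "svm_dtw") {
      # alignment, features and default C are label-independent, so build
      # them once per fold; the SVM dual depends on the features only
      # through the linear Gram matrix, so each fold's feature matrix is
      # replaced by an exact low-dimensional factor G with G G' = F F'
      # (identical solution, far less kernel arithmetic per refit)
      cache <- lapply(seq_len(nrow(folds)), function(i) {
        al <- align_dataset(values[folds$train[[i]]], values[folds$test[[i]]])
        Ftr <- flatten_features(al$train)
        Fte <- flatten_features(al$test)
        K <- tcrossprod(Ftr)
        eg <- eigen(K, symmetric = TRUE)
        list(G = eg$vectors %*% diag(sqrt(pmax(eg$values, 0))),
             K = K, Kte = Fte %*% t(Ftr),
             C = if (is.null(spec$svm_C)) svm_default_C(Ftr) else spec$svm_C)
      })
      vapply(seq_len(n_permutations), function(p) {
        pl <- sample(labels)
        correct <- 0L
        total <- 0L
        for (i in seq_len(nrow(folds))) {
          tr_lab <- pl[folds$train[[i]]]
          te_lab <- pl[folds$test[[i]]]
          pred <- if (length(unique(tr_lab)) < 2) {
            rep(tr_lab[1], length(te_lab))
          } else {
            ovr_gram_predict(cache[[i]]$G, cache[[i]]$K, cache[[i]]$Kte,
                             tr_lab, cache[[i]]$C, grip_tasks(),
                             spec$svm_tolerance)
          }
          correct <- correct + sum(pred == te_lab)
          total <- total + length(te_lab)
        }
        100 * correct / total
      }, numeric(1))
    } else {
      vapply(seq_len(n_permutations), function(p) {
        ds_p <- dataset
        ds_p$trials$task <- sample(labels)
        suppressWarnings(run_cv(ds_p, spec)$da)
      }, numeric(1))
    }
  })
  ci <- unname(quantile(das, c(0.025, 0.975)))
  structure(list(das = das, mean = mean(das), ci = ci, threshold = ci[2],
                 n_permutations = as.integer(n_permutations), seed = seed,
                 scheme = spec$scheme, classifier = spec$classifier),
            class = "grip_permtest")
}

#' @export
print.grip_permtest <- function(x, ...) {
  cat("<grip_permtest> ", x$classifier, " / ", x$scheme, ", ",
      x$n_permutations, " permutations\n", sep = "")
  cat(sprintf("  chance-level DA: %.1f%% (CI %.1f-%.1f%%), threshold %.1f%%\n",
              x$mean, x$ci[1], x$ci[2], x$threshold))
  invisible(x)
}

#' @rdname tidy.grip_cv
#' @method tidy grip_permtest
#' @export
tidy.grip_permtest <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$das), da = x$das)
}

#' @rdname tidy.grip_cv
#' @method glance grip_permtest
#' @export
glance.grip_permtest <- function(x, ...) {
  tibble::tibble(
    mean_da = x$mean, ci_lower = x$ci[1], ci_upper = x$ci[2],
    threshold = x$threshold, n_permutations = x$n_permutations,
    scheme = x$scheme, classifier = x$classifier
  )
}

# One-vs-rest linear SVM on a per-fold Gram factor G (G G' equals the
# training feature Gram matrix), predicting test labels through the cached
# train/test kernel blocks. Solves the identical dual problem as training
# on the raw features.
ovr_gram_predict <- function(G, K, Kte, labels, C, classes, tolerance) {
  dec_te <- matrix(0, nrow(Kte), length(classes))
  for (k in seq_along(classes)) {
    y <- factor(ifelse(labels == classes[k], "pos", "neg"),
                levels = c("pos", "neg"))
    if (length(unique(y)) < 2) {
      dec_te[, k] <- if (y[1] == "pos") Inf else -Inf
      next
    }
    fit <- e1071::svm(G, y, type = "C-classification", kernel = "linear",
                      cost = C, scale = FALSE, tolerance = tolerance)
    beta <- fit$coefs[, 1]
    idx <- fit$index
    dtr <- K[, idx, drop = FALSE] %*% beta - fit$rho
    s <- if (mean(dtr[y == "pos"]) < mean(dtr[y == "neg"])) -1 else 1
    dec_te[, k] <- s * (Kte[, idx, drop = FALSE] %*% beta - fit$rho)
  }
  classes[max.col(dec_te, ties.method = "first")]
}

#' Paired comparison of per-subject decoding accuracies
#'
#' Two-sided Wilcoxon signed-rank test on paired per-subject DAs from two
#' conditions, Bonferroni-adjusted for the caller's family of comparisons.
#' The exact null distribution is used for n <= 25 when the differences
#' have no ties or zeros; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param da_a,da_b Equal-length (>= 5) numeric vectors of per-subject DAs,
#'   paired by subject.
#' @param n_comparisons Bonferroni family size.
#' @return One-row tibble with `statistic`, `p_value`, `p_adjusted`,
#'   `n_comparisons` and `method`.
#' @export
compare_conditions <- function(da_a, da_b, n_comparisons = 1) {
  stopifnot(length(da_a) == length(da_b), length(da_a) >= 5,
            n_comparisons >= 1)
  d <- da_a - da_b
  if (all(d == 0)) {
    warn("all paired differences are zero; p = 1")
    return(tibble::tibble(statistic = NA_real_, p_value = 1, p_adjusted = 1,
                          n_comparisons = n_comparisons,
                          method = "Wilcoxon signed rank (degenerate)"))
  }
  dz <- d[d != 0]
  exact_ok <- length(d) <= 25 && !any(d == 0) && !any(duplicated(abs(dz)))
  wt <- suppressWarnings(
    wilcox.test(da_a, da_b, paired = TRUE, exact = exact_ok, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    p_adjusted = min(1, wt$p.value * n_comparisons),
    n_comparisons = n_comparisons,
    method = wt$method
  )
}

#' Per-class sensitivity table across analyses
#'
#' Assembles the per-class sensitivities of several cross-validation
#' results into one table (rows = the six movement tasks, one column per
#' analysis), optionally formatted as `"98.6 (0.6)"` strings.
#'
#' @param results Named list of `grip_cv` objects; the names become the
#'   column labels.
#' @param digits Rounding for the formatted display.
#' @param format If `TRUE` return display strings, else numeric
#'   `<name>_sensitivity` / `<name>_se` columns.
#' @return A tibble with one row per movement task.
#' @export
sensitivity_table <- function(results, digits = 1, format = TRUE) {
  stopifnot(length(results) >= 1, !is.null(names(results)),
            all(nzchar(names(results))))
  out <- tibble::tibble(task = grip_tasks())
  for (nm in names(results)) {
    s <- results[[nm]]$sensitivity
    s <- s[match(out$task, s$task), ]
    if (format) {
      out[[nm]] <- sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                           s$sensitivity, s$se)
    } else {
      out[[paste0(nm, "_sensitivity")]] <- s$sensitivity
      out[[paste0(nm, "_se")]] <- s$se
    }
  }
  out
}
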