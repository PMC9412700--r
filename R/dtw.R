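#' Multivariate dynamic time warping
#'
#' Aligns two time-by-channel series by the warping path minimizing the
#' cumulative Euclidean distance between c-dimensional samples (dependent /
#' multivariate warping), with the standard step pattern
#' \{(1,0), (0,1), (1,1)\} and fixed endpoints. The path starts at (1, 1),
#' ends at (t_x, t_y), and each step increments one or both indices by one.
#'
#' @param x,y Numeric time-by-channel matrices (vectors are treated as one
#'   channel) with equal channel counts and at least one sample each.
#' @return List with `distance` (nonnegative; symmetric in `x`, `y`) and
#'   `path` (L-by-2 integer matrix of index pairs into `x` and `y`).
#' @export
#' @examples
#' dtw_warp(c(0, 1, 2), c(0, 2))
dtw_warp <- function(x, y) {
  x <- as_series_matrix(x)
  y <- as_series_matrix(y)
  if (ncol(x) != ncol(y)) abort("channel count mismatch between series")
  .dtw_core(x, y)
}

as_series_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    x
  } else {
    matrix(as.double(x), ncol = 1)
  }
}

#' Warp-resample a trial to a template's length
#'
#' Computes the DTW path between `x` and the template and collapses `x` onto
#' the template's time base: all `x` samples the path maps to one template
#' index are averaged per channel, and a template index stretch against a
#' single `x` sample replicates that sample. The output always has exactly
#' the template's number of rows, so a dataset warped to one template lives
#' in a fixed-size feature space. `warp_to_template(t, t)` returns `t`
#' exactly.
#'
#' @param x Time-by-channel matrix to resample.
#' @param template Time-by-channel matrix defining the target length.
#' @return Matrix with `nrow(template)` rows and `ncol(x)` columns.
#' @export
warp_to_template <- function(x, template) {
  x <- as_series_matrix(x)
  template <- as_series_matrix(template)
  if (ncol(x) != ncol(template)) abort("channel count mismatch with template")
  al <- .dtw_core(x, template)
  .warp_average_core(x, al$path, nrow(template))
}

#' Select a representative template trial
#'
#' Scores a reduced set of trial pairings (trial `i` against trial
#' `i + floor(n/2)` for `i = 1, ..., floor(n/2) - 1`) rather than all pairs:
#' pair `i` gets the score `s_i = rho_i * (1 - d_i)`, where `d_i` is the raw
#' DTW distance normalized so the largest pairing distance is 1, and `rho_i`
#' is the Pearson correlation between the two path-expanded (aligned)
#' series flattened across channels. The first trial of the best-scoring
#' pair is the template; ties break to the lowest pairing index. A trial
#' that is an outlier scores low in its pairings and is never selected.
#'
#' If all pairings have zero raw distance (identical trials), all `d_i` are
#' set to 0 and the scores reduce to the correlations.
#'
#' @param values List of at least 4 velocity time-by-channel matrices.
#' @return List with `template_index` (index into `values`), `template`
#'   (its matrix) and `scores`, a tibble with one row per pairing
#'   (`i`, `j`, `rho`, `dist_raw`, `dist`, `score`).
#' @export
select_template <- function(values) {
  n <- length(values)
  if (n < 4) abort("template selection needs at least 4 trials")
  half <- n %/% 2L
  idx_i <- seq_len(half - 1L)
  idx_j <- idx_i + half

  rho <- numeric(length(idx_i))
  dist_raw <- numeric(length(idx_i))
  for (k in seq_along(idx_i)) {
    x <- as_series_matrix(values[[idx_i[k]]])
    y <- as_series_matrix(values[[idx_j[k]]])
    al <- .dtw_core(x, y)
    dist_raw[k] <- al$distance
    xe <- as.vector(x[al$path[, 1], , drop = FALSE])
    ye <- as.vector(y[al$path[, 2], , drop = FALSE])
    if (sd(xe) == 0 || sd(ye) == 0) {
      abort("all-constant trial makes the pairing correlation undefined")
    }
    rho[k] <- cor(xe, ye)
  }
  max_d <- max(dist_raw)
  dist <- if (max_d > 0) dist_raw / max_d else rep(0, length(dist_raw))
  score <- rho * (1 - dist)
  best <- which.max(score)                 # first max: lowest pairing index
  list(
    template_index = idx_i[best],
    template = as_series_matrix(values[[idx_i[best]]]),
    scores = tibble::tibble(i = idx_i, j = idx_j, rho = rho,
                            dist_raw = dist_raw, dist = dist, score = score)
  )
}

#' Align training and test trials to a training-fold template
#'
#' Selects the template from the training trials only (no test-set leakage),
#' then warp-resamples every training and test trial to its length, giving
#' fixed-size feature matrices for the SVM.
#'
#' @param train_values List of >= 4 velocity matrices (training fold).
#' @param test_values List of velocity matrices (may be empty).
#' @return List with `template_index`, `template`, `scores`, and
#'   `train`/`test`: lists of aligned matrices of the template's length.
#' @export
align_dataset <- function(train_values, test_values = list()) {
  sel <- select_template(train_values)
  tpl <- sel$template
  sel$train <- lapply(train_values, warp_to_template, template = tpl)
  sel$test <- lapply(test_values, warp_to_template, template = tpl)
  sel
}

#' Flatten aligned trials into an SVM feature matrix
#'
#' @param aligned List of aligned matrices sharing one shape.
#' @return Numeric matrix, one row per trial, `t_template * n_channels`
#'   columns (column-major flattening).
#' @export
flatten_features <- function(aligned) {
  if (length(aligned) == 0) return(matrix(numeric(0), nrow = 0))
  d <- length(aligned[[1]])
  out <- vapply(aligned, function(m) as.vector(m), numeric(d))
  t(out)
}
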