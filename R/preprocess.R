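#' Preprocessing parameters
#'
#' @param smoothing_window Moving-average width in seconds (default 0.1 s).
#' @param target_rate Output sampling rate in Hz after downsampling
#'   (default 16 Hz; natural hand movements are low-frequency, so this
#'   shrinks the feature space without losing movement content).
#' @param source_rate Acquisition rate in Hz (default 100 Hz).
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(smoothing_window = 0.1, target_rate = 16,
                              source_rate = 100) {
  stopifnot(smoothing_window > 0, target_rate > 0,
            target_rate <= source_rate)
  structure(list(smoothing_window = smoothing_window,
                 target_rate = target_rate, source_rate = source_rate),
            class = "preprocess_params")
}

#' Calibration normalization of raw sensor values
#'
#' Maps each channel affinely so the calibration minimum (flat hand) becomes
#' 0 and the calibration maximum (fist) becomes 1:
#' `y = (x - min) / (max - min)`. Values outside the calibration range pass
#' through the same affine map and may leave `[0, 1]`. This removes the
#' montage- and hand-geometry-dependent scale of the raw device angles.
#'
#' @param values Time-by-channel numeric matrix of raw sensor values.
#' @param cal_min,cal_max Per-channel calibration extrema (length =
#'   channel count); `max > min` required per channel.
#' @return Matrix of the same shape, normalized.
#' @export
#' @examples
#' normalize_calibration(matrix(c(10, 20, 30), ncol = 1), 10, 30)
normalize_calibration <- function(values, cal_min, cal_max) {
  values <- as.matrix(values)
  cal_min <- rep_len(cal_min, ncol(values))
  cal_max <- rep_len(cal_max, ncol(values))
  if (any(cal_max <= cal_min)) {
    abort(paste0("calibration max <= min for channel ",
                 which(cal_max <= cal_min)[1]))
  }
  sweep(sweep(values, 2, cal_min, `-`), 2, cal_max - cal_min, `/`)
}

#' Centered moving-average smoothing
#'
#' Window length is `round(window * sample_rate)` samples, centered; for an
#' even window `w` the span is `[i - w/2, i + w/2 - 1]`. Edges use the mean
#' of the available samples (shrinking window), so output length equals
#' input length.
#'
#' @param values Time-by-channel matrix (at least 2 rows).
#' @param window Window width in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @return Smoothed matrix of identical shape.
#' @export
smooth_trial <- function(values, window = 0.1, sample_rate = 100) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 2) abort("trial shorter than 2 samples")
  w <- round(window * sample_rate)
  if (w < 1) abort("smoothing window shorter than one sample")
  kb <- floor(w / 2)                       # samples before i
  ka <- w - kb - 1L                        # samples after i
  lo <- pmax(seq_len(n) - kb, 1L)
  hi <- pmin(seq_len(n) + ka, n)
  cs <- apply(values, 2, cumsum)
  cs <- rbind(0, cs)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' Temporal derivative (angular velocity)
#'
#' Forward first difference scaled by the sampling rate, giving units of
#' (normalized angle) per second; the output is one sample shorter than the
#' input. Velocity, unlike posture, is largely independent of hand geometry,
#' which is why the decoders consume it.
#'
#' @param values Time-by-channel matrix (at least 2 rows).
#' @param sample_rate Sampling rate in Hz.
#' @return Matrix with `nrow(values) - 1` rows.
#' @export
differentiate_trial <- function(values, sample_rate = 100) {
  values <- as.matrix(values)
  if (nrow(values) < 2) abort("cannot differentiate fewer than 2 samples")
  diff(values) * sample_rate
}

#' Downsample by linear interpolation
#'
#' Resamples each channel onto a uniform grid at `target_rate` spanning the
#' same time interval; the new length is
#' `floor((t - 1) * target_rate / source_rate) + 1`. Anti-alias smoothing is
#' assumed already applied by [smooth_trial()].
#'
#' @param values Time-by-channel matrix.
#' @param target_rate Output rate in Hz, `<= source_rate`.
#' @param source_rate Current rate in Hz.
#' @return Matrix at the new rate.
#' @export
downsample_trial <- function(values, target_rate = 16, source_rate = 100) {
  values <- as.matrix(values)
  if (target_rate > source_rate) abort("target_rate exceeds source rate")
  t_old <- nrow(values)
  t_src <- seq(0, (t_old - 1) / source_rate, by = 1 / source_rate)
  m <- floor((t_old - 1) * target_rate / source_rate) + 1L
  t_new <- (seq_len(m) - 1) / target_rate
  out <- vapply(seq_len(ncol(values)),
                function(j) approx(t_src, values[, j], xout = t_new)$y,
                numeric(m))
  matrix(out, nrow = m, dimnames = list(NULL, colnames(values)))
}

#' Preprocess one raw trial to angular velocity
#'
#' Pipeline: calibration normalization, centered moving-average smoothing,
#' temporal differentiation, then linear-interpolation downsampling.
#' Smoothing precedes differencing to keep derivative noise down, and
#' downsampling comes last to preserve derivative fidelity.
#'
#' @param values Raw time-by-channel matrix.
#' @param cal_min,cal_max Per-channel calibration extrema.
#' @param params A [preprocess_params()].
#' @return Velocity matrix at `params$target_rate`.
#' @export
preprocess_trial <- function(values, cal_min, cal_max,
                             params = preprocess_params()) {
  x <- normalize_calibration(values, cal_min, cal_max)
  x <- smooth_trial(x, params$smoothing_window, params$source_rate)
  x <- differentiate_trial(x, params$source_rate)
  downsample_trial(x, params$target_rate, params$source_rate)
}

#' Preprocess every trial of a dataset
#'
#' Applies [preprocess_trial()] with each subject's own calibration,
#' returning a velocity-stage dataset at `params$target_rate`.
#'
#' @param dataset A raw-stage `glove_dataset`.
#' @param params A [preprocess_params()].
#' @return A velocity-stage `glove_dataset`.
#' @export
preprocess_dataset <- function(dataset, params = preprocess_params()) {
  validate_glove_dataset(dataset)
  tr <- dataset$trials
  if (nrow(tr) > 0 && any(tr$stage != "raw")) {
    abort("preprocess_dataset expects raw-stage trials")
  }
  if (nrow(tr) > 0 && any(tr$sample_rate != params$source_rate)) {
    abort("trial sample_rate does not match params$source_rate")
  }
  cals <- lapply(unique(tr$subject_id), function(s) calibration_for(dataset, s))
  names(cals) <- unique(tr$subject_id)
  tr$values <- purrr::map2(tr$values, tr$subject_id, function(v, s) {
    cal <- cals[[s]]
    preprocess_trial(v, cal$min, cal$max, params)
  })
  tr$stage <- "velocity"
  tr$sample_rate <- params$target_rate
  dataset$trials <- tr
  dataset
}
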