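#' Movement-task labels and glove channel names
#'
#' The six movement classes are fixed: each trial is one sequence of four
#' thumb-opposition grips (fingers D2..D5 against the thumb D1) belonging to
#' one of six tasks. The glove records 15 flexion sensors, three joints
#' (J1..J3) per digit (D1..D5); abduction and inertial channels are not part
#' of the container.
#'
#' @return `grip_tasks()` returns the six task labels in the within-run block
#'   order; `glove_channels()` returns the 15 channel names in fixed
#'   D1J1..D5J3 order.
#' @export
#' @examples
#' grip_tasks()
#' glove_channels()
grip_tasks <- function() {
  c("clothes_peg", "fingertip_touching", "rubiks_cw", "rubiks_ccw",
    "small_rubiks_cw", "small_rubiks_ccw")
}

#' @rdname grip_tasks
#' @export
glove_channels <- function() {
  paste0("D", rep(1:5, each = 3), "J", rep(1:3, times = 5))
}

trial_stages <- function() c("raw", "normalized", "velocity", "aligned")

#' Assemble a glove dataset
#'
#' A `glove_dataset` bundles trial-segmented multichannel angular time series
#' with per-subject metadata and calibration extrema. Trials live in a tibble
#' with one row per trial and the time-by-channel matrix in a list column, so
#' ragged trial lengths are natural and the tibble can be filtered/joined
#' with the usual dplyr verbs.
#'
#' @param trials Tibble with columns `subject_id` (character), `run`, `block`,
#'   `trial` (integers), `task` (one of [grip_tasks()]), `stage` (one of
#'   `"raw"`, `"normalized"`, `"velocity"`, `"aligned"`), `sample_rate` (Hz)
#'   and `values` (list of numeric time-by-channel matrices).
#' @param subjects Tibble with columns `subject_id`, `age` (years),
#'   `age_group` (`"young"` or `"old"`) and `hand_size` (wrist to
#'   middle-finger tip, cm).
#' @param calibration Tibble with columns `subject_id`, `channel`, `min`,
#'   `max`: per-channel sensor extrema from the calibration postures
#'   (flat hand and fist, among others).
#' @return An object of class `glove_dataset`.
#' @export
glove_dataset <- function(trials, subjects, calibration) {
  out <- structure(
    list(
      trials = tibble::as_tibble(trials),
      subjects = tibble::as_tibble(subjects),
      calibration = tibble::as_tibble(calibration)
    ),
    class = "glove_dataset"
  )
  validate_glove_dataset(out)
}

#' Validate a glove dataset
#'
#' Checks the container invariants: every trial resolves to a subject with
#' metadata and calibration, task labels come from the fixed six-class set,
#' all trials share one channel count, every trial has at least two samples,
#' and calibration satisfies `max > min` per channel.
#'
#' @param x A `glove_dataset`.
#' @return `x`, invisibly unchanged, or an error describing the first
#'   violated invariant (naming the offending trial or subject).
#' @export
validate_glove_dataset <- function(x) {
  stopifnot(inherits(x, "glove_dataset"))
  tr <- x$trials
  need <- c("subject_id", "run", "block", "trial", "task", "stage",
            "sample_rate", "values")
  missing_cols <- setdiff(need, names(tr))
  if (length(missing_cols)) {
    abort(paste0("trials tibble lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_task <- which(!tr$task %in% grip_tasks())
  if (length(bad_task)) {
    abort(paste0("unknown task label '", tr$task[bad_task[1]],
                 "' in trial row ", bad_task[1],
                 " (subject ", tr$subject_id[bad_task[1]], ")"))
  }
  bad_stage <- which(!tr$stage %in% trial_stages())
  if (length(bad_stage)) {
    abort(paste0("unknown stage '", tr$stage[bad_stage[1]],
                 "' in trial row ", bad_stage[1]))
  }
  if (nrow(tr) > 0) {
    ncs <- vapply(tr$values, ncol, integer(1))
    if (any(ncs != ncs[1])) {
      i <- which(ncs != ncs[1])[1]
      abort(paste0("trial row ", i, " (subject ", tr$subject_id[i],
                   ") has ", ncs[i], " channels; dataset uses ", ncs[1]))
    }
    nts <- vapply(tr$values, nrow, integer(1))
    if (any(nts < 2)) {
      i <- which(nts < 2)[1]
      abort(paste0("trial row ", i, " has fewer than 2 samples"))
    }
    missing_subj <- setdiff(unique(tr$subject_id), x$subjects$subject_id)
    if (length(missing_subj)) {
      abort(paste0("no subject metadata for subject ", missing_subj[1]))
    }
    missing_cal <- setdiff(unique(tr$subject_id), unique(x$calibration$subject_id))
    if (length(missing_cal)) {
      abort(paste0("no calibration for subject ", missing_cal[1]))
    }
  }
  if (nrow(x$calibration) > 0 && any(x$calibration$max <= x$calibration$min)) {
    i <- which(x$calibration$max <= x$calibration$min)[1]
    abort(paste0("calibration max <= min for subject ",
                 x$calibration$subject_id[i], ", channel ",
                 x$calibration$channel[i]))
  }
  invisible(x)
}

#' @export
print.glove_dataset <- function(x, ...) {
  cat("<glove_dataset>\n")
  cat("  trials:  ", nrow(x$trials), " (",
      length(unique(x$trials$subject_id)), " subjects)\n", sep = "")
  if (nrow(x$trials) > 0) {
    cat("  channels:", ncol(x$trials$values[[1]]), "\n")
    cat("  stages:  ", paste(unique(x$trials$stage), collapse = ", "), "\n")
    cat("  rate:    ", paste(unique(x$trials$sample_rate), collapse = ", "),
        "Hz\n")
  }
  invisible(x)
}

n_channels <- function(dataset) {
  if (nrow(dataset$trials) == 0) return(0L)
  ncol(dataset$trials$values[[1]])
}

#' Extract the calibration of one subject as a min/max matrix
#' @noRd
calibration_for <- function(dataset, subject) {
  cal <- dataset$calibration[dataset$calibration$subject_id == subject, ]
  if (nrow(cal) == 0) abort(paste0("no calibration for subject ", subject))
  cal <- cal[order(match(cal$channel, glove_channels())), ]
  list(min = cal$min, max = cal$max, channel = cal$channel)
}
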