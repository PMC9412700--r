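#' Write a glove dataset to disk
#'
#' Serializes a [glove_dataset()] as a directory of per-trial CSV files
#' (columns = channels with a header row, rows = samples) plus a
#' `metadata.json` sidecar holding the trial index, subject metadata,
#' calibration extrema, the task-label set and the channel ordering. The
#' layout round-trips through [read_dataset()]; numeric values are written
#' with full double precision.
#'
#' @param dataset A `glove_dataset`.
#' @param path Directory to create (must not already contain a dataset unless
#'   `overwrite = TRUE`).
#' @param overwrite Replace an existing container at `path`?
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, overwrite = FALSE) {
  validate_glove_dataset(dataset)
  if (dir.exists(path)) {
    if (!overwrite && file.exists(file.path(path, "metadata.json"))) {
      abort(paste0("dataset already exists at ", path,
                   " (use overwrite = TRUE)"))
    }
  } else {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory ", path))
  }
  trial_dir <- file.path(path, "trials")
  dir.create(trial_dir, showWarnings = FALSE)

  tr <- dataset$trials
  files <- character(nrow(tr))
  chan <- if (nrow(tr) > 0) colnames_or_default(tr$values[[1]]) else glove_channels()
  for (i in seq_len(nrow(tr))) {
    files[i] <- sprintf("trials/trial_%05d.csv", i)
    m <- tr$values[[i]]
    colnames(m) <- chan
    readr::write_csv(tibble::as_tibble(m), file.path(path, files[i]),
                     progress = FALSE)
  }
  meta <- list(
    format = "gripdecode-dataset",
    version = 1L,
    tasks = grip_tasks(),
    channels = chan,
    trials = dplyr::mutate(dplyr::select(tr, -"values"), file = files),
    subjects = dataset$subjects,
    calibration = dataset$calibration
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

colnames_or_default <- function(m) {
  cn <- colnames(m)
  if (is.null(cn)) {
    if (ncol(m) == 15L) glove_channels() else paste0("ch", seq_len(ncol(m)))
  } else cn
}

#' Read a glove dataset from disk
#'
#' Inverse of [write_dataset()]: loads the `metadata.json` sidecar and the
#' per-trial CSV files and re-validates every container invariant (subject
#' resolution, task labels, constant channel count).
#'
#' @param path Directory produced by [write_dataset()].
#' @return A `glove_dataset`.
#' @export
read_dataset <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file)) {
    abort(paste0("no dataset at ", path, ": missing metadata.json"))
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  tr_meta <- tibble::as_tibble(meta$trials)
  n <- nrow(tr_meta)
  values <- vector("list", max(n, 0L))
  if (n > 0) {
    for (i in seq_len(n)) {
      f <- file.path(path, tr_meta$file[i])
      if (!file.exists(f)) abort(paste0("missing trial file ", tr_meta$file[i]))
      df <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
      values[[i]] <- as.matrix(df)
    }
    tr <- dplyr::mutate(
      dplyr::select(tr_meta, -"file"),
      run = as.integer(.data$run),
      block = as.integer(.data$block),
      trial = as.integer(.data$trial),
      values = values
    )
  } else {
    tr <- empty_trials_tibble()
  }
  subjects <- tibble::as_tibble(meta$subjects)
  if (nrow(subjects) > 0) {
    subjects$age <- as.double(subjects$age)
    subjects$hand_size <- as.double(subjects$hand_size)
  }
  calibration <- tibble::as_tibble(meta$calibration)
  if (nrow(calibration) > 0) {
    calibration$min <- as.double(calibration$min)
    calibration$max <- as.double(calibration$max)
  }
  glove_dataset(tr, subjects, calibration)
}

empty_trials_tibble <- function() {
  tibble::tibble(
    subject_id = character(), run = integer(), block = integer(),
    trial = integer(), task = character(), stage = character(),
    sample_rate = numeric(), values = list()
  )
}
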