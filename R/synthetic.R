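#' Configuration for the synthetic data-glove simulator
#'
#' The simulator emulates the structure of a two-age-group glove study:
#' each subject performs `runs` runs of `blocks_per_run` blocks, each block
#' holding `trials_per_block` repetitions of one movement task, with the
#' block-to-task assignment fixed across runs and subjects. One trial is a
#' sequence of four thumb-opposition grips (fingers D2..D5 in order), each a
#' smooth raised-cosine flexion--extension pulse on the channels that the
#' task's grip recruits.
#'
#' Subject idiosyncrasy enters through a hand-size-proportional amplitude, a
#' per-subject tempo factor (slower in the old group), per-trial duration
#' jitter and additive Gaussian sensor noise. Classes differ in which
#' channel groups co-activate and in grip amplitude ratios; the clockwise /
#' counterclockwise variants of the two cube tasks differ only by a small
#' waveform asymmetry, making them deliberately the hardest pairs.
#'
#' @param n_subjects_per_group Subjects per age group (young, old).
#' @param runs Runs per subject.
#' @param blocks_per_run Blocks per run; tasks are assigned to blocks in the
#'   fixed [grip_tasks()] order (cycling if more than six blocks).
#' @param trials_per_block Repetitions of the block's task.
#' @param sample_rate Sampling rate in Hz.
#' @param base_duration Nominal seconds per four-grip trial (2 s per grip).
#' @param duration_jitter Coefficient of variation of trial duration.
#' @param noise_sd Sensor noise standard deviation as a fraction of the
#'   subject's full-flexion amplitude.
#' @param hand_size_range_young,hand_size_range_old Uniform range (cm) of
#'   hand length (wrist to middle-finger tip) per group.
#' @param tempo_slowdown_old Multiplicative trial-duration factor (>= 1) for
#'   the old group.
#' @param amp_jitter_young,amp_jitter_old Per-grip amplitude jitter CV; the
#'   larger old-group value models reduced movement precision.
#' @param equalize_classes If `TRUE` all six tasks share one kinematic
#'   pattern, removing class information (decoders should fall to chance).
#' @param seed Integer seed; all randomness flows from one R Mersenne
#'   Twister generator seeded with it.
#' @return A `synthetic_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(n_subjects_per_group = 1, runs = 1,
#'                         trials_per_block = 2)
#' ds <- generate_dataset(cfg)
#' ds
synthetic_config <- function(n_subjects_per_group = 17,
                             runs = 5,
                             blocks_per_run = 6,
                             trials_per_block = 10,
                             sample_rate = 100,
                             base_duration = 8,
                             duration_jitter = 0.1,
                             noise_sd = 0.02,
                             hand_size_range_young = c(16, 22),
                             hand_size_range_old = c(16, 22),
                             tempo_slowdown_old = 1.2,
                             amp_jitter_young = 0.03,
                             amp_jitter_old = 0.08,
                             equalize_classes = FALSE,
                             seed = 1L) {
  cfg <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    runs = as.integer(runs),
    blocks_per_run = as.integer(blocks_per_run),
    trials_per_block = as.integer(trials_per_block),
    sample_rate = sample_rate,
    base_duration = base_duration,
    duration_jitter = duration_jitter,
    noise_sd = noise_sd,
    hand_size_range_young = hand_size_range_young,
    hand_size_range_old = hand_size_range_old,
    tempo_slowdown_old = tempo_slowdown_old,
    amp_jitter_young = amp_jitter_young,
    amp_jitter_old = amp_jitter_old,
    equalize_classes = isTRUE(equalize_classes),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_subjects_per_group >= 1, cfg$runs >= 1, cfg$blocks_per_run >= 1,
    cfg$trials_per_block >= 1, cfg$sample_rate > 0, cfg$base_duration > 0,
    cfg$duration_jitter >= 0, cfg$noise_sd >= 0, cfg$tempo_slowdown_old >= 1
  )
  structure(cfg, class = "synthetic_config")
}

# Channel recruitment per task: one 4 x 15 weight matrix (grips D2..D5 by
# channels D1J1..D5J3) plus a waveform skew (peak position of the flexion
# pulse within a grip). Joint weighting J1 > J2 > J3 reflects stronger
# proximal flexion. Weights stay <= 0.95 so that jittered trials remain
# inside the full-flexion calibration envelope.
class_kinematics <- function(equalize = FALSE) {
  digit_idx <- function(d) (d - 1L) * 3L + 1:3
  base_weights <- function(thumb, finger, others, joints, profile) {
    w <- matrix(0, nrow = 4, ncol = 15)
    for (g in 1:4) {
      w[g, digit_idx(1L)] <- profile[g] * thumb * joints
      w[g, digit_idx(g + 1L)] <- profile[g] * finger * joints
      for (d in setdiff(2:5, g + 1L)) {
        w[g, digit_idx(d)] <- profile[g] * others * joints
      }
    }
    w
  }
  # weight patterns differ in *direction*, not merely overall scale (which
  # per-subject tempo rescales anyway): thumb/finger balance, co-activation
  # of the non-gripping fingers, proximal vs distal joint emphasis, and the
  # amplitude profile over the four sequenced grips. The cw/ccw variants of
  # each cube share one weight pattern and differ only in the waveform
  # asymmetry, making them the deliberately hardest pairs.
  spec <- list(
    clothes_peg        = list(w = base_weights(0.55, 0.85, 0.05,
                                               c(1.0, 0.8, 0.6),
                                               c(1, 1, 1, 1)), skew = 0.50),
    fingertip_touching = list(w = base_weights(0.30, 0.95, 0.00,
                                               c(0.6, 0.9, 1.0),
                                               c(1, 0.8, 0.9, 0.7)), skew = 0.50),
    rubiks_cw          = list(w = base_weights(0.55, 0.70, 0.30,
                                               c(1.0, 0.7, 0.4),
                                               c(0.8, 1, 1, 0.85)), skew = 0.42),
    rubiks_ccw         = list(w = base_weights(0.55, 0.70, 0.30,
                                               c(1.0, 0.7, 0.4),
                                               c(0.8, 1, 1, 0.85)), skew = 0.58),
    small_rubiks_cw    = list(w = base_weights(0.85, 0.90, 0.10,
                                               c(0.8, 1.0, 0.7),
                                               c(1, 0.9, 0.8, 1)), skew = 0.45),
    small_rubiks_ccw   = list(w = base_weights(0.85, 0.90, 0.10,
                                               c(0.8, 1.0, 0.7),
                                               c(1, 0.9, 0.8, 1)), skew = 0.55)
  )
  if (equalize) {
    for (k in seq_along(spec)) spec[[k]] <- spec[["clothes_peg"]]
    names(spec) <- grip_tasks()
  }
  spec[grip_tasks()]
}

# Raised-cosine flexion-extension pulse on [0, 1] with peak at `skew`.
grip_pulse <- function(u, skew = 0.5) {
  out <- numeric(length(u))
  rising <- u >= 0 & u <= skew
  falling <- u > skew & u <= 1
  out[rising] <- 0.5 * (1 - cos(pi * u[rising] / skew))
  out[falling] <- 0.5 * (1 + cos(pi * (u[falling] - skew) / (1 - skew)))
  out
}

#' Calibration extrema from subject amplitude parameters
#'
#' Builds the per-channel calibration record the glove's posture calibration
#' would produce: the flat-hand posture gives the per-channel minimum (the
#' resting sensor offset) and the fist posture gives the maximum (offset
#' plus the subject's full-flexion amplitude). Noise-free simulated trials
#' lie inside this envelope by construction.
#'
#' @param subject_id Subject identifier.
#' @param offset Per-channel resting offset (device units); scalar recycled.
#' @param amplitude Full-flexion amplitude (device units), `> 0`.
#' @param channels Channel names.
#' @return Tibble with columns `subject_id`, `channel`, `min`, `max`.
#' @export
#' @examples
#' generate_calibration("S01", offset = 0, amplitude = 1)
generate_calibration <- function(subject_id, offset, amplitude,
                                 channels = glove_channels()) {
  stopifnot(all(amplitude > 0))
  tibble::tibble(
    subject_id = subject_id,
    channel = channels,
    min = rep_len(offset, length(channels)),
    max = rep_len(offset, length(channels)) + rep_len(amplitude, length(channels))
  )
}

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a glove dataset
#'
#' Generates a complete [glove_dataset()] under the experiment structure and
#' idiosyncrasy model described in [synthetic_config()]. Deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `glove_dataset` of raw-stage trials with calibration and
#'   subject metadata.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_rng(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  kin <- class_kinematics(cfg$equalize_classes)
  groups <- c(rep("young", cfg$n_subjects_per_group),
              rep("old", cfg$n_subjects_per_group))
  n_subj <- length(groups)
  subject_ids <- sprintf("S%02d", seq_len(n_subj))

  subjects <- tibble::tibble(
    subject_id = subject_ids,
    age_group = groups,
    age = ifelse(groups == "young",
                 round(runif(n_subj, 22, 37)),
                 round(runif(n_subj, 62, 80))),
    hand_size = ifelse(
      groups == "young",
      runif(n_subj, cfg$hand_size_range_young[1], cfg$hand_size_range_young[2]),
      runif(n_subj, cfg$hand_size_range_old[1], cfg$hand_size_range_old[2])
    )
  )
  # amplitude proportional to hand size; offsets are montage-dependent
  subjects$amplitude <- 2.0 * subjects$hand_size
  offsets <- lapply(seq_len(n_subj), function(i) runif(15, 10, 20))
  tempo <- (1 + 0.05 * rnorm(n_subj)) *
    ifelse(groups == "old", cfg$tempo_slowdown_old, 1)
  tempo <- pmax(tempo, 0.5)
  amp_jit <- ifelse(groups == "old", cfg$amp_jitter_old, cfg$amp_jitter_young)

  task_of_block <- grip_tasks()[((seq_len(cfg$blocks_per_run) - 1L) %% 6L) + 1L]

  rows <- vector("list", n_subj * cfg$runs * cfg$blocks_per_run *
                   cfg$trials_per_block)
  k <- 0L
  for (s in seq_len(n_subj)) {
    for (r in seq_len(cfg$runs)) {
      for (b in seq_len(cfg$blocks_per_run)) {
        task <- task_of_block[b]
        for (tr in seq_len(cfg$trials_per_block)) {
          k <- k + 1L
          rows[[k]] <- list(
            subject_id = subject_ids[s], run = r, block = b, trial = tr,
            task = task,
            values = simulate_trial(
              kin[[task]], cfg, amplitude = subjects$amplitude[s],
              offset = offsets[[s]], tempo = tempo[s], amp_jitter = amp_jit[s]
            )
          )
        }
      }
    }
  }

  trials <- tibble::tibble(
    subject_id = vapply(rows, `[[`, character(1), "subject_id"),
    run = vapply(rows, `[[`, integer(1), "run"),
    block = vapply(rows, `[[`, integer(1), "block"),
    trial = vapply(rows, `[[`, integer(1), "trial"),
    task = vapply(rows, `[[`, character(1), "task"),
    stage = "raw",
    sample_rate = cfg$sample_rate,
    values = lapply(rows, `[[`, "values")
  )
  calibration <- dplyr::bind_rows(lapply(seq_len(n_subj), function(i) {
    generate_calibration(subject_ids[i], offsets[[i]], subjects$amplitude[i])
  }))
  glove_dataset(trials,
                dplyr::select(subjects, "subject_id", "age", "age_group",
                              "hand_size"),
                calibration)
}

# One trial: four sequential grips with short inter-grip gaps; amplitude and
# duration jittered per trial; Gaussian sensor noise added on top.
simulate_trial <- function(kin, cfg, amplitude, offset, tempo, amp_jitter) {
  dur <- cfg$base_duration * tempo *
    max(0.5, 1 + cfg$duration_jitter * rnorm(1))
  n_t <- max(round(dur * cfg$sample_rate) + 1L, 8L)
  tt <- seq(0, dur, length.out = n_t)
  gap_frac <- 0.1
  seg <- dur / 4
  grip_dur <- seg * (1 - gap_frac)
  x <- matrix(0, nrow = n_t, ncol = 15)
  for (g in 1:4) {
    u <- (tt - (g - 1) * seg) / grip_dur
    pulse <- grip_pulse(u, kin$skew)
    gain <- pmin(kin$w[g, ] * (1 + amp_jitter * rnorm(15)), 1)
    x <- x + outer(pulse, gain)
  }
  x <- amplitude * x
  if (cfg$noise_sd > 0) {
    x <- x + matrix(rnorm(n_t * 15, sd = cfg$noise_sd * amplitude),
                    nrow = n_t)
  }
  sweep(x, 2, offset, `+`)
}
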