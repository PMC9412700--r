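# Shared fixtures, built once per test run and memoized: generating and
# preprocessing synthetic datasets is the expensive part of most tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 2 subjects x 2 runs x 6 blocks x 3 trials, raw stage
tiny_raw_dataset <- function() {
  fixture("tiny_raw", function() {
    generate_dataset(synthetic_config(
      n_subjects_per_group = 1, runs = 2, trials_per_block = 3, seed = 101
    ))
  })
}

tiny_velocity_dataset <- function() {
  fixture("tiny_vel", function() preprocess_dataset(tiny_raw_dataset()))
}

# 4 subjects x 1 run x 6 blocks x 10 trials: the across-subject benchmark
# design (60 trials per subject)
bench_velocity_dataset <- function() {
  fixture("bench_vel", function() {
    preprocess_dataset(generate_dataset(synthetic_config(
      n_subjects_per_group = 2, runs = 1, trials_per_block = 10, seed = 11
    )))
  })
}

# memoized across acceptance blocks: the chance-level permutation run
bench_permtest <- function() {
  fixture("bench_perm", function() {
    permutation_test(bench_velocity_dataset(), cv_spec("loso", "svm_dtw"),
                     n_permutations = 200, seed = 29)
  })
}

# brute-force DTW oracle: memoized recursion over the three admissible
# steps, Euclidean point distance; independent of the package's DP code
dtw_oracle <- function(x, y) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  n <- nrow(x); m <- nrow(y)
  memo <- array(NA_real_, dim = c(n, m))
  point <- function(i, j) sqrt(sum((x[i, ] - y[j, ])^2))
  rec <- function(i, j) {
    if (i == 0 || j == 0) return(if (i == 0 && j == 0) 0 else Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- point(i, j) + min(rec(i - 1, j - 1), rec(i - 1, j), rec(i, j - 1))
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

random_series <- function(len, ch) matrix(rnorm(len * ch), len, ch)
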