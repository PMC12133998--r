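# Shared fixtures: memoized synthetic corpora, pipeline runs, and
# independent brute-force oracles. Everything is generated in code at test
# time; nothing is read from disk fixtures.

.fixture_env <- new.env(parent = emptyenv())

# The reference session: 10 blocks x 80 trials at 1000 Hz, fixed seed.
default_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    dir <- file.path(tempdir(), "fptrials-default-corpus")
    .fixture_env$corpus <- synthesize_corpus(synthetic_config(), seed = 101, dir = dir)
  }
  .fixture_env$corpus
}

# Default pipeline run over the reference session (memoized).
default_run <- function() {
  if (is.null(.fixture_env$run)) {
    corpus <- default_corpus()
    out <- file.path(corpus$dir, "out")
    cfg <- default_pipeline_config(corpus$dir, out)
    stats <- suppressMessages(run_pipeline(cfg, quiet = TRUE))
    .fixture_env$run <- list(config = cfg, stats = stats, out = out)
  }
  .fixture_env$run
}

# A fresh small corpus for unit tests (not memoized; cheap).
small_corpus <- function(n_blocks = 2L, n_trials = 8L, seed = 5L, ...) {
  synthesize_corpus(
    synthetic_config(n_blocks = n_blocks, n_trials_per_block = n_trials, ...),
    seed = seed, dir = tempfile("fptrials-small-"))
}

# One block of the reference session, read back and filtered as the
# pipeline does (memoized per block) — input for the bin-statistic oracle.
filtered_block <- function(block) {
  key <- paste0("blk", block)
  if (is.null(.fixture_env[[key]])) {
    corpus <- default_corpus()
    rec <- read_raw_recording(corpus$raw_paths[block], corpus$recording_spec)
    .fixture_env[[key]] <- filter_recording(rec, filter_spec(rec$sampling_rate))
  }
  .fixture_env[[key]]
}

# Independent brute-force statistics for one trial, computed directly from
# the filtered continuous block and the ground-truth schedule: no
# segmentation, baseline, or binstats code involved beyond the filter.
brute_force_trial <- function(rec, sched_row, vars = c("Mx", "My"),
                              baseline_ms = c(0, 215),
                              bins = list(pre = c(-150, -1), post = c(0, 149))) {
  fs <- rec$sampling_rate
  fix <- as.integer(round(sched_row$fix_onset_ms * fs / 1000))
  anchor <- as.integer(round(sched_row$resp_onset_ms * fs / 1000))
  out <- list()
  for (v in vars) {
    x <- rec$channels[[v]]
    base_idx <- (fix + baseline_ms[1L]):(fix + baseline_ms[2L]) + 1L
    xb <- x - sum(x[base_idx]) / length(base_idx)
    for (bn in names(bins)) {
      idx <- (anchor + bins[[bn]][1L]):(anchor + bins[[bn]][2L]) + 1L
      slice <- xb[idx]
      m <- sum(slice) / length(slice)
      out[[paste0(v, "_", bn, "_mean")]] <- m
      out[[paste0(v, "_", bn, "_sd")]] <- sqrt(sum((slice - m)^2) / (length(slice) - 1L))
      out[[paste0(v, "_", bn, "_range")]] <- max(slice) - min(slice)
    }
  }
  out
}

# Map the oracle's bin names onto the package's column labels.
oracle_column <- function(name) {
  sub("_post_", "_0_150_", sub("_pre_", "_m150_0_", name))
}

# Relative error guarded against zero denominators.
rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)

# Write a tiny hand-rolled DSV recording file; returns the path.
write_manual_recording <- function(lines, name = "fp_subj001_block001.txt") {
  dir <- tempfile("manual-")
  dir.create(dir)
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}
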