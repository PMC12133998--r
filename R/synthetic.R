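# Seeded synthetic recordings with known ground truth.
#
# The generator emulates the structure of a Simon-task posturography
# session: blocks of level-held trigger schedules (fixation 128 -> stimulus
# {1,2,4,8} -> response {32,64} -> ITI 0) over sway-like moment channels.
# It targets the statistical structure the pipeline must recover (trial
# counts, onsets, condition labels, planted variance effects), not
# biomechanical fidelity.

#' Configure the synthetic-recording generator
#'
#' Defaults mirror the validation-study design: 1000-Hz sampling, 10 blocks
#' of 80 trials, fixation intervals almost always 216 or 217 ms with rare
#' values in 214–250 ms, stimulus codes `{1, 2, 4, 8}` (target x position:
#' 1 = target1/left, 2 = target1/right, 4 = target2/left,
#' 8 = target2/right), response codes 32 (correct) / 64 (incorrect).
#'
#' Each moment channel is a sum of slow sway sinusoids (< 1 Hz, random
#' phase per block), white noise, and optionally 50-Hz line noise. A
#' variance effect can be planted: within a window locked to the response
#' onset, the white-noise sd of one channel is multiplied by
#' `effect_multiplier` for trials whose stimulus code is in
#' `effect_condition_codes` (default: left-position trials). With the
#' default multiplier 1 no effect is planted.
#'
#' @param sampling_rate Hz.
#' @param n_blocks,n_trials_per_block Session size.
#' @param subject Subject number used in file names.
#' @param fix_main_ms,fix_main_prob,fix_tail_range_ms Fixation duration
#'   model: values in `fix_main_ms` each with probability
#'   `fix_main_prob / length(fix_main_ms)`, otherwise uniform on the tail
#'   range.
#' @param start_code,stimulus_codes,response_codes Trigger vocabulary.
#' @param p_correct Probability of the correct-response code.
#' @param rt_meanlog,rt_sdlog,rt_min_ms Log-normal response-time model (ms).
#' @param response_hold_ms How long the response code is held.
#' @param iti_range_ms Uniform inter-trial-interval range (code 0).
#' @param lead_in_ms Pre-trial samples (code 0) at the start of each block.
#' @param channels Channel names to synthesize.
#' @param sway_freqs_hz,sway_amps Sway sinusoid frequencies (Hz) and
#'   amplitudes (N·m).
#' @param noise_sd White-noise standard deviation (N·m).
#' @param line_noise_amp,line_noise_hz Optional mains interference.
#' @param effect_multiplier,effect_channel,effect_window_ms,effect_condition_codes
#'   Planted variance effect (see above); the window is half-open
#'   `[w1, w2)` in ms relative to response onset.
#' @param header_lines,delimiter,n_pins,pin_high_v,pin_low_v On-disk format
#'   of the synthesized raw files.
#' @return An object of class `fp_synthetic_config`.
#' @export
synthetic_config <- function(sampling_rate = 1000,
                             n_blocks = 10L,
                             n_trials_per_block = 80L,
                             subject = 1L,
                             fix_main_ms = c(216L, 217L),
                             fix_main_prob = 0.97,
                             fix_tail_range_ms = c(214L, 250L),
                             start_code = 128L,
                             stimulus_codes = c(1L, 2L, 4L, 8L),
                             response_codes = c(32L, 64L),
                             p_correct = 0.9,
                             rt_meanlog = log(450),
                             rt_sdlog = 0.25,
                             rt_min_ms = 150L,
                             response_hold_ms = 500L,
                             iti_range_ms = c(1000L, 1500L),
                             lead_in_ms = 500L,
                             channels = c("Mx", "My"),
                             sway_freqs_hz = c(0.1, 0.25, 0.4),
                             sway_amps = c(0.8, 0.4, 0.2),
                             noise_sd = 0.3,
                             line_noise_amp = 0,
                             line_noise_hz = 50,
                             effect_multiplier = 1,
                             effect_channel = "Mx",
                             effect_window_ms = c(-150, 0),
                             effect_condition_codes = c(1L, 4L),
                             header_lines = 3L,
                             delimiter = "\t",
                             n_pins = 8L,
                             pin_high_v = 5,
                             pin_low_v = 0) {
  stopifnot(sampling_rate > 0, n_blocks >= 1, n_trials_per_block >= 1,
            length(sway_freqs_hz) == length(sway_amps),
            noise_sd >= 0, effect_multiplier >= 0,
            p_correct >= 0, p_correct <= 1)
  if (max(c(start_code, stimulus_codes, response_codes)) > 2^n_pins - 1L) {
    stop("trigger codes exceed the 2^n_pins - 1 vocabulary", call. = FALSE)
  }
  structure(as.list(environment()), class = "fp_synthetic_config")
}

# Independent, reproducible RNG seed per (seed, block, stream), < 2^31.
.block_seed <- function(seed, block, stream = 0L) {
  ((seed %% 65536L) * 29989L + block * 1013L + stream * 17L) %% 2147483647L
}

#' Generate the ground-truth trial schedule
#'
#' Draws every trial's fixation duration, stimulus code, response time,
#' response code, and inter-trial interval, and lays the trials out as a
#' level-held trigger timeline per block. The schedule is deterministic in
#' `(config, seed)` and uses an independent RNG stream per block, so adding
#' blocks never changes earlier blocks.
#'
#' @param config An [synthetic_config()] object.
#' @param seed Integer seed.
#' @return Data frame of class `fp_schedule`, one row per trial: onsets (ms
#'   from block start) of fixation, stimulus, response, and ITI, durations,
#'   codes, and condition labels (`position`, `target`, `correct`).
#' @export
generate_schedule <- function(config, seed) {
  stopifnot(inherits(config, "fp_synthetic_config"))
  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    set.seed(.block_seed(seed, b, 0L))
    n <- config$n_trials_per_block
    tail_p <- 1 - config$fix_main_prob
    use_tail <- runif(n) < tail_p
    fix <- ifelse(use_tail,
                  sample(seq(config$fix_tail_range_ms[1L], config$fix_tail_range_ms[2L]),
                         n, replace = TRUE),
                  sample(config$fix_main_ms, n, replace = TRUE))
    stim_code <- sample(config$stimulus_codes, n, replace = TRUE)
    rt <- pmax(config$rt_min_ms, round(rlnorm(n, config$rt_meanlog, config$rt_sdlog)))
    correct <- runif(n) < config$p_correct
    resp_code <- ifelse(correct, config$response_codes[1L], config$response_codes[2L])
    iti <- round(runif(n, config$iti_range_ms[1L], config$iti_range_ms[2L]))

    fix_onset <- integer(n); t <- config$lead_in_ms
    stim_onset <- resp_onset <- iti_onset <- integer(n)
    for (i in seq_len(n)) {
      fix_onset[i] <- t
      stim_onset[i] <- fix_onset[i] + fix[i]
      resp_onset[i] <- stim_onset[i] + rt[i]
      iti_onset[i] <- resp_onset[i] + config$response_hold_ms
      t <- iti_onset[i] + iti[i]
    }
    data.frame(subject = config$subject, block = b, trial = seq_len(n),
               fix_onset_ms = as.integer(fix_onset), fix_dur_ms = as.integer(fix),
               stim_onset_ms = as.integer(stim_onset), rt_ms = as.integer(rt),
               resp_onset_ms = as.integer(resp_onset),
               resp_hold_ms = as.integer(config$response_hold_ms),
               iti_onset_ms = as.integer(iti_onset), iti_dur_ms = as.integer(iti),
               stim_code = as.integer(stim_code),
               resp_code = as.integer(resp_code),
               position = ifelse(stim_code %in% c(1L, 4L), "left", "right"),
               target = ifelse(stim_code %in% c(1L, 2L), "target1", "target2"),
               correct = correct)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("fp_schedule", "data.frame")
  out
}

# ms -> 0-based sample index on the recording grid.
.ms_to_sample <- function(ms, fs) as.integer(round(ms * fs / 1000))

#' Synthesize one block's raw recording (and optionally its DSV file)
#'
#' Builds the per-sample trigger code series from the level-held schedule
#' and the moment channels from the configured channel model, and returns
#' them as an `fp_recording`. With `path`, also writes the recording in the
#' package's raw-file dialect: `header_lines` manufacturer-style junk
#' lines, a column-name row, then tab- (or comma-) separated samples with
#' columns `time`, one per channel, and one voltage column per pin (LSB
#' first) — so reading the file back exercises header skipping and pin
#' decoding.
#'
#' @param schedule An `fp_schedule` restricted to one block (or the full
#'   schedule plus `block`).
#' @param config The [synthetic_config()] that produced the schedule.
#' @param seed The same seed passed to [generate_schedule()].
#' @param block Which block to synthesize.
#' @param path Optional output file path.
#' @return An `fp_recording` (invisibly carries `path` as attribute when
#'   written).
#' @export
synthesize_recording <- function(schedule, config, seed, block = NULL, path = NULL) {
  stopifnot(inherits(config, "fp_synthetic_config"))
  if (!is.null(block)) schedule <- schedule[schedule$block == block, , drop = FALSE]
  b <- unique(schedule$block)
  if (length(b) != 1L) stop("schedule must cover exactly one block; give `block`", call. = FALSE)
  fs <- config$sampling_rate
  end_ms <- schedule$iti_onset_ms[nrow(schedule)] + schedule$iti_dur_ms[nrow(schedule)]
  n <- .ms_to_sample(end_ms, fs)

  codes <- integer(n)  # lead-in and ITIs stay 0
  for (i in seq_len(nrow(schedule))) {
    fx <- .ms_to_sample(schedule$fix_onset_ms[i], fs)
    st <- .ms_to_sample(schedule$stim_onset_ms[i], fs)
    rs <- .ms_to_sample(schedule$resp_onset_ms[i], fs)
    it <- .ms_to_sample(schedule$iti_onset_ms[i], fs)
    codes[(fx + 1L):st] <- config$start_code
    codes[(st + 1L):rs] <- schedule$stim_code[i]
    codes[(rs + 1L):it] <- schedule$resp_code[i]
  }

  tsec <- (seq_len(n) - 1L) / fs
  channels <- list()
  for (ci in seq_along(config$channels)) {
    ch <- config$channels[ci]
    set.seed(.block_seed(seed, b, stream = ci))
    sway <- numeric(n)
    if (length(config$sway_freqs_hz) && any(config$sway_amps != 0)) {
      phases <- runif(length(config$sway_freqs_hz), 0, 2 * pi)
      for (k in seq_along(config$sway_freqs_hz)) {
        sway <- sway + config$sway_amps[k] *
          sin(2 * pi * config$sway_freqs_hz[k] * tsec + phases[k])
      }
    }
    noise <- rnorm(n, 0, config$noise_sd)
    if (config$effect_multiplier != 1 && identical(ch, config$effect_channel)) {
      hit <- schedule$stim_code %in% config$effect_condition_codes
      for (i in which(hit)) {
        rs <- .ms_to_sample(schedule$resp_onset_ms[i], fs)
        lo <- rs + ceiling(config$effect_window_ms[1L] * fs / 1000)
        hi <- rs + ceiling(config$effect_window_ms[2L] * fs / 1000) - 1L
        lo <- max(lo, 0L); hi <- min(hi, n - 1L)
        if (lo <= hi) {
          idx <- (lo + 1L):(hi + 1L)
          noise[idx] <- noise[idx] * config$effect_multiplier
        }
      }
    }
    x <- sway + noise
    if (config$line_noise_amp > 0) {
      phase_l <- runif(1, 0, 2 * pi)
      x <- x + config$line_noise_amp * sin(2 * pi * config$line_noise_hz * tsec + phase_l)
    }
    channels[[ch]] <- x
  }

  rec <- structure(
    list(subject = config$subject, block = as.integer(b),
         sampling_rate = fs, n_samples = n,
         time = tsec * 1000, channels = channels,
         trigger_codes = codes),
    class = "fp_recording")

  if (!is.null(path)) {
    pins <- encode_pin_levels(codes, config$n_pins, config$pin_high_v, config$pin_low_v)
    body <- data.table::as.data.table(c(
      list(time = as.integer(round(rec$time))),
      channels,
      setNames(lapply(seq_len(ncol(pins)), function(j) pins[, j]),
               paste0("pin", seq_len(ncol(pins)) - 1L))))
    hdr <- c("synthetic force-plate export",
             sprintf("subject %d block %d sampling_rate %g Hz", config$subject, b, fs),
             sprintf("%d samples, %d channels", n, length(channels)))
    writeLines(hdr[seq_len(config$header_lines)], path)
    data.table::fwrite(body, path, sep = config$delimiter, append = TRUE,
                       col.names = TRUE)
    attr(rec, "path") <- path
  }
  rec
}

#' Format spec matching the synthesized raw files
#'
#' @param config An [synthetic_config()] object.
#' @return A [recording_format_spec()] that reads files written by
#'   [synthesize_recording()].
#' @export
corpus_recording_spec <- function(config) {
  recording_format_spec(
    channel_columns = setNames(config$channels, config$channels),
    sampling_rate = config$sampling_rate,
    delimiter = config$delimiter,
    header_lines = config$header_lines,
    time_column = "time",
    pin_columns = paste0("pin", seq_len(config$n_pins) - 1L),
    pin_high_threshold = (config$pin_high_v + config$pin_low_v) / 2)
}

#' Generate a full synthetic corpus on disk
#'
#' Writes, per block, one raw force-plate file
#' (`fp_subj<NNN>_block<NNN>.txt`) and one behavioral table
#' (`exp_subj<NNN>_block<NNN>.csv` with `trial`, `position`, `target`,
#' `correct`, `rt_ms`), plus the complete ground-truth schedule
#' (`truth_subj<NNN>_schedule.csv`). Identical `(config, seed)` yield
#' byte-identical files. Ground truth is always emitted beside the raw
#' data so downstream checks never have to re-derive it from the signal.
#'
#' @param config An [synthetic_config()] object.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return An object of class `fp_corpus`: list with `raw_paths`,
#'   `exp_paths`, `truth_path`, `schedule`, `recording_spec`, `config`,
#'   `seed`, `dir`.
#' @export
synthesize_corpus <- function(config, seed, dir) {
  stopifnot(inherits(config, "fp_synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- generate_schedule(config, seed)
  raw_paths <- character(config$n_blocks)
  exp_paths <- character(config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    raw_paths[b] <- file.path(dir, sprintf("fp_subj%03d_block%03d.txt", config$subject, b))
    synthesize_recording(schedule, config, seed, block = b, path = raw_paths[b])
    sb <- schedule[schedule$block == b, , drop = FALSE]
    exp_paths[b] <- file.path(dir, sprintf("exp_subj%03d_block%03d.csv", config$subject, b))
    data.table::fwrite(sb[, c("trial", "position", "target", "correct", "rt_ms")],
                       exp_paths[b], sep = ",")
  }
  truth_path <- file.path(dir, sprintf("truth_subj%03d_schedule.csv", config$subject))
  data.table::fwrite(as.data.frame(schedule), truth_path, sep = ",")
  structure(list(raw_paths = raw_paths, exp_paths = exp_paths,
                 truth_path = truth_path, schedule = schedule,
                 recording_spec = corpus_recording_spec(config),
                 config = config, seed = seed, dir = dir),
            class = "fp_corpus")
}

#' @export
print.fp_corpus <- function(x, ...) {
  cat("<fp_corpus> subject", x$config$subject, "-", x$config$n_blocks,
      "block(s) x", x$config$n_trials_per_block, "trial(s), seed", x$seed, "\n")
  cat("  dir:", x$dir, "\n")
  invisible(x)
}
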