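# Epoching on the start trigger, baseline correction, derived variables.

seg_spec <- segmentation_spec(n_trials = 8L)

# One small block, segmented (no filtering: segmentation is orthogonal).
segment_small <- function(corpus, block = 1L, spec = seg_spec) {
  rec <- synthesize_recording(corpus$schedule, corpus$config, corpus$seed, block = block)
  ev <- extract_events(rec$trigger_codes, rec$sampling_rate)
  list(rec = rec, events = ev, segs = segment_recording(rec, ev, spec))
}

test_that("trial boundaries equal the planted fixation onsets and tile the recording", {
  corpus <- small_corpus()
  sched <- corpus$schedule[corpus$schedule$block == 1L, ]
  x <- segment_small(corpus)
  segs <- x$segs

  expect_length(segs, nrow(sched))
  starts <- vapply(segs, `[[`, integer(1), "start_sample")
  expect_identical(starts, sched$fix_onset_ms)
  expect_identical(vapply(segs, `[[`, integer(1), "trial"), seq_len(nrow(sched)))

  # partition: segments cover [first onset, end] without overlap;
  # the lead-in before the first start trigger belongs to no trial
  lens <- vapply(segs, `[[`, integer(1), "n_samples")
  expect_identical(sum(lens), x$rec$n_samples - sched$fix_onset_ms[1L])
  expect_identical(starts[-1L], starts[-length(starts)] + lens[-length(lens)])
  expect_gt(starts[1L], 0L)

  # within-trial events: onsets relative to trial start, inside the trial
  for (s in segs) {
    expect_true(all(s$events$onset >= 0L & s$events$onset < s$n_samples))
    expect_identical(s$events$code[1L], 128L)
    expect_identical(s$events$onset[1L], 0L)
  }
})

test_that("condition labels resolve from the planted codes; unknown codes get 'unknown'", {
  corpus <- small_corpus()
  sched <- corpus$schedule[corpus$schedule$block == 1L, ]
  segs <- segment_small(corpus)$segs
  map <- c(`1` = "target1_left", `2` = "target1_right",
           `4` = "target2_left", `8` = "target2_right")
  expect_identical(vapply(segs, function(s) s$conditions[["stimulus"]], character(1)),
                   unname(map[as.character(sched$stim_code)]))
  expect_identical(vapply(segs, function(s) s$conditions[["correctness"]], character(1)),
                   ifelse(sched$correct, "correct", "incorrect"))

  # a condition map over codes never sent resolves to "unknown", not dropped
  spec_u <- segmentation_spec(n_trials = 8L,
                              condition_maps = list(phantom = c(`200` = "x")))
  segs_u <- segment_small(corpus, spec = spec_u)$segs
  expect_true(all(vapply(segs_u, function(s) s$conditions[["phantom"]],
                         character(1)) == "unknown"))
})

test_that("a trial without a response event is flagged incomplete; others unaffected", {
  corpus <- small_corpus(n_blocks = 1L)
  rec <- synthesize_recording(corpus$schedule, corpus$config, corpus$seed, block = 1L)
  sched <- corpus$schedule
  # erase trial 3's response event by overwriting its samples with the stimulus code
  rs <- sched$resp_onset_ms[3L]; it <- sched$iti_onset_ms[3L]
  rec$trigger_codes[(rs + 1L):it] <- sched$stim_code[3L]
  ev <- extract_events(rec$trigger_codes, rec$sampling_rate)
  segs <- segment_recording(rec, ev, seg_spec)
  complete <- vapply(segs, `[[`, logical(1), "complete")
  expect_false(complete[3L])
  expect_true(all(complete[-3L]))
})

test_that("segmentation refuses recordings without start triggers and warns on count mismatch", {
  corpus <- small_corpus(n_blocks = 1L)
  rec <- synthesize_recording(corpus$schedule, corpus$config, corpus$seed, block = 1L)
  ev <- extract_events(rec$trigger_codes, rec$sampling_rate)
  expect_error(segment_recording(rec, ev, segmentation_spec(start_trigger = 200L)),
               "no start-trigger")
  expect_warning(segment_recording(rec, ev, segmentation_spec(n_trials = 99L)),
                 "expected 99")
})

test_that("baseline correction zeroes the 216-sample fixation mean and is idempotent", {
  corpus <- small_corpus()
  segs <- segment_small(corpus)$segs
  bc <- baseline_correct(segs, seg_spec)
  for (s in bc) {
    expect_true(s$baseline_applied)
    # onset of code 128 is trial start; closed interval [0, 215] ms = 216 samples
    idx <- 1:216
    scale <- max(abs(s$channels$Mx), 1)
    expect_lt(abs(mean(s$channels$Mx[idx])) / scale, 1e-9)
    expect_lt(abs(mean(s$channels$My[idx])) / max(abs(s$channels$My), 1), 1e-9)
  }
  twice <- baseline_correct(bc, seg_spec)
  expect_lt(max(abs(twice[[1]]$channels$Mx - bc[[1]]$channels$Mx)), 1e-12)

  # a constant channel becomes identically zero
  cs <- segs
  for (i in seq_along(cs)) cs[[i]]$channels$Mx <- rep(2.5, cs[[i]]$n_samples)
  cbc <- baseline_correct(cs, seg_spec, vars = "Mx")
  expect_lt(max(abs(cbc[[1]]$channels$Mx)), 1e-12)
})

test_that("missing baseline trigger leaves the trial uncorrected with a warning", {
  corpus <- small_corpus()
  segs <- segment_small(corpus)$segs
  spec_b <- segmentation_spec(n_trials = 8L, baseline_trigger = 200L)
  expect_warning(bc <- baseline_correct(segs, spec_b), "without a baseline-trigger")
  expect_false(bc[[1]]$baseline_applied)
  expect_equal(bc[[1]]$channels$Mx, segs[[1]]$channels$Mx)
})

test_that("a baseline interval exceeding the trial is truncated with a warning", {
  corpus <- small_corpus()
  segs <- segment_small(corpus)$segs
  long <- segmentation_spec(n_trials = 8L,
                            baseline_interval_ms = c(0, 10 * 60 * 1000))
  expect_warning(bc <- baseline_correct(segs, long, vars = "Mx"), "truncated")
  s <- bc[[1]]
  expect_lt(abs(mean(s$channels$Mx)) / max(abs(s$channels$Mx), 1), 1e-9)
})

test_that("derived variables are appended pointwise without touching existing channels", {
  corpus <- small_corpus()
  segs <- segment_small(corpus)$segs

  d1 <- add_derived_variable(segs, "Mx_copy", function(ch) ch$Mx)
  expect_equal(d1[[1]]$channels$Mx_copy, segs[[1]]$channels$Mx)

  d2 <- add_derived_variable(segs, "Mdiff", function(ch) ch$Mx - ch$My)
  expect_equal(d2[[3]]$channels$Mdiff,
               segs[[3]]$channels$Mx - segs[[3]]$channels$My)
  expect_equal(d2[[3]]$channels$Mx, segs[[3]]$channels$Mx)

  # normalization against a constant channel scales pointwise
  withFz <- segs
  for (i in seq_along(withFz)) withFz[[i]]$channels$Fz <- rep(4, withFz[[i]]$n_samples)
  class(withFz) <- "fp_segments"
  d3 <- add_derived_variable(withFz, "MxN", function(ch) ch$Mx / ch$Fz)
  expect_equal(d3[[2]]$channels$MxN, segs[[2]]$channels$Mx / 4)

  expect_error(add_derived_variable(segs, "Mx", function(ch) ch$Mx), "already exists")
})
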