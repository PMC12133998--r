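# Bin resolution, lock location, and per-trial bin statistics.

test_that("bins resolve to contiguous half-open intervals of the given width", {
  b <- resolve_bins(bin_spec(boundaries = c(-150, 150), bin_width_ms = 150))
  expect_identical(nrow(b), 2L)
  expect_equal(b$start_ms, c(-150, 0))
  expect_equal(b$end_ms, c(0, 150))
  expect_identical(b$label, c("m150_0", "0_150"))

  b3 <- resolve_bins(bin_spec(boundaries = c(0, 450), bin_width_ms = 150))
  expect_equal(b3$start_ms, c(0, 150, 300))
  expect_equal(b3$end_ms, c(150, 300, 450))

  expect_error(resolve_bins(bin_spec(boundaries = c(-150, 150), bin_width_ms = 200)),
               "not divisible")
  expect_error(bin_spec(boundaries = c(150, -150)), "increasing")
})

make_segments <- function(corpus, block = 1L) {
  rec <- synthesize_recording(corpus$schedule, corpus$config, corpus$seed, block = block)
  ev <- extract_events(rec$trigger_codes, rec$sampling_rate)
  segment_recording(rec, ev, segmentation_spec(n_trials = corpus$config$n_trials_per_block))
}

test_that("the lock anchor is the first (or last) matching event onset", {
  corpus <- small_corpus()
  sched <- corpus$schedule[corpus$schedule$block == 1L, ]
  segs <- make_segments(corpus)
  for (i in seq_along(segs)) {
    a <- locate_lock(segs[[i]], c(32L, 64L))
    expect_identical(a, sched$resp_onset_ms[i] - sched$fix_onset_ms[i])
  }
  # a single-code lock matches only trials carrying that code
  seg1 <- segs[[1L]]
  other <- setdiff(c(32L, 64L), sched$resp_code[1L])
  expect_identical(locate_lock(seg1, sched$resp_code[1L]),
                   sched$resp_onset_ms[1L] - sched$fix_onset_ms[1L])
  expect_true(is.na(locate_lock(seg1, other)))
  expect_identical(locate_lock(seg1, c(32L, 64L), "last"),
                   locate_lock(seg1, c(32L, 64L), "first"))
})

test_that("a constant channel gives mean = c, sd = 0, range = 0 in every bin", {
  corpus <- small_corpus()
  segs <- make_segments(corpus)
  for (i in seq_along(segs)) segs[[i]]$channels$Mx <- rep(4.2, segs[[i]]$n_samples)
  st <- compute_bin_stats(segs, bin_spec(vars = "Mx"))
  expect_true(all(abs(st$Mx_m150_0_mean - 4.2) < 1e-12))
  expect_true(all(st$Mx_m150_0_sd == 0))
  expect_true(all(st$Mx_0_150_range == 0))
})

test_that("a ramp channel recovers the exact brute-force slice mean", {
  corpus <- small_corpus()
  sched <- corpus$schedule[corpus$schedule$block == 1L, ]
  segs <- make_segments(corpus)
  # channel = 0-based sample index within the trial
  for (i in seq_along(segs)) segs[[i]]$channels$Mx <- as.numeric(seq_len(segs[[i]]$n_samples) - 1L)
  st <- compute_bin_stats(segs, bin_spec(vars = "Mx"))
  anchor <- sched$resp_onset_ms - sched$fix_onset_ms
  # bin [0, 150): samples anchor .. anchor+149; mean of 150 consecutive integers
  expect_equal(st$Mx_0_150_mean, anchor + mean(0:149))
  expect_equal(st$Mx_m150_0_mean, anchor + mean(-150:-1))
  # sd of consecutive integers is slice-independent
  expect_equal(st$Mx_0_150_sd, rep(sd(0:149), nrow(st)))
  expect_equal(st$Mx_0_150_range, rep(149, nrow(st)))
})

test_that("adjacent bins partition the locked window; each 150-ms bin holds 150 samples", {
  corpus <- small_corpus()
  segs <- make_segments(corpus)
  # count samples per bin by making the channel an indicator through statistics
  count_stat <- list(n = function(x) length(x))
  st <- compute_bin_stats(segs, bin_spec(vars = "Mx", statistics = count_stat))
  expect_true(all(st$Mx_m150_0_n == 150))
  expect_true(all(st$Mx_0_150_n == 150))
  # partition: union is [-150, 150) = 300 samples, no sample in both bins
  wide <- compute_bin_stats(segs, bin_spec(boundaries = c(-150, 150),
                                           bin_width_ms = 300, vars = "Mx",
                                           statistics = count_stat))
  expect_true(all(wide$Mx_m150_150_n == 300))
})

test_that("pipeline statistics equal an independent brute-force computation", {
  corpus <- small_corpus(n_blocks = 1L, n_trials = 10L)
  sched <- corpus$schedule
  rec <- synthesize_recording(sched, corpus$config, corpus$seed, block = 1L)
  ev <- extract_events(rec$trigger_codes, rec$sampling_rate)
  spec <- segmentation_spec(n_trials = 10L)
  segs <- baseline_correct(segment_recording(rec, ev, spec), spec)
  st <- compute_bin_stats(segs, bin_spec())
  for (i in seq_len(nrow(sched))) {
    oracle <- brute_force_trial(rec, sched[i, ])
    for (nm in names(oracle)) {
      expect_lt(rel_err(st[[oracle_column(nm)]][i], oracle[[nm]]), 1e-12)
    }
  }
})

test_that("sd uses the n-1 denominator and range is a nonnegative scalar", {
  corpus <- small_corpus()
  segs <- make_segments(corpus)
  st <- compute_bin_stats(segs, bin_spec())
  s <- segs[[1L]]
  anchor <- locate_lock(s, c(32L, 64L))
  slice <- s$channels$Mx[(anchor - 150 + 1):(anchor)]
  m <- mean(slice)
  expect_equal(st$Mx_m150_0_sd[1L], sqrt(sum((slice - m)^2) / 149))
  expect_true(all(st$Mx_m150_0_range >= 0))
  expect_true(all(st$My_0_150_range >= 0))
})

test_that("adding a statistic extends the table without perturbing existing columns", {
  corpus <- small_corpus()
  segs <- make_segments(corpus)
  st3 <- compute_bin_stats(segs, bin_spec())
  plus <- c(default_statistics(), list(rms = function(x) sqrt(mean(x^2))))
  st4 <- compute_bin_stats(segs, bin_spec(statistics = plus))
  for (cl in stat_column_names(st3)) expect_equal(st4[[cl]], st3[[cl]])
  expect_true("Mx_m150_0_rms" %in% names(st4))
  expect_identical(length(stat_column_names(st4)), 16L)
})

test_that("trials without a lock event yield missing statistics, never zeros", {
  corpus <- small_corpus(n_blocks = 1L)
  rec <- synthesize_recording(corpus$schedule, corpus$config, corpus$seed, block = 1L)
  sched <- corpus$schedule
  rs <- sched$resp_onset_ms[2L]; it <- sched$iti_onset_ms[2L]
  rec$trigger_codes[(rs + 1L):it] <- sched$stim_code[2L]  # no response in trial 2
  ev <- extract_events(rec$trigger_codes, rec$sampling_rate)
  segs <- segment_recording(rec, ev, segmentation_spec(n_trials = 8L))
  expect_warning(st <- compute_bin_stats(segs, bin_spec()), "without a lock event")
  expect_true(st$lock_missing[2L])
  expect_true(all(is.na(unlist(st[2L, stat_column_names(st)]))))
  expect_false(any(is.na(unlist(st[1L, stat_column_names(st)]))))
})
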