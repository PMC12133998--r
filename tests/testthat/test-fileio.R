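# File naming contract, raw-recording reading, and stats serialization.

test_that("file names yield subject and block; missing subject tag is refused", {
  id <- parse_data_filename("exp1_fp_subj001_block001.txt")
  expect_identical(id$subject, 1L)
  expect_identical(id$block, 1L)

  id <- parse_data_filename("exp1_subj001.csv")
  expect_identical(id$subject, 1L)
  expect_true(is.na(id$block))

  expect_identical(parse_data_filename("/some/dir/study_subj042_block007_v2.tsv"),
                   list(subject = 42L, block = 7L))

  expect_error(parse_data_filename("exp1_block001.txt"), "subj")

  corpus <- small_corpus()
  for (p in c(corpus$raw_paths, corpus$exp_paths)) {
    id <- parse_data_filename(p)
    expect_identical(id$subject, corpus$config$subject)
  }
})

test_that("a hand-written recording reads back verbatim, with or without header lines", {
  body <- c("0\t0.5\t-0.2\t128",
            "1\t0.6\t-0.1\t128",
            "2\t0.7\t0.0\t1")
  spec <- recording_format_spec(
    channel_columns = c(Mx = 2L, My = 3L), sampling_rate = 1000,
    delimiter = "\t", header_lines = 0L, time_column = 1L, trigger_column = 4L)
  rec <- read_raw_recording(write_manual_recording(body), spec)
  expect_identical(rec$n_samples, 3L)
  expect_identical(rec$subject, 1L)
  expect_identical(rec$block, 1L)
  expect_equal(rec$channels$Mx, c(0.5, 0.6, 0.7))
  expect_equal(rec$channels$My, c(-0.2, -0.1, 0.0))
  expect_identical(rec$trigger_codes, c(128L, 128L, 1L))
  expect_equal(rec$time, c(0, 1, 2))

  spec2 <- recording_format_spec(
    channel_columns = c(Mx = 2L, My = 3L), sampling_rate = 1000,
    delimiter = "\t", header_lines = 2L, time_column = 1L, trigger_column = 4L)
  rec2 <- read_raw_recording(
    write_manual_recording(c("junk header", "more junk", body)), spec2)
  expect_equal(rec2[c("channels", "trigger_codes", "time")],
               rec[c("channels", "trigger_codes", "time")])
})

test_that("reading is invariant to the delimiter given the matching spec", {
  vals <- list(time = 0:4, Mx = c(0.1, -0.2, 0.3, -0.4, 0.5),
               My = c(1, 2, 3, 4, 5), trig = c(0, 128, 128, 4, 4))
  recs <- lapply(c("\t", ",", ";"), function(d) {
    lines <- do.call(paste, c(vals, sep = d))
    spec <- recording_format_spec(
      channel_columns = c(Mx = 2L, My = 3L), sampling_rate = 1000,
      delimiter = d, time_column = 1L, trigger_column = 4L)
    read_raw_recording(write_manual_recording(lines), spec)
  })
  expect_equal(recs[[1]]$channels, recs[[2]]$channels)
  expect_equal(recs[[1]]$channels, recs[[3]]$channels)
  expect_identical(recs[[1]]$trigger_codes, recs[[2]]$trigger_codes)
  expect_identical(recs[[1]]$trigger_codes, recs[[3]]$trigger_codes)
})

test_that("pin columns are decoded on read; all-128 file decodes to all-128 codes", {
  # code 128 = only pin 7 high; independent oracle: per-row sum of 2^p
  volts <- matrix(0, nrow = 4, ncol = 8)
  volts[, 8] <- 5
  oracle <- as.integer(volts[1, ] %*% 2^(0:7) / 5)  # 128
  lines <- apply(cbind(0:3, 0.1, volts), 1, paste, collapse = "\t")
  spec <- recording_format_spec(
    channel_columns = c(Mx = 2L), sampling_rate = 1000,
    time_column = 1L, pin_columns = 3:10, pin_high_threshold = 2.5)
  rec <- read_raw_recording(write_manual_recording(lines), spec)
  expect_identical(rec$trigger_codes, rep(oracle, 4L))
  expect_identical(rec$trigger_codes, rep(128L, 4L))
})

test_that("malformed raw files are rejected with informative errors", {
  spec <- recording_format_spec(
    channel_columns = c(Mx = 2L), sampling_rate = 1000,
    time_column = 1L, trigger_column = 3L)
  expect_error(
    read_raw_recording(write_manual_recording(c("0\t1\t0", "1\t2", "2\t3\t0")), spec),
    "line 2")
  expect_error(
    read_raw_recording(write_manual_recording(c("0\tok\t0", "1\t2\t0")), spec),
    "non-numeric")
  expect_error(
    read_raw_recording(write_manual_recording(character(0)), spec),
    "no data rows")
})

test_that("format spec validation rejects contradictory layouts", {
  expect_error(recording_format_spec(channel_columns = c(Mx = 2L),
                                     sampling_rate = 0, trigger_column = 3L),
               "sampling_rate")
  expect_error(recording_format_spec(channel_columns = c(Mx = 2L),
                                     sampling_rate = 1000),
               "exactly one")
  expect_error(recording_format_spec(channel_columns = c(Mx = 2L),
                                     sampling_rate = 1000,
                                     trigger_column = 2L),
               "disjoint")
})

test_that("trial-stats tables round-trip losslessly, including missing cells", {
  path <- tempfile(fileext = ".csv")

  empty <- data.frame(subject = integer(), block = integer(), trial = integer(),
                      Mx_m150_0_mean = numeric())
  write_trial_stats(empty, path)
  back <- read_trial_stats(path)
  expect_identical(nrow(back), 0L)
  expect_identical(names(back), names(empty))

  set.seed(3)
  tab <- data.frame(subject = 1L, block = 1L, trial = 1:2,
                    stimulus = c("target1_left", "unknown"),
                    Mx_m150_0_mean = rnorm(2) * 1e-4,
                    Mx_m150_0_sd = exp(rnorm(2)))
  tab$Mx_m150_0_sd[2] <- NA  # incomplete trial
  write_trial_stats(tab, path)
  back <- read_trial_stats(path)
  expect_identical(back$trial, tab$trial)
  expect_identical(back$stimulus, tab$stimulus)
  expect_true(is.na(back$Mx_m150_0_sd[2]))
  expect_lt(max(rel_err(back$Mx_m150_0_mean, tab$Mx_m150_0_mean)), 1e-9)

  dup <- rbind(tab, tab[1, ])
  expect_error(write_trial_stats(dup, path), "duplicate")
})
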