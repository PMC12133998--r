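# Config-driven end-to-end processing: filter -> segment -> baseline ->
# time-locked bin statistics -> optional behavioral merge.

#' Default pipeline configuration
#'
#' Builds a fully resolved pipeline configuration whose defaults equal the
#' validation settings: 4th-order 10-Hz low-pass with a 2000-sample
#' reversed prefix; trials started and baselined on code 128 with interval
#' `[0, 215]` ms; stimulus codes `{1, 2, 4, 8}`, response codes
#' `{32, 64}`; statistics mean/sd/range of `Mx` and `My` over bins
#' `[-150, 0)` and `[0, 150)` ms locked to the response onset. So the
#' documented default run is the reference pipeline.
#'
#' @param input_dir Directory containing raw force-plate files.
#' @param output_dir Directory for the stats table, effective config, and
#'   log.
#' @param input_pattern Glob for raw files within `input_dir`.
#' @param format List of [recording_format_spec()] arguments describing the
#'   raw-file layout.
#' @param exp_dir,exp_pattern Optional behavioral-table inputs; when given,
#'   the behavioral tables are prepared and merged with the trial
#'   statistics.
#' @param ... Overrides for individual config entries, named
#'   `section.key`, e.g. `filter.enabled = FALSE`,
#'   `binstats.bin_width_ms = 100`.
#' @return An object of class `fp_pipeline_config` (a nested named list;
#'   fully serializable with [write_pipeline_config()]).
#' @export
default_pipeline_config <- function(input_dir, output_dir,
                                    input_pattern = "fp_subj*.txt",
                                    format = list(
                                      delimiter = "\t",
                                      header_lines = 3L,
                                      sampling_rate = 1000,
                                      time_column = "time",
                                      channel_columns = list(Mx = "Mx", My = "My"),
                                      pin_columns = as.list(paste0("pin", 0:7)),
                                      pin_high_threshold = 2.5),
                                    exp_dir = NULL,
                                    exp_pattern = "exp_subj*.csv",
                                    ...) {
  cfg <- list(
    input = list(dir = input_dir, pattern = input_pattern, format = format),
    filter = list(enabled = TRUE, order = 4L, cutoff_hz = 10,
                  pad_count = 2000L),
    triggers = list(min_glitch_ms = 0),
    segmentation = list(start_trigger = 128L, n_trials = 80L,
                        stimulus_triggers = c(1L, 2L, 4L, 8L),
                        response_triggers = c(32L, 64L),
                        baseline_enabled = TRUE,
                        baseline_trigger = 128L,
                        baseline_interval_ms = c(0, 215),
                        condition_maps = list(
                          stimulus = list(`1` = "target1_left",
                                          `2` = "target1_right",
                                          `4` = "target2_left",
                                          `8` = "target2_right"),
                          correctness = list(`32` = "correct",
                                             `64` = "incorrect"))),
    binstats = list(lock_triggers = c(32L, 64L),
                    boundaries_ms = c(-150, 150),
                    bin_width_ms = 150,
                    vars = c("Mx", "My"),
                    statistics = c("mean", "sd", "range"),
                    lock_which = "first"),
    tables = list(exp_dir = exp_dir, exp_pattern = exp_pattern),
    output = list(dir = output_dir))
  dots <- list(...)
  for (nm in names(dots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || is.null(cfg[[parts[1L]]])) {
      stop("unknown config override '", nm, "' (use section.key)", call. = FALSE)
    }
    cfg[[parts[1L]]][[parts[2L]]] <- dots[[nm]]
  }
  structure(cfg, class = "fp_pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' Configurations are serialized as YAML. [run_pipeline()] writes the
#' effective (fully resolved) configuration next to its outputs, so a run
#' can be reproduced exactly from the emitted file.
#'
#' @param path YAML file path.
#' @param config An `fp_pipeline_config`.
#' @return `read_pipeline_config()` returns an `fp_pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("input", "filter", "triggers", "segmentation", "binstats",
                "tables", "output")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config file '", path, "' lacks section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "fp_pipeline_config")
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "fp_pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Build the per-module spec objects out of the flat config lists.
.specs_from_config <- function(config) {
  fmt <- config$input$format
  rspec <- recording_format_spec(
    channel_columns = unlist(fmt$channel_columns),
    sampling_rate = fmt$sampling_rate,
    delimiter = fmt$delimiter,
    header_lines = fmt$header_lines %||% 0L,
    time_column = fmt$time_column,
    pin_columns = if (!is.null(fmt$pin_columns)) unlist(fmt$pin_columns),
    trigger_column = fmt$trigger_column,
    pin_high_threshold = fmt$pin_high_threshold %||% 2.5)
  sseg <- config$segmentation
  sspec <- segmentation_spec(
    start_trigger = sseg$start_trigger,
    n_trials = sseg$n_trials,
    stimulus_triggers = sseg$stimulus_triggers,
    response_triggers = sseg$response_triggers,
    condition_maps = lapply(sseg$condition_maps, function(m) unlist(m)),
    baseline_trigger = sseg$baseline_trigger,
    baseline_interval_ms = sseg$baseline_interval_ms)
  bn <- config$binstats
  bspec <- bin_spec(lock_triggers = bn$lock_triggers,
                    boundaries = bn$boundaries_ms,
                    bin_width_ms = bn$bin_width_ms,
                    vars = bn$vars,
                    statistics = .statistic_registry(bn$statistics),
                    lock_which = bn$lock_which %||% "first")
  fspec <- if (isTRUE(config$filter$enabled)) {
    filter_spec(sampling_rate = fmt$sampling_rate,
                order = config$filter$order,
                cutoff_hz = config$filter$cutoff_hz,
                pad_count = config$filter$pad_count)
  }
  list(recording = rspec, segmentation = sspec, binstats = bspec, filter = fspec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full processing pipeline
#'
#' Executes, for every raw file matching the input glob, the fixed stage
#' order: read and decode triggers, low-pass filter (unless disabled),
#' extract events, suppress glitches (off by default), segment into
#' trials, baseline-correct (unless disabled), and compute event-locked
#' bin statistics. The per-block tables are concatenated (with a global
#' trial counter), written to `output.dir/trial_stats.csv`, and — when
#' behavioral inputs are configured — merged with the prepared behavioral
#' tables into `merged.csv`. The effective configuration
#' (`effective_config.yaml`) and a per-file log (`pipeline_log.txt`) are
#' written next to the outputs; the run is deterministic for fixed inputs.
#'
#' @param config An `fp_pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return The trial-statistics table (class `fp_trial_stats`),
#'   invisibly; when behavioral data were merged, the merged table is
#'   attached as attribute `"merged"`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "fp_pipeline_config"))
  specs <- .specs_from_config(config)
  files <- sort(Sys.glob(file.path(config$input$dir, config$input$pattern)))
  if (length(files) == 0L) {
    stop("no input files match '", config$input$pattern, "' in ",
         config$input$dir, call. = FALSE)
  }
  dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
  log <- c(paste("stage order: read -> filter -> events -> segment ->",
                 "baseline -> binstats -> combine"),
           paste("filter:", if (is.null(specs$filter)) "disabled" else
             sprintf("order %d, cutoff %g Hz, pad %d", specs$filter$order,
                     specs$filter$cutoff_hz, specs$filter$pad_count)),
           paste("baseline:", if (isTRUE(config$segmentation$baseline_enabled))
             "enabled" else "disabled"))

  all_stats <- vector("list", length(files))
  for (fi in seq_along(files)) {
    f <- files[fi]
    stage <- "read"
    res <- tryCatch({
      rec <- read_raw_recording(f, specs$recording)
      if (!is.null(specs$filter)) {
        stage <- "filter"
        rec <- filter_recording(rec, specs$filter)
      }
      stage <- "events"
      events <- extract_events(rec$trigger_codes, rec$sampling_rate)
      if (config$triggers$min_glitch_ms > 0) {
        events <- suppress_glitches(events, config$triggers$min_glitch_ms,
                                    rec$sampling_rate)
      }
      stage <- "segment"
      segs <- segment_recording(rec, events, specs$segmentation)
      if (isTRUE(config$segmentation$baseline_enabled)) {
        stage <- "baseline"
        segs <- baseline_correct(segs, specs$segmentation, specs$binstats$vars)
      }
      stage <- "binstats"
      compute_bin_stats(segs, specs$binstats)
    }, error = function(e) {
      stop("pipeline failed at stage '", stage, "' for file '", basename(f),
           "': ", conditionMessage(e), call. = FALSE)
    })
    n_inc <- sum(!res$complete)
    log <- c(log, sprintf("%s: %d trial(s), %d incomplete, %d without lock event",
                          basename(f), nrow(res), n_inc, sum(res$lock_missing)))
    if (!quiet) message(log[length(log)])
    all_stats[[fi]] <- res
  }
  bins <- attr(all_stats[[1L]], "bins")
  stats <- do.call(rbind, lapply(all_stats, as.data.frame))
  stats$trial_global <- seq_len(nrow(stats))
  stats <- stats[, c(setdiff(names(stats), "trial_global")[1:3], "trial_global",
                     setdiff(names(stats), c("subject", "block", "trial", "trial_global"))),
                 drop = FALSE]
  attr(stats, "bins") <- bins
  class(stats) <- c("fp_trial_stats", "data.frame")

  write_trial_stats(stats, file.path(config$output$dir, "trial_stats.csv"))
  write_pipeline_config(config, file.path(config$output$dir, "effective_config.yaml"))

  merged <- NULL
  if (!is.null(config$tables$exp_dir)) {
    exp_files <- sort(Sys.glob(file.path(config$tables$exp_dir,
                                         config$tables$exp_pattern)))
    if (length(exp_files)) {
      exp <- prep_exp_data(exp_files)
      # positional alignment within (subject, block): verify counts first
      tab_fp <- table(paste(stats$subject, stats$block))
      tab_ex <- table(paste(exp$subject, exp$block))
      if (!identical(sort(names(tab_fp)), sort(names(tab_ex))) ||
          any(tab_fp[names(tab_ex)] != tab_ex)) {
        stop("behavioral and force-plate trial counts differ per (subject, block); ",
             "refusing positional alignment", call. = FALSE)
      }
      merged <- combine_data(exp, stats, suffixes = c(".exp", ".fp"))
      data.table::fwrite(merged, file.path(config$output$dir, "merged.csv"),
                         sep = ",", na = "NA")
      log <- c(log, sprintf("merged %d behavioral file(s): %d rows",
                            length(exp_files), nrow(merged)))
    }
  }
  writeLines(log, file.path(config$output$dir, "pipeline_log.txt"))
  if (!is.null(merged)) attr(stats, "merged") <- merged
  invisible(stats)
}
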