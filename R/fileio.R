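# Reading raw force-plate DSV exports and (de)serializing trial statistics.

#' Parse subject and block numbers from a data file name
#'
#' Force-plate exports usually carry no subject or block information inside
#' the file, so both are encoded in the file name: the literal string
#' `"subj"` followed by the subject number and, for per-block files, the
#' literal string `"block"` followed by the block number
#' (e.g. `exp1_fp_subj001_block001.txt`). Matching is case-sensitive, uses
#' the first occurrence of each tag in the basename, and ignores leading
#' zeros. A file holding all blocks of a subject may omit the block tag.
#'
#' @param filename Path or basename of a data file.
#' @return A list with integer components `subject` and `block`
#'   (`block` is `NA` when the file name carries no block tag).
#' @examples
#' parse_data_filename("exp1_fp_subj001_block001.txt")
#' parse_data_filename("exp1_subj012.csv")
#' @export
parse_data_filename <- function(filename) {
  stopifnot(is.character(filename), length(filename) == 1L)
  base <- basename(filename)
  subj <- regmatches(base, regexpr("subj[0-9]+", base))
  if (length(subj) == 0L) {
    stop("file name '", base, "' does not contain 'subj' followed by a subject number",
         call. = FALSE)
  }
  subject <- as.integer(sub("subj", "", subj, fixed = TRUE))
  blk <- regmatches(base, regexpr("block[0-9]+", base))
  block <- if (length(blk) == 0L) NA_integer_ else as.integer(sub("block", "", blk, fixed = TRUE))
  list(subject = subject, block = block)
}

#' Describe the on-disk layout of a raw force-plate export
#'
#' Manufacturers export plain-text DSV files that differ in delimiter,
#' header length, and column arrangement. A format spec pins all of this
#' down explicitly; nothing is auto-detected. Columns may be referenced by
#' name (a column-name row is then expected directly after the skipped
#' header lines) or by 1-based index (no name row expected).
#'
#' Exactly one of `pin_columns` (raw per-pin voltages, least-significant pin
#' first) or `trigger_column` (an already-decoded integer code column) must
#' be given. Decimal separators must be `"."`; convert locale-specific
#' exports before reading.
#'
#' @param channel_columns Named character or integer vector mapping channel
#'   names (e.g. `c(Mx = "Mx", My = "My")`) to file columns.
#' @param sampling_rate Sampling rate in Hz.
#' @param delimiter Field delimiter: `"\t"`, `","`, or `";"`.
#' @param header_lines Number of leading non-data lines to skip.
#' @param time_column Optional column holding time in ms; when absent, time
#'   is synthesized as `sample_index / sampling_rate * 1000` (0-based).
#' @param pin_columns Ordered columns holding per-pin voltages, least
#'   significant bit first.
#' @param trigger_column Column holding already-decoded integer trigger codes.
#' @param pin_high_threshold Voltage above which a pin counts as high.
#' @return An object of class `fp_recording_spec`.
#' @seealso [read_raw_recording()], [decode_pin_levels()]
#' @export
recording_format_spec <- function(channel_columns,
                                  sampling_rate,
                                  delimiter = "\t",
                                  header_lines = 0L,
                                  time_column = NULL,
                                  pin_columns = NULL,
                                  trigger_column = NULL,
                                  pin_high_threshold = 2.5) {
  if (!delimiter %in% c("\t", ",", ";")) {
    stop("delimiter must be one of tab, comma, or semicolon", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  }
  header_lines <- as.integer(header_lines)
  if (is.na(header_lines) || header_lines < 0L) {
    stop("header_lines must be a non-negative integer", call. = FALSE)
  }
  if (is.null(names(channel_columns)) || any(!nzchar(names(channel_columns)))) {
    stop("channel_columns must be a fully named vector (channel name -> file column)",
         call. = FALSE)
  }
  if (is.null(pin_columns) == is.null(trigger_column)) {
    stop("exactly one of pin_columns or trigger_column must be given", call. = FALSE)
  }
  all_refs <- c(unname(channel_columns), time_column, pin_columns, trigger_column)
  if (anyDuplicated(all_refs)) {
    stop("time, channel, and pin/trigger columns must reference disjoint columns",
         call. = FALSE)
  }
  structure(
    list(delimiter = delimiter,
         header_lines = header_lines,
         sampling_rate = sampling_rate,
         time_column = time_column,
         channel_columns = channel_columns,
         pin_columns = pin_columns,
         trigger_column = trigger_column,
         pin_high_threshold = pin_high_threshold),
    class = "fp_recording_spec")
}

# Resolve a column reference (name or 1-based index) against a parsed table.
.resolve_column <- function(df, ref, what, path) {
  if (is.character(ref)) {
    if (!ref %in% names(df)) {
      stop("column '", ref, "' (", what, ") not found in '", basename(path), "'",
           call. = FALSE)
    }
    return(df[[ref]])
  }
  ref <- as.integer(ref)
  if (is.na(ref) || ref < 1L || ref > ncol(df)) {
    stop("column index ", ref, " (", what, ") out of range for '", basename(path),
         "' with ", ncol(df), " columns", call. = FALSE)
  }
  df[[ref]]
}

.check_numeric_column <- function(x, what, path) {
  if (is.numeric(x)) return(as.numeric(x))
  conv <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(conv) & !is.na(x))
  if (length(bad)) {
    stop("non-numeric value '", x[bad[1L]], "' in ", what, " column of '",
         basename(path), "' (data row ", bad[1L], ")", call. = FALSE)
  }
  conv
}

#' Read one raw force-plate recording
#'
#' Reads a DSV export according to a [recording_format_spec()], producing a
#' continuous recording with real-valued channels and an integer trigger
#' code per sample. Subject and block identity are taken from the file name
#' (see [parse_data_filename()]). When the spec lists raw pin columns, they
#' are decoded into codes via [decode_pin_levels()].
#'
#' @param path Path to the file; its basename must satisfy the
#'   `subj`/`block` naming contract.
#' @param spec A [recording_format_spec()].
#' @return An object of class `fp_recording`: a list with `subject`,
#'   `block`, `sampling_rate`, `n_samples`, `time` (ms), `channels` (named
#'   list of numeric vectors), and `trigger_codes` (integer per sample).
#' @export
read_raw_recording <- function(path, spec) {
  stopifnot(inherits(spec, "fp_recording_spec"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  id <- parse_data_filename(path)

  uses_names <- any(vapply(
    c(spec$channel_columns, spec$time_column, spec$pin_columns, spec$trigger_column),
    is.character, logical(1L)))

  nf <- count.fields(path, sep = spec$delimiter, skip = spec$header_lines,
                     quote = "", comment.char = "")
  if (length(nf) == 0L || (uses_names && length(nf) == 1L)) {
    stop("no data rows in '", basename(path), "' after skipping ",
         spec$header_lines, " header line(s)", call. = FALSE)
  }
  ref_count <- nf[if (uses_names) 2L else 1L]
  bad <- which(nf != ref_count)
  if (uses_names) bad <- setdiff(bad, 1L)
  if (length(bad)) {
    stop("ragged row in '", basename(path), "': line ",
         spec$header_lines + bad[1L], " has ", nf[bad[1L]],
         " fields, expected ", ref_count, call. = FALSE)
  }

  df <- data.table::fread(path, sep = spec$delimiter, skip = spec$header_lines,
                          header = uses_names, data.table = TRUE,
                          colClasses = NULL, showProgress = FALSE)
  n <- nrow(df)
  if (n == 0L) stop("no data rows in '", basename(path), "'", call. = FALSE)

  channels <- lapply(seq_along(spec$channel_columns), function(i) {
    ref <- spec$channel_columns[[i]]
    .check_numeric_column(.resolve_column(df, ref, paste0("channel ", names(spec$channel_columns)[i]), path),
                          paste0("channel ", names(spec$channel_columns)[i]), path)
  })
  names(channels) <- names(spec$channel_columns)

  time <- if (!is.null(spec$time_column)) {
    .check_numeric_column(.resolve_column(df, spec$time_column, "time", path), "time", path)
  } else {
    (seq_len(n) - 1L) / spec$sampling_rate * 1000
  }

  trigger_codes <- if (!is.null(spec$pin_columns)) {
    pins <- vapply(seq_along(spec$pin_columns), function(i) {
      .check_numeric_column(.resolve_column(df, spec$pin_columns[[i]], paste0("pin ", i - 1L), path),
                            paste0("pin ", i - 1L), path)
    }, numeric(n))
    decode_pin_levels(pins, spec$pin_high_threshold)
  } else {
    as.integer(.check_numeric_column(
      .resolve_column(df, spec$trigger_column, "trigger", path), "trigger", path))
  }

  structure(
    list(subject = id$subject, block = id$block,
         sampling_rate = spec$sampling_rate, n_samples = n,
         time = time, channels = channels, trigger_codes = trigger_codes),
    class = "fp_recording")
}

#' @export
print.fp_recording <- function(x, ...) {
  cat("<fp_recording> subject", x$subject,
      if (!is.na(x$block)) paste("block", x$block) else "(all blocks)",
      "\n  ", x$n_samples, "samples @", x$sampling_rate, "Hz (",
      round(x$n_samples / x$sampling_rate, 1), "s )\n",
      "  channels:", paste(names(x$channels), collapse = ", "), "\n",
      "  trigger codes:", paste(sort(unique(x$trigger_codes)), collapse = " "), "\n")
  invisible(x)
}

#' Write / read a trial-statistics table
#'
#' Serializes a per-trial statistics table (one row per trial, one column
#' per variable-by-bin-by-statistic) as comma-separated text with full
#' double precision, and reads it back losslessly to within text round-trip
#' error. Rows are keyed by `(subject, block, trial)`; duplicate keys are
#' refused. Missing values (incomplete trials) survive the round trip.
#'
#' @param stats A data frame with key columns `subject`, `block`, `trial`.
#' @param path Output (input) file path.
#' @return `write_trial_stats()` returns `path` invisibly;
#'   `read_trial_stats()` returns the table as a data frame of class
#'   `fp_trial_stats`.
#' @export
write_trial_stats <- function(stats, path) {
  key <- c("subject", "block", "trial")
  if (!all(key %in% names(stats))) {
    stop("stats table must contain key columns subject, block, trial", call. = FALSE)
  }
  dup <- duplicated(stats[key])
  if (any(dup)) {
    d <- stats[dup, key, drop = FALSE][1L, ]
    stop("duplicate (subject, block, trial) key: (", d$subject, ", ", d$block,
         ", ", d$trial, ")", call. = FALSE)
  }
  data.table::fwrite(stats, path, sep = ",", na = "NA", quote = "auto")
  invisible(path)
}

#' @rdname write_trial_stats
#' @export
read_trial_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, sep = ",", na.strings = "NA",
                                        showProgress = FALSE))
  class(df) <- c("fp_trial_stats", "data.frame")
  df
}
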