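# Trial segmentation, baseline correction, and derived variables.

#' Specify how a continuous recording is segmented into trials
#'
#' A trial spans from one start-trigger onset (inclusive) to the sample
#' before the next start-trigger onset; the final trial runs to the end of
#' the recording. Because triggers are level-held, consecutive trials tile
#' the recording after the first start onset. The defaults are the Simon
#' validation settings: fixation onset (code 128) starts a trial and also
#' anchors the baseline interval, stimulus codes are `{1, 2, 4, 8}` and
#' response codes `{32, 64}` (correct / incorrect).
#'
#' `condition_maps` resolves per-trial condition labels from trigger codes:
#' each named map is a named character vector `code -> label`; the first
#' within-trial event whose code appears in a map supplies that condition's
#' label, and trials without any matching event get `"unknown"`.
#'
#' @param start_trigger Trigger code(s) whose onsets delimit trials.
#' @param n_trials Expected number of trials per block, or `NULL`; a
#'   mismatch between expected and observed counts is a warning, not an
#'   error.
#' @param stimulus_triggers,response_triggers Codes marking stimulus and
#'   response onsets; a trial missing either class is flagged incomplete
#'   (kept, never dropped).
#' @param condition_maps Named list of named character vectors mapping
#'   codes to condition labels.
#' @param baseline_trigger Code whose onset anchors the baseline interval
#'   (may equal the start trigger; the trial's own start onset is then used).
#' @param baseline_interval_ms Closed interval `c(a, b)` in ms relative to
#'   the baseline-trigger onset. At 1000 Hz the default `c(0, 215)` covers
#'   exactly 216 samples.
#' @return An object of class `fp_segmentation_spec`.
#' @export
segmentation_spec <- function(start_trigger = 128L,
                              n_trials = NULL,
                              stimulus_triggers = c(1L, 2L, 4L, 8L),
                              response_triggers = c(32L, 64L),
                              condition_maps = list(
                                stimulus = c(`1` = "target1_left",
                                             `2` = "target1_right",
                                             `4` = "target2_left",
                                             `8` = "target2_right"),
                                correctness = c(`32` = "correct",
                                                `64` = "incorrect")),
                              baseline_trigger = 128L,
                              baseline_interval_ms = c(0, 215)) {
  if (length(start_trigger) == 0L) stop("start_trigger must be nonempty", call. = FALSE)
  if (length(baseline_interval_ms) != 2L ||
      baseline_interval_ms[1L] > baseline_interval_ms[2L]) {
    stop("baseline_interval_ms must be c(a, b) with a <= b", call. = FALSE)
  }
  if (!is.null(n_trials) && (!is.numeric(n_trials) || n_trials < 1)) {
    stop("n_trials must be a positive integer or NULL", call. = FALSE)
  }
  structure(list(start_trigger = as.integer(start_trigger),
                 n_trials = if (is.null(n_trials)) NULL else as.integer(n_trials),
                 stimulus_triggers = as.integer(stimulus_triggers),
                 response_triggers = as.integer(response_triggers),
                 condition_maps = condition_maps,
                 baseline_trigger = as.integer(baseline_trigger),
                 baseline_interval_ms = as.numeric(baseline_interval_ms)),
            class = "fp_segmentation_spec")
}

.resolve_conditions <- function(trial_events, condition_maps) {
  vapply(condition_maps, function(map) {
    codes <- as.integer(names(map))
    hit <- which(trial_events$code %in% codes)
    if (length(hit) == 0L) "unknown" else unname(map[as.character(trial_events$code[hit[1L]])])
  }, character(1L))
}

#' Segment a recording into per-trial epochs
#'
#' Splits a (typically filtered) continuous recording at the onsets of the
#' start trigger. Trial `i` covers samples
#' `[onset_i, onset_{i+1})`; the last trial extends to the end of the
#' recording; samples before the first start onset belong to no trial.
#' Within-trial events are attached with onsets re-expressed relative to
#' trial start, condition labels are resolved via the spec's
#' `condition_maps`, and trials lacking a stimulus or response event are
#' flagged `complete = FALSE` but retained — exclusion is the analyst's
#' decision (see [exclude_rows()]).
#'
#' @param rec An `fp_recording`.
#' @param events Event table for `rec` from [extract_events()] (optionally
#'   cleaned with [suppress_glitches()]).
#' @param spec An [segmentation_spec()].
#' @return An object of class `fp_segments`: a list of `fp_segment`
#'   objects, one per trial, numbered 1..n within the block.
#' @export
segment_recording <- function(rec, events, spec) {
  stopifnot(inherits(rec, "fp_recording"), inherits(spec, "fp_segmentation_spec"))
  start_idx <- which(events$code %in% spec$start_trigger)
  if (length(start_idx) == 0L) {
    stop("no start-trigger event (code ",
         paste(spec$start_trigger, collapse = "/"), ") found in recording of subject ",
         rec$subject, call. = FALSE)
  }
  onsets <- events$onset[start_idx]
  n_trials <- length(onsets)
  if (!is.null(spec$n_trials) && n_trials != spec$n_trials) {
    warning("expected ", spec$n_trials, " trials but found ", n_trials,
            " start-trigger onsets (subject ", rec$subject,
            if (!is.na(rec$block)) paste0(", block ", rec$block) else "",
            "); proceeding with the observed trials", call. = FALSE)
  }
  ends <- c(onsets[-1L] - 1L, rec$n_samples - 1L)  # 0-based inclusive

  segments <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    s0 <- onsets[i]; s1 <- ends[i]
    rng <- (s0 + 1L):(s1 + 1L)  # 1-based slice
    ev_in <- events[events$onset >= s0 & events$onset <= s1, , drop = FALSE]
    ev_in$offset <- pmin(ev_in$offset, s1)
    ev_in$onset <- ev_in$onset - s0
    ev_in$offset <- ev_in$offset - s0
    ev_in$duration_ms <- (ev_in$offset - ev_in$onset + 1L) / rec$sampling_rate * 1000
    rownames(ev_in) <- NULL
    conditions <- .resolve_conditions(ev_in, spec$condition_maps)
    complete <- any(ev_in$code %in% spec$stimulus_triggers) &&
      any(ev_in$code %in% spec$response_triggers)
    segments[[i]] <- structure(
      list(subject = rec$subject, block = rec$block, trial = i,
           start_sample = s0, n_samples = s1 - s0 + 1L,
           sampling_rate = rec$sampling_rate,
           time_ms = (seq_along(rng) - 1L) / rec$sampling_rate * 1000,
           channels = lapply(rec$channels, function(ch) ch[rng]),
           events = ev_in, conditions = conditions,
           complete = complete, baseline_applied = FALSE),
      class = "fp_segment")
  }
  structure(segments, class = "fp_segments")
}

#' @export
print.fp_segments <- function(x, ...) {
  n_inc <- sum(!vapply(x, `[[`, logical(1L), "complete"))
  b <- x[[1L]]
  cat("<fp_segments>", length(x), "trial(s), subject", b$subject,
      if (!is.na(b$block)) paste("block", b$block) else "", "\n")
  cat("  channels:", paste(names(b$channels), collapse = ", "),
      "| incomplete:", n_inc,
      "| baseline applied:", sum(vapply(x, `[[`, logical(1L), "baseline_applied")),
      "\n")
  invisible(x)
}

#' @export
print.fp_segment <- function(x, ...) {
  cat("<fp_segment> subject", x$subject,
      if (!is.na(x$block)) paste("block", x$block) else "", "trial", x$trial,
      "|", x$n_samples, "samples\n")
  cat("  conditions:", paste(names(x$conditions), x$conditions,
                             sep = "=", collapse = ", "), "\n")
  cat("  events:", paste(x$events$code, collapse = " "),
      "| complete:", x$complete, "| baseline:", x$baseline_applied, "\n")
  invisible(x)
}

# Baseline interval as a 1-based sample slice within a segment, or NULL.
.baseline_samples <- function(seg, spec) {
  ev <- seg$events
  hit <- which(ev$code == spec$baseline_trigger)
  if (length(hit) == 0L) return(NULL)
  onset <- ev$onset[hit[1L]]  # relative, 0-based
  fs <- seg$sampling_rate
  a <- spec$baseline_interval_ms[1L]; b <- spec$baseline_interval_ms[2L]
  lo <- onset + ceiling(a * fs / 1000)
  hi <- onset + floor(b * fs / 1000)
  lo_c <- max(lo, 0L); hi_c <- min(hi, seg$n_samples - 1L)
  if (lo_c > hi_c) return(NULL)
  list(idx = (lo_c + 1L):(hi_c + 1L), truncated = (lo_c != lo || hi_c != hi))
}

#' Baseline-correct trial segments
#'
#' Subtracts from each listed channel the mean over the baseline interval —
#' by default the fixation period, a phase without cognitive or muscular
#' task demands — from every sample of the trial. The interval is closed in
#' ms at sample resolution: at 1000 Hz the default `[0, 215]` relative to
#' the fixation onset averages exactly 216 samples. The correction is
#' idempotent: after it, the interval mean is 0, so reapplying changes
#' nothing beyond float noise.
#'
#' Trials without a baseline-trigger event keep their channels uncorrected
#' and are flagged (warning); an interval running past the trial end is
#' truncated to the available samples (warning).
#'
#' @param segments An `fp_segments` object (or a single `fp_segment`).
#' @param spec The [segmentation_spec()] used for segmentation.
#' @param vars Channel names to correct; default all channels.
#' @return The segments with corrected channels and `baseline_applied` set.
#' @export
baseline_correct <- function(segments, spec, vars = NULL) {
  single <- inherits(segments, "fp_segment")
  segs <- if (single) list(segments) else segments
  stopifnot(inherits(spec, "fp_segmentation_spec"))
  n_missing <- 0L; n_trunc <- 0L
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    v <- if (is.null(vars)) names(seg$channels) else vars
    bad <- setdiff(v, names(seg$channels))
    if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
    bs <- .baseline_samples(seg, spec)
    if (is.null(bs)) {
      n_missing <- n_missing + 1L
      seg$baseline_missing <- TRUE
    } else {
      if (bs$truncated) n_trunc <- n_trunc + 1L
      for (ch in v) {
        seg$channels[[ch]] <- seg$channels[[ch]] - mean(seg$channels[[ch]][bs$idx])
      }
      seg$baseline_applied <- TRUE
    }
    segs[[i]] <- seg
  }
  if (n_missing > 0L) {
    warning(n_missing, " trial(s) without a baseline-trigger event (code ",
            spec$baseline_trigger, "); left uncorrected and flagged", call. = FALSE)
  }
  if (n_trunc > 0L) {
    warning("baseline interval truncated to trial bounds in ", n_trunc,
            " trial(s)", call. = FALSE)
  }
  if (single) segs[[1L]] else structure(segs, class = "fp_segments")
}

#' Add a derived per-sample variable to every segment
#'
#' Computes a new channel as a pure per-sample function of the existing
#' channels — e.g. a normalized moment `Mx / Fz` or a difference
#' `Mx - My` — and appends it to every trial. Existing channels are never
#' modified.
#'
#' @param segments An `fp_segments` object.
#' @param name Name of the new channel; must not collide with an existing
#'   one.
#' @param transform Function receiving a data frame with one column per
#'   existing channel and returning a numeric vector of the same length.
#' @return The segments with the new channel appended.
#' @examples
#' \dontrun{
#' segs <- add_derived_variable(segs, "Mdiff", function(ch) ch$Mx - ch$My)
#' }
#' @export
add_derived_variable <- function(segments, name, transform) {
  stopifnot(inherits(segments, "fp_segments"), is.function(transform))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    if (name %in% names(seg$channels)) {
      stop("channel '", name, "' already exists", call. = FALSE)
    }
    new <- transform(as.data.frame(seg$channels))
    if (!is.numeric(new) || length(new) != seg$n_samples) {
      stop("transform must return a numeric vector of length ", seg$n_samples,
           " (trial ", seg$trial, ")", call. = FALSE)
    }
    seg$channels[[name]] <- as.numeric(new)
    segments[[i]] <- seg
  }
  segments
}
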