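# Event-locked time bins and per-trial descriptive statistics.

#' Built-in bin statistics
#'
#' The default statistic set for [compute_bin_stats()]: the mean, the
#' sample standard deviation (`n - 1` denominator), and the range as a
#' single nonnegative scalar `max - min`. A statistic is any pure function
#' from a numeric slice to a single number, so the set is user-extensible.
#'
#' @return Named list of functions.
#' @export
default_statistics <- function() {
  list(mean = function(x) mean(x),
       sd = function(x) stats::sd(x),
       range = function(x) max(x) - min(x))
}

# Statistics referenced by registry name in serialized configs.
.statistic_registry <- function(names) {
  reg <- default_statistics()
  missing <- setdiff(names, names(reg))
  if (length(missing)) {
    stop("unknown statistic name(s): ", paste(missing, collapse = ", "),
         "; registry provides ", paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[names]
}

#' Specify event-locked time bins and statistics
#'
#' Bins are defined in ms relative to a lock event — by default the
#' response onset (codes 32/64), with boundaries `c(-150, 150)` and width
#' 150 ms, i.e. one 150-ms bin before and one after the response. Bins are
#' half-open `[start, end)` so each sample is counted exactly once; the
#' anchor sample (t = 0) falls in the bin whose interval contains 0.
#'
#' @param lock_triggers Codes of the lock event; the first (or last, see
#'   `lock_which`) within-trial event with one of these codes anchors
#'   t = 0.
#' @param boundaries Increasing ms offsets relative to the anchor; the span
#'   `last - first` must be divisible by `bin_width_ms`.
#' @param bin_width_ms Width of each bin in ms.
#' @param vars Channel names to summarize.
#' @param statistics Named list of functions slice -> scalar; default
#'   [default_statistics()].
#' @param lock_which `"first"` (default) or `"last"` matching event; `"last"`
#'   suits designs with multiple sub-tasks per trial.
#' @return An object of class `fp_bin_spec`.
#' @export
bin_spec <- function(lock_triggers = c(32L, 64L),
                     boundaries = c(-150, 150),
                     bin_width_ms = 150,
                     vars = c("Mx", "My"),
                     statistics = default_statistics(),
                     lock_which = c("first", "last")) {
  lock_which <- match.arg(lock_which)
  if (length(boundaries) < 2L || any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing with at least two values", call. = FALSE)
  }
  if (!is.numeric(bin_width_ms) || bin_width_ms <= 0) {
    stop("bin_width_ms must be > 0", call. = FALSE)
  }
  if (is.null(names(statistics)) || any(!nzchar(names(statistics))) ||
      !all(vapply(statistics, is.function, logical(1L)))) {
    stop("statistics must be a fully named list of functions", call. = FALSE)
  }
  structure(list(lock_triggers = as.integer(lock_triggers),
                 boundaries = as.numeric(boundaries),
                 bin_width_ms = as.numeric(bin_width_ms),
                 vars = vars, statistics = statistics,
                 lock_which = lock_which),
            class = "fp_bin_spec")
}

# "-150" -> "m150" so bin labels are syntactic in column names.
.ms_label <- function(v) {
  ifelse(v < 0, paste0("m", format(abs(v), trim = TRUE, scientific = FALSE)),
         format(v, trim = TRUE, scientific = FALSE))
}

#' Resolve bin boundaries into contiguous half-open intervals
#'
#' Tiles `[first boundary, last boundary)` with intervals of width
#' `bin_width_ms`. The validation settings `boundaries = c(-150, 150)`,
#' `bin_width_ms = 150` resolve to `[-150, 0)` and `[0, 150)`.
#'
#' @param spec An [bin_spec()] object.
#' @return Data frame with columns `start_ms`, `end_ms`, and `label` (e.g.
#'   `"m150_0"` for `[-150, 0)`).
#' @export
resolve_bins <- function(spec) {
  stopifnot(inherits(spec, "fp_bin_spec"))
  span <- spec$boundaries[length(spec$boundaries)] - spec$boundaries[1L]
  n_bins <- span / spec$bin_width_ms
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("bin span ", span, " ms is not divisible by bin width ",
         spec$bin_width_ms, " ms", call. = FALSE)
  }
  n_bins <- as.integer(round(n_bins))
  starts <- spec$boundaries[1L] + (seq_len(n_bins) - 1L) * spec$bin_width_ms
  ends <- starts + spec$bin_width_ms
  data.frame(start_ms = starts, end_ms = ends,
             label = paste0(.ms_label(starts), "_", .ms_label(ends)))
}

#' Locate the time-lock anchor within a trial
#'
#' Returns the onset sample (relative to trial start, 0-based) of the
#' first — or last, per the spec — within-trial event whose code is one of
#' the lock triggers; `NA` when no event matches (the trial's statistics
#' are then missing).
#'
#' @param seg An `fp_segment`.
#' @param lock_triggers Integer code vector.
#' @param lock_which `"first"` or `"last"`.
#' @return Integer sample index or `NA`.
#' @export
locate_lock <- function(seg, lock_triggers, lock_which = "first") {
  hit <- which(seg$events$code %in% as.integer(lock_triggers))
  if (length(hit) == 0L) return(NA_integer_)
  i <- if (identical(lock_which, "last")) hit[length(hit)] else hit[1L]
  as.integer(seg$events$onset[i])
}

#' Compute per-trial statistics over event-locked bins
#'
#' For every trial, channel in `spec$vars`, and resolved bin, gathers the
#' samples whose time relative to the lock anchor falls in `[start, end)`
#' ms and applies each statistic. At 1000 Hz a 150-ms bin holds exactly 150
#' samples. Bins cut short by the trial edges use the available samples and
#' set the `truncated` flag; a bin left empty, or a trial without a lock
#' event, yields `NA` values (never silent zeros) and a flag.
#'
#' @param segments An `fp_segments` object (typically baseline-corrected;
#'   the two steps are independent).
#' @param spec An [bin_spec()] object.
#' @return A data frame of class `fp_trial_stats`: key columns `subject`,
#'   `block`, `trial`, the resolved condition labels, `complete`,
#'   `lock_missing`, `truncated`, and one column per variable x bin x
#'   statistic named `<var>_<binlabel>_<stat>` (e.g. `Mx_m150_0_sd`). The
#'   resolved bin table is attached as attribute `"bins"`.
#' @export
compute_bin_stats <- function(segments, spec) {
  stopifnot(inherits(segments, "fp_segments"), inherits(spec, "fp_bin_spec"))
  bins <- resolve_bins(spec)
  first <- segments[[1L]]
  bad <- setdiff(spec$vars, names(first$channels))
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)

  stat_names <- names(spec$statistics)
  col_names <- unlist(lapply(spec$vars, function(v)
    unlist(lapply(bins$label, function(b) paste(v, b, stat_names, sep = "_")))))

  n <- length(segments)
  fs <- first$sampling_rate
  vals <- matrix(NA_real_, nrow = n, ncol = length(col_names),
                 dimnames = list(NULL, col_names))
  lock_missing <- logical(n)
  truncated <- logical(n)
  n_nolock <- 0L

  for (i in seq_len(n)) {
    seg <- segments[[i]]
    anchor <- locate_lock(seg, spec$lock_triggers, spec$lock_which)
    if (is.na(anchor)) {
      lock_missing[i] <- TRUE
      n_nolock <- n_nolock + 1L
      next
    }
    col <- 0L
    for (v in spec$vars) {
      x <- seg$channels[[v]]
      for (b in seq_len(nrow(bins))) {
        # sample s (0-based) is in the bin iff start <= (s - anchor)*1000/fs < end
        lo <- anchor + ceiling(bins$start_ms[b] * fs / 1000)
        hi <- anchor + ceiling(bins$end_ms[b] * fs / 1000) - 1L
        lo_c <- max(lo, 0L); hi_c <- min(hi, seg$n_samples - 1L)
        if (lo_c != lo || hi_c != hi) truncated[i] <- TRUE
        if (lo_c > hi_c) {
          col <- col + length(stat_names)
          next  # empty after truncation: NA values, flag already set
        }
        slice <- x[(lo_c + 1L):(hi_c + 1L)]
        for (s in seq_along(stat_names)) {
          vals[i, col + s] <- spec$statistics[[s]](slice)
        }
        col <- col + length(stat_names)
      }
    }
  }
  if (n_nolock > 0L) {
    warning(n_nolock, " trial(s) without a lock event (code ",
            paste(spec$lock_triggers, collapse = "/"),
            "); their statistics are missing", call. = FALSE)
  }

  cond_names <- names(first$conditions)
  conds <- lapply(cond_names, function(cn)
    vapply(segments, function(s) s$conditions[[cn]], character(1L)))
  names(conds) <- cond_names

  out <- data.frame(
    subject = vapply(segments, `[[`, integer(1L), "subject"),
    block = vapply(segments, `[[`, integer(1L), "block"),
    trial = vapply(segments, `[[`, integer(1L), "trial"))
  for (cn in cond_names) out[[cn]] <- conds[[cn]]
  out$complete <- vapply(segments, `[[`, logical(1L), "complete")
  out$lock_missing <- lock_missing
  out$truncated <- truncated
  out <- cbind(out, as.data.frame(vals))
  attr(out, "bins") <- bins
  class(out) <- c("fp_trial_stats", "data.frame")
  out
}

#' @export
print.fp_trial_stats <- function(x, ...) {
  cat("<fp_trial_stats>", nrow(x), "trial(s),",
      length(stat_column_names(x)), "statistic column(s)\n")
  NextMethod()
}

#' Names of the statistic value columns of a trial-stats table
#'
#' Helper separating the `<var>_<bin>_<stat>` value columns from the key,
#' condition, and flag columns.
#'
#' @param stats An `fp_trial_stats` data frame.
#' @return Character vector of column names.
#' @export
stat_column_names <- function(stats) {
  meta <- c("subject", "block", "trial", "trial_global", "complete",
            "lock_missing", "truncated")
  setdiff(names(stats)[vapply(stats, is.numeric, logical(1L))], meta)
}
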