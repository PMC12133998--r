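# Parallel-port trigger decoding and run-length event extraction.
#
# Triggers are level-held: the experiment sets the port to a code and holds
# it until the next event, so the code series is piecewise constant and a
# maximal constant run is one event.

#' Decode per-pin voltages into integer trigger codes
#'
#' A parallel port with `N` pins can transmit `2^N` distinct codes. Each
#' sample's code is the sum of `2^p` over the pins `p` (0-based, least
#' significant pin first) whose voltage exceeds `threshold`.
#'
#' @param pins Numeric matrix (or data frame) of voltages, one row per
#'   sample, one column per pin, least significant pin in column 1. A plain
#'   vector is treated as a single pin.
#' @param threshold Voltage above which a pin counts as high.
#' @return Integer vector of trigger codes, one per sample.
#' @examples
#' decode_pin_levels(cbind(c(0, 5), c(0, 5)), 2.5)  # 0, 3
#' @export
decode_pin_levels <- function(pins, threshold = 2.5) {
  if (is.data.frame(pins)) pins <- as.matrix(pins)
  if (!is.matrix(pins)) pins <- matrix(pins, ncol = 1L)
  if (ncol(pins) < 1L) stop("at least one pin column is required", call. = FALSE)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  bad <- which(!is.finite(pins))
  if (length(bad)) {
    s <- ((bad[1L] - 1L) %% nrow(pins)) + 1L
    stop("non-finite pin voltage at sample ", s, call. = FALSE)
  }
  weights <- 2^(seq_len(ncol(pins)) - 1L)
  as.integer(as.vector((pins > threshold) %*% weights))
}

#' Encode integer trigger codes as per-pin voltage levels
#'
#' Inverse of [decode_pin_levels()]: expands each code into `n_pins` voltage
#' columns (least significant pin first), writing `high_v` for set bits and
#' `low_v` otherwise. Used when synthesizing raw files and for checking the
#' decode/encode identity.
#'
#' @param codes Integer vector of codes in `[0, 2^n_pins - 1]`.
#' @param n_pins Number of pins.
#' @param high_v,low_v Voltages written for high and low pins.
#' @return Numeric matrix with `length(codes)` rows and `n_pins` columns.
#' @export
encode_pin_levels <- function(codes, n_pins = 8L, high_v = 5, low_v = 0) {
  codes <- as.integer(codes)
  if (any(codes < 0L | codes > 2^n_pins - 1L)) {
    stop("codes must lie in [0, 2^n_pins - 1]", call. = FALSE)
  }
  bits <- vapply(seq_len(n_pins) - 1L,
                 function(p) bitwAnd(codes, bitwShiftL(1L, p)) > 0L,
                 logical(length(codes)))
  if (!is.matrix(bits)) bits <- matrix(bits, nrow = length(codes))
  matrix(ifelse(bits, high_v, low_v), nrow = length(codes))
}

#' Extract level-held trigger events from a code series
#'
#' Run-length encodes the per-sample code series: each maximal run of one
#' code becomes one event with an onset and an (inclusive) offset sample.
#' Events tile the recording with no gaps or overlap; code 0 (all pins low,
#' e.g. the inter-trial interval) is an ordinary event. All time-locking in
#' the package references event onsets, i.e. the first sample at which a
#' new code is observed.
#'
#' @param codes Integer vector of per-sample trigger codes.
#' @param sampling_rate Sampling rate in Hz (used for `duration_ms`).
#' @return A data frame with one row per event: `code`, `onset` and
#'   `offset` (0-based sample indices, offset inclusive), `duration_ms`.
#' @examples
#' extract_events(c(0, 0, 128, 128, 128, 1, 1), 1000)
#' @export
extract_events <- function(codes, sampling_rate) {
  if (length(codes) == 0L) stop("code series is empty", call. = FALSE)
  r <- rle(as.integer(codes))
  ends <- cumsum(r$lengths)
  onsets <- ends - r$lengths  # 0-based
  data.frame(code = r$values,
             onset = onsets,
             offset = ends - 1L,
             duration_ms = r$lengths / sampling_rate * 1000)
}

#' Merge transient glitch events into their neighbours
#'
#' When several pins switch within one sample of each other the decoded
#' series can show a one-or-two-sample spurious code at each transition.
#' Runs shorter than `min_duration_ms` are absorbed into the preceding
#' event (the first event, having no predecessor, is absorbed into the
#' following one, with a warning). Neighbouring events that end up with the
#' same code are coalesced. With `min_duration_ms = 0` (the default
#' throughout the package) the input is returned unchanged.
#'
#' @param events Event table from [extract_events()].
#' @param min_duration_ms Minimum legitimate event duration in ms.
#' @param sampling_rate Sampling rate in Hz.
#' @return Event table of the same shape, tiling the same sample range.
#' @export
suppress_glitches <- function(events, min_duration_ms, sampling_rate) {
  stopifnot(min_duration_ms >= 0)
  if (min_duration_ms == 0 || nrow(events) <= 1L) return(events)

  repeat {
    len <- events$offset - events$onset + 1L
    short <- which(len / sampling_rate * 1000 < min_duration_ms)
    if (length(short) == 0L || length(short) == nrow(events)) break
    i <- short[1L]
    if (i == 1L) {
      warning("first trigger event (code ", events$code[1L],
              ") shorter than ", min_duration_ms, " ms; merged into the following event",
              call. = FALSE)
      events$onset[2L] <- events$onset[1L]
      events <- events[-1L, , drop = FALSE]
    } else {
      events$offset[i - 1L] <- events$offset[i]
      events <- events[-i, , drop = FALSE]
    }
    # coalesce neighbours that now share a code
    same <- which(diff(events$code) == 0L)
    while (length(same)) {
      j <- same[1L]
      events$offset[j] <- events$offset[j + 1L]
      events <- events[-(j + 1L), , drop = FALSE]
      same <- which(diff(events$code) == 0L)
    }
  }
  events$duration_ms <- (events$offset - events$onset + 1L) / sampling_rate * 1000
  rownames(events) <- NULL
  events
}
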