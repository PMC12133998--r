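# Low-pass filter design and the reversed-prefix zero-phase scheme.
#
# The default filter is the field's conventional choice for kinesiological
# data: a fourth-order low-pass Butterworth with a 10-Hz cut-off. It is
# applied forward and backward (zero net phase), with the first pad_count
# samples prepended in reverse order before each pass and dropped after, so
# the start-up transient of each pass falls on padding, not on data.

#' Specify the default low-pass filter
#'
#' @param sampling_rate Sampling rate of the recording in Hz.
#' @param order Filter order (default 4).
#' @param cutoff_hz Low-pass cut-off frequency in Hz (default 10); must be
#'   below the Nyquist frequency `sampling_rate / 2`.
#' @param pad_count Number of samples prepended in reverse order before
#'   each filtering pass (default 2000).
#' @return An object of class `fp_filter_spec`.
#' @export
filter_spec <- function(sampling_rate, order = 4L, cutoff_hz = 10,
                        pad_count = 2000L) {
  order <- as.integer(order)
  pad_count <- as.integer(pad_count)
  if (is.na(order) || order < 1L) stop("order must be a positive integer", call. = FALSE)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0) stop("cutoff_hz must be > 0", call. = FALSE)
  if (cutoff_hz >= sampling_rate / 2) {
    stop("cutoff_hz (", cutoff_hz, ") must be below the Nyquist frequency ",
         sampling_rate / 2, " Hz", call. = FALSE)
  }
  if (is.na(pad_count) || pad_count < 0L) stop("pad_count must be >= 0", call. = FALSE)
  structure(list(order = order, cutoff_hz = cutoff_hz,
                 sampling_rate = sampling_rate, pad_count = pad_count),
            class = "fp_filter_spec")
}

#' Design the discrete low-pass Butterworth filter
#'
#' Designs the digital Butterworth low-pass via the bilinear transform with
#' frequency prewarping, so the single-pass magnitude at the cut-off is
#' exactly `2^(-1/2)` and the DC gain is 1. The returned coefficients have
#' a unit leading denominator coefficient and all poles strictly inside the
#' unit circle (checked).
#'
#' Any rational filter can be substituted for the default: every function
#' that applies a filter accepts an `fp_filter_coef` object, so users can
#' wrap their own `(b, a)` coefficients with [as_filter_coef()].
#'
#' @param spec An [filter_spec()] object.
#' @return An object of class `fp_filter_coef` with numerator `b` and
#'   denominator `a` coefficient vectors.
#' @export
design_lowpass_butterworth <- function(spec) {
  stopifnot(inherits(spec, "fp_filter_spec"))
  ba <- signal::butter(spec$order, spec$cutoff_hz / (spec$sampling_rate / 2),
                       type = "low")
  as_filter_coef(ba$b, ba$a)
}

#' Wrap numerator/denominator coefficients as a filter object
#'
#' @param b,a Numerator and denominator coefficients of a rational
#'   discrete-time transfer function (denominator normalized so `a[1] = 1`;
#'   normalization is applied if needed). Stability (all poles strictly
#'   inside the unit circle) is verified.
#' @return An object of class `fp_filter_coef`.
#' @export
as_filter_coef <- function(b, a) {
  if (a[1L] == 0) stop("leading denominator coefficient must be nonzero", call. = FALSE)
  b <- as.numeric(b) / a[1L]
  a <- as.numeric(a) / a[1L]
  if (length(a) > 1L) {
    poles <- polyroot(rev(a))
    if (any(Mod(poles) >= 1)) {
      stop("unstable filter: pole(s) on or outside the unit circle", call. = FALSE)
    }
  }
  structure(list(b = b, a = a, order = length(a) - 1L), class = "fp_filter_coef")
}

#' @export
print.fp_filter_coef <- function(x, ...) {
  cat("<fp_filter_coef> order", x$order, "rational digital filter\n")
  cat("  b:", signif(x$b, 6), "\n  a:", signif(x$a, 6), "\n")
  invisible(x)
}

#' Single-pass magnitude response of a designed filter
#'
#' Evaluates `|H(e^{i 2 pi f / fs})|` directly from the coefficient
#' polynomials. The two-pass (forward-backward) scheme squares this
#' magnitude.
#'
#' @param coeffs An `fp_filter_coef` object.
#' @param freq_hz Frequencies at which to evaluate, in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric vector of single-pass amplitude gains.
#' @export
filter_gain <- function(coeffs, freq_hz, sampling_rate) {
  stopifnot(inherits(coeffs, "fp_filter_coef"))
  vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / sampling_rate)
    num <- sum(coeffs$b * z^(seq_along(coeffs$b) - 1L))
    den <- sum(coeffs$a * z^(seq_along(coeffs$a) - 1L))
    Mod(num / den)
  }, numeric(1L))
}

# One causal pass with the reversed prefix absorbed and dropped.
.pass_with_prefix <- function(x, coeffs, pad_count) {
  k <- min(pad_count, length(x) - 1L)
  if (k > 0L) {
    padded <- c(rev(x[seq_len(k)]), x)
    y <- as.numeric(signal::filter(coeffs$b, coeffs$a, padded))
    y[-seq_len(k)]
  } else {
    as.numeric(signal::filter(coeffs$b, coeffs$a, x))
  }
}

#' Zero-phase filtering with a reversed-prefix pad
#'
#' Applies the filter forward and backward so the net phase shift is zero
#' and the effective amplitude response is the squared single-pass
#' magnitude. Before each pass the first `pad_count` samples of the series
#' about to be filtered are prepended in reverse order and the
#' corresponding outputs dropped afterwards, so each pass starts from a
#' mirrored continuation of the data rather than from zeros and the
#' start-up transient never reaches the retained samples. Each pass runs
#' from zero initial filter state. With `pad_count = 0` this degenerates to
#' plain forward-backward filtering.
#'
#' @param x Numeric series; must be longer than the filter order.
#' @param coeffs An `fp_filter_coef` object (e.g. from
#'   [design_lowpass_butterworth()]).
#' @param pad_count Number of samples to prepend in reverse order before
#'   each pass; capped at `length(x) - 1`.
#' @return Filtered series of the same length as `x`.
#' @export
zero_phase_filter_mirrored <- function(x, coeffs, pad_count = 2000L) {
  stopifnot(inherits(coeffs, "fp_filter_coef"), pad_count >= 0)
  if (length(x) < coeffs$order + 1L) {
    stop("series of length ", length(x), " is too short to filter (order ",
         coeffs$order, ")", call. = FALSE)
  }
  forward <- .pass_with_prefix(x, coeffs, pad_count)
  rev(.pass_with_prefix(rev(forward), coeffs, pad_count))
}

#' Filter all (or selected) channels of a recording
#'
#' Filtering is applied to the whole continuous block before segmentation,
#' matching the processing order filter -> segment -> baseline -> bin
#' statistics.
#'
#' @param rec An `fp_recording`.
#' @param spec An [filter_spec()] (its `sampling_rate` must equal the
#'   recording's) or an `fp_filter_coef` object.
#' @param channels Channel names to filter; default all.
#' @param pad_count Pad length when `spec` is a coefficient object;
#'   ignored otherwise (taken from the spec).
#' @return The recording with the listed channels replaced by their
#'   zero-phase filtered versions.
#' @export
filter_recording <- function(rec, spec, channels = NULL, pad_count = 2000L) {
  stopifnot(inherits(rec, "fp_recording"))
  if (inherits(spec, "fp_filter_spec")) {
    if (spec$sampling_rate != rec$sampling_rate) {
      stop("filter spec sampling rate (", spec$sampling_rate,
           ") differs from recording (", rec$sampling_rate, ")", call. = FALSE)
    }
    coeffs <- design_lowpass_butterworth(spec)
    pad_count <- spec$pad_count
  } else if (inherits(spec, "fp_filter_coef")) {
    coeffs <- spec
  } else {
    stop("spec must be an fp_filter_spec or fp_filter_coef", call. = FALSE)
  }
  if (is.null(channels)) channels <- names(rec$channels)
  missing <- setdiff(channels, names(rec$channels))
  if (length(missing)) {
    stop("unknown channel(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (ch in channels) {
    rec$channels[[ch]] <- zero_phase_filter_mirrored(rec$channels[[ch]], coeffs, pad_count)
  }
  rec
}
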