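#' Signal-cleaning configuration
#'
#' Parameters of the cleaning chain applied to every recording before
#' kinetic quantification.
#'
#' @param pacing_hz Field-stimulation pacing frequency in Hz. All
#'   recordings are paced at a fixed rate (default 1.2 Hz) so kinetic
#'   parameters need no frequency correction.
#' @param ma_window Moving-average filter width in frames (default 2, a
#'   minimal smoother at ~3 ms per frame).
#' @param events_to_average Number of paced events averaged into the
#'   representative beat (default 5).
#' @param interpeak_tol Tolerated relative deviation of each inter-onset
#'   interval from the pacing period (default 0.1). A recording whose
#'   events drift beyond this is rejected as unpaced.
#' @param onset_frac Event onset is the rising crossing of this fraction of
#'   the event amplitude (default 0.1).
#' @param pre_frac Fraction of a pacing period included ahead of each onset
#'   in the event window, so the averaged beat keeps a pre-upstroke
#'   baseline segment (default 0.05).
#' @return A `ttm_cleaning_config` list.
#' @export
cleaning_config <- function(pacing_hz = 1.2, ma_window = 2L,
                            events_to_average = 5L, interpeak_tol = 0.1,
                            onset_frac = 0.1, pre_frac = 0.05) {
  stopifnot(pacing_hz > 0, ma_window >= 1, events_to_average >= 1,
            interpeak_tol > 0, interpeak_tol < 0.5,
            onset_frac > 0, onset_frac < 1,
            pre_frac >= 0, pre_frac < 0.5)
  structure(
    list(pacing_hz = pacing_hz, ma_window = as.integer(ma_window),
         events_to_average = as.integer(events_to_average),
         interpeak_tol = interpeak_tol, onset_frac = onset_frac,
         pre_frac = pre_frac),
    class = "ttm_cleaning_config"
  )
}

#' Ratiometric motion-artifact correction
#'
#' The membrane label is co-localised with the voltage dye and recorded
#' simultaneously, so contraction-induced intensity modulation (the motion
#' artifact, MA) affects the AP and Ca channels multiplicatively in the
#' same way it modulates the MA channel. Dividing by the mean-normalised MA
#' trace removes that common modulation: `out_i = signal_i / (ma_i /
#' mean(ma))`. A constant MA trace leaves the signal untouched.
#'
#' @param signal An AP or Ca `ttm_trace`.
#' @param ma The motion-artifact `ttm_trace` (same length and rate,
#'   strictly positive).
#' @return The corrected `ttm_trace`.
#' @export
ratiometric_correct <- function(signal, ma) {
  if (nrow(signal) != nrow(ma)) {
    .ttm_stop("Signal and MA traces must have equal length.",
              "ttm_error_input")
  }
  if (abs(trace_fps(signal) - trace_fps(ma)) > 1e-9 * trace_fps(signal)) {
    .ttm_stop("Signal and MA traces must share the sampling rate.",
              "ttm_error_input")
  }
  if (any(ma$value <= 0)) {
    .ttm_stop(
      "MA trace must be strictly positive for ratiometric correction; offset-correct it upstream.",
      "ttm_error_domain")
  }
  retrace(signal, signal$value / (ma$value / mean(ma$value)))
}

#' Invert a trace about its mid-range
#'
#' The voltage dye's fluorescence decreases with depolarisation, so the raw
#' optical AP is upside down. Reflection about the mid-range, `(max + min)
#' - x`, restores an upward-going action potential while preserving
#' positivity (needed by the downstream pseudo-ratio). Applying it twice
#' returns the input.
#'
#' @param trace A `ttm_trace`.
#' @return The inverted `ttm_trace`.
#' @export
invert_trace <- function(trace) {
  v <- trace$value
  retrace(trace, (max(v) + min(v)) - v)
}

#' Pseudo-ratio dF/F_min normalisation
#'
#' Converts a fluorescence trace to the dimensionless pseudo-ratio
#' `(F - F_min) / F_min`, where `F_min` is the trace minimum. The output
#' minimum is exactly 0 and the result is invariant to positive rescaling
#' of the input.
#'
#' @param trace A `ttm_trace` with strictly positive minimum.
#' @return The normalised `ttm_trace`.
#' @export
delta_f_over_f <- function(trace) {
  f_min <- min(trace$value)
  if (f_min <= 0) {
    .ttm_stop(
      "dF/F_min requires a strictly positive trace minimum; offset-correct the trace upstream.",
      "ttm_error_domain")
  }
  retrace(trace, (trace$value - f_min) / f_min)
}

#' Trailing moving-average filter
#'
#' `out_i = mean(in_(i-window+1) .. in_i)`; the first `window - 1` samples
#' average over the available prefix so the length is preserved and onsets
#' are not shifted earlier. The default pipeline uses a minimal 2-frame
#' window.
#'
#' @param trace A `ttm_trace`.
#' @param window Window width in samples (1 = identity).
#' @return The filtered `ttm_trace`.
#' @export
moving_average <- function(trace, window = 2L) {
  n <- nrow(trace)
  window <- as.integer(window)
  if (window < 1 || window > n) {
    .ttm_stop("`window` must be between 1 and the trace length.",
              "ttm_error_input")
  }
  cs <- cumsum(trace$value)
  out <- numeric(n)
  i <- seq_len(n)
  lo <- pmax(i - window + 1L, 1L)
  out <- (cs[i] - c(0, cs)[lo]) / (i - lo + 1L)
  retrace(trace, out)
}

#' Detect paced events in a trace
#'
#' Each beat is first located by its steep half-amplitude rising crossing
#' (a robust peak-region marker; amplitude = max minus the lower-decile
#' baseline, with a half-period refractory against noise re-crossings).
#' The event onset is then found by backtracking from the marker to the
#' rising crossing of `onset_frac` of the amplitude. The inter-peak
#' intervals (marker spacing) must all agree with the pacing period within
#' `interpeak_tol`; a failed check marks the whole recording for
#' rejection. Each complete event spans one pacing period starting
#' `pre_frac` of a period before its onset, so the averaged beat keeps a
#' pre-upstroke baseline segment.
#'
#' @param trace A cleaned `ttm_trace` with upward-going events.
#' @param config A [cleaning_config()].
#' @return A `ttm_events` object: tibble of event `onset` sample indices,
#'   peak-region `marker` indices and window `start` indices, with
#'   attributes `window` (samples), `period` (samples) and `pass`
#'   (pacing-consistency flag).
#' @export
detect_events <- function(trace, config = cleaning_config()) {
  v <- trace$value
  n <- length(v)
  fps <- trace_fps(trace)
  period <- fps / config$pacing_hz
  if (n < 2 * period) {
    .ttm_stop("Trace must span at least two pacing periods.",
              "ttm_error_input")
  }
  baseline <- unname(quantile(v, 0.1, names = FALSE))
  amp <- max(v) - baseline
  if (amp <= .Machine$double.eps * max(1, abs(baseline))) {
    .ttm_stop("No events detected (flat trace).",
              "ttm_error_insufficient_events")
  }
  thr_mark <- baseline + 0.5 * amp
  cross <- which(v[-1] >= thr_mark & v[-n] < thr_mark) + 1L
  markers <- integer(0)
  for (i in cross) {
    if (length(markers) == 0 || i - markers[length(markers)] > period / 2) {
      markers <- c(markers, i)
    }
  }
  if (length(markers) == 0) {
    .ttm_stop("No events detected.", "ttm_error_insufficient_events")
  }
  thr_on <- baseline + config$onset_frac * amp
  onsets <- vapply(markers, function(m) {
    below <- which(v[seq_len(m)] < thr_on)
    if (length(below) == 0) 1L else as.integer(max(below) + 1L)
  }, integer(1))
  window <- as.integer(floor(period))
  pre <- as.integer(floor(config$pre_frac * period))
  starts <- onsets - pre
  keep <- starts >= 1L & (starts + window - 1L) <= n
  if (sum(keep) < config$events_to_average) {
    .ttm_stop(sprintf(
      "Only %d complete events detected; %d required for averaging.",
      sum(keep), config$events_to_average),
      "ttm_error_insufficient_events")
  }
  pass <- all(abs(diff(markers[keep]) - period) <=
                config$interpeak_tol * period)
  out <- tibble(onset = onsets[keep], marker = markers[keep],
                start = starts[keep])
  attr(out, "window") <- window
  attr(out, "period") <- period
  attr(out, "pass") <- pass
  attr(out, "pre") <- pre
  class(out) <- c("ttm_events", class(out))
  out
}

#' Average paced events into a representative beat
#'
#' Aligns the first `events_to_average` complete event windows at their
#' onsets and takes the pointwise mean. Recordings whose events failed the
#' pacing-consistency check are rejected rather than averaged.
#'
#' @param trace The `ttm_trace` the events were detected on.
#' @param events A `ttm_events` from [detect_events()].
#' @param config A [cleaning_config()].
#' @return A `ttm_trace` of one pacing period (the averaged beat), time
#'   origin 0.
#' @export
average_events <- function(trace, events, config = cleaning_config()) {
  if (!isTRUE(attr(events, "pass"))) {
    .ttm_stop(
      "Inter-onset intervals do not match the pacing frequency; recording rejected.",
      "ttm_error_interpeak")
  }
  k <- config$events_to_average
  if (nrow(events) < k) {
    .ttm_stop(sprintf("Need %d events, have %d.", k, nrow(events)),
              "ttm_error_insufficient_events")
  }
  window <- attr(events, "window")
  starts <- events$start[seq_len(k)]
  mat <- vapply(starts,
                function(s) trace$value[s:(s + window - 1L)],
                numeric(window))
  ttm_trace(rowMeans(mat), fps = trace_fps(trace),
            channel = trace_channel(trace), t0 = 0)
}

#' Run the full cleaning chain on one channel
#'
#' Applies, in order: ratiometric motion-artifact correction (AP and Ca,
#' when an MA trace is supplied), inversion (AP only), pseudo-ratio
#' dF/F_min (AP and Ca), the moving-average filter, event detection with
#' the pacing-consistency check, and event averaging. Contraction traces
#' skip correction, inversion and dF/F: they are filtered and
#' event-averaged identically.
#'
#' @param trace A raw `ttm_trace` (channel `AP`, `Ca` or `Co`).
#' @param ma Optional motion-artifact `ttm_trace` for ratiometric
#'   correction.
#' @param config A [cleaning_config()].
#' @return The averaged-beat `ttm_trace`.
#' @export
clean_trace <- function(trace, ma = NULL, config = cleaning_config()) {
  ch <- trace_channel(trace)
  x <- trace
  if (ch %in% c("AP", "Ca") && !is.null(ma)) {
    x <- ratiometric_correct(x, ma)
  }
  if (ch == "AP") x <- invert_trace(x)
  if (ch %in% c("AP", "Ca")) x <- delta_f_over_f(x)
  x <- moving_average(x, config$ma_window)
  ev <- detect_events(x, config)
  average_events(x, ev, config)
}
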