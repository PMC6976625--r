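#' Full-wave rectification
#'
#' Replaces every sample by its absolute value; rate, label and start time are
#' unchanged. First stage of the discharge-envelope chain.
#'
#' @param trace An `fl_trace`.
#' @return An `fl_trace` with nonnegative samples.
#' @export
rectify <- function(trace) {
  check_trace(trace)
  retrace(trace, abs(trace$value))
}

#' Median detrend
#'
#' Subtracts the channel median, the digital stand-in for slow baseline drift
#' removal applied before rectification.
#'
#' @inheritParams rectify
#' @return An `fl_trace` with median 0.
#' @export
detrend_median <- function(trace) {
  check_trace(trace)
  retrace(trace, trace$value - median(trace$value))
}

#' Weighted central moving average (Hamming window)
#'
#' Smooths a trace with a Hamming-weighted central moving average: each output
#' sample is the weighted mean of its neighbours under a Hamming window of
#' `window_len` samples, normalized to sum 1. Near the edges the weights are
#' renormalized over the available samples, which avoids the droop a
#' zero-padded convolution produces on short traces.
#'
#' @inheritParams rectify
#' @param window_len Odd window length in samples, between 1 and the trace
#'   length.
#' @return The smoothed `fl_trace`.
#' @export
smooth_wcma <- function(trace, window_len) {
  check_trace(trace)
  n <- nrow(trace)
  if (length(window_len) != 1 || window_len %% 2 != 1 ||
      window_len < 1 || window_len > n) {
    abort("`window_len` must be a single odd integer in [1, length(trace)]")
  }
  if (window_len == 1) return(retrace(trace, trace$value))
  w <- hamming_weights(window_len)
  num <- stats::filter(c(rep(0, (window_len - 1) / 2), trace$value,
                         rep(0, (window_len - 1) / 2)),
                       w, sides = 2)
  den <- stats::filter(c(rep(0, (window_len - 1) / 2), rep(1, n),
                         rep(0, (window_len - 1) / 2)),
                       w, sides = 2)
  half <- (window_len - 1) / 2
  keep <- seq.int(half + 1, half + n)
  retrace(trace, as.numeric(num[keep] / den[keep]))
}

# symmetric Hamming window normalized to sum 1
hamming_weights <- function(m) {
  k <- seq_len(m) - 1
  w <- 0.54 - 0.46 * cos(2 * pi * k / (m - 1))
  w / sum(w)
}

#' Resample a trace onto a uniform grid at a new rate
#'
#' Produces a uniformly sampled trace at `new_rate` over the same time span.
#' When downsampling, a zero-phase Hamming-windowed FIR low-pass (cutoff 90%
#' of the new Nyquist frequency, unit DC gain, odd-reflection edge padding)
#' is applied first so the decimation does not alias; samples are then taken
#' by linear interpolation on the new grid.
#'
#' @inheritParams rectify
#' @param new_rate Target sampling rate in Hz (> 0).
#' @return An `fl_trace` sampled at `new_rate`.
#' @export
resample_uniform <- function(trace, new_rate) {
  check_trace(trace)
  if (!is.numeric(new_rate) || length(new_rate) != 1 || new_rate <= 0) {
    abort("`new_rate` must be a single positive number (Hz)")
  }
  rate <- trace_rate(trace)
  if (isTRUE(all.equal(new_rate, rate))) {
    return(retrace(trace, trace$value))
  }
  x <- trace$value
  if (new_rate < rate) {
    x <- antialias_lowpass(x, rate, new_rate)
  }
  span <- (nrow(trace) - 1) / rate
  m <- floor(span * new_rate) + 1
  t_new <- (seq_len(m) - 1) / new_rate
  y <- approx((trace$time - trace_t0(trace)), x, xout = t_new)$y
  retrace(trace, y, rate = new_rate)
}

# symmetric (hence zero-phase) Hamming-windowed sinc low-pass, taps
# normalized to unit DC gain, edges handled by odd reflection; tap count
# scales with the decimation ratio so the transition band stays below the
# new Nyquist frequency
antialias_lowpass <- function(x, rate, new_rate) {
  half <- ceiling(10 * rate / new_rate)
  ntaps <- 2L * half + 1L
  n <- length(x)
  if (n <= ntaps + 1L) return(x)
  w <- signal::fir1(ntaps - 1L, 0.9 * new_rate / rate)
  w <- w / sum(w)
  xe <- c(2 * x[1] - x[(half + 1):2], x, 2 * x[n] - x[(n - 1):(n - half)])
  y <- stats::filter(xe, w, sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Discharge envelope of a raw ventral-root trace
#'
#' The preprocessing chain that turns a raw recording into a smooth,
#' nonnegative discharge envelope in which bursting appears as quasi-periodic
#' wave oscillation events: optional median detrend, full-wave rectification,
#' Hamming-window smoothing, and resampling to an analysis rate. The stages
#' are applied exactly in that order, so the result equals composing
#' [detrend_median()], [rectify()], [smooth_wcma()] and [resample_uniform()]
#' by hand.
#'
#' @inheritParams rectify
#' @param resample_rate Analysis sampling rate in Hz (default 200).
#' @param window_s Hamming smoothing window duration in seconds (default
#'   0.25 s, about 1/15 of the slowest expected locomotor cycle); rounded to
#'   the nearest odd sample count at the raw rate.
#' @param detrend If `TRUE` (default) subtract the channel median before
#'   rectifying.
#' @param subtract_baseline If `TRUE`, subtract the envelope median and clamp
#'   at zero (default `FALSE`).
#' @return An `fl_envelope`: nonnegative samples plus a provenance record
#'   (rectified, window length, resample rate, detrend and baseline flags).
#' @examples
#' tr <- new_trace(rnorm(4000), rate = 1000, channel = "RL2")
#' env <- envelope(tr)
#' envelope_provenance(env)
#' @export
envelope <- function(trace, resample_rate = 200, window_s = 0.25,
                     detrend = TRUE, subtract_baseline = FALSE) {
  check_trace(trace)
  rate <- trace_rate(trace)
  wl <- 2 * floor(window_s * rate / 2) + 1
  wl <- max(1L, min(wl, nrow(trace) - (1 - nrow(trace) %% 2)))
  if (wl %% 2 == 0) wl <- wl - 1
  x <- trace
  if (detrend) x <- detrend_median(x)
  x <- rectify(x)
  x <- smooth_wcma(x, wl)
  x <- resample_uniform(x, resample_rate)
  v <- x$value
  if (subtract_baseline) v <- pmax(v - median(v), 0)
  v <- pmax(v, 0) # rectified + positive-weight smoothing; guard roundoff
  new_envelope(v, trace_rate(x), trace_channel(trace), trace_t0(trace),
    provenance = list(
      rectified = TRUE, detrend = detrend,
      window_len = wl, window_s = wl / rate,
      source_rate = rate, resample_rate = resample_rate,
      baseline_subtracted = subtract_baseline
    ))
}

check_trace <- function(trace) {
  if (!inherits(trace, "fl_trace")) abort("expected an `fl_trace`")
  if (!all(is.finite(trace$value))) abort("trace samples must all be finite")
  invisible(trace)
}
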