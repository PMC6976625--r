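#' Detect locomotor bursts in a discharge envelope
#'
#' Quasi-periodic oscillation events are extracted with a robust two-threshold
#' (hysteresis) rule applied to the envelope's elevation above its baseline
#' median: a burst opens when the envelope exceeds `median + k_mad * MAD` and
#' closes when its elevation above the median falls below `hysteresis` times
#' the opening elevation (`median + hysteresis * k_mad * MAD`). Measuring the
#' closing level above baseline keeps the detector usable when the noise
#' floor itself sits well above zero. Events separated by gaps shorter than
#' `min_gap_s` are merged, then events shorter than `min_dur_s` are dropped.
#' Because both levels are derived from robust statistics of the data,
#' detection is invariant to uniform amplitude scaling of the envelope. For a
#' noiseless envelope whose MAD collapses to zero (a clean gate at duty below
#' 50%), the opening threshold falls back to half the maximum elevation above
#' the median.
#'
#' @param env An `fl_envelope` (a nonnegative `fl_trace` is accepted).
#' @param k_mad Threshold height in MADs above the median (default 3).
#' @param hysteresis Closing threshold as a fraction of the opening threshold
#'   (default 0.5).
#' @param min_dur_s Minimum burst duration in seconds (default 0.2).
#' @param min_gap_s Gaps shorter than this are merged (default 0.3 s).
#' @return An `fl_bursts` tibble with columns `onset`, `offset`, `peak`
#'   (seconds, seconds, envelope units), sorted and non-overlapping, carrying
#'   the channel label and threshold as attributes. A flat envelope yields an
#'   empty train with attribute `degenerate = TRUE` and a warning.
#' @examples
#' tr <- new_trace(rep(c(0, 1), each = 500, times = 4), rate = 100)
#' detect_bursts(envelope(tr, window_s = 0.05, detrend = FALSE))
#' @export
detect_bursts <- function(env, k_mad = 3, hysteresis = 0.5,
                          min_dur_s = 0.2, min_gap_s = 0.3) {
  check_trace(env)
  if (k_mad < 0 || hysteresis <= 0 || hysteresis > 1 ||
      min_dur_s < 0 || min_gap_s < 0) {
    abort("invalid burst-detector configuration")
  }
  v <- env$value
  med <- median(v)
  scale <- mad(v)
  if (scale > 0) {
    thr <- med + k_mad * scale
  } else if (max(v) > med) {
    # noiseless envelope (e.g. a clean gate at duty < 50%): MAD collapses to
    # zero, so fall back to half-maximum detection above the median
    thr <- med + 0.5 * (max(v) - med)
  } else {
    warn(sprintf("channel %s: flat envelope, no bursts", trace_channel(env)))
    return(empty_bursts(env, med, degenerate = TRUE))
  }
  lo <- med + hysteresis * (thr - med)
  if (!any(v > thr)) {
    warn(sprintf("channel %s: sub-threshold envelope, no bursts",
                 trace_channel(env)))
    return(empty_bursts(env, thr, degenerate = TRUE))
  }
  # vectorized hysteresis: state is last-observed crossing, carried forward
  s <- rep(NA_real_, length(v))
  s[v > thr] <- 1
  s[v < lo] <- 0
  if (is.na(s[1])) s[1] <- 0
  idx <- cummax(ifelse(is.na(s), 0L, seq_along(s)))
  state <- s[pmax(idx, 1L)]
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on_runs <- which(runs$values == 1)
  if (length(on_runs) == 0) {
    return(empty_bursts(env, thr, degenerate = FALSE))
  }
  dt <- 1 / trace_rate(env)
  t <- env$time
  onset <- t[starts[on_runs]]
  offset <- pmin(t[ends[on_runs]] + dt, t[length(t)])
  ev <- merge_gaps(onset, offset, min_gap_s)
  keep <- (ev$offset - ev$onset) >= min_dur_s
  ev <- ev[keep, , drop = FALSE]
  peak <- vapply(seq_len(nrow(ev)), function(i) {
    max(v[t >= ev$onset[i] & t <= ev$offset[i]])
  }, numeric(1))
  out <- tibble(onset = ev$onset, offset = ev$offset, peak = peak)
  structure(out,
    class = c("fl_bursts", class(out)),
    channel = trace_channel(env), threshold = thr,
    hysteresis = hysteresis, degenerate = FALSE,
    provenance = envelope_provenance(env)
  )
}

empty_bursts <- function(env, thr, degenerate) {
  out <- tibble(onset = numeric(), offset = numeric(), peak = numeric())
  structure(out,
    class = c("fl_bursts", class(out)),
    channel = trace_channel(env), threshold = thr,
    degenerate = degenerate, provenance = envelope_provenance(env)
  )
}

merge_gaps <- function(onset, offset, min_gap_s) {
  if (length(onset) <= 1) return(data.frame(onset = onset, offset = offset))
  keep_on <- onset[1]
  res_on <- c()
  res_off <- c()
  cur_off <- offset[1]
  for (i in seq_along(onset)[-1]) {
    if (onset[i] - cur_off < min_gap_s) {
      cur_off <- offset[i]
    } else {
      res_on <- c(res_on, keep_on)
      res_off <- c(res_off, cur_off)
      keep_on <- onset[i]
      cur_off <- offset[i]
    }
  }
  data.frame(onset = c(res_on, keep_on), offset = c(res_off, cur_off))
}

#' Per-burst timing metrics
#'
#' Cycle period is onset-to-onset (the convention that makes phase definitions
#' unambiguous); burst duration is offset minus onset; instantaneous cycle
#' frequency is the reciprocal period. The last event has no following onset,
#' so its period and frequency are `NA`.
#'
#' @param train An `fl_bursts` tibble from [detect_bursts()].
#' @return A tibble with one row per burst: `onset`, `offset`, `duration_s`,
#'   `period_s`, `freq_hz`, plus a logical `short_cycle` flagging events whose
#'   period is below half the median period (candidate extra bursts). With
#'   fewer than two events the period columns are all `NA`.
#' @export
burst_metrics <- function(train) {
  stopifnot(inherits(train, "fl_bursts"))
  n <- nrow(train)
  period <- if (n >= 2) c(diff(train$onset), NA_real_) else rep(NA_real_, n)
  med <- median(period, na.rm = TRUE)
  out <- tibble(
    onset = train$onset, offset = train$offset,
    duration_s = train$offset - train$onset,
    period_s = period,
    freq_hz = 1 / period,
    short_cycle = !is.na(period) & !is.na(med) & period < 0.5 * med
  )
  attr(out, "channel") <- attr(train, "channel")
  out
}

#' Instantaneous cycle frequencies of a burst train
#'
#' @param x An `fl_bursts` train or the tibble returned by [burst_metrics()].
#' @return Numeric vector of instantaneous frequencies in Hz (one per complete
#'   cycle).
#' @export
cycle_frequencies <- function(x) {
  if (inherits(x, "fl_bursts")) x <- burst_metrics(x)
  as.numeric(x$freq_hz[!is.na(x$freq_hz)])
}

#' Export / import a burst train as CSV
#'
#' @param train An `fl_bursts` tibble.
#' @param path CSV path; columns `channel`, `onset_s`, `offset_s`, `peak`.
#' @return `write_bursts()` the path, invisibly; `read_bursts()` an
#'   `fl_bursts` tibble.
#' @export
write_bursts <- function(train, path) {
  df <- data.frame(
    channel = attr(train, "channel") %||% "unlabeled",
    onset_s = sprintf("%.17g", train$onset),
    offset_s = sprintf("%.17g", train$offset),
    peak = sprintf("%.17g", train$peak)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bursts
#' @export
read_bursts <- function(path) {
  df <- read.csv(path)
  out <- tibble(onset = df$onset_s, offset = df$offset_s, peak = df$peak)
  structure(out,
    class = c("fl_bursts", class(out)),
    channel = if (nrow(df)) df$channel[1] else "unlabeled",
    threshold = NA_real_, degenerate = FALSE, provenance = NULL
  )
}
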