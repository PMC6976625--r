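#' Build a uniformly sampled voltage trace
#'
#' A trace is the basic container for one channel of an extracellular
#' ventral-root recording: a tibble with columns `time` (seconds) and `value`
#' (voltage, arbitrary units), uniformly sampled, carrying the sampling rate,
#' channel label and start time as attributes.
#'
#' @param samples Numeric vector of finite voltage samples (length >= 2), or a
#'   data frame with a `value` column.
#' @param rate Sampling rate in Hz (> 0).
#' @param channel Channel label, e.g. `"RL2"`, `"LL5"`, or `"unlabeled"`.
#'   Root labels encode side (L/R) and lumbar segment (L2/L5).
#' @param t0 Start time in seconds.
#' @return A tibble of class `fl_trace` with columns `time` and `value`.
#' @examples
#' tr <- new_trace(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), rate = 1000)
#' trace_rate(tr)
#' @export
new_trace <- function(samples, rate, channel = "unlabeled", t0 = 0) {
  if (is.data.frame(samples)) samples <- samples$value
  samples <- as.numeric(samples)
  if (length(samples) < 2) abort("a trace needs at least 2 samples")
  if (!all(is.finite(samples))) abort("trace samples must all be finite")
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz)")
  }
  out <- tibble(
    time = t0 + (seq_along(samples) - 1) / rate,
    value = samples
  )
  structure(out,
    class = c("fl_trace", class(out)),
    rate = rate, channel = as.character(channel)[1], t0 = t0
  )
}

new_envelope <- function(samples, rate, channel, t0, provenance) {
  stopifnot(all(samples >= 0))
  out <- new_trace(samples, rate, channel, t0)
  structure(out,
    class = unique(c("fl_envelope", class(out))),
    provenance = provenance
  )
}

#' Trace metadata accessors
#'
#' @param x An `fl_trace` (or `fl_envelope`).
#' @return `trace_rate()` the sampling rate in Hz; `trace_channel()` the
#'   channel label; `trace_t0()` the start time in seconds;
#'   `envelope_provenance()` the preprocessing record of an envelope.
#' @export
trace_rate <- function(x) attr(x, "rate")

#' @rdname trace_rate
#' @export
trace_channel <- function(x) attr(x, "channel") %||% "unlabeled"

#' @rdname trace_rate
#' @export
trace_t0 <- function(x) attr(x, "t0") %||% 0

#' @rdname trace_rate
#' @export
envelope_provenance <- function(x) attr(x, "provenance")

#' Side and segment of a root label
#'
#' Parses labels of the form `"RL2"`, `"LL5"` into side (`"L"`/`"R"`) and
#' lumbar segment (`"L2"`/`"L5"`).
#'
#' @param channel Character vector of channel labels.
#' @return A tibble with columns `channel`, `side`, `segment` (NA when
#'   unlabeled).
#' @export
parse_root_label <- function(channel) {
  ok <- grepl("^[LR]L[25]$", channel)
  tibble(
    channel = channel,
    side = ifelse(ok, substr(channel, 1, 1), NA_character_),
    segment = ifelse(ok, substr(channel, 2, 3), NA_character_)
  )
}

#' @export
print.fl_trace <- function(x, ...) {
  cat(sprintf(
    "<%s> channel %s, %d samples @ %g Hz, t0 = %g s\n",
    if (inherits(x, "fl_envelope")) "envelope" else "trace",
    trace_channel(x), nrow(x), trace_rate(x), trace_t0(x)
  ))
  NextMethod()
}

# rebuild a trace of the same flavour as `template` with new samples/rate
retrace <- function(template, samples, rate = trace_rate(template),
                    provenance = NULL) {
  if (inherits(template, "fl_envelope") || !is.null(provenance)) {
    new_envelope(samples, rate, trace_channel(template), trace_t0(template),
      provenance %||% envelope_provenance(template))
  } else {
    new_trace(samples, rate, trace_channel(template), trace_t0(template))
  }
}

#' Write and read multi-channel trace files
#'
#' Recordings are stored as plain CSV, one column per channel (header carries
#' the root labels, e.g. `RL2,LL2,RL5,LL5`), with a YAML sidecar holding
#' `rate_hz`, `units`, `t0_s` and free-form metadata (`genotype`, `prep_id`).
#' Samples are written in full double precision so a write/read round trip is
#' exact.
#'
#' @param traces Named list of `fl_trace` objects sharing rate, length and t0.
#' @param path Path of the CSV file; the sidecar is written next to it as
#'   `<path>.meta.yaml`.
#' @param meta Named list of extra metadata for the sidecar.
#' @return `write_traces()` returns `path` invisibly; `read_traces()` returns
#'   a named list of `fl_trace`.
#' @export
write_traces <- function(traces, path, meta = list()) {
  stopifnot(is.list(traces), length(traces) >= 1, !is.null(names(traces)))
  rates <- vapply(traces, trace_rate, numeric(1))
  lens <- vapply(traces, nrow, integer(1))
  if (length(unique(rates)) != 1 || length(unique(lens)) != 1) {
    abort("all channels must share one rate and length")
  }
  cols <- lapply(traces, function(tr) sprintf("%.17g", tr$value))
  df <- as.data.frame(cols, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- c(
    list(rate_hz = unname(rates[1]), units = "au",
         t0_s = trace_t0(traces[[1]])),
    meta
  )
  yaml::write_yaml(side, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  df <- read.csv(path, check.names = FALSE)
  out <- lapply(names(df), function(ch) {
    new_trace(df[[ch]], rate = meta$rate_hz, channel = ch,
              t0 = meta$t0_s %||% 0)
  })
  names(out) <- names(df)
  attr(out, "meta") <- meta
  out
}
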