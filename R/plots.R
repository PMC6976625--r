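#' Plot methods
#'
#' `autoplot()` methods render each result type as a ggplot: traces and
#' envelopes as time series (optionally with detected bursts shaded), phase
#' samples as circular diagrams, correlograms and frequency densities as
#' curves, and soma densities as heat maps with marginals alongside.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name fictloc-plots
NULL

#' @rdname fictloc-plots
#' @param bursts Optional `fl_bursts` train to shade onto the trace.
#' @export
autoplot.fl_trace <- function(object, bursts = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)",
                  title = trace_channel(object))
  if (!is.null(bursts) && nrow(bursts)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(bursts),
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    )
  }
  p
}

#' @rdname fictloc-plots
#' @export
autoplot.fl_phases <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phase_deg)) +
    ggplot2::geom_histogram(breaks = seq(0, 360, by = 15),
                            fill = "steelblue", colour = "white") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "cycles",
                  title = attr(object, "pair") %||% "phase distribution")
}

#' @rdname fictloc-plots
#' @export
autoplot.fl_correlogram <- function(object, ...) {
  ggplot2::ggplot(object$corr, ggplot2::aes(.data$lag_s, .data$coef)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_lag_s,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "lag (s)", y = "correlation",
                  title = sprintf("%s  (CCC = %.2f)",
                                  object$pair, object$ccc_index))
}

#' @rdname fictloc-plots
#' @export
autoplot.fl_modes <- function(object, ...) {
  ggplot2::ggplot(object$density, ggplot2::aes(.data$freq_hz, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$modes, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "cycle frequency (Hz)", y = "density (peak = 1)")
}

#' @rdname fictloc-plots
#' @export
autoplot.fl_density <- function(object, ...) {
  ggplot2::ggplot(object$map, ggplot2::aes(.data$ml, .data$dv,
                                           fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(x = "ML (fraction of hemicord width)",
                  y = "DV (fraction of cord height)", fill = "density")
}

#' @rdname fictloc-plots
#' @export
autoplot.fl_rhythmicity <- function(object, ...) {
  ggplot2::ggplot(object$corr, ggplot2::aes(.data$lag_s, .data$coef)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$period_s,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "lag (s)", y = "autocorrelation",
                  title = sprintf("%s  (rhythmicity %.2f, period %.2f s)",
                                  object$channel, object$index,
                                  object$period_s))
}
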