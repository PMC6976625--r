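#' Broom-style tidiers
#'
#' `tidy()` returns one row per statistic; `glance()` returns a one-row
#' model-level summary.
#'
#' @param x An `fl_htest`, `fl_rhythmicity`, `fl_correlogram` or `fl_swim`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name fictloc-tidiers
NULL

#' @rdname fictloc-tidiers
#' @export
tidy.fl_htest <- function(x, ...) {
  tibble(
    method = x$method,
    statistic = x$statistic,
    statistic_name = x$statistic_name,
    p.value = x$p.value,
    n1 = x$n1 %||% NA_integer_,
    n2 = x$n2 %||% NA_integer_
  )
}

#' @rdname fictloc-tidiers
#' @export
glance.fl_htest <- function(x, ...) {
  out <- tidy(x)
  if (!is.null(x$df1)) out$df1 <- x$df1
  if (!is.null(x$df2)) out$df2 <- x$df2
  out
}

#' @rdname fictloc-tidiers
#' @export
tidy.fl_rhythmicity <- function(x, ...) {
  tibble(channel = x$channel, rhythmicity = x$index,
         period_s = x$period_s, rhythmic = x$rhythmic)
}

#' @rdname fictloc-tidiers
#' @export
tidy.fl_correlogram <- function(x, ...) {
  tibble(pair = x$pair, ccc_index = x$ccc_index,
         peak_lag_s = x$peak_lag_s, cycle_period_s = x$cycle_period_s)
}

#' @rdname fictloc-tidiers
#' @export
tidy.fl_swim <- function(x, ...) {
  tibble(mean_period_s = x$mean_period_s,
         n_cycles = nrow(x$phases),
         missed = x$missed,
         miss_ratio_per_s = x$miss_ratio_per_s)
}

#' @rdname fictloc-tidiers
#' @export
glance.fl_swim <- function(x, ...) {
  cs <- circular_stats(x$phases)
  dplyr::bind_cols(tidy(x),
                   tibble(mean_phase_deg = cs$mean_deg, R = cs$R))
}
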