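#' Swim cycle-period and alternation metrics for one bout
#'
#' Hindlimb tracking of neonatal swimming yields, per limb, the times of full
#' flexion and full extension. Cycle periods are the successive full-flexion
#' intervals of each limb; left-right coordination is quantified by the
#' per-cycle phase of the right-hindlimb flexion within the left-hindlimb
#' cycle (same estimator as [pair_phases()]). A cycle is a missed alternation
#' when its phase falls outside the half-cycle window `[90, 270]` degrees,
#' and the miss ratio is the missed count divided by the mean cycle period.
#'
#' @param bout Data frame with columns `limb` (`"LH"`, `"RH"`), `event`
#'   (`"full_flexion"`, `"full_extension"`), `time_s`, and optionally `x`,
#'   `y` image coordinates. Times must be strictly increasing within a limb
#'   and event types must alternate.
#' @param cycle_event Event defining a cycle (default `"full_flexion"`).
#' @param window_deg Alternation window in degrees (default `c(90, 270)`).
#' @return A list of class `fl_swim`: `per_limb` (tibble `limb`, `n_cycles`,
#'   `mean_period_s`, `cv_period`), `phases` (`fl_phases`, LH reference),
#'   `mean_period_s` (both limbs pooled), `missed`, `miss_ratio_per_s`.
#' @export
swim_metrics <- function(bout, cycle_event = "full_flexion",
                         window_deg = c(90, 270)) {
  bout <- as_tibble(bout)
  need <- c("limb", "event", "time_s")
  if (!all(need %in% names(bout))) {
    abort(paste("bout needs columns:", paste(need, collapse = ", ")))
  }
  check_bout(bout)
  flex <- function(l) {
    sort(bout$time_s[bout$limb == l & bout$event == cycle_event])
  }
  lh <- flex("LH")
  rh <- flex("RH")
  if (length(lh) < 3 || length(rh) < 3) {
    abort(sprintf("need at least 3 %s events per limb", cycle_event))
  }
  per_limb <- purrr::map_dfr(list(LH = lh, RH = rh), function(t) {
    p <- diff(t)
    tibble(n_cycles = length(p), mean_period_s = mean(p),
           cv_period = sd(p) / mean(p))
  }, .id = "limb")
  ph <- pair_phases(lh, rh, pair = "LH/RH")
  missed <- sum(ph$phase_deg < window_deg[1] | ph$phase_deg > window_deg[2]) +
    attr(ph, "n_skipped")
  mean_period <- mean(c(diff(lh), diff(rh)))
  structure(list(
    per_limb = per_limb, phases = ph,
    mean_period_s = mean_period,
    missed = missed,
    miss_ratio_per_s = missed / mean_period
  ), class = "fl_swim")
}

check_bout <- function(bout) {
  for (l in unique(bout$limb)) {
    sub <- bout[bout$limb == l, ]
    sub <- sub[order(sub$time_s), ]
    if (any(diff(sub$time_s) <= 0)) {
      abort(sprintf("limb %s: event times must be strictly increasing", l))
    }
    if (any(sub$event[-1] == sub$event[-nrow(sub)])) {
      abort(sprintf("limb %s: flexion/extension events must alternate", l))
    }
  }
  invisible(bout)
}

#' @export
print.fl_swim <- function(x, ...) {
  cat(sprintf(
    "<swim bout> mean cycle period %.3f s, %d missed alternation(s), miss ratio %.3f /s\n",
    x$mean_period_s, x$missed, x$miss_ratio_per_s
  ))
  invisible(x)
}

#' Vestibulospinal reflex paw displacement
#'
#' The reflex test rotates the pup 90 degrees and measures how far the
#' hindpaw travels between the start of the rotation and maximal extension.
#' The end frame is rotated 90 degrees counterclockwise about the image
#' center so both frames share one orientation (in centered coordinates
#' `(x, y) -> (-y, x)`), an optional manual alignment translation is applied,
#' and the Euclidean distance between the paw positions is returned. When no
#' extension occurred the end point is taken from the frame at 200 ms and the
#' measurement is flagged.
#'
#' @param start_paw,end_paw Numeric `(x, y)` paw coordinates in the start
#'   frame and end frame (pixels or mm).
#' @param center Image center used as the rotation origin (default `c(0, 0)`,
#'   i.e. coordinates already centered).
#' @param alignment Translation `(dx, dy)` applied to the rotated end frame
#'   (the manual overlay re-alignment; default none).
#' @param no_extension Set when no extension was detected and `end_paw` comes
#'   from the 200 ms frame.
#' @return A one-row tibble: `distance`, `end_x`, `end_y` (rotated, aligned
#'   end-paw position), `no_extension`.
#' @examples
#' vestibulo_displacement(c(1, 0), c(0, 1)) # rotated end (-1, 0): distance 2
#' @export
vestibulo_displacement <- function(start_paw, end_paw, center = c(0, 0),
                                   alignment = c(0, 0), no_extension = FALSE) {
  pts <- list(start_paw = start_paw, end_paw = end_paw,
              center = center, alignment = alignment)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (length(p) != 2 || !all(is.finite(p))) {
      abort(sprintf("`%s` must be two finite coordinates", nm))
    }
  }
  rel <- end_paw - center
  rot <- c(-rel[2], rel[1]) + center + alignment
  tibble(
    distance = sqrt(sum((start_paw - rot)^2)),
    end_x = rot[1], end_y = rot[2],
    no_extension = isTRUE(no_extension)
  )
}

#' Read a swim-event table
#'
#' CSV columns: `limb`, `event`, `time_s`, and optional `x`, `y`.
#'
#' @param path CSV file path.
#' @return A tibble of swim events, validated for ordering and alternation.
#' @export
read_swim_events <- function(path) {
  df <- as_tibble(read.csv(path))
  check_bout(df)
  df
}
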