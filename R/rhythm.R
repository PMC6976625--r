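#' Per-cycle phases of one root relative to another
#'
#' For each reference cycle `[onset_k, onset_{k+1})`, the phase of the target
#' root is `360 * (t - onset_k) / period_k` degrees, where `t` is the first
#' target onset falling inside the cycle. Cycles containing no target onset
#' are skipped and counted (this tolerates occasional extra or missing
#' bursts). 0 degrees means synchrony, 180 degrees strict alternation.
#'
#' @param reference,target `fl_bursts` trains (or bare numeric onset vectors).
#' @param pair Optional label for the ordered pair; defaults to
#'   `"<ref>/<target>"` from the channel attributes.
#' @return An `fl_phases` tibble with columns `cycle`, `ref_onset`,
#'   `period_s`, `phase_deg` (in `[0, 360)`), carrying `pair` and `n_skipped`
#'   attributes. Disjoint spans yield an empty sample with a warning.
#' @examples
#' ref <- seq(0, 40, by = 4)
#' pair_phases(ref, ref + 2) # alternation: all phases 180
#' @export
pair_phases <- function(reference, target, pair = NULL) {
  ref_lab <- if (inherits(reference, "fl_bursts")) attr(reference, "channel") else "ref"
  tar_lab <- if (inherits(target, "fl_bursts")) attr(target, "channel") else "target"
  ref <- onsets_of(reference)
  tar <- onsets_of(target)
  pair <- pair %||% paste0(ref_lab, "/", tar_lab)
  if (length(ref) < 2 || length(tar) < 1 ||
      max(tar) < ref[1] || min(tar) >= ref[length(ref)]) {
    if (length(ref) >= 2 && length(tar) >= 1) {
      warn(sprintf("pair %s: reference and target spans are disjoint", pair))
    }
    return(new_phases(tibble(cycle = integer(), ref_onset = numeric(),
                             period_s = numeric(), phase_deg = numeric()),
                      pair, n_skipped = max(0L, length(ref) - 1L)))
  }
  k <- seq_len(length(ref) - 1)
  first_in <- findInterval(ref[k], tar) + 1L # first target onset >= ref onset
  t_tar <- ifelse(first_in <= length(tar), tar[first_in], NA_real_)
  period <- diff(ref)
  inside <- !is.na(t_tar) & t_tar < ref[k + 1]
  phase <- 360 * (t_tar - ref[k]) / period
  out <- tibble(
    cycle = k[inside],
    ref_onset = ref[k][inside],
    period_s = period[inside],
    phase_deg = phase[inside] %% 360
  )
  new_phases(out, pair, n_skipped = sum(!inside))
}

onsets_of <- function(x) {
  if (inherits(x, "fl_bursts")) sort(x$onset) else sort(as.numeric(x))
}

new_phases <- function(df, pair, n_skipped) {
  structure(df,
    class = unique(c("fl_phases", class(df))),
    pair = pair, n_skipped = n_skipped
  )
}

#' Circular summary statistics and Rayleigh test of a phase sample
#'
#' Computes the circular mean direction, the mean resultant length R, the
#' circular standard deviation `sqrt(-2 log R)` (in degrees), and the Rayleigh
#' test of non-uniformity. The Rayleigh p-value uses the standard series
#' approximation with the small-sample correction; `method = "simulation"`
#' replaces it with a Monte Carlo p-value under uniformity, useful below about
#' n = 10.
#'
#' @param phases An `fl_phases` tibble or a numeric vector of phases in
#'   degrees.
#' @param method `"asymptotic"` (default) or `"simulation"`.
#' @param n_sim Monte Carlo replicates for `method = "simulation"`.
#' @return A one-row tibble: `pair`, `n`, `mean_deg` (in `[0, 360)`, `NA` when
#'   the resultant is numerically zero), `R`, `circ_sd_deg`, `rayleigh_z`,
#'   `rayleigh_p`, `n_skipped`.
#' @export
circular_stats <- function(phases, method = c("asymptotic", "simulation"),
                           n_sim = 9999) {
  method <- match.arg(method)
  deg <- if (is.data.frame(phases)) phases$phase_deg else as.numeric(phases)
  n <- length(deg)
  if (n < 2) abort("need at least 2 phases")
  rad <- deg * pi / 180
  C <- mean(cos(rad))
  S <- mean(sin(rad))
  R <- sqrt(C^2 + S^2)
  mean_deg <- if (R < 1e-8) NA_real_ else (atan2(S, C) * 180 / pi) %% 360
  circ_sd <- sqrt(pmax(-2 * log(pmax(R, .Machine$double.xmin)), 0)) * 180 / pi
  z <- n * R^2
  if (method == "asymptotic") {
    p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                      (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
    p <- min(max(p, 0), 1)
  } else {
    r_sim <- vapply(seq_len(n_sim), function(i) {
      a <- runif(n, 0, 2 * pi)
      sqrt(mean(cos(a))^2 + mean(sin(a))^2)
    }, numeric(1))
    p <- (1 + sum(r_sim >= R)) / (n_sim + 1)
  }
  tibble(
    pair = attr(phases, "pair") %||% NA_character_,
    n = n, mean_deg = mean_deg, R = R,
    circ_sd_deg = if (R < 1e-8) Inf else circ_sd,
    rayleigh_z = z, rayleigh_p = p,
    n_skipped = attr(phases, "n_skipped") %||% NA_integer_
  )
}

#' Normalized cross-correlogram and CCC rhythm-strength index
#'
#' Computes the Pearson-normalized cross-correlation between two envelopes
#' over lags in `[-max_lag_s, +max_lag_s]` after mean removal: at each lag the
#' coefficient is the exact Pearson correlation of the overlapping segments,
#' so it always lies in `[-1, 1]` and equals 1 at lag 0 for a trace with
#' itself. Positive lag means `b` follows `a`.
#'
#' The cross-correlation coefficient index (CCC, a bounded, unit-free summary
#' of rhythm strength) is the signed mean of the correlogram over a window of
#' half a mean cycle period centered on lag 0 (lags within a quarter period
#' of zero). Over that window a synchronous rhythmic pair averages strongly
#' positive, an alternating pair strongly negative, and an arrhythmic pair
#' near zero; averaging over a full period would cancel the oscillation and
#' return ~0 for every pair. `peak_lag_s` is the lag of the local maximum
#' nearest zero.
#'
#' @param a,b `fl_envelope`s (or `fl_trace`s) at the same rate.
#' @param max_lag_s Maximum lag in seconds (default 10).
#' @param cycle_period_s Mean cycle period used for the CCC window; when
#'   `NULL` it is estimated from the autocorrelation of `a`.
#' @return A list of class `fl_correlogram`: `corr` (tibble `lag_s`, `coef`),
#'   `ccc_index`, `peak_lag_s`, `cycle_period_s`, `pair`.
#' @export
cross_correlogram <- function(a, b, max_lag_s = 10, cycle_period_s = NULL) {
  check_trace(a); check_trace(b)
  if (!isTRUE(all.equal(trace_rate(a), trace_rate(b)))) {
    abort("envelopes must share one sampling rate")
  }
  n <- min(nrow(a), nrow(b))
  if (sd(a$value[1:n]) == 0 || sd(b$value[1:n]) == 0) {
    abort("zero-variance input")
  }
  rate <- trace_rate(a)
  L <- min(floor(max_lag_s * rate), n - 3)
  x <- a$value[1:n]
  y <- b$value[1:n]
  cc <- lagged_pearson(x, y, L)
  lags <- (-L:L) / rate
  if (is.null(cycle_period_s)) {
    ac <- autocorr_rhythmicity(a, max_lag_s = max_lag_s)
    cycle_period_s <- ac$period_s
  }
  pk <- nearest_local_max(lags, cc)
  ccc <- ccc_index(lags, cc, cycle_period_s)
  structure(list(
    corr = tibble(lag_s = lags, coef = cc),
    ccc_index = ccc, peak_lag_s = pk,
    cycle_period_s = cycle_period_s,
    pair = paste0(trace_channel(a), "/", trace_channel(b))
  ), class = "fl_correlogram")
}

# exact Pearson correlation of the overlapping segments at each lag in -L..L,
# computed with one FFT cross-product plus prefix sums (O(n log n + L))
lagged_pearson <- function(x, y, L) {
  n <- length(x)
  z <- stats::convolve(x, y, type = "open") # z[n - l] = sum x_i y_{i+l}
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2)
  one_lag <- function(l) {
    if (l >= 0) {
      m <- n - l
      sx <- cx[m]; sx2 <- cx2[m]
      sy <- cy[n] - if (l > 0) cy[l] else 0
      sy2 <- cy2[n] - if (l > 0) cy2[l] else 0
    } else {
      m <- n + l
      sx <- cx[n] - cx[-l]; sx2 <- cx2[n] - cx2[-l]
      sy <- cy[m]; sy2 <- cy2[m]
    }
    sxy <- z[n - l]
    num <- sxy - sx * sy / m
    den <- sqrt(max(sx2 - sx^2 / m, 0) * max(sy2 - sy^2 / m, 0))
    if (den <= 0) 0 else max(min(num / den, 1), -1)
  }
  vapply(-L:L, one_lag, numeric(1))
}

# lag of the local maximum nearest zero; micro-ripple is screened out by
# requiring a topographic prominence of 5% of the correlogram's range
nearest_local_max <- function(lags, cc) {
  m <- length(cc)
  is_max <- c(FALSE, cc[2:(m - 1)] > cc[1:(m - 2)] &
                cc[2:(m - 1)] >= cc[3:m], FALSE)
  idx <- which(is_max)
  if (length(idx)) {
    prom_min <- 0.05 * diff(range(cc))
    idx <- idx[vapply(idx, function(i) prominence(cc, i) >= prom_min,
                      logical(1))]
  }
  if (!length(idx)) return(lags[which.max(cc)])
  cand <- lags[idx]
  cand[order(abs(cand), -sign(cand))][1]
}

ccc_index <- function(lags, cc, period_s) {
  if (is.null(period_s) || !is.finite(period_s) || period_s <= 0) {
    period_s <- 2 * max(abs(lags))
  }
  win <- abs(lags) <= period_s / 4
  mean(cc[win])
}

#' Autocorrelation rhythmicity index
#'
#' The normalized autocorrelogram of the envelope is scanned for its first
#' local maximum at positive lag past the central lobe; the height of that
#' peak is the rhythmicity index (1 = perfectly periodic, about 0 for
#' aperiodic discharge) and its lag estimates the cycle period. The envelope
#' is called rhythmic when the index exceeds 0.2.
#'
#' @param env An `fl_envelope` with nonzero variance.
#' @param max_lag_s Longest lag scanned, seconds (default 30 or half the
#'   span, whichever is smaller).
#' @return A list of class `fl_rhythmicity`: `index`, `period_s`, `rhythmic`,
#'   `corr` (tibble `lag_s`, `coef`), `channel`.
#' @export
autocorr_rhythmicity <- function(env, max_lag_s = 30) {
  check_trace(env)
  v <- env$value
  if (sd(v) == 0) abort("constant envelope: autocorrelation undefined")
  rate <- trace_rate(env)
  L <- min(floor(max_lag_s * rate), length(v) - 3)
  cc <- lagged_pearson(v, v, L)
  pos <- cc[(L + 2):(2 * L + 1)] # lags 1..L
  m <- length(pos)
  loc_max <- which(pos[2:(m - 1)] > pos[1:(m - 2)] &
                     pos[2:(m - 1)] >= pos[3:m]) + 1L
  if (length(loc_max)) { # screen out micro-ripple on flat stretches
    prom_min <- 0.05 * diff(range(pos))
    loc_max <- loc_max[vapply(loc_max, function(i)
      prominence(pos, i) >= prom_min, logical(1))]
  }
  if (length(loc_max) == 0) {
    idx <- which.max(pos)
  } else {
    idx <- loc_max[1]
  }
  index <- pos[idx]
  structure(list(
    index = index, period_s = idx / rate,
    rhythmic = index > 0.2,
    corr = tibble(lag_s = (-L:L) / rate, coef = cc),
    channel = trace_channel(env)
  ), class = "fl_rhythmicity")
}

#' Kernel-density mode structure of a cycle-frequency sample
#'
#' Gaussian kernel density of the instantaneous cycle frequencies on a fixed
#' grid from 0 to the sample maximum plus four bandwidths, rescaled so the
#' peak equals 1 (the convention used for frequency-distribution plots).
#' Modes are the local maxima whose topographic prominence is at least 20% of
#' the peak, reported in ascending order; this separates genuine slow/fast
#' locomotor modes from ripple.
#'
#' @param freqs Numeric vector of instantaneous cycle frequencies in Hz
#'   (n >= 5), e.g. from [cycle_frequencies()].
#' @param bandwidth Gaussian kernel standard deviation in Hz (default
#'   0.02); `NULL` falls back to Silverman's rule.
#' @param grid_n Grid resolution (default 512).
#' @return A list of class `fl_modes`: `density` (tibble `freq_hz`,
#'   `density`, peak-normalized), `modes` (Hz, ascending), `bandwidth_hz`.
#' @export
frequency_modes <- function(freqs, bandwidth = 0.02, grid_n = 512) {
  freqs <- as.numeric(freqs)
  if (length(freqs) < 5) abort("need at least 5 frequency values")
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    abort("frequencies must be finite and positive")
  }
  bw <- bandwidth %||% stats::bw.nrd0(freqs)
  if (bw <= 0) abort("`bandwidth` must be positive")
  d <- density(freqs, bw = bw, kernel = "gaussian",
               from = 0, to = max(freqs) + 4 * bw, n = grid_n)
  y <- d$y / max(d$y)
  modes <- d$x[find_modes(y, min_prominence = 0.2)]
  structure(list(
    density = tibble(freq_hz = d$x, density = y),
    modes = sort(modes), bandwidth_hz = bw
  ), class = "fl_modes")
}

# indices of local maxima with topographic prominence >= min_prominence
find_modes <- function(y, min_prominence) {
  m <- length(y)
  cand <- which(y[2:(m - 1)] > y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m]) + 1L
  if (y[1] > y[2]) cand <- c(1L, cand)
  if (y[m] > y[m - 1]) cand <- c(cand, m)
  keep <- vapply(cand, function(i) prominence(y, i) >= min_prominence,
                 logical(1))
  cand[keep]
}

# topographic prominence: walk outward to the nearest strictly higher sample;
# the base on each side is the minimum met on the way (the whole side if none
# is higher); prominence is the drop to the higher of the two bases
prominence <- function(y, i) {
  h <- y[i]
  side_base <- function(seg) {
    if (length(seg) == 0) return(-Inf)
    hi <- which(seg > h)
    if (length(hi) == 0) min(seg) else min(seg[seq_len(hi[1])])
  }
  lb <- side_base(rev(y[seq_len(i - 1)]))
  rb <- side_base(if (i < length(y)) y[(i + 1):length(y)] else numeric())
  h - max(lb, rb)
}

#' Two-sample Kolmogorov-Smirnov comparison of frequency distributions
#'
#' Compares two empirical cycle-frequency distributions with the two-sample
#' Kolmogorov-Smirnov test (asymptotic p-value): D is the supremum distance
#' between the two empirical CDFs.
#'
#' @param a,b Numeric samples (each n >= 2), e.g. pooled instantaneous cycle
#'   frequencies of two genotype groups.
#' @return An `fl_htest` with `statistic` (D), `p.value`, `n1`, `n2`.
#' @export
ks_compare <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) abort("each sample needs n >= 2")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  new_htest(
    method = "Two-sample Kolmogorov-Smirnov test",
    statistic = unname(kt$statistic), statistic_name = "D",
    p.value = unname(kt$p.value),
    n1 = length(a), n2 = length(b)
  )
}

new_htest <- function(method, statistic, statistic_name, p.value, ...) {
  structure(
    list(method = method, statistic = statistic,
         statistic_name = statistic_name, p.value = p.value, ...),
    class = "fl_htest"
  )
}

#' @export
print.fl_htest <- function(x, ...) {
  cat(sprintf("%s\n  %s = %.4g, p = %.4g\n",
              x$method, x$statistic_name, x$statistic, x$p.value))
  invisible(x)
}
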