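#' Simulation configuration
#'
#' Collects every knob of the seeded generators with validated defaults. The
#' defaults describe a typical drug-evoked fictive-locomotion preparation:
#' four ventral roots (RL2, LL2, RL5, LL5) bursting at about 0.25 Hz with
#' left-right and flexor-extensor alternation and diagonal synchrony, plus
#' two-cluster soma distributions and alternating swim bouts.
#'
#' @param seed Integer seed; every generator is fully reproducible from it.
#' @param rate_hz Simulated sampling rate (default 1000 Hz; configurable up
#'   to acquisition fidelity).
#' @param duration_s Recording length (default 256 s, about 60 cycles at the
#'   default period).
#' @param period_s Mean locomotor cycle period for the fixed-period process
#'   (default 4 s).
#' @param t_slow_s,t_fast_s,p_switch Two-state Markov cycle process: slow and
#'   fast mean periods and the per-cycle switching probability. When
#'   `t_slow_s` is `NULL` (default) the process is fixed-period.
#' @param jitter_cv Coefficient of variation of the cycle period (default
#'   0.05).
#' @param duty Burst duration as a fraction of the cycle (default 0.35).
#' @param phase_offsets_deg Named per-channel phase offsets in degrees
#'   (defaults: RL2 0, LL2 180, RL5 180, LL5 0 — left-right and
#'   flexor-extensor alternation, diagonal synchrony).
#' @param amplitude Burst envelope amplitude (a.u.).
#' @param noise_sd Baseline Gaussian noise SD (default 0.05 -> SNR about 10
#'   in the carrier band).
#' @param carrier_band_hz Band of the within-burst noise carrier (default
#'   50-450 Hz).
#' @param extra_burst_prob Per-cycle probability of an extra (non-locomotor)
#'   burst; applied to RL5, and at half this rate to LL5 (default 0).
#' @param n_cells,cluster_weights,cluster_means,cluster_sds Soma-position
#'   mixture: cell count, mixture weights, per-cluster `(ml, dv)` means and
#'   SDs. Defaults: a major central cluster at (0.50, 0.35), weight 0.75, and
#'   a minor medial cluster at (0.15, 0.40), weight 0.25, SD 0.08 (declared
#'   fixture values, not measurements).
#' @param h_range_um,w_range_um Section height / hemicord width ranges used
#'   to invert the normalization (µm).
#' @param n_embryos Embryos the cells are attributed to (default 4).
#' @param swim_n_cycles,swim_period_s,swim_jitter_cv Swim bout: cycle count,
#'   mean cycle period (default 0.5 s) and period CV.
#' @param lapse_prob Per-cycle probability of entering an alternation lapse.
#' @param lapse_run_mean Mean lapse run length in cycles (geometric).
#' @param swim_phase_jitter_deg SD of the per-cycle phase jitter of the right
#'   hindlimb (default 10 degrees).
#' @return A validated list of class `fl_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       rate_hz = 1000, duration_s = 256,
                       period_s = 4, t_slow_s = NULL, t_fast_s = NULL,
                       p_switch = 0.1, jitter_cv = 0.05, duty = 0.35,
                       phase_offsets_deg = c(RL2 = 0, LL2 = 180,
                                             RL5 = 180, LL5 = 0),
                       amplitude = 1, noise_sd = 0.05,
                       carrier_band_hz = c(50, 450),
                       extra_burst_prob = 0,
                       n_cells = 300,
                       cluster_weights = c(central = 0.75, medial = 0.25),
                       cluster_means = list(central = c(0.50, 0.35),
                                            medial = c(0.15, 0.40)),
                       cluster_sds = c(central = 0.08, medial = 0.08),
                       h_range_um = c(380, 480), w_range_um = c(280, 380),
                       n_embryos = 4,
                       swim_n_cycles = 40, swim_period_s = 0.5,
                       swim_jitter_cv = 0.05,
                       lapse_prob = 0, lapse_run_mean = 2,
                       swim_phase_jitter_deg = 10) {
  cfg <- as.list(environment())
  stopifnot(
    rate_hz > 0, duration_s > 0, period_s > 0, jitter_cv >= 0,
    duty > 0, duty < 1, amplitude > 0, noise_sd >= 0,
    length(carrier_band_hz) == 2, all(carrier_band_hz > 0),
    carrier_band_hz[1] < carrier_band_hz[2],
    carrier_band_hz[2] < rate_hz / 2,
    p_switch >= 0, p_switch <= 1,
    extra_burst_prob >= 0, extra_burst_prob <= 1,
    n_cells >= 1, all(cluster_sds > 0),
    swim_n_cycles >= 3, swim_period_s > 0, swim_jitter_cv >= 0,
    lapse_prob >= 0, lapse_prob <= 1, lapse_run_mean >= 1
  )
  if (any(phase_offsets_deg < 0) || any(phase_offsets_deg >= 360)) {
    abort("phase offsets must lie in [0, 360)")
  }
  if (abs(sum(cluster_weights) - 1) > 1e-8) {
    abort("cluster weights must sum to 1")
  }
  if (!is.null(t_slow_s) && (is.null(t_fast_s) || t_slow_s <= 0 || t_fast_s <= 0)) {
    abort("two-state process needs positive t_slow_s and t_fast_s")
  }
  structure(cfg, class = "fl_sim_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

# per-cycle periods from the configured cycle process, with ground truth
draw_periods <- function(cfg, n_max) {
  if (is.null(cfg$t_slow_s)) {
    base <- rep(cfg$period_s, n_max)
    regime <- rep("fixed", n_max)
  } else {
    state <- integer(n_max)
    state[1] <- sample(1:2, 1)
    flip <- runif(n_max - 1) < cfg$p_switch
    for (i in seq_len(n_max - 1)) {
      state[i + 1] <- if (flip[i]) 3L - state[i] else state[i]
    }
    base <- c(cfg$t_slow_s, cfg$t_fast_s)[state]
    regime <- c("slow", "fast")[state]
  }
  jit <- 1 + cfg$jitter_cv * rnorm(n_max)
  periods <- pmax(base * jit, 0.3 * base)
  list(periods = periods, regime = regime)
}

#' Simulate a four-root fictive-locomotion recording
#'
#' Generates RL2, LL2, RL5, LL5 voltage traces with the coordination
#' structure of drug-evoked fictive locomotion: a reference onset train from
#' a fixed-period or two-state (slow/fast) Markov cycle process, per-channel
#' phase offsets (left-right and flexor-extensor alternation, diagonal
#' synchrony), bursts rendered as band-limited noise carriers under a
#' smoothed rectangular envelope of duration `duty * period`, baseline
#' Gaussian noise, and optional extra bursts injected preferentially into
#' RL5. The full ground truth (per-cycle periods, regimes, per-channel burst
#' windows, extra-burst flags) is returned so every downstream metric can be
#' checked without re-detection.
#'
#' @param cfg An [sim_config()].
#' @return A list of class `fl_sim_fl`: `traces` (named list of `fl_trace`),
#'   `truth` (tibble `channel`, `cycle`, `onset`, `offset`, `period_s`,
#'   `regime`, `extra`), `ref_onsets`, `config`.
#' @export
simulate_ventral_roots <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "fl_sim_config"))
  with_seed(cfg$seed, {
    mean_T <- if (is.null(cfg$t_slow_s)) cfg$period_s else
      mean(c(cfg$t_slow_s, cfg$t_fast_s))
    n_max <- ceiling(cfg$duration_s / (0.5 * mean_T)) + 8
    dp <- draw_periods(cfg, n_max)
    onsets <- 1 + cumsum(c(0, dp$periods[-n_max]))
    keep <- onsets + dp$periods <= cfg$duration_s - 0.5
    if (sum(keep) < 3) abort("`duration_s` too short for 3 cycles")
    onsets <- onsets[keep]
    periods <- dp$periods[keep]
    regime <- dp$regime[keep]
    n_cyc <- length(onsets)
    ns <- floor(cfg$duration_s * cfg$rate_hz)
    tgrid <- (seq_len(ns) - 1) / cfg$rate_hz
    channels <- names(cfg$phase_offsets_deg)
    truth <- list()
    traces <- list()
    for (ch in channels) {
      off <- cfg$phase_offsets_deg[[ch]] / 360
      b_on <- onsets + off * periods
      b_dur <- cfg$duty * periods
      extra_p <- if (ch == "RL5") cfg$extra_burst_prob else
        if (ch == "LL5") cfg$extra_burst_prob / 2 else 0
      is_extra <- runif(n_cyc) < extra_p
      ex_on <- b_on[is_extra] + (cfg$duty + 0.1) * periods[is_extra] +
        runif(sum(is_extra)) * 0.2 * periods[is_extra]
      ex_dur <- 0.3 * cfg$duty * periods[is_extra]
      all_on <- c(b_on, ex_on)
      all_dur <- c(b_dur, ex_dur)
      gate <- burst_gate(tgrid, all_on, all_dur)
      carrier <- band_noise(ns, cfg$rate_hz, cfg$carrier_band_hz)
      v <- cfg$amplitude * gate * carrier + rnorm(ns, 0, cfg$noise_sd)
      traces[[ch]] <- new_trace(v, cfg$rate_hz, channel = ch)
      truth[[ch]] <- tibble(
        channel = ch,
        cycle = c(seq_len(n_cyc), which(is_extra)),
        onset = all_on, offset = all_on + all_dur,
        period_s = c(periods, periods[is_extra]),
        regime = c(regime, regime[is_extra]),
        extra = c(rep(FALSE, n_cyc), rep(TRUE, sum(is_extra)))
      )
    }
    structure(list(
      traces = traces,
      truth = dplyr::arrange(dplyr::bind_rows(truth), .data$channel, .data$onset),
      ref_onsets = onsets, ref_periods = periods, ref_regime = regime,
      config = cfg
    ), class = "fl_sim_fl")
  })
}

# smoothed rectangular gate: raised-cosine edges over 10% of each burst
burst_gate <- function(tgrid, onsets, durations) {
  g <- numeric(length(tgrid))
  for (i in seq_along(onsets)) {
    on <- onsets[i]; dur <- durations[i]; edge <- 0.1 * dur
    lo <- findInterval(on, tgrid)
    hi <- findInterval(on + dur, tgrid)
    if (hi <= lo) next
    idx <- lo:min(hi, length(tgrid))
    u <- tgrid[idx] - on
    w <- rep(1, length(u))
    w[u < edge] <- 0.5 * (1 - cos(pi * u[u < edge] / edge))
    w[u > dur - edge] <- 0.5 * (1 - cos(pi * (dur - u[u > dur - edge]) / edge))
    w[u < 0 | u > dur] <- 0
    g[idx] <- pmax(g[idx], w)
  }
  g
}

# unit-variance band-limited Gaussian noise carrier
band_noise <- function(n, rate, band) {
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sd(x)
}

#' Simulate a two-cluster soma-position table
#'
#' Draws normalized (ML, DV) soma positions from a two-component Gaussian
#' mixture truncated to the unit hemicord square — a major central cluster
#' and a minor medial cluster — then inverts the normalization for sampled
#' section heights and widths to produce the raw polar measurements
#' `(d_um, alpha_deg, H_um, W_um)`. Running the result back through
#' [normalize_positions()] reproduces the sampled fractions to machine
#' precision.
#'
#' @param cfg An [sim_config()].
#' @param genotype,level Labels attached to every record.
#' @return A tibble of class `fl_sim_positions`: one row per cell with raw
#'   measurements, normalized coordinates (`ml`, `dv`, `ml_pct`, `dv_pct`),
#'   `embryo_id`, `genotype`, `level`, and the ground-truth `cluster` label.
#' @export
simulate_positions <- function(cfg = sim_config(), genotype = "control",
                               level = "lumbar") {
  stopifnot(inherits(cfg, "fl_sim_config"))
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_cells
    comp <- sample(names(cfg$cluster_weights), n, replace = TRUE,
                   prob = cfg$cluster_weights)
    draw_one <- function(k) {
      mu <- cfg$cluster_means[[k]]
      sdv <- cfg$cluster_sds[[k]]
      repeat {
        p <- rnorm(2, mu, sdv)
        if (all(p >= 0 & p <= 1)) return(p)
      }
    }
    pts <- unname(t(vapply(comp, draw_one, numeric(2))))
    ml <- pts[, 1]; dv <- pts[, 2]
    H <- runif(n, cfg$h_range_um[1], cfg$h_range_um[2])
    W <- runif(n, cfg$w_range_um[1], cfg$w_range_um[2])
    dx <- ml * W
    dy <- dv * H
    d <- sqrt(dx^2 + dy^2)
    alpha <- atan2(dy, dx) * 180 / pi
    out <- tibble(
      embryo_id = paste0("e", 1 + (seq_len(n) - 1) %% cfg$n_embryos),
      genotype = genotype, level = level,
      d_um = d, alpha_deg = alpha, H_um = H, W_um = W,
      ml = ml, dv = dv, ml_pct = 100 * ml, dv_pct = 100 * dv,
      cluster = comp
    )
    structure(out, class = c("fl_sim_positions", class(out)))
  })
}

#' Simulate a neonatal swim bout with alternation lapses
#'
#' Left-hindlimb full-flexion times follow the configured period with
#' multiplicative jitter; the right hindlimb flexes in antiphase (180
#' degrees) except during lapse runs — entered per cycle with probability
#' `lapse_prob` and lasting a geometric number of cycles — in which it moves
#' nearly in phase with the left limb. Full extensions fall midway between
#' flexions. The per-cycle ground-truth lapse labels are returned.
#'
#' @param cfg An [sim_config()].
#' @return A list of class `fl_sim_swim`: `events` (tibble `limb`, `event`,
#'   `time_s`, `x`, `y`), `truth` (tibble `cycle`, `lapse`), `config`.
#' @export
simulate_swim <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "fl_sim_config"))
  with_seed(cfg$seed + 2L, {
    n <- cfg$swim_n_cycles
    periods <- pmax(cfg$swim_period_s *
                      (1 + cfg$swim_jitter_cv * rnorm(n)),
                    0.3 * cfg$swim_period_s)
    lh <- 0.5 + cumsum(c(0, periods[-n]))
    lapse <- logical(n)
    i <- 1
    while (i <= n) {
      if (runif(1) < cfg$lapse_prob) {
        run <- 1 + stats::rgeom(1, 1 / cfg$lapse_run_mean)
        lapse[i:min(n, i + run - 1)] <- TRUE
        i <- i + run
      } else {
        i <- i + 1
      }
    }
    jit <- cfg$swim_phase_jitter_deg / 360
    frac <- ifelse(lapse, 0.05, 0.5) + jit * rnorm(n)
    frac <- pmin(pmax(frac, 0.01), 0.95)
    rh <- lh + frac * periods
    mk <- function(t, limb) {
      ext <- head(t, -1) + diff(t) / 2
      ev <- tibble(
        limb = limb,
        event = c(rep("full_flexion", length(t)),
                  rep("full_extension", length(ext))),
        time_s = c(t, ext),
        x = 50 * cos(2 * pi * seq_along(c(t, ext))),
        y = 30 * sin(2 * pi * seq_along(c(t, ext)))
      )
      ev[order(ev$time_s), ]
    }
    events <- dplyr::bind_rows(mk(lh, "LH"), mk(rh, "RH"))
    structure(list(
      events = events,
      truth = tibble(cycle = seq_len(n), lapse = lapse),
      config = cfg
    ), class = "fl_sim_swim")
  })
}
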