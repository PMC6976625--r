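#' Fictive-locomotion analysis of one or more preparations
#'
#' Runs the full rhythm pipeline: per channel, envelope extraction, burst
#' detection, timing metrics, autocorrelation rhythmicity and frequency-mode
#' structure; per ordered root pair, circular phase statistics and the
#' cross-correlogram with its CCC rhythm-strength index; and, when
#' preparations from two or more genotypes are supplied, a two-sample
#' Kolmogorov-Smirnov comparison of the pooled instantaneous cycle-frequency
#' distributions for each genotype pair.
#'
#' @param recordings One recording (a named list of `fl_trace`s with channel
#'   names mappable to RL2, LL2, RL5, LL5) or a list of such recordings; each
#'   recording may carry `genotype` and `prep_id` attributes, or be a list
#'   with elements `traces`, `genotype`, `prep_id`.
#' @param resample_rate,window_s Envelope parameters, see [envelope()].
#' @param k_mad,hysteresis,min_dur_s,min_gap_s Burst-detector parameters, see
#'   [detect_bursts()].
#' @param max_lag_s Correlogram lag range (default 10 s).
#' @param mode_bandwidth_hz Kernel bandwidth for [frequency_modes()].
#' @param window Optional analysis interval `c(start_s, end_s)`; by default
#'   the whole trace is analyzed (recordings are conventionally trimmed to
#'   the stable final stretch upstream).
#' @return A report: list of class `fl_report` with elements `meta`,
#'   `channels` (per prep/channel burst counts, rhythmicity, modes),
#'   `pairs` (per prep/pair circular statistics and CCC),
#'   `frequencies` (per prep/channel instantaneous frequencies),
#'   `group_tests` (KS comparisons, when applicable), `warnings`.
#' @export
analyze_fl <- function(recordings,
                       resample_rate = 200, window_s = 0.25,
                       k_mad = 3, hysteresis = 0.5,
                       min_dur_s = 0.2, min_gap_s = 0.3,
                       max_lag_s = 10, mode_bandwidth_hz = 0.02,
                       window = NULL) {
  preps <- as_recording_list(recordings)
  warnings <- character()
  chan_rows <- list()
  pair_rows <- list()
  freq_rows <- list()
  modes_by <- list()
  for (p in seq_along(preps)) {
    rec <- preps[[p]]
    traces <- rec$traces
    if (!is.null(window)) {
      traces <- lapply(traces, function(tr) {
        keep <- tr$time >= window[1] & tr$time <= window[2]
        new_trace(tr$value[keep], trace_rate(tr), trace_channel(tr),
                  t0 = tr$time[keep][1])
      })
    }
    envs <- lapply(traces, envelope,
                   resample_rate = resample_rate, window_s = window_s)
    trains <- withCallingHandlers(
      lapply(envs, detect_bursts, k_mad = k_mad, hysteresis = hysteresis,
             min_dur_s = min_dur_s, min_gap_s = min_gap_s),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    rhyth <- lapply(envs, function(e) {
      if (sd(e$value) == 0) NULL else autocorr_rhythmicity(e, max_lag_s)
    })
    for (ch in names(traces)) {
      freqs <- cycle_frequencies(trains[[ch]])
      fm <- if (length(freqs) >= 5) frequency_modes(freqs, mode_bandwidth_hz)
      modes_by[[paste(rec$prep_id, ch, sep = "/")]] <- fm
      chan_rows[[length(chan_rows) + 1]] <- tibble(
        prep_id = rec$prep_id, genotype = rec$genotype, channel = ch,
        n_bursts = nrow(trains[[ch]]),
        mean_period_s = mean(diff(trains[[ch]]$onset)),
        mean_duration_s = mean(trains[[ch]]$offset - trains[[ch]]$onset),
        rhythmicity = rhyth[[ch]]$index %||% NA_real_,
        period_autocorr_s = rhyth[[ch]]$period_s %||% NA_real_,
        modes_hz = list(fm$modes %||% numeric())
      )
      if (length(freqs)) {
        freq_rows[[length(freq_rows) + 1]] <- tibble(
          prep_id = rec$prep_id, genotype = rec$genotype,
          channel = ch, freq_hz = freqs
        )
      }
    }
    pairs <- root_pairs(names(traces))
    for (i in seq_len(nrow(pairs))) {
      aa <- pairs$a[i]; bb <- pairs$b[i]
      ph <- pair_phases(trains[[aa]], trains[[bb]])
      cs <- if (nrow(ph) >= 2) circular_stats(ph) else NULL
      xc <- if (sd(envs[[aa]]$value) > 0 && sd(envs[[bb]]$value) > 0) {
        cross_correlogram(envs[[aa]], envs[[bb]], max_lag_s,
                          cycle_period_s = rhyth[[aa]]$period_s)
      } else {
        list(ccc_index = NA_real_, peak_lag_s = NA_real_)
      }
      pair_rows[[length(pair_rows) + 1]] <- tibble(
        prep_id = rec$prep_id, genotype = rec$genotype,
        pair = paste0(aa, "/", bb),
        n = nrow(ph),
        mean_deg = cs$mean_deg %||% NA_real_,
        R = cs$R %||% NA_real_,
        circ_sd_deg = cs$circ_sd_deg %||% NA_real_,
        rayleigh_p = cs$rayleigh_p %||% NA_real_,
        n_skipped = attr(ph, "n_skipped"),
        ccc_index = xc$ccc_index, peak_lag_s = xc$peak_lag_s
      )
    }
  }
  freqs_tbl <- dplyr::bind_rows(freq_rows)
  group_tests <- list()
  if (nrow(freqs_tbl) > 0) {
    gts <- unique(freqs_tbl$genotype)
    gts <- gts[!is.na(gts)]
    if (length(gts) >= 2) {
      for (i in seq_len(length(gts) - 1)) {
        for (j in seq.int(i + 1, length(gts))) {
          fa <- freqs_tbl$freq_hz[freqs_tbl$genotype == gts[i]]
          fb <- freqs_tbl$freq_hz[freqs_tbl$genotype == gts[j]]
          if (length(fa) >= 2 && length(fb) >= 2) {
            kt <- ks_compare(fa, fb)
            group_tests[[paste(gts[i], gts[j], sep = " vs ")]] <- kt
          }
        }
      }
    }
  }
  new_report("fictive_locomotion",
    meta = list(
      n_preps = length(preps),
      params = list(resample_rate = resample_rate, window_s = window_s,
                    k_mad = k_mad, hysteresis = hysteresis,
                    min_dur_s = min_dur_s, min_gap_s = min_gap_s,
                    max_lag_s = max_lag_s,
                    mode_bandwidth_hz = mode_bandwidth_hz)
    ),
    channels = dplyr::bind_rows(chan_rows),
    pairs = dplyr::bind_rows(pair_rows),
    frequencies = freqs_tbl,
    modes = modes_by,
    group_tests = group_tests,
    warnings = warnings
  )
}

as_recording_list <- function(recordings) {
  is_rec <- function(x) is.list(x) && all(vapply(x, inherits, logical(1),
                                                 "fl_trace"))
  wrap <- function(x, id) {
    if (is_rec(x)) {
      list(traces = check_channels(x),
           genotype = attr(x, "genotype") %||% NA_character_,
           prep_id = attr(x, "prep_id") %||% id)
    } else if (is.list(x) && !is.null(x$traces)) {
      list(traces = check_channels(x$traces),
           genotype = x$genotype %||% NA_character_,
           prep_id = x$prep_id %||% id)
    } else {
      abort("each recording must be a named list of fl_trace objects")
    }
  }
  if (is_rec(recordings) ||
      (is.list(recordings) && !is.null(recordings$traces))) {
    list(wrap(recordings, "prep1"))
  } else {
    ids <- names(recordings) %||% paste0("prep", seq_along(recordings))
    purrr::map2(recordings, ids, wrap)
  }
}

check_channels <- function(traces) {
  expected <- c("RL2", "LL2", "RL5", "LL5")
  nm <- names(traces)
  if (is.null(nm) || !all(nzchar(nm))) {
    nm <- vapply(traces, trace_channel, character(1))
    names(traces) <- nm
  }
  unknown <- setdiff(nm, expected)
  if (length(unknown)) {
    abort(sprintf("unmappable channel(s) %s; expected labels among: %s",
                  paste(unknown, collapse = ", "),
                  paste(expected, collapse = ", ")))
  }
  traces
}

root_pairs <- function(channels) {
  cmb <- utils::combn(channels, 2)
  tibble(a = cmb[1, ], b = cmb[2, ])
}

#' Spatial-distribution analysis of two groups of somata
#'
#' Per axial level: normalizes raw measurements if needed, builds per-group
#' density maps and marginals, and compares the two groups' (ML, DV)
#' distributions with the two-sample Hotelling's T-squared test. Levels with
#' fewer than 3 cells in either group are skipped with a warning recorded in
#' the report.
#'
#' @param positions Data frame of cell positions (see [normalize_positions()]
#'   / [read_positions()]) with a group column and a level column.
#' @param group_col,level_col Column names (defaults `"genotype"`,
#'   `"level"`).
#' @param per_embryo If `TRUE`, test embryo-mean positions instead of
#'   per-cell positions (default `FALSE`: sections from all embryos pool).
#' @param grid_n,bandwidth Density-map parameters, see [density_maps()].
#' @param p_adjust Multiplicity correction across levels, a method name for
#'   [stats::p.adjust()] (default `"none"`: levels are reported separately).
#' @return An `fl_report` with `tests` (tibble: level, T2, F, dfs, p, ns),
#'   `densities` (per level/group `fl_density`), `warnings`.
#' @export
analyze_positions <- function(positions, group_col = "genotype",
                              level_col = "level", per_embryo = FALSE,
                              grid_n = 50, bandwidth = 0.05,
                              p_adjust = "none") {
  df <- as_tibble(positions)
  if (!all(c("ml", "dv") %in% names(df))) {
    if (all(c("d_um", "alpha_deg", "H_um", "W_um") %in% names(df))) {
      df <- normalize_positions(df)
    } else {
      abort("positions need ml/dv or raw measurement columns")
    }
  }
  if (!group_col %in% names(df)) abort(sprintf("missing column `%s`", group_col))
  if (!level_col %in% names(df)) df[[level_col]] <- "all"
  groups <- sort(unique(df[[group_col]]))
  warnings <- character()
  tests <- list()
  densities <- list()
  for (lev in sort(unique(df[[level_col]]))) {
    sub <- df[df[[level_col]] == lev, ]
    for (g in groups) {
      gsub <- sub[sub[[group_col]] == g, ]
      if (nrow(gsub) >= 1) {
        densities[[paste(lev, g, sep = "/")]] <-
          density_maps(gsub, grid_n = grid_n, bandwidth = bandwidth)
      }
    }
    if (length(groups) < 2) {
      warnings <- c(warnings,
                    sprintf("level %s: single group, test skipped", lev))
      next
    }
    a <- sub[sub[[group_col]] == groups[1], ]
    b <- sub[sub[[group_col]] == groups[2], ]
    if (per_embryo) {
      a <- dplyr::summarise(dplyr::group_by(a, .data$embryo_id),
                            ml = mean(.data$ml), dv = mean(.data$dv))
      b <- dplyr::summarise(dplyr::group_by(b, .data$embryo_id),
                            ml = mean(.data$ml), dv = mean(.data$dv))
    }
    if (nrow(a) < 3 || nrow(b) < 3) {
      warnings <- c(warnings,
                    sprintf("level %s: fewer than 3 cells in a group, test skipped", lev))
      next
    }
    ht <- hotelling_t2(a, b)
    tests[[lev]] <- tibble(
      level = lev, t2 = ht$statistic, f = ht$f,
      df1 = ht$df1, df2 = ht$df2, p = ht$p.value,
      n1 = ht$n1, n2 = ht$n2
    )
  }
  tests_tbl <- dplyr::bind_rows(tests)
  if (nrow(tests_tbl) > 0) {
    tests_tbl$p_adj <- stats::p.adjust(tests_tbl$p, method = p_adjust)
  }
  new_report("positions",
    meta = list(groups = groups, per_embryo = per_embryo,
                params = list(grid_n = grid_n, bandwidth = bandwidth,
                              p_adjust = p_adjust)),
    tests = tests_tbl, densities = densities, warnings = warnings
  )
}

#' Group analysis of neonatal swim bouts
#'
#' Computes [swim_metrics()] per bout and compares mean cycle period and miss
#' ratio between two groups with rank-based (Mann-Whitney) tests. Malformed
#' bouts are skipped with a warning; the run continues.
#'
#' @param bouts A list of swim-event data frames (see [swim_metrics()]), or a
#'   single data frame with an `animal_id` column; group labels come from a
#'   `genotype` column or a `groups` vector parallel to `bouts`.
#' @param groups Optional character vector of group labels, one per bout.
#' @return An `fl_report` with `per_animal` (tibble: animal, group, mean
#'   period, missed, miss ratio), `group_tests`, `warnings`.
#' @export
analyze_swim <- function(bouts, groups = NULL) {
  if (is.data.frame(bouts)) {
    if (!"animal_id" %in% names(bouts)) {
      bouts <- list(bout1 = bouts)
    } else {
      bouts <- split(as_tibble(bouts), bouts$animal_id)
    }
  }
  ids <- names(bouts) %||% paste0("bout", seq_along(bouts))
  warnings <- character()
  rows <- list()
  for (i in seq_along(bouts)) {
    b <- as_tibble(bouts[[i]])
    g <- groups[i] %||% (if ("genotype" %in% names(b)) b$genotype[1] else NA)
    m <- tryCatch(swim_metrics(b), error = function(e) {
      warnings <<- c(warnings, sprintf("%s: %s", ids[i], conditionMessage(e)))
      NULL
    })
    if (is.null(m)) next
    rows[[length(rows) + 1]] <- tibble(
      animal_id = ids[i], group = as.character(g),
      mean_period_s = m$mean_period_s, n_cycles = nrow(m$phases),
      missed = m$missed, miss_ratio_per_s = m$miss_ratio_per_s
    )
  }
  per_animal <- dplyr::bind_rows(rows)
  group_tests <- list()
  gts <- unique(per_animal$group)
  gts <- gts[!is.na(gts)]
  if (length(gts) == 2) {
    a <- per_animal[per_animal$group == gts[1], ]
    b <- per_animal[per_animal$group == gts[2], ]
    for (metric in c("mean_period_s", "miss_ratio_per_s")) {
      wt <- suppressWarnings(wilcox.test(a[[metric]], b[[metric]]))
      group_tests[[metric]] <- new_htest(
        method = sprintf("Mann-Whitney U test (%s, %s vs %s)",
                         metric, gts[1], gts[2]),
        statistic = unname(wt$statistic), statistic_name = "W",
        p.value = wt$p.value, n1 = nrow(a), n2 = nrow(b)
      )
    }
  }
  new_report("swim",
    meta = list(n_bouts = length(bouts), groups = gts),
    per_animal = per_animal, group_tests = group_tests, warnings = warnings
  )
}

new_report <- function(kind, ...) {
  structure(c(list(kind = kind, schema = "fl-report/1"), list(...)),
            class = "fl_report")
}

#' @export
print.fl_report <- function(x, ...) {
  cat(sprintf("<fl_report: %s>\n", x$kind))
  for (nm in setdiff(names(x), c("kind", "schema"))) {
    obj <- x[[nm]]
    if (is.data.frame(obj)) {
      cat(sprintf("  $%s: %d row(s)\n", nm, nrow(obj)))
    } else if (is.list(obj)) {
      cat(sprintf("  $%s: %d element(s)\n", nm, length(obj)))
    }
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Serialize a report deterministically
#'
#' `report_json()` renders a report as canonical JSON (fixed 15 significant
#' digits, stable key order), so the same inputs always produce byte-identical
#' text; `write_report()` writes it plus flat CSV tables to a directory.
#'
#' @param report An `fl_report`.
#' @param dir Output directory (created if missing).
#' @return `report_json()` a JSON string; `write_report()` the directory,
#'   invisibly.
#' @export
report_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "fl_density")) {
      x <- list(n = x$n, bandwidth = x$bandwidth, grid_n = x$grid_n)
    }
    if (inherits(x, "fl_htest")) x <- unclass(x)
    if (is.data.frame(x)) return(as.data.frame(x))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  payload <- strip(unclass(report))
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(15),
                                null = "null", na = "null", pretty = TRUE))
}

#' @rdname report_json
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  for (nm in names(report)) {
    obj <- report[[nm]]
    if (is.data.frame(obj) && nrow(obj)) {
      flat <- obj
      for (cl in names(flat)) {
        if (is.list(flat[[cl]])) {
          flat[[cl]] <- vapply(flat[[cl]], function(v)
            paste(signif(v, 10), collapse = ";"), character(1))
        }
      }
      write.csv(flat, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}
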