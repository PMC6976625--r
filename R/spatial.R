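#' Normalize soma positions into fractional spinal-cord coordinates
#'
#' Each soma is measured in a transverse section as a distance `d_um` and an
#' angle `alpha_deg` from the ventral limit of the central canal, together
#' with the section's spinal-cord height `H_um` (ventral limit of the central
#' canal to the dorsal-most edge) and hemicord width `W_um` (central canal to
#' the most lateral edge). The normalized dorso-ventral and medio-lateral
#' positions are
#' \deqn{DV = d \sin(\alpha) / H, \qquad ML = d \cos(\alpha) / W,}
#' expressed as percentages of spinal-cord height and hemicord width.
#'
#' Angles beyond 90 degrees place the soma in the opposite hemicord; with
#' `mirror = TRUE` (default) those cells are reflected onto one hemicord so
#' both sides pool, matching the convention of plotting a single half of the
#' cord. Values pushed slightly outside `[0, 100]` by measurement noise are
#' clamped with a warning, not dropped.
#'
#' @param positions Data frame with columns `d_um`, `alpha_deg`, `H_um`,
#'   `W_um` (any other columns are carried through).
#' @param mirror Fold left-side cells onto the right hemicord (default TRUE).
#' @return The input as a tibble with added columns `dv_pct`, `ml_pct`
#'   (percent) and `dv`, `ml` (fractions of H and W in `[0, 1]`).
#' @examples
#' normalize_positions(data.frame(d_um = 2, alpha_deg = 30, H_um = 4, W_um = 8))
#' @export
normalize_positions <- function(positions, mirror = TRUE) {
  positions <- as_tibble(positions)
  need <- c("d_um", "alpha_deg", "H_um", "W_um")
  if (!all(need %in% names(positions))) {
    abort(paste("positions need columns:", paste(need, collapse = ", ")))
  }
  with_cols <- positions
  if (any(with_cols$H_um <= 0) || any(with_cols$W_um <= 0)) {
    abort("H_um and W_um must be positive")
  }
  if (any(with_cols$d_um < 0)) abort("d_um must be nonnegative")
  a <- with_cols$alpha_deg * pi / 180
  dv <- with_cols$d_um * sin(a) / with_cols$H_um
  ml <- with_cols$d_um * cos(a) / with_cols$W_um
  if (mirror) ml <- abs(ml)
  out_of_range <- dv < 0 | dv > 1 | ml < 0 | ml > 1
  if (any(out_of_range)) {
    warn(sprintf("%d cell(s) outside the unit section; clamped to [0, 1]",
                 sum(out_of_range)))
    dv <- pmin(pmax(dv, 0), 1)
    ml <- pmin(pmax(ml, 0), 1)
  }
  dplyr::mutate(with_cols, dv = dv, ml = ml,
                dv_pct = 100 * dv, ml_pct = 100 * ml)
}

#' Soma density maps and marginals over the hemicord section
#'
#' Gaussian kernel density of normalized (ML, DV) soma positions on a regular
#' grid over the unit hemicord square, with boundary correction (each grid
#' point is reweighted by the kernel mass falling inside the square) and
#' renormalized to integrate to 1. One-dimensional marginal densities along
#' DV and ML use the same bandwidth and correction.
#'
#' @param positions Data frame with columns `ml` and `dv` (fractions in
#'   `[0, 1]`), e.g. from [normalize_positions()].
#' @param grid_n Grid resolution per axis (default 50).
#' @param bandwidth Gaussian kernel standard deviation in fraction units
#'   (default 0.05).
#' @return A list of class `fl_density`: `map` (long tibble `ml`, `dv`,
#'   `density`), `marginal_ml` and `marginal_dv` (tibbles `pos`, `density`),
#'   `n`, `bandwidth`.
#' @export
density_maps <- function(positions, grid_n = 50, bandwidth = 0.05) {
  df <- as_tibble(positions)
  if (!all(c("ml", "dv") %in% names(df))) {
    abort("positions need `ml` and `dv` columns (fractions); run normalize_positions()")
  }
  df <- df[complete.cases(df[c("ml", "dv")]), ]
  if (nrow(df) < 1) abort("need at least one position")
  if (bandwidth <= 0) abort("`bandwidth` must be positive")
  gx <- seq(0, 1, length.out = grid_n)
  k2 <- MASS::kde2d(df$ml, df$dv, h = 4 * bandwidth, n = grid_n,
                    lims = c(0, 1, 0, 1))
  inside <- function(g) pnorm((1 - g) / bandwidth) - pnorm(-g / bandwidth)
  corr <- outer(inside(k2$x), inside(k2$y))
  z <- k2$z / corr
  cell <- (gx[2] - gx[1])^2
  z <- z / (sum(z) * cell)
  marg <- function(v) {
    d <- density(v, bw = bandwidth, from = 0, to = 1, n = grid_n)
    y <- d$y / inside(d$x)
    y <- y / (sum(y) * (d$x[2] - d$x[1]))
    tibble(pos = d$x, density = y)
  }
  map <- tibble(
    ml = rep(k2$x, times = grid_n),
    dv = rep(k2$y, each = grid_n),
    density = as.vector(z)
  )
  structure(list(
    map = map, marginal_ml = marg(df$ml), marginal_dv = marg(df$dv),
    n = nrow(df), bandwidth = bandwidth, grid_n = grid_n
  ), class = "fl_density")
}

#' Two-sample Hotelling's T-squared test on 2D soma positions
#'
#' The two-dimensional generalization of the two-sample Student's t-test,
#' used to compare the (ML, DV) distributions of two groups of interneurons:
#' \deqn{T^2 = \frac{n_1 n_2}{n_1+n_2}\,
#'   (\bar x_1-\bar x_2)^\top S_p^{-1} (\bar x_1-\bar x_2)}
#' with pooled covariance \eqn{S_p}; under the null,
#' \eqn{F = T^2 (n_1+n_2-3) / (2 (n_1+n_2-2))} follows an F distribution with
#' `(2, n1+n2-3)` degrees of freedom.
#'
#' @param a,b Data frames (or 2-column matrices) of positions; data frames
#'   use columns `ml` and `dv`.
#' @return An `fl_htest` with `statistic` (T2), `f`, `df1`, `df2`, `p.value`,
#'   `n1`, `n2`, and the mean difference `delta`.
#' @export
hotelling_t2 <- function(a, b) {
  xa <- as_xy(a); xb <- as_xy(b)
  n1 <- nrow(xa); n2 <- nrow(xb)
  if (n1 < 3 || n2 < 3) abort("each group needs n >= 3 positions")
  d <- colMeans(xa) - colMeans(xb)
  sp <- ((n1 - 1) * stats::cov(xa) + (n2 - 1) * stats::cov(xb)) / (n1 + n2 - 2)
  det_sp <- det(sp)
  if (!is.finite(det_sp) || det_sp < .Machine$double.eps) {
    abort(paste("pooled covariance is singular; jitter the positions or use",
                "an exact/permutation comparison"))
  }
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(sp, d))
  f <- t2 * (n1 + n2 - 3) / (2 * (n1 + n2 - 2))
  p <- pf(f, 2, n1 + n2 - 3, lower.tail = FALSE)
  new_htest(
    method = "Two-sample Hotelling's T-squared test",
    statistic = t2, statistic_name = "T2", p.value = p,
    f = f, df1 = 2, df2 = n1 + n2 - 3, n1 = n1, n2 = n2, delta = d
  )
}

as_xy <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2)
    m <- x
  } else {
    x <- as_tibble(x)
    if (!all(c("ml", "dv") %in% names(x))) {
      abort("positions need `ml` and `dv` columns")
    }
    m <- cbind(x$ml, x$dv)
  }
  storage.mode(m) <- "double"
  m[complete.cases(m), , drop = FALSE]
}

#' Export a density map as CSV matrices with axis headers
#'
#' Writes the 2D map as a `grid_n x grid_n` matrix (rows = ML grid, columns
#' = DV grid, both spelled out in headers) plus the two marginals as
#' two-column tables.
#'
#' @param d An `fl_density` from [density_maps()].
#' @param path Base path; writes `<path>_map.csv`, `<path>_marginal_ml.csv`,
#'   `<path>_marginal_dv.csv`.
#' @return `path`, invisibly.
#' @export
write_density <- function(d, path) {
  stopifnot(inherits(d, "fl_density"))
  z <- matrix(d$map$density, nrow = d$grid_n)
  gx <- seq(0, 1, length.out = d$grid_n)
  df <- data.frame(ml = gx, z)
  names(df) <- c("ml", sprintf("dv_%0.4f", gx))
  write.csv(df, paste0(path, "_map.csv"), row.names = FALSE)
  write.csv(d$marginal_ml, paste0(path, "_marginal_ml.csv"),
            row.names = FALSE)
  write.csv(d$marginal_dv, paste0(path, "_marginal_dv.csv"),
            row.names = FALSE)
  invisible(path)
}

#' Read a soma-position table
#'
#' CSV columns: `embryo_id`, `genotype`, `level`, and either raw measurements
#' (`d_um`, `alpha_deg`, `H_um`, `W_um`) or precomputed `dv_pct`, `ml_pct`.
#' Raw measurements are normalized on read.
#'
#' @param path CSV file path.
#' @param ... Passed to [normalize_positions()].
#' @return A tibble with `dv`, `ml` (fractions) and `dv_pct`, `ml_pct`.
#' @export
read_positions <- function(path, ...) {
  df <- as_tibble(read.csv(path))
  if (all(c("d_um", "alpha_deg", "H_um", "W_um") %in% names(df))) {
    normalize_positions(df, ...)
  } else if (all(c("dv_pct", "ml_pct") %in% names(df))) {
    dplyr::mutate(df, dv = .data$dv_pct / 100, ml = .data$ml_pct / 100)
  } else {
    abort("positions file needs raw (d_um, alpha_deg, H_um, W_um) or precomputed (dv_pct, ml_pct) columns")
  }
}
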