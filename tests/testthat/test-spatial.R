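test_that("position normalization matches the closed form", {
  at_canal <- normalize_positions(
    data.frame(d_um = 0, alpha_deg = 45, H_um = 400, W_um = 300))
  expect_equal(c(at_canal$dv_pct, at_canal$ml_pct), c(0, 0))

  dorsal <- normalize_positions(
    data.frame(d_um = 400, alpha_deg = 90, H_um = 400, W_um = 300))
  expect_equal(dorsal$dv_pct, 100)
  expect_equal(dorsal$ml_pct, 0, tolerance = 1e-10)

  oblique <- normalize_positions(
    data.frame(d_um = 2, alpha_deg = 30, H_um = 4, W_um = 8))
  expect_equal(oblique$dv_pct, 25, tolerance = 1e-10)
  expect_equal(oblique$ml_pct, 100 * 2 * cos(pi / 6) / 8, tolerance = 1e-10)
  expect_equal(oblique$ml_pct, 21.65, tolerance = 1e-3)

  expect_error(normalize_positions(
    data.frame(d_um = 1, alpha_deg = 10, H_um = 0, W_um = 5)), "positive")
  expect_error(normalize_positions(
    data.frame(d_um = -1, alpha_deg = 10, H_um = 5, W_um = 5)), "nonnegative")
})

test_that("slightly out-of-section cells are clamped with a warning", {
  df <- data.frame(d_um = 420, alpha_deg = 90, H_um = 400, W_um = 300)
  expect_warning(out <- normalize_positions(df), "clamped")
  expect_equal(out$dv, 1)
})

test_that("left-side cells mirror onto one hemicord", {
  df <- data.frame(d_um = 100, alpha_deg = c(60, 120), H_um = 400,
                   W_um = 300)
  out <- normalize_positions(df)
  expect_equal(out$ml[1], out$ml[2], tolerance = 1e-12)
  expect_equal(out$dv[1], out$dv[2], tolerance = 1e-12)
})

test_that("normalization inverts the generator transform to 1e-12", {
  cfg <- sim_config(seed = 61, n_cells = 500)
  sim <- simulate_positions(cfg)
  renorm <- normalize_positions(sim[, c("d_um", "alpha_deg", "H_um", "W_um")])
  expect_lt(max(abs(renorm$dv - sim$dv)), 1e-12)
  expect_lt(max(abs(renorm$ml - sim$ml)), 1e-12)
})

test_that("density maps integrate to one and peak where the data sit", {
  single <- density_maps(tibble::tibble(ml = 0.4, dv = 0.62), grid_n = 50,
                         bandwidth = 0.05)
  cell <- (1 / 49)^2
  expect_lt(abs(sum(single$map$density) * cell - 1), 1e-6)
  top <- single$map[which.max(single$map$density), ]
  expect_lt(abs(top$ml - 0.4), 1 / 49 + 1e-9)
  expect_lt(abs(top$dv - 0.62), 1 / 49 + 1e-9)

  set.seed(62)
  cl <- rbind(
    cbind(rnorm(300, 0.30, 0.05), rnorm(300, 0.30, 0.05)),
    cbind(rnorm(300, 0.70, 0.05), rnorm(300, 0.72, 0.05))
  )
  cl <- cl[cl[, 1] > 0 & cl[, 1] < 1 & cl[, 2] > 0 & cl[, 2] < 1, ]
  dm <- density_maps(tibble::tibble(ml = cl[, 1], dv = cl[, 2]),
                     grid_n = 50, bandwidth = 0.05)
  z <- matrix(dm$map$density, nrow = 50)
  mx <- matrix_local_maxima(z)
  gx <- seq(0, 1, length.out = 50)
  peaks <- cbind(gx[mx[, 1]], gx[mx[, 2]])
  strong <- peaks[z[mx] > 0.2 * max(z), , drop = FALSE]
  expect_equal(nrow(strong), 2)
  slack <- 1 / 49 + 0.05
  expect_true(any(abs(strong[, 1] - 0.30) < slack &
                    abs(strong[, 2] - 0.30) < slack))
  expect_true(any(abs(strong[, 1] - 0.70) < slack &
                    abs(strong[, 2] - 0.72) < slack))
})

test_that("a uniform sample produces an approximately flat map", {
  set.seed(63)
  dm <- density_maps(tibble::tibble(ml = runif(1e4), dv = runif(1e4)),
                     grid_n = 50, bandwidth = 0.08)
  expect_lt(max(abs(dm$map$density - 1)), 0.15)
})

test_that("Hotelling T2 matches the matrix oracle and degenerates to zero", {
  a <- tibble::tibble(ml = c(0.1, 0.2, 0.3, 0.25, 0.15),
                      dv = c(0.5, 0.45, 0.55, 0.6, 0.52))
  b <- tibble::tibble(ml = c(0.32, 0.28, 0.40, 0.35, 0.31),
                      dv = c(0.47, 0.52, 0.58, 0.50, 0.44))
  ht <- hotelling_t2(a, b)
  orc <- oracle_hotelling(cbind(a$ml, a$dv), cbind(b$ml, b$dv))
  expect_lt(abs(ht$statistic - orc$t2), 1e-10)
  expect_lt(abs(ht$f - orc$f), 1e-10)
  expect_lt(abs(ht$p.value - orc$p), 1e-10)

  same <- hotelling_t2(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  expect_error(hotelling_t2(a[1:2, ], b), "n >= 3")
  degen <- tibble::tibble(ml = c(0.1, 0.2, 0.3), dv = c(0.1, 0.2, 0.3) * 2)
  expect_error(hotelling_t2(degen, degen + 0.01), "singular")

  expect_equal(glance(ht)$df1, 2)
})

test_that("Hotelling T2 is invariant under common affine transforms", {
  set.seed(64)
  xa <- cbind(rnorm(20, 0.4, 0.1), rnorm(20, 0.5, 0.08))
  xb <- cbind(rnorm(25, 0.45, 0.1), rnorm(25, 0.48, 0.08))
  p0 <- hotelling_t2(xa, xb)$p.value
  A <- matrix(c(2, 0.5, -0.3, 1.5), 2)
  shift <- c(5, -3)
  ta <- sweep(xa %*% A, 2, shift, "+")
  tb <- sweep(xb %*% A, 2, shift, "+")
  expect_lt(abs(hotelling_t2(ta, tb)$p.value - p0), 1e-8)
})

test_that("Hotelling power rises monotonically with the ML mean shift", {
  set.seed(65)
  power_at <- function(shift, reps = 400) {
    mean(replicate(reps, {
      xa <- cbind(rnorm(30, 0.4, 0.1), rnorm(30, 0.5, 0.1))
      xb <- cbind(rnorm(30, 0.4 + shift, 0.1), rnorm(30, 0.5, 0.1))
      hotelling_t2(xa, xb)$p.value < 0.05
    }))
  }
  pw <- vapply(c(0, 0.05, 0.1, 0.2), power_at, numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_lt(pw[1], 0.12)
  expect_gt(pw[4], 0.9)
})

test_that("density maps export as matrices with axis headers", {
  dm <- density_maps(tibble::tibble(ml = runif(30), dv = runif(30)),
                     grid_n = 20, bandwidth = 0.1)
  base <- file.path(withr::local_tempdir(), "dens")
  write_density(dm, base)
  back <- read.csv(paste0(base, "_map.csv"))
  expect_equal(dim(back), c(20, 21))
  expect_equal(back$ml, seq(0, 1, length.out = 20))
  marg <- read.csv(paste0(base, "_marginal_dv.csv"))
  expect_equal(names(marg), c("pos", "density"))
})

test_that("position files round trip, raw or precomputed", {
  cfg <- sim_config(seed = 66, n_cells = 40)
  sim <- simulate_positions(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(sim[, c("embryo_id", "genotype", "level", "d_um", "alpha_deg",
                    "H_um", "W_um")], path, row.names = FALSE)
  back <- read_positions(path)
  expect_equal(back$dv, sim$dv, tolerance = 1e-6)

  write.csv(data.frame(embryo_id = "e1", genotype = "g", level = "lumbar",
                       dv_pct = 40, ml_pct = 55), path, row.names = FALSE)
  pre <- read_positions(path)
  expect_equal(pre$ml, 0.55)
})
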