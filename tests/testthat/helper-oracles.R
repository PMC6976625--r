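# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results by the most direct route
# (per-sample loops, explicit matrix algebra) so they stay independent of the
# package's vectorized implementations.

# direct per-sample weighted-sum smoother with edge renormalization
oracle_wcma <- function(x, window_len) {
  n <- length(x)
  half <- (window_len - 1) / 2
  k <- seq_len(window_len) - 1
  w <- 0.54 - 0.46 * cos(2 * pi * k / (window_len - 1))
  w <- w / sum(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- (i - half):(i + half)
    ok <- js >= 1 & js <= n
    out[i] <- sum(w[ok] * x[js[ok]]) / sum(w[ok])
  }
  out
}

# sample-by-sample hysteresis state machine with merge/drop post-processing,
# mirroring the detector's declared rule: open above median + k*MAD, close
# below median + hysteresis*k*MAD
oracle_bursts <- function(v, t, rate, k_mad = 3, hysteresis = 0.5,
                          min_dur_s = 0.2, min_gap_s = 0.3) {
  med <- median(v)
  thr <- if (mad(v) > 0) med + k_mad * mad(v) else med + 0.5 * (max(v) - med)
  lo <- med + hysteresis * (thr - med)
  state <- 0
  onsets <- c()
  offsets <- c()
  for (i in seq_along(v)) {
    if (state == 0 && v[i] > thr) {
      state <- 1
      onsets <- c(onsets, t[i])
    } else if (state == 1 && v[i] < lo) {
      state <- 0
      offsets <- c(offsets, min(t[i - 1] + 1 / rate, t[length(t)]))
    }
  }
  if (state == 1) offsets <- c(offsets, t[length(t)])
  if (length(onsets) == 0) {
    return(data.frame(onset = numeric(), offset = numeric(),
                      peak = numeric()))
  }
  # merge short gaps
  m_on <- onsets[1]
  res <- list()
  cur_off <- offsets[1]
  for (i in seq_along(onsets)[-1]) {
    if (onsets[i] - cur_off < min_gap_s) {
      cur_off <- offsets[i]
    } else {
      res[[length(res) + 1]] <- c(m_on, cur_off)
      m_on <- onsets[i]
      cur_off <- offsets[i]
    }
  }
  res[[length(res) + 1]] <- c(m_on, cur_off)
  ev <- do.call(rbind, res)
  keep <- (ev[, 2] - ev[, 1]) >= min_dur_s
  ev <- ev[keep, , drop = FALSE]
  peaks <- apply(ev, 1, function(e) max(v[t >= e[1] & t <= e[2]]))
  data.frame(onset = ev[, 1], offset = ev[, 2], peak = peaks)
}

# explicit matrix-formula two-sample Hotelling's T2
oracle_hotelling <- function(xa, xb) {
  n1 <- nrow(xa); n2 <- nrow(xb)
  d <- colMeans(xa) - colMeans(xb)
  sp <- ((n1 - 1) * cov(xa) + (n2 - 1) * cov(xb)) / (n1 + n2 - 2)
  t2 <- (n1 * n2 / (n1 + n2)) * as.numeric(t(d) %*% solve(sp) %*% d)
  f <- t2 * (n1 + n2 - 3) / (2 * (n1 + n2 - 2))
  list(t2 = t2, f = f, p = pf(f, 2, n1 + n2 - 3, lower.tail = FALSE))
}

# sup distance between two empirical CDFs by direct evaluation
oracle_ks_d <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- ecdf(a)(grid)
  fb <- ecdf(b)(grid)
  max(abs(fa - fb))
}

# Best-Fisher rejection sampler for the von Mises distribution (radians)
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  out %% (2 * pi)
}

# build an fl_bursts train directly from onset/offset vectors
make_train <- function(onset, offset = onset + 1, peak = rep(1, length(onset)),
                       channel = "RL2") {
  out <- tibble::tibble(onset = onset, offset = offset, peak = peak)
  structure(out,
    class = c("fl_bursts", class(out)),
    channel = channel, threshold = NA_real_, degenerate = FALSE,
    provenance = NULL
  )
}

# a rough "random envelope" generator for oracle-equivalence checks:
# nonnegative, drifting, with occasional high bumps
random_envelope <- function(n, rate = 200) {
  x <- abs(stats::filter(rnorm(n), rep(1 / 8, 8), sides = 2,
                         circular = TRUE))
  bumps <- rbinom(1, 4, 0.8)
  for (b in seq_len(bumps)) {
    c0 <- sample.int(n, 1)
    w <- sample(10:80, 1)
    idx <- pmax(1, c0 - w):pmin(n, c0 + w)
    x[idx] <- x[idx] + runif(1, 2, 6) * exp(-((idx - c0) / (w / 2))^2)
  }
  new_trace(as.numeric(x), rate = rate, channel = "RL2")
}

# local maxima of a matrix (8-neighbour), returned as row/col indices
matrix_local_maxima <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  res <- list()
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (z[i, j] == max(nb) && sum(nb == max(nb)) == 1) {
        res[[length(res) + 1]] <- c(i, j)
      }
    }
  }
  do.call(rbind, res)
}
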