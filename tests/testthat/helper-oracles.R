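# Independent oracles and fixture generators for the test suite.

# Brute-force burst search: explicit O(n^2) neighbor counting and explicit
# run merging, kept deliberately naive and independent of the package
# implementation. Returns a matrix of burst intervals (start, end).
oracle_intervals <- function(ts, L, M, T) {
  n <- length(ts)
  if (!n) return(matrix(numeric(0), 0, 2))
  qual <- logical(n)
  for (i in seq_len(n))
    qual[i] <- sum(ts >= ts[i] - T / 2 & ts <= ts[i] + T / 2) >= M
  out <- matrix(numeric(0), 0, 2)
  i <- 1L
  while (i <= n) {
    if (qual[i]) {
      j <- i
      while (j < n && qual[j + 1L]) j <- j + 1L
      if (j - i + 1L >= L) out <- rbind(out, c(ts[i], ts[j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

oracle_burst_search <- function(stream, L = 25, M = 15, T = 500,
                                mode = "dual-color") {
  ts <- timestamps(stream)
  if (mode == "all-photon") {
    ints <- oracle_intervals(ts, L, M, T)
  } else {
    a <- oracle_intervals(ts[excitation(stream) == "Dex"], L, M, T)
    b <- oracle_intervals(ts[excitation(stream) == "Aex"], L, M, T)
    ints <- matrix(numeric(0), 0, 2)
    if (nrow(a) && nrow(b))
      for (i in seq_len(nrow(a)))
        for (j in seq_len(nrow(b))) {
          s <- max(a[i, 1], b[j, 1]); e <- min(a[i, 2], b[j, 2])
          if (s <= e) ints <- rbind(ints, c(s, e))
        }
    if (nrow(ints)) ints <- ints[order(ints[, 1]), , drop = FALSE]
  }
  # naive per-interval tallies
  cat4 <- paste0(excitation(stream),
                 ifelse(channel(stream) == "D", "Dem", "Aem"))
  counts <- t(apply(ints, 1, function(iv) {
    inb <- ts >= iv[1] & ts <= iv[2]
    c(sum(cat4[inb] == "DexDem"), sum(cat4[inb] == "DexAem"),
      sum(cat4[inb] == "AexDem"), sum(cat4[inb] == "AexAem"))
  }))
  if (!nrow(ints)) counts <- matrix(integer(0), 0, 4)
  list(intervals = ints, counts = counts)
}

# Random photon stream with background plus dense clusters, n <= n_max
# photons; exercises both qualification and run-splitting paths.
random_stream <- function(seed, n_max = 2000, span_us = 2e5) {
  set.seed(seed)
  n_bg <- sample(50:300, 1)
  t_bg <- runif(n_bg, 0, span_us)
  n_cl <- sample(0:4, 1)
  t_cl <- unlist(lapply(seq_len(n_cl), function(i) {
    center <- runif(1, 0, span_us)
    width <- runif(1, 200, 2000)
    center + runif(sample(20:120, 1), -width / 2, width / 2)
  }))
  t <- floor(sort(c(t_bg, t_cl)))
  if (length(t) > n_max) t <- t[seq_len(n_max)]
  m <- length(t)
  new("PhotonStream",
      timestamps = t,
      channel = sample(c("D", "A"), m, replace = TRUE),
      excitation = sample(c("Dex", "Aex"), m, replace = TRUE),
      alternationPeriodUs = 50, groundTruth = data.frame())
}

expect_same_bursts <- function(bset, oracle) {
  b <- bursts(bset)
  expect_equal(nrow(b), nrow(oracle$intervals))
  if (nrow(b)) {
    expect_equal(b$start_us, unname(oracle$intervals[, 1]))
    expect_equal(b$end_us, unname(oracle$intervals[, 2]))
    expect_equal(unname(as.matrix(
      b[, c("n_DexDem", "n_DexAem", "n_AexDem", "n_AexAem")])),
      unname(oracle$counts))
  }
}

# One-species config used across simulation tests.
one_species_config <- function(duration_s = 2, fret_e = 0.5, D = 1.0,
                               bg = 0, seed = 1L, ...) {
  sp <- simSpecies("sp", fret_e = fret_e, diffusion_rate_D = D,
                   brightness_dex = 300, brightness_aex = 200, fraction = 1)
  simConfig(sp, duration_s = duration_s,
            background_rate_donor = bg, background_rate_acceptor = bg,
            seed = seed, ...)
}

# Truncated-normal E* sample (rejection; stays inside [0, 1]).
rtrunc_e <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= 0 & x <= 1])
  }
  out[seq_len(n)]
}

# Three-state E* sample with given weights.
three_state_sample <- function(n, means = c(0.30, 0.60, 0.90),
                               weights = c(0.5, 0.3, 0.2), sd = 0.05) {
  k <- sample.int(3, n, replace = TRUE, prob = weights)
  vapply(k, function(i) rtrunc_e(1, means[i], sd), numeric(1))
}

# Exact (noise-free) two-component duration histogram.
exact_mixture_hist <- function(D1, D2, A, delta_us = 200, nbins = 60,
                               N = 1e5) {
  t <- seq_len(nbins) * delta_us / 1000
  new("DurationHistogram", deltaUs = delta_us, tMs = t,
      counts = N * mixtureTail(t, D1, D2, A))
}

# Dense grid-search oracle for the bound fraction: minimizes the slope
# mismatch over A in steps of 1e-3, independent of the bisection solver.
grid_search_A <- function(hist, D1, D2, t1 = 2, t2 = 8) {
  sel <- hist@tMs >= t1 & hist@tMs <= t2 & hist@counts > 0
  tu <- hist@tMs[sel]
  tc <- tu - mean(tu)
  meas <- -sum(log(hist@counts[sel]) * tc) / sum(tc^2)
  grid <- seq(0, 1, by = 1e-3)
  mod <- vapply(grid, function(a) {
    y <- log(mixtureTail(tu, D1, D2, a))
    -sum(y * tc) / sum(tc^2)
  }, numeric(1))
  grid[which.min(abs(mod - meas))]
}

# Burst table wrapper around plain E* values (for filter tests).
burstset_from_e <- function(e_star, spacing_us = 1e4) {
  n <- length(e_star)
  st <- seq_len(n) * spacing_us
  b <- data.frame(start_us = st, end_us = st + 1000, duration_ms = 1,
                  n_DexDem = 100L, n_DexAem = 100L, n_AexDem = 0L,
                  n_AexAem = 100L, E_star = e_star, S = 2 / 3)
  new("BurstSet", bursts = b, params = list(), provenance = "test fixture")
}
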