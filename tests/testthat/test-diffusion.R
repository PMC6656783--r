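test_that("duration histogram bins and conserves bursts", {
  h <- burstDurationHistogram(c(1.0, 1.0, 1.0), 200)
  expect_equal(sum(h@counts), 3)
  expect_equal(sum(h@counts > 0), 1)
  expect_equal(h@tMs[h@counts > 0], 1.0)
  set.seed(1)
  d <- rexp(5000, 1)
  expect_equal(sum(burstDurationHistogram(d, 200)@counts), 5000)
  expect_error(burstDurationHistogram(d, 20), "delta_us")
})

test_that("D estimate is exact on noiseless exponential histograms", {
  t <- (1:50) * 0.2
  h <- new("DurationHistogram", deltaUs = 200, tMs = t,
           counts = 1000 * exp(-1.0 * t))
  expect_equal(estimateD(h)@DHat, 1.0, tolerance = 1e-12)
  # the reported fast-diffusion regime, via the full tail form N*D*exp(-Dt)
  h2 <- new("DurationHistogram", deltaUs = 200, tMs = t,
            counts = 5e4 * 1.10 * exp(-1.10 * t))
  expect_equal(estimateD(h2)@DHat, 1.10, tolerance = 1e-12)
  expect_error(estimateD(h, 5, 2), "t1_ms")
})

test_that("simulated exponential durations give a log-linear tail", {
  set.seed(2)
  h <- burstDurationHistogram(rexp(20000, 1.0), 200)
  est <- estimateD(h)
  expect_lt(est@ci95[1], 1.0)
  expect_gt(est@ci95[2], 1.0)
})

test_that("CI covers the truth in >= 90% of replicates per diffusion regime", {
  for (D in c(0.60, 1.10)) {
    hits <- 0
    for (r in 1:50) {
      set.seed(r)
      est <- estimateD(burstDurationHistogram(rexp(20000, D), 200))
      if (est@ci95[1] <= D && D <= est@ci95[2]) hits <- hits + 1
    }
    expect_gte(hits, 45)
  }
})

test_that("mixture tail reduces to single exponentials at the endpoints", {
  t <- seq(0.2, 10, by = 0.2)
  expect_equal(mixtureTail(t, 0.6, 1.1, 0), 1.1 * exp(-1.1 * t))
  expect_equal(mixtureTail(t, 0.6, 1.1, 1), 0.6 * exp(-0.6 * t))
  expect_equal(mixtureTail(0, 0.6, 1.1, 0.3, N = 2),
               2 * (0.3 * 0.6 + 0.7 * 1.1))
  expect_error(mixtureTail(1, -1, 1, 0.5))
  expect_error(mixtureTail(1, 1, 1, 1.5))
})

test_that("model log-slope magnitude strictly decreases with A when D1 < D2", {
  t <- seq(2, 8, by = 0.2)
  tc <- t - mean(t)
  slopes <- vapply(seq(0, 1, 0.1), function(a) {
    y <- log(mixtureTail(t, 0.6, 1.1, a))
    -sum(y * tc) / sum(tc^2)
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("bound fraction is exact on noiseless mixture histograms", {
  for (A in c(0, 0.25, 0.5, 0.75, 1)) {
    h <- exact_mixture_hist(0.60, 1.10, A)
    bf <- estimateBoundFraction(h, 0.60, 1.10)
    expect_lt(abs(bf@AHat - A), 0.001)
    expect_false(bf@clamped)
    # agrees with the independent dense grid search
    expect_lt(abs(bf@AHat - grid_search_A(h, 0.60, 1.10)), 2e-3)
  }
})

test_that("solver and grid search agree on noisy mixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    nb <- rbinom(1, 30000, 0.5)
    d <- c(rexp(nb, 0.6), rexp(30000 - nb, 1.1))
    h <- burstDurationHistogram(d, 200)
    bf <- estimateBoundFraction(h, 0.6, 1.1)
    expect_lt(abs(bf@AHat - grid_search_A(h, 0.6, 1.1)), 2e-3)
  }
})

test_that("out-of-range measured slopes clamp with a flag", {
  t <- (1:50) * 0.2
  h <- new("DurationHistogram", deltaUs = 200, tMs = t,
           counts = 1000 * exp(-2.0 * t))  # faster than D2 = 1.1
  bf <- estimateBoundFraction(h, 0.6, 1.1)
  expect_true(bf@clamped)
  expect_equal(bf@AHat, 0)
  expect_error(estimateBoundFraction(h, 1.1, 1.1), "differ")
})

test_that("per-state bound fractions recover construction ground truth", {
  # all closed-state bursts slow (A = 1), all open-state bursts fast (A = 0)
  set.seed(11)
  n <- 6000
  e_closed <- rtrunc_e(n, 0.85, 0.04)
  e_open <- rtrunc_e(n, 0.30, 0.04)
  b <- burstset_from_e(c(e_closed, e_open))
  b@bursts$duration_ms <- c(rexp(n, 0.6), rexp(n, 1.1))
  wins <- list(open = c(0.1, 0.55), closed = c(0.55, 1.0))
  res <- perStateBoundFraction(b, wins, 0.6, 1.1, min_bursts = 1000)
  expect_gt(res$closed@AHat, 0.9)
  expect_lt(res$open@AHat, 0.1)
})

test_that("mixed per-state bound fractions recover within 0.1", {
  A_true <- c(open = 0.8, intermediate = 0.5, closed = 0.2)
  means <- c(open = 0.30, intermediate = 0.60, closed = 0.90)
  set.seed(12)
  n <- 150000
  parts <- lapply(names(A_true), function(s) {
    nb <- rbinom(1, n, A_true[[s]])
    data.frame(e = rtrunc_e(n, means[[s]], 0.04),
               dur = c(rexp(nb, 0.6), rexp(n - nb, 1.1)))
  })
  all <- do.call(rbind, parts)
  b <- burstset_from_e(all$e)
  b@bursts$duration_ms <- all$dur
  wins <- list(open = c(0.1, 0.45), intermediate = c(0.45, 0.75),
               closed = c(0.75, 1.0))
  res <- perStateBoundFraction(b, wins, 0.6, 1.1, delta_us = 400)
  for (s in names(A_true))
    expect_lt(abs(res[[s]]@AHat - A_true[[s]]), 0.1)
})

test_that("undersized and overlapping state windows are rejected", {
  set.seed(13)
  b <- burstset_from_e(rtrunc_e(500, 0.5, 0.05))
  b@bursts$duration_ms <- rexp(500, 1)
  w <- capture_warnings(res <- perStateBoundFraction(
    b, list(a = c(0, 0.5), b = c(0.5, 1)), 0.6, 1.1, min_bursts = 1000))
  expect_true(all(grepl("not estimated", w)))
  expect_true(all(vapply(res, is.null, logical(1))))
  expect_error(perStateBoundFraction(
    b, list(a = c(0, 0.6), b = c(0.5, 1)), 0.6, 1.1), "disjoint")
})

test_that("Stokes-Einstein ratio follows the cube-root mass law", {
  expect_equal(stokesEinsteinRatio(70, 70), 1)
  expect_equal(stokesEinsteinRatio(10, 80), 2)
  expect_equal(round(stokesEinsteinRatio(70, 2500), 2), 3.29)
  # measured relative diffusion ratio for free vs ribosome-bound protein
  # (1.10 / 0.65 = 1.7) stays below the rigid-sphere prediction
  expect_lt(1.10 / 0.65, stokesEinsteinRatio(70, 2500))
  expect_error(stokesEinsteinRatio(0, 1))
})
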