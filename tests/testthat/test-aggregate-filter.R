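test_that("high-FRET flags follow strict inequality at the threshold", {
  expect_equal(flagHighFret(c(0.5, 0.5, 0.5), 0.9), c(0L, 0L, 0L))
  expect_equal(flagHighFret(c(0.95, 0.2, 0.91), 0.9), c(1L, 0L, 1L))
  expect_equal(flagHighFret(c(0.9, 0.90001), 0.9), c(0L, 1L))
  expect_equal(flagHighFret(c(NA, 0.95), 0.9), c(0L, 1L))
})

test_that("neighbor statistic counts n neighbors each side, zeros at edges", {
  X <- rep(1L, 9)
  expect_equal(neighborStatistic(X, i = 5, n = 3)$Ti, 6L)
  expect_equal(neighborStatistic(X, i = 5, n = 3)$p_hat_i, 1)
  expect_equal(neighborStatistic(X, i = 1, n = 3)$Ti, 3L)
  # alternating indicators: the +-1 and +-3 neighbors of a 1 are 0s, the
  # +-2 neighbors are 1s, so the neighbor sum is exactly 2
  alt <- rep(c(1L, 0L), 6)
  expect_equal(neighborStatistic(alt, i = 5, n = 3)$Ti, 2L)
  expect_equal(neighborStatistic(alt, i = 5, n = 3)$p_hat_i, 1 / 3)
  # the center burst itself is excluded from its own statistic
  X2 <- c(0L, 0L, 0L, 1L, 0L, 0L, 0L)
  expect_equal(neighborStatistic(X2, i = 4, n = 3)$Ti, 0L)
  expect_error(neighborStatistic(X, i = 10, n = 3), "out of range")
})

test_that("filter removes an embedded aggregate run and nothing else", {
  e <- rep(0.5, 1000)
  e[500:507] <- 0.95
  res <- applyAggregateFilter(burstset_from_e(e), n = 3, e = 0.9, w = 1)
  expect_equal(res$report@removedIds, 500:507)
  expect_equal(length(res$bursts), 992)
  # survivors keep their E* values
  expect_equal(Estar(res$bursts), e[-(500:507)])
})

test_that("filter removes nothing when no burst is high-FRET", {
  e <- runif(500, 0.2, 0.8)
  res <- applyAggregateFilter(burstset_from_e(e), n = 3, e = 0.9, w = 0.5)
  expect_equal(length(res$report@removedIds), 0)
  expect_equal(length(res$bursts), 500)
})

test_that("null removal fraction matches the closed-form binomial oracle", {
  # hand-derived: p' = 0.3, n = 3, w = 0.5 -> bound = 6*(0.3+0.5*sqrt(0.21))
  # = 3.175, so rejection needs T >= 4; p' * P[Binom(6, 0.3) >= 4] = 0.021141
  direct <- 0.3 * sum(choose(6, 4:6) * 0.3^(4:6) * 0.7^(6 - (4:6)))
  expect_equal(nullRemovalFraction(0.3, n = 3, w = 0.5), direct,
               tolerance = 1e-12)
  expect_equal(round(nullRemovalFraction(0.3, 3, 0.5), 4), 0.0211)
  expect_equal(nullRemovalFraction(0, 3, 0.5), 0)
  expect_equal(nullRemovalFraction(0.3, 3, 100), 0)  # acceptance covers [0,1]
})

test_that("Monte-Carlo removal on independent bursts matches the oracle", {
  set.seed(77)
  n <- 20000
  e <- ifelse(runif(n) < 0.3, 0.95, 0.5)
  res <- applyAggregateFilter(burstset_from_e(e), n = 3, e = 0.9, w = 0.5)
  expected <- nullRemovalFraction(0.3, 3, 0.5)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(res$report@removedFraction - expected), 3 * se)
})

test_that("filter is idempotent on its own output", {
  set.seed(78)
  e <- ifelse(runif(5000) < 0.2, 0.95, 0.5)
  e[1000:1008] <- 0.97
  first <- applyAggregateFilter(burstset_from_e(e), n = 3, e = 0.9, w = 1)
  second <- applyAggregateFilter(first$bursts, n = 3, e = 0.9, w = 1)
  # p-hat' drifts only marginally, so a second pass removes (almost)
  # nothing beyond null-level false positives
  expect_lt(second$report@removedFraction,
            3 * nullRemovalFraction(second$report@pHatPrime, 3, 1) + 1e-3)
})

test_that("filter finds >= 90% of labelled injected aggregates", {
  cfg <- one_species_config(duration_s = 60, fret_e = 0.5, bg = 1500,
                            seed = 41, aggregate_burst_runs = 6)
  ps <- injectAggregates(simulatePhotonStream(cfg), cfg)
  bs <- thresholdBursts(burstSearch(ps), 250)
  # label detected bursts by overlap with ground-truth aggregate transits
  gt <- groundTruth(ps)
  agg <- gt[gt$is_aggregate, ]
  b <- bursts(bs)
  is_agg <- vapply(seq_len(nrow(b)), function(i)
    any(b$start_us[i] <= agg$end_us & b$end_us[i] >= agg$start_us),
    logical(1))
  res <- applyAggregateFilter(bs, n = 3, e = 0.9, w = 1)
  caught <- intersect(which(is_agg), res$report@removedIds)
  expect_gte(length(caught) / sum(is_agg), 0.9)
})

test_that("empty input produces an empty report", {
  empty <- new("BurstSet", bursts = data.frame(), params = list(),
               provenance = character(0))
  res <- applyAggregateFilter(empty)
  expect_equal(length(res$bursts), 0)
  expect_true(is.na(res$report@pHatPrime))
})
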