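test_that("photon stream is reproducible, sorted and phase-consistent", {
  cfg <- one_species_config(duration_s = 2, bg = 1000, seed = 11)
  ps1 <- simulatePhotonStream(cfg)
  ps2 <- simulatePhotonStream(cfg)
  expect_identical(timestamps(ps1), timestamps(ps2))
  expect_identical(channel(ps1), channel(ps2))
  expect_identical(excitation(ps1), excitation(ps2))
  expect_false(is.unsorted(timestamps(ps1)))
  expect_true(all(timestamps(ps1) == floor(timestamps(ps1))))
  # excitation label is a pure function of timestamp and period
  phase <- ifelse(floor(timestamps(ps1) / 50) %% 2 == 0, "Dex", "Aex")
  expect_identical(excitation(ps1), phase)
})

test_that("with zero background every photon lies inside a true transit", {
  cfg <- one_species_config(duration_s = 2, bg = 0, seed = 3)
  ps <- simulatePhotonStream(cfg)
  gt <- groundTruth(ps)
  inside <- vapply(timestamps(ps), function(t)
    any(t >= floor(gt$start_us) & t <= gt$end_us), logical(1))
  expect_true(all(inside))
})

test_that("transit durations are exponential with the configured rate", {
  cfg <- one_species_config(duration_s = 500, D = 1.0, bg = 0, seed = 7)
  ps <- simulatePhotonStream(cfg)
  gt <- groundTruth(ps)
  dur_ms <- (gt$end_us - gt$start_us) / 1000
  expect_gt(nrow(gt), 8000)
  # sample mean within 3 standard errors of 1/D
  se <- 1 / sqrt(length(dur_ms))
  expect_lt(abs(mean(dur_ms) - 1.0), 3 * se)
  # survival function agrees with exp(-D t)
  ks <- suppressWarnings(stats::ks.test(dur_ms, "pexp", 1.0))
  expect_gt(ks$p.value, 0.01)
})

test_that("ground-truth transit E* converges to the species FRET", {
  cfg <- one_species_config(duration_s = 100, fret_e = 0.5, bg = 0,
                            seed = 5)
  ps <- simulatePhotonStream(cfg)
  dex <- excitation(ps) == "Dex"
  e_emp <- mean(channel(ps)[dex] == "A")
  expect_lt(abs(e_emp - 0.5), 3 / sqrt(sum(dex)))
})

test_that("configuration errors are rejected", {
  sp <- simSpecies("a", fraction = 1)
  expect_error(simConfig(sp, duration_s = 0), "duration_s")
  expect_error(simConfig(sp, duration_s = 1, alternation_period_us = 0),
               "alternation_period_us")
  expect_error(simConfig(list(sp, sp), duration_s = 1), "sum to 1")
  expect_error(simSpecies("x", fret_e = 1.5), "fret_e")
  expect_error(simSpecies("x", diffusion_rate_D = 0), "diffusion_rate_D")
  expect_error(simSpecies("x", stoich_class = "donor-only",
                          brightness_aex = 10), "donor-only")
  expect_error(simSpecies("x", stoich_class = "acceptor-only",
                          brightness_dex = 10), "acceptor-only")
})

test_that("aggregate injection adds labelled runs and is identity at zero", {
  cfg0 <- one_species_config(duration_s = 5, bg = 500, seed = 2)
  ps <- simulatePhotonStream(cfg0)
  expect_identical(injectAggregates(ps, cfg0), ps)

  cfg5 <- one_species_config(duration_s = 5, bg = 500, seed = 2,
                             aggregate_burst_runs = 5)
  psa <- injectAggregates(ps, cfg5)
  gt <- groundTruth(psa)
  agg <- gt[gt$is_aggregate, ]
  expect_gte(nrow(agg), 5 * 6)
  expect_lte(nrow(agg), 5 * 12)
  expect_true(all(agg$fret_e > 0.9))
  expect_false(is.unsorted(timestamps(psa)))
  expect_gt(length(psa), length(ps))
})

test_that("injected aggregates appear as runs of consecutive high-E bursts", {
  cfg <- one_species_config(duration_s = 20, fret_e = 0.5, bg = 1500,
                            seed = 13, aggregate_burst_runs = 1)
  ps <- injectAggregates(simulatePhotonStream(cfg), cfg)
  bs <- thresholdBursts(burstSearch(ps), 250)
  x <- flagHighFret(bs, 0.9)
  runs <- rle(x)
  expect_gte(max(runs$lengths[runs$values == 1]), 6)
})

test_that("simulated burst tables match their generating model", {
  cfg <- one_species_config(fret_e = 0.5, D = 1.0, seed = 21)
  bt <- simulateBurstTable(cfg, 20000)
  expect_equal(length(bt), 20000)
  e <- Estar(bt)
  expect_lt(abs(mean(e, na.rm = TRUE) - 0.5), 0.01)
  dur <- bursts(bt)$duration_ms
  expect_lt(abs(mean(dur) - 1.0), 3 / sqrt(length(dur)))
  expect_error(simulateBurstTable(cfg, 0), "n_bursts")
})

test_that("two-species burst-table duration tail follows the mixture law", {
  sp1 <- simSpecies("bound", fret_e = 0.5, diffusion_rate_D = 0.6,
                    fraction = 0.5)
  sp2 <- simSpecies("free", fret_e = 0.5, diffusion_rate_D = 1.1,
                    fraction = 0.5)
  cfg <- simConfig(list(sp1, sp2), duration_s = 1, seed = 31)
  bt <- simulateBurstTable(cfg, 60000)
  h <- burstDurationHistogram(bursts(bt)$duration_ms, 200)
  bf <- estimateBoundFraction(h, 0.6, 1.1)
  expect_lt(abs(bf@AHat - 0.5), 0.1)
})

test_that("titration simulation follows the binding isotherm", {
  tt <- simulateTitration(20e-9, c(0, 20e-9), n_bursts_per_point = 50000,
                          seed = 4)
  expect_equal(tt$bound_fraction[1], 0)
  expect_lt(abs(tt$bound_fraction[2] - 0.5), 3 * sqrt(0.25 / 50000))
  expect_error(simulateTitration(0, 1e-9), "kd")
  expect_error(simulateTitration(1e-9, -1e-9), "concentrations")
})

test_that("dissociation simulation decays at the configured rate", {
  flat <- simulateDissociation(0, c(0, 5, 10), n_per_point = 1000, seed = 6)
  expect_true(all(flat$bound_fraction == 1))
  half <- simulateDissociation(0.5, log(2) / 0.5, n_per_point = 50000,
                               seed = 6)
  expect_lt(abs(half$bound_fraction - 0.5), 3 * sqrt(0.25 / 50000))
  expect_error(simulateDissociation(-1, 1), "koff")
  expect_error(simulateDissociation(1, -1), "times")
})
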