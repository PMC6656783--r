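test_that("empty and unsorted streams are handled", {
  empty <- new("PhotonStream", timestamps = numeric(0),
               channel = character(0), excitation = character(0),
               alternationPeriodUs = 50, groundTruth = data.frame())
  expect_equal(length(burstSearch(empty)), 0)
  bad <- empty
  bad@timestamps <- c(10, 5)
  bad@channel <- c("D", "D")
  bad@excitation <- c("Dex", "Dex")
  expect_error(burstSearch(bad))
})

test_that("a hand-built dense cluster gives exactly one burst with all its photons", {
  # 30 Dex + 30 Aex photons interleaved within ~400 us, flanked by sparse
  # background at 1 photon / 10 ms
  t_dex <- 50000 + (0:29) * 13
  t_aex <- t_dex + 6
  t_bg <- c(seq(0, 40000, by = 10000), seq(60000, 100000, by = 10000))
  ts <- sort(c(t_dex, t_aex, t_bg))
  ex <- character(length(ts))
  ex[ts %in% t_dex] <- "Dex"
  ex[ts %in% t_aex] <- "Aex"
  ex[ts %in% t_bg] <- rep(c("Dex", "Aex"), length.out = length(t_bg))
  ch <- ifelse(ex == "Dex", "D", "A")
  ps <- new("PhotonStream", timestamps = ts, channel = ch,
            excitation = ex, alternationPeriodUs = 50,
            groundTruth = data.frame())
  bs <- burstSearch(ps, L = 25, M = 15, T = 500, mode = "all-photon")
  expect_equal(length(bs), 1)
  expect_equal(totalPhotons(bs), 60)
  # dual-color also finds it (each stream has 30 photons >= L = 25)
  bd <- burstSearch(ps, L = 25, M = 15, T = 500, mode = "dual-color")
  expect_equal(length(bd), 1)
})

test_that("uniform sparse background yields no bursts at default parameters", {
  set.seed(9)
  n <- 1000  # 100 photons/s for 10 s
  ts <- floor(sort(runif(n, 0, 1e7)))
  ps <- new("PhotonStream", timestamps = ts,
            channel = sample(c("D", "A"), n, TRUE),
            excitation = sample(c("Dex", "Aex"), n, TRUE),
            alternationPeriodUs = 50, groundTruth = data.frame())
  expect_equal(length(burstSearch(ps)), 0)
  expect_equal(length(burstSearch(ps, mode = "all-photon")), 0)
})

test_that("burst search matches the brute-force oracle on random streams", {
  for (seed in 1:30) {
    ps <- random_stream(seed, n_max = 600)
    for (mode in c("all-photon", "dual-color")) {
      got <- burstSearch(ps, L = 10, M = 8, T = 500, mode = mode)
      ora <- oracle_burst_search(ps, L = 10, M = 8, T = 500, mode = mode)
      expect_same_bursts(got, ora)
    }
  }
})

test_that("dual-color burst intervals are contained in all-photon intervals", {
  for (seed in 31:40) {
    ps <- random_stream(seed, n_max = 800)
    dc <- bursts(burstSearch(ps, L = 10, M = 8, T = 500,
                             mode = "dual-color"))
    ap <- bursts(burstSearch(ps, L = 10, M = 8, T = 500,
                             mode = "all-photon"))
    if (nrow(dc) == 0) next
    contained <- vapply(seq_len(nrow(dc)), function(i)
      any(ap$start_us <= dc$start_us[i] & ap$end_us >= dc$end_us[i]),
      logical(1))
    expect_true(all(contained))
  }
})

test_that("every photon lies in at most one burst", {
  cfg <- one_species_config(duration_s = 5, bg = 1500, seed = 17)
  ps <- simulatePhotonStream(cfg)
  b <- bursts(burstSearch(ps))
  if (nrow(b) > 1) {
    expect_true(all(b$start_us[-1] > b$end_us[-nrow(b)]))
  }
  expect_lte(sum(totalPhotons(burstSearch(ps))), length(ps))
})

test_that("E* and S are invariant under uniform time translation", {
  cfg <- one_species_config(duration_s = 3, bg = 1000, seed = 19)
  ps <- simulatePhotonStream(cfg)
  shifted <- new("PhotonStream", timestamps = timestamps(ps) + 1e6,
                 channel = channel(ps), excitation = excitation(ps),
                 alternationPeriodUs = 50, groundTruth = data.frame())
  b1 <- bursts(burstSearch(ps))
  b2 <- bursts(burstSearch(shifted))
  expect_equal(b2$E_star, b1$E_star)
  expect_equal(b2$S, b1$S)
  expect_equal(b2$start_us, b1$start_us + 1e6)
})

test_that("thresholding keeps bursts strictly above the photon bound", {
  e <- c(0.5, 0.5, 0.5)
  b <- burstset_from_e(e)
  b@bursts$n_DexDem <- c(50L, 100L, 200L)
  b@bursts$n_DexAem <- c(50L, 100L, 100L)
  b@bursts$n_AexAem <- c(0L, 50L, 100L)   # totals: 100, 250, 400
  expect_equal(length(thresholdBursts(b, 250)), 1)  # 250 itself removed
  expect_equal(length(thresholdBursts(b, 0)), 3)
  expect_equal(length(thresholdBursts(b, 100)), 2)
})

test_that("computeES matches its defining ratios and handles zeros", {
  es <- computeES(c(50, 0, 60, 0), c(50, 100, 40, 0), c(100, 100, 0, 50))
  expect_equal(es$E_star, c(0.5, 1.0, 0.4, NA))
  expect_equal(es$S, c(0.5, 0.5, 1.0, 0))
})

test_that("stoichiometry selection keeps doubly-labelled species", {
  da <- simSpecies("da", fret_e = 0.6, fraction = 0.6)
  donly <- simSpecies("donly", stoich_class = "donor-only",
                      brightness_aex = 0, fraction = 0.4)
  cfg <- simConfig(list(da, donly), duration_s = 1, seed = 23)
  bt <- simulateBurstTable(cfg, 5000)
  sel <- selectSpecies(bt, 0.3, 0.8)
  expect_true(all(bursts(sel)$species == "da"))
  keep_all <- bursts(bt)[!is.na(Sratio(bt)), ]
  rownames(keep_all) <- NULL
  expect_identical(bursts(selectSpecies(bt, 0, 1)), keep_all)
  expect_equal(length(selectSpecies(bt, 0.001, 0.002)), 0)
  expect_error(selectSpecies(bt, 0.8, 0.3))
})

test_that("ES histogram conserves counts and marginalizes correctly", {
  cfg <- one_species_config(fret_e = 0.6, seed = 29)
  bt <- simulateBurstTable(cfg, 2000)
  h <- esHistogram(bt)
  ok <- !is.na(Estar(bt)) & !is.na(Sratio(bt))
  expect_equal(sum(h$counts), sum(ok))
  marg_e <- rowSums(h$counts)
  e1d <- table(cut(Estar(bt)[ok], h$e_bins, include.lowest = TRUE))
  expect_equal(as.numeric(marg_e), as.numeric(e1d))
  # counts conserved under bin refinement
  h2 <- esHistogram(bt, e_bins = seq(0, 1, 0.01), s_bins = seq(0, 1, 0.01))
  expect_equal(sum(h2$counts), sum(h$counts))
  # single burst occupies a single cell
  h1 <- esHistogram(bt[1])
  expect_equal(sum(h1$counts > 0), 1)
})
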