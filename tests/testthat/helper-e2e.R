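# Shared end-to-end photon-level study: a three-state site partially bound
# to the small ribosomal subunit. State weights (0.25, 0.30, 0.45) at E*
# means (0.30, 0.60, 0.90); within each state a bound (D = 0.60 ms^-1)
# and a free (D = 1.10 ms^-1) sub-population with bound fractions
# (0.10, 0.25, 0.40) — binding strongest for the closed state. Streams are
# simulated in independent chunks (separate measurements) and pooled.

e2e_state_weights <- c(open = 0.25, intermediate = 0.30, closed = 0.45)
e2e_state_means <- c(open = 0.30, intermediate = 0.60, closed = 0.90)
e2e_bound_fractions <- c(open = 0.10, intermediate = 0.25, closed = 0.40)
e2e_windows <- list(open = c(0.15, 0.45), intermediate = c(0.45, 0.75),
                    closed = c(0.75, 1.0))

e2e_species <- function() {
  out <- list()
  for (s in names(e2e_state_weights)) {
    w <- e2e_state_weights[[s]]; A <- e2e_bound_fractions[[s]]
    e <- e2e_state_means[[s]]
    out <- c(out, list(
      simSpecies(paste0(s, "_bound"), fret_e = e, diffusion_rate_D = 0.60,
                 brightness_dex = 300, brightness_aex = 200,
                 fraction = w * A),
      simSpecies(paste0(s, "_free"), fret_e = e, diffusion_rate_D = 1.10,
                 brightness_dex = 300, brightness_aex = 200,
                 fraction = w * (1 - A))))
  }
  out
}

# Simulate, search, threshold, select, filter one chunk; label surviving
# bursts by their overlapping ground-truth transit. Returns the burst
# data.frame plus a state label column ('aggregate' / NA for unmatched).
e2e_chunk <- function(seed, chunk_s = 600) {
  cfg <- simConfig(e2e_species(), duration_s = chunk_s,
                   transit_rate_hz = 20, min_gap_us = 2000,
                   aggregate_burst_runs = 2, seed = seed)
  ps <- injectAggregates(simulatePhotonStream(cfg), cfg)
  bs <- thresholdBursts(burstSearch(ps), 250)
  bs <- selectSpecies(bs, 0.3, 0.8)
  res <- applyAggregateFilter(bs, n = 3, e = 0.9, w = 1)
  b <- bursts(res$bursts)
  gt <- groundTruth(ps)
  gi <- findInterval(b$start_us, gt$start_us)
  lab <- ifelse(gi >= 1 & b$start_us <= gt$end_us[pmax(gi, 1)] + 500,
                gt$species[pmax(gi, 1)], NA_character_)
  b$state <- sub("_(bound|free)$", "", lab)
  b$state[grepl("^aggregate", b$state)] <- "aggregate"
  b
}

run_e2e_study <- function(seed, n_chunks = 12, chunk_s = 600) {
  chunks <- lapply(seq_len(n_chunks), function(i)
    e2e_chunk(seed * 1000L + i, chunk_s))
  offset <- 0
  for (i in seq_along(chunks)) {
    chunks[[i]]$start_us <- chunks[[i]]$start_us + offset
    chunks[[i]]$end_us <- chunks[[i]]$end_us + offset
    offset <- offset + chunk_s * 1e6
  }
  b <- do.call(rbind, chunks)
  rownames(b) <- NULL
  bset <- new("BurstSet", bursts = b[, setdiff(names(b), "state")],
              params = list(), provenance = "pooled end-to-end study")
  mix <- selectModel(Estar(bset), sigma_bounds = c(0.01, 0.10))
  pops <- statePopulations(mix)
  perA <- perStateBoundFraction(bset, e2e_windows, 0.60, 1.10,
                                delta_us = 400)
  truth <- table(factor(b$state, levels = names(e2e_state_weights)))
  list(bursts = bset, mixture = mix, populations = pops,
       per_state_A = vapply(perA, function(x)
         if (is.null(x)) NA_real_ else x@AHat, numeric(1)),
       truth_populations = 100 * as.numeric(truth) / sum(truth),
       n_bursts = length(bset))
}
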