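# Synthetic photon streams and burst tables with known ground truth.
#
# The generator emulates the photon statistics the downstream estimators
# assume: molecules transit the confocal volume at Poisson times, transit
# durations are exponential with a species-specific rate D (ms^-1), photon
# emission during a transit is Poisson at constant (rectangular) brightness,
# donor-excitation photons of a donor-acceptor molecule are routed to the
# acceptor channel with probability E*, and lasers alternate every 50 us.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Define a simulated molecular species
#'
#' A species is one diffusing population with a fixed apparent FRET
#' efficiency, labeling class, relative diffusion rate and brightness.
#' Brightness is the photon emission rate while the molecule sits in the
#' excitation volume and the matching laser is on.
#'
#' @param name character label.
#' @param fret_e apparent FRET efficiency in [0, 1]; ignored for
#'   acceptor-only species.
#' @param stoich_class one of \code{"donor-acceptor"}, \code{"donor-only"},
#'   \code{"acceptor-only"}.
#' @param diffusion_rate_D transit-duration rate in ms^-1 (> 0); mean transit
#'   lasts 1/D milliseconds.
#' @param brightness_dex photons per ms emitted during donor-excitation
#'   periods of a transit (>= 0).
#' @param brightness_aex photons per ms during acceptor-excitation periods
#'   (>= 0); must be 0 for donor-only species.
#' @param fraction population fraction in [0, 1]; fractions of all species
#'   in a config must sum to 1.
#' @return a list of class \code{simSpecies}.
#' @examples
#' simSpecies("free", fret_e = 0.6, diffusion_rate_D = 1.1,
#'            brightness_dex = 200, brightness_aex = 120, fraction = 1)
#' @export
simSpecies <- function(name, fret_e = 0.5,
                       stoich_class = c("donor-acceptor", "donor-only",
                                        "acceptor-only"),
                       diffusion_rate_D = 1.0,
                       brightness_dex = 200, brightness_aex = 120,
                       fraction = 1) {
  stoich_class <- match.arg(stoich_class)
  if (fret_e < 0 || fret_e > 1) stop("fret_e must be in [0, 1]")
  if (diffusion_rate_D <= 0) stop("diffusion_rate_D must be > 0")
  if (brightness_dex < 0 || brightness_aex < 0)
    stop("brightness must be >= 0")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (stoich_class == "donor-only" && brightness_aex != 0)
    stop("donor-only species cannot emit under acceptor excitation")
  if (stoich_class == "acceptor-only" && brightness_dex != 0)
    stop("acceptor-only species cannot emit under donor excitation ",
         "(direct excitation is modelled at the config level)")
  structure(list(name = name, fret_e = fret_e, stoich_class = stoich_class,
                 diffusion_rate_D = diffusion_rate_D,
                 brightness_dex = brightness_dex,
                 brightness_aex = brightness_aex, fraction = fraction),
            class = "simSpecies")
}

#' Configure a photon-stream simulation
#'
#' @param species list of \code{\link{simSpecies}}; fractions must sum to 1.
#' @param duration_s measurement length in seconds (> 0).
#' @param alternation_period_us laser alternation period in microseconds
#'   (default 50; the full donor+acceptor cycle is twice this).
#' @param transit_rate_hz molecule transits per second (Poisson); a
#'   convention of the generator, chosen to give well-separated bursts.
#' @param background_rate_donor,background_rate_acceptor uniform Poisson
#'   background, photons per second, per detection channel.
#' @param aggregate_burst_runs number of fluorescent-aggregate events to
#'   inject with [injectAggregates()] (default 0).
#' @param aggregate_run_length_range integer pair, consecutive bright
#'   transits per aggregate (default 6-12).
#' @param aggregate_e_min minimum apparent FRET of aggregate transits
#'   (default 0.9).
#' @param min_gap_us minimum separation between consecutive transits in
#'   microseconds (default 0: pure Poisson transit starts). A positive
#'   value thins coincident transits (hard-core placement), emulating the
#'   strongly diluted single-molecule regime in which two molecules
#'   essentially never occupy the excitation volume back to back; use it
#'   for studies that rely on burst durations mapping one-to-one onto
#'   single-molecule transits.
#' @param direct_excitation,donor_leakage optional routing probabilities
#'   (default 0: the analysis works on uncorrected E*).
#' @param seed integer; the same seed and config reproduce the stream
#'   bit-for-bit.
#' @return a list of class \code{simConfig}.
#' @export
simConfig <- function(species, duration_s,
                      alternation_period_us = 50,
                      transit_rate_hz = 20,
                      background_rate_donor = 1500,
                      background_rate_acceptor = 1500,
                      aggregate_burst_runs = 0,
                      aggregate_run_length_range = c(6L, 12L),
                      aggregate_e_min = 0.9,
                      min_gap_us = 0,
                      direct_excitation = 0, donor_leakage = 0,
                      seed = 1L) {
  if (inherits(species, "simSpecies")) species <- list(species)
  if (!length(species) || !all(vapply(species, inherits, TRUE, "simSpecies")))
    stop("species must be a list of simSpecies objects")
  fr <- vapply(species, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) stop("species fractions must sum to 1")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (alternation_period_us <= 0)
    stop("alternation_period_us must be > 0")
  if (background_rate_donor < 0 || background_rate_acceptor < 0 ||
      transit_rate_hz < 0)
    stop("rates must be >= 0")
  if (length(aggregate_run_length_range) != 2 ||
      aggregate_run_length_range[1] > aggregate_run_length_range[2] ||
      aggregate_run_length_range[1] < 1)
    stop("aggregate_run_length_range must be an increasing positive pair")
  structure(list(species = species, duration_s = duration_s,
                 alternation_period_us = alternation_period_us,
                 transit_rate_hz = transit_rate_hz,
                 background_rate_donor = background_rate_donor,
                 background_rate_acceptor = background_rate_acceptor,
                 aggregate_burst_runs = as.integer(aggregate_burst_runs),
                 aggregate_run_length_range =
                   as.integer(aggregate_run_length_range),
                 aggregate_e_min = aggregate_e_min,
                 min_gap_us = min_gap_us,
                 direct_excitation = direct_excitation,
                 donor_leakage = donor_leakage,
                 seed = as.integer(seed)),
            class = "simConfig")
}

# Excitation phase from timestamp: the donor laser is on during even
# periods of the alternation cycle.
.phase_of <- function(t_us, period_us) {
  ifelse((floor(t_us / period_us) %% 2) == 0, "Dex", "Aex")
}

# Emit photons for a block of transits (vectorized over transits and
# photons). Returns timestamp/channel/excitation vectors (unsorted).
.emit_transits <- function(start_us, dur_us, fret_e, b_dex, b_aex,
                           leakage, period_us) {
  dur_ms <- dur_us / 1000
  rmax <- pmax(b_dex, b_aex)
  n <- rpois(length(dur_ms), rmax * dur_ms)
  idx <- rep.int(seq_along(n), n)
  if (!length(idx))
    return(list(t = numeric(0), ch = character(0), ex = character(0)))
  t <- floor(start_us[idx] + runif(length(idx)) * dur_us[idx])  # 1-us timer
  ex <- .phase_of(t, period_us)
  # thin the homogeneous proposal down to the phase-dependent rate
  rate <- ifelse(ex == "Dex", b_dex[idx], b_aex[idx])
  keep <- runif(length(idx)) < rate / rmax[idx]
  t <- t[keep]; ex <- ex[keep]; idx <- idx[keep]
  ch <- character(length(t))
  dex <- ex == "Dex"
  # donor-excitation photons: sensitized acceptor emission w.p. fret_e
  # (plus leakage of donor photons into the acceptor channel)
  p_acc <- fret_e[idx] + (1 - fret_e[idx]) * leakage
  ch[dex] <- ifelse(runif(sum(dex)) < p_acc[dex], "A", "D")
  ch[!dex] <- "A"
  list(t = t, ch = ch, ex = ex)
}

#' Simulate a us-ALEX photon stream
#'
#' Generates a time-sorted photon record for freely diffusing molecules:
#' Poisson transit start times, exponential transit durations (rate =
#' species \code{diffusion_rate_D}), Poisson photon emission at constant
#' brightness within each transit, binomial donor/acceptor routing by the
#' species FRET efficiency, and uniform Poisson background in both
#' channels. Timestamps are quantized to integer microseconds. The true
#' transit intervals are kept in the \code{groundTruth} slot.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \linkS4class{PhotonStream}.
#' @examples
#' sp <- simSpecies("x", fret_e = 0.5, diffusion_rate_D = 1,
#'                  brightness_dex = 300, brightness_aex = 200, fraction = 1)
#' ps <- simulatePhotonStream(simConfig(sp, duration_s = 1, seed = 7))
#' ps
#' @export
simulatePhotonStream <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  .with_seed(config$seed, {
    dur_us <- config$duration_s * 1e6
    per <- config$alternation_period_us
    n_tr <- rpois(1, config$transit_rate_hz * config$duration_s)
    starts <- sort(runif(n_tr, 0, dur_us))
    fr <- vapply(config$species, `[[`, numeric(1), "fraction")
    sp_idx <- sample.int(length(fr), n_tr, replace = TRUE, prob = fr)
    D <- vapply(config$species, `[[`, numeric(1), "diffusion_rate_D")
    e <- vapply(config$species, `[[`, numeric(1), "fret_e")
    cls <- vapply(config$species, `[[`, character(1), "stoich_class")
    bdx <- vapply(config$species, `[[`, numeric(1), "brightness_dex")
    bax <- vapply(config$species, `[[`, numeric(1), "brightness_aex")
    # direct acceptor excitation during Dex periods, if enabled, makes an
    # acceptor-only molecule visible in the Dex stream
    bdx_eff <- ifelse(cls == "acceptor-only",
                      config$direct_excitation * bax, bdx)
    e_eff <- ifelse(cls == "donor-only", 0,
                    ifelse(cls == "acceptor-only", 1, e))
    durs <- rexp(n_tr, rate = D[sp_idx]) * 1000  # us
    if (config$min_gap_us > 0 && n_tr > 1) {
      # hard-core thinning: drop transits starting within min_gap_us of
      # the previous kept transit's end
      keep <- logical(n_tr)
      last_end <- -Inf
      for (i in seq_len(n_tr)) {
        if (starts[i] >= last_end + config$min_gap_us) {
          keep[i] <- TRUE
          last_end <- starts[i] + durs[i]
        }
      }
      starts <- starts[keep]; durs <- durs[keep]; sp_idx <- sp_idx[keep]
      n_tr <- length(starts)
    }
    ph <- .emit_transits(starts, durs, e_eff[sp_idx], bdx_eff[sp_idx],
                         bax[sp_idx], config$donor_leakage, per)
    # background, per channel, uniform over the measurement
    nbd <- rpois(1, config$background_rate_donor * config$duration_s)
    nba <- rpois(1, config$background_rate_acceptor * config$duration_s)
    tb <- floor(c(runif(nbd, 0, dur_us), runif(nba, 0, dur_us)))
    cb <- c(rep("D", nbd), rep("A", nba))
    t_all <- c(ph$t, tb)
    ch_all <- c(ph$ch, cb)
    ex_all <- c(ph$ex, .phase_of(tb, per))
    o <- order(t_all)
    gt <- data.frame(
      start_us = starts, end_us = starts + durs,
      species = vapply(config$species, `[[`, character(1), "name")[sp_idx],
      fret_e = e_eff[sp_idx], is_aggregate = FALSE,
      stringsAsFactors = FALSE)
    new("PhotonStream", timestamps = t_all[o], channel = ch_all[o],
        excitation = ex_all[o], alternationPeriodUs = per,
        groundTruth = gt)
  })
}

#' Inject fluorescent-aggregate artifacts into a photon stream
#'
#' Large fluorescent aggregates traverse the excitation volume slowly and
#' produce runs of 6-12 consecutive, correlated bursts with unrealistically
#' high apparent FRET (E* > 0.9). This models each aggregate event as a run
#' of consecutive bright transits (2-5x the brightest species, equally
#' bright in both excitation periods so they pass dual-color search and
#' intermediate-S selection), separated by a few milliseconds so the burst
#' search resolves them as distinct bursts. Ground-truth rows are labelled
#' \code{is_aggregate = TRUE}.
#'
#' @param stream a \linkS4class{PhotonStream}.
#' @param config the \code{\link{simConfig}} (uses
#'   \code{aggregate_burst_runs}, \code{aggregate_run_length_range},
#'   \code{aggregate_e_min}; seeded from \code{config$seed}).
#' @return a time-sorted \linkS4class{PhotonStream} including the injected
#'   photons and labelled ground truth.
#' @export
injectAggregates <- function(stream, config) {
  stopifnot(is(stream, "PhotonStream"), inherits(config, "simConfig"))
  n_runs <- config$aggregate_burst_runs
  if (n_runs == 0) return(stream)
  .with_seed(config$seed + 104729L, {  # distinct sub-stream of randomness
    per <- stream@alternationPeriodUs
    dur_us <- config$duration_s * 1e6
    rng <- config$aggregate_run_length_range
    base_b <- max(vapply(config$species, `[[`, numeric(1),
                         "brightness_dex"), 100)
    t <- list(); ch <- list(); ex <- list(); gt <- list()
    for (r in seq_len(n_runs)) {
      len <- sample(seq(rng[1], rng[2]), 1)
      b <- runif(1, 2, 5) * base_b
      e_run <- runif(1, min(config$aggregate_e_min + 0.02, 0.99), 0.99)
      durs <- rexp(len, rate = 0.5) * 1000           # slow, bright transits
      gaps <- runif(len, 2000, 5000)                 # us between transits
      starts <- runif(1, 0, dur_us) + cumsum(gaps) + c(0, cumsum(durs))[1:len]
      ph <- .emit_transits(starts, durs, rep(e_run, len), rep(b, len),
                           rep(b, len), 0, per)
      t[[r]] <- ph$t; ch[[r]] <- ph$ch; ex[[r]] <- ph$ex
      gt[[r]] <- data.frame(start_us = starts, end_us = starts + durs,
                            species = sprintf("aggregate_%d", r),
                            fret_e = e_run, is_aggregate = TRUE,
                            stringsAsFactors = FALSE)
    }
    t_all <- c(stream@timestamps, unlist(t))
    ch_all <- c(stream@channel, unlist(ch))
    ex_all <- c(stream@excitation, unlist(ex))
    o <- order(t_all)
    gt_all <- rbind(stream@groundTruth, do.call(rbind, gt))
    gt_all <- gt_all[order(gt_all$start_us), , drop = FALSE]
    rownames(gt_all) <- NULL
    new("PhotonStream", timestamps = t_all[o], channel = ch_all[o],
        excitation = ex_all[o], alternationPeriodUs = per,
        groundTruth = gt_all)
  })
}

#' Simulate a burst table directly (burst-level shortcut)
#'
#' Skips photon-level detection and draws bursts straight from the model the
#' duration estimators assume: species chosen by population fraction,
#' duration exponential with the species rate D, donor-excitation photon
#' count Poisson with mean \code{brightness_dex * duration / 2} (the donor
#' laser is on half the time), sensitized acceptor counts binomial with the
#' species FRET efficiency, acceptor-excitation counts Poisson likewise.
#'
#' @param config a \code{\link{simConfig}} (uses species and seed).
#' @param n_bursts number of bursts to draw (> 0).
#' @param seed optional override of \code{config$seed}.
#' @return a \linkS4class{BurstSet} with a \code{species} column.
#' @export
simulateBurstTable <- function(config, n_bursts, seed = config$seed) {
  stopifnot(inherits(config, "simConfig"))
  if (!is.numeric(n_bursts) || n_bursts <= 0)
    stop("n_bursts must be > 0")
  n_bursts <- as.integer(n_bursts)
  .with_seed(seed, {
    fr <- vapply(config$species, `[[`, numeric(1), "fraction")
    sp <- sample.int(length(fr), n_bursts, replace = TRUE, prob = fr)
    D <- vapply(config$species, `[[`, numeric(1), "diffusion_rate_D")[sp]
    e <- vapply(config$species, `[[`, numeric(1), "fret_e")[sp]
    cls <- vapply(config$species, `[[`, character(1), "stoich_class")[sp]
    bdx <- vapply(config$species, `[[`, numeric(1), "brightness_dex")[sp]
    bax <- vapply(config$species, `[[`, numeric(1), "brightness_aex")[sp]
    e <- ifelse(cls == "donor-only", 0, ifelse(cls == "acceptor-only", 1, e))
    dur_ms <- rexp(n_bursts, rate = D)
    nDex <- rpois(n_bursts, bdx * dur_ms / 2)
    nDexAem <- rbinom(n_bursts, nDex, e)
    nDexDem <- nDex - nDexAem
    nAexAem <- rpois(n_bursts, bax * dur_ms / 2)
    # bursts laid end to end with 10 ms spacing: start times are bookkeeping
    starts <- cumsum(c(0, head(dur_ms * 1000 + 10000, -1)))
    es <- computeES(nDexDem, nDexAem, nAexAem)
    b <- data.frame(start_us = starts, end_us = starts + dur_ms * 1000,
                    duration_ms = dur_ms,
                    n_DexDem = nDexDem, n_DexAem = nDexAem,
                    n_AexDem = 0L, n_AexAem = nAexAem,
                    E_star = es$E_star, S = es$S,
                    species = vapply(config$species, `[[`, character(1),
                                     "name")[sp],
                    stringsAsFactors = FALSE)
    new("BurstSet", bursts = b,
        params = list(source = "simulateBurstTable", seed = seed),
        provenance = "simulated burst table")
  })
}

#' Simulate an equilibrium binding titration
#'
#' Draws bound fractions around the hyperbolic binding isotherm
#' f(c) = c / (K_D + c) with binomial sampling noise at
#' \code{n_bursts_per_point} observations per concentration.
#'
#' @param kd dissociation constant, molar (> 0).
#' @param concentrations molar concentrations (>= 0).
#' @param n_bursts_per_point bursts classified per titration point.
#' @param seed integer seed.
#' @return data.frame with columns \code{concentration},
#'   \code{bound_fraction}, \code{n}.
#' @export
simulateTitration <- function(kd, concentrations, n_bursts_per_point = 2000,
                              seed = 1L) {
  if (kd <= 0) stop("kd must be > 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  .with_seed(seed, {
    f <- concentrations / (kd + concentrations)
    k <- rbinom(length(f), n_bursts_per_point, f)
    data.frame(concentration = concentrations,
               bound_fraction = k / n_bursts_per_point,
               n = n_bursts_per_point)
  })
}

#' Simulate a dissociation time course
#'
#' Draws bound fractions around the exponential decay exp(-k_off * t) with
#' binomial sampling noise, emulating complex dissociation after removal of
#' the stabilizing nucleotide.
#'
#' @param koff dissociation rate, per minute (>= 0).
#' @param times minutes (>= 0).
#' @param n_per_point observations per time point.
#' @param seed integer seed.
#' @return data.frame with columns \code{time_min}, \code{bound_fraction},
#'   \code{n}.
#' @export
simulateDissociation <- function(koff, times, n_per_point = 2000, seed = 1L) {
  if (koff < 0) stop("koff must be >= 0")
  if (any(times < 0)) stop("times must be >= 0")
  .with_seed(seed, {
    f <- exp(-koff * times)
    k <- rbinom(length(f), n_per_point, f)
    data.frame(time_min = times, bound_fraction = k / n_per_point,
               n = n_per_point)
  })
}
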