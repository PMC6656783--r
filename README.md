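# alexburst

Burst analysis for microsecond alternating-laser-excitation (us-ALEX)
single-molecule FRET of freely diffusing molecules.

## The problem

A FRET-labelled protein — the motivating system is the twin-ATPase
ribosome-recycling factor ABCE1, whose two ATP sites interconvert between
open, intermediate and closed conformations — diffuses through a confocal
excitation volume for about a millisecond at a time, emitting a burst of
photons. Two lasers alternating every 50 us give every burst two
coordinates:

* apparent FRET efficiency
  **E\* = n_DexAem / (n_DexDem + n_DexAem)** — a proxy for the
  donor–acceptor distance and hence the conformational state;
* stoichiometry
  **S = (n_DexDem + n_DexAem) / (n_DexDem + n_DexAem + n_AexAem)** —
  which separates doubly labelled molecules (intermediate S) from
  donor-only and acceptor-only species.

The burst *duration* distribution adds a third, label-free observable: its
exponential tail `P(t; D) = N·D·exp(−D·t)` has a decay rate D (ms⁻¹) that
drops when the protein binds a ribosomal subunit, so a two-component tail
`N·(A·D1·e^{−D1 t} + (1−A)·D2·e^{−D2 t})` yields the ribosome-bound
fraction A.

`alexburst` implements the full chain in S4:

1. **Burst search** — sliding-window detection (≥ M photons within T us,
   runs of ≥ L photons; defaults M = 15, T = 500, L = 25), dual-color or
   all-photon, photon threshold > 250, E*/S per burst.
2. **Aggregate filter** — a Bernoulli/binomial hypothesis test that
   removes runs of correlated high-E\* bursts produced by fluorescent
   aggregates, with a closed-form null oracle.
3. **State decomposition** — 1–3 Gaussian mixture fit of the E\*
   histogram with constrained widths; minimal adequate model order;
   populations from normalized component areas.
4. **Diffusion analysis** — burst-duration histogram, log-slope estimator
   for D with a Poisson-calibrated 95% CI, bound-fraction estimator by
   slope matching, per-state bound fractions, Stokes–Einstein
   `(m2/m1)^(1/3)` consistency check.
5. **Binding kinetics** — K_D from titrations, k_off from dissociation
   time courses, `k_on = (k_off/60)/K_D`, mean association time
   `1/(k_on·c)`.
6. **Synthetic data** — a seeded photon-stream generator (Poisson
   transits, exponential durations, binomial FRET routing, Poisson
   background, 1-us timestamps, ground truth attached) so every stage is
   testable without instrument data.

## Worked example

Simulate a three-state equilibrium (50/30/20% at E\* = 0.30/0.60/0.90),
detect and filter bursts, and decompose the states:

```r
library(alexburst)
sp <- list(
  simSpecies("open",   fret_e = 0.30, diffusion_rate_D = 1.10,
             brightness_dex = 300, brightness_aex = 200, fraction = 0.5),
  simSpecies("inter",  fret_e = 0.60, diffusion_rate_D = 1.10,
             brightness_dex = 300, brightness_aex = 200, fraction = 0.3),
  simSpecies("closed", fret_e = 0.90, diffusion_rate_D = 1.10,
             brightness_dex = 300, brightness_aex = 200, fraction = 0.2))
cfg <- simConfig(sp, duration_s = 300, min_gap_us = 2000, seed = 42)
stream <- simulatePhotonStream(cfg)

bs  <- selectSpecies(thresholdBursts(burstSearch(stream), 250), 0.3, 0.8)
bs
#> BurstSet with 1882 bursts
#>   photons/burst: median 410 [251, 2581]
#>   E*: mean 0.512 (defined for 1882 bursts)

flt <- applyAggregateFilter(bs)
fit <- selectModel(Estar(flt$bursts), sigma_bounds = c(0.01, 0.10))
fit
#> MixtureResult: 3 component(s), reduced chi-square 0.657
#>   mean 0.300  sigma 0.030  weight 0.502
#>   mean 0.602  sigma 0.031  weight 0.294
#>   mean 0.894  sigma 0.019  weight 0.205
round(statePopulations(fit), 1)
#>         open intermediate       closed
#>         50.2         29.4         20.5
```

The fit recovers the generating means to 0.006 and the populations to
under one percentage point. The same burst set yields the diffusion
constant of the (here purely free, D = 1.10 ms⁻¹) population:

```r
estimateD(burstDurationHistogram(flt$bursts))
#> DiffusionEstimate: D = 1.067 ms^-1 [95% CI 0.891, 1.243], 23 bins in [2, 8] ms
```

and the kinetics arithmetic chains the printed binding regime:

```r
kon <- associationRate(0.5, 20e-9)   # k_off = 0.5/min, K_D = 20 nM
kon                                  # 416667 /M/s, i.e. ~4e5
meanAssociationTime(kon, 1e-6)       # 2.4 s at 1 uM ribosome
```

`runPipeline()` chains all stages from one config (R list or YAML; see
`inst/scripts/run_pipeline.R` for a command-line wrapper), writing burst
tables, state and diffusion JSON and a reproducibility manifest.

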