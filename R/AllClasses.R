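#' @import methods
#' @importFrom stats rexp rpois runif rbinom rnorm optim lm coef confint
#'   pbinom dnorm quantile uniroot setNames predict sd median qt
#' @importFrom utils read.csv write.csv head tail
#' @importFrom graphics hist
NULL

#' PhotonStream: a time-ordered photon record
#'
#' Container for the raw observable of a diffusion-based us-ALEX experiment:
#' one row per detected photon, carrying its arrival time (microseconds,
#' integer-quantized), detection channel (donor or acceptor emission) and
#' excitation phase (donor- or acceptor-excitation period of the laser
#' alternation). The excitation phase is a pure function of the timestamp and
#' the alternation period. Synthetic streams additionally carry a
#' ground-truth table of molecule transits for validation.
#'
#' @slot timestamps numeric, photon arrival times in microseconds, sorted
#'   non-decreasing.
#' @slot channel character, \code{"D"} (donor emission) or \code{"A"}
#'   (acceptor emission), one per photon.
#' @slot excitation character, \code{"Dex"} or \code{"Aex"}, one per photon.
#' @slot alternationPeriodUs numeric(1), duration of one excitation period in
#'   microseconds (donor and acceptor periods alternate, full cycle is twice
#'   this value).
#' @slot groundTruth data.frame of true transit intervals
#'   (\code{start_us}, \code{end_us}, \code{species}, \code{fret_e},
#'   \code{is_aggregate}); zero rows for experimental data.
#'
#' @seealso [simulatePhotonStream()], [burstSearch()]
#' @export
setClass("PhotonStream",
  slots = c(
    timestamps          = "numeric",
    channel             = "character",
    excitation          = "character",
    alternationPeriodUs = "numeric",
    groundTruth         = "data.frame"
  ),
  prototype = prototype(
    timestamps = numeric(0), channel = character(0),
    excitation = character(0), alternationPeriodUs = 50,
    groundTruth = data.frame()
  )
)

setValidity("PhotonStream", function(object) {
  msg <- character(0)
  n <- length(object@timestamps)
  if (length(object@channel) != n || length(object@excitation) != n)
    msg <- c(msg, "timestamps, channel and excitation must have equal length")
  if (n > 1 && is.unsorted(object@timestamps))
    msg <- c(msg, "timestamps must be non-decreasing")
  if (!all(object@channel %in% c("D", "A")))
    msg <- c(msg, "channel values must be 'D' or 'A'")
  if (!all(object@excitation %in% c("Dex", "Aex")))
    msg <- c(msg, "excitation values must be 'Dex' or 'Aex'")
  if (length(object@alternationPeriodUs) != 1 ||
      object@alternationPeriodUs <= 0)
    msg <- c(msg, "alternationPeriodUs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' BurstSet: detected single-molecule bursts
#'
#' One row per burst with its time interval, photon counts split by
#' (excitation period, detection channel), the apparent FRET efficiency E*
#' and the stoichiometry S. Counts use ALEX notation: \code{n_DexDem} =
#' donor-excitation donor-emission, \code{n_DexAem} = donor-excitation
#' acceptor-emission (sensitized emission), \code{n_AexAem} =
#' acceptor-excitation acceptor-emission, \code{n_AexDem} recorded but never
#' used in E*/S. E* and S are \code{NA} where their denominator is zero.
#'
#' @slot bursts data.frame with columns \code{start_us}, \code{end_us},
#'   \code{duration_ms}, \code{n_DexDem}, \code{n_DexAem}, \code{n_AexDem},
#'   \code{n_AexAem}, \code{E_star}, \code{S} (plus optional provenance
#'   columns such as \code{species} or \code{is_aggregate} for synthetic
#'   data), ordered by \code{start_us}.
#' @slot params list, the search/threshold/filter parameters that produced
#'   the set.
#' @slot provenance character, free-form notes on the processing chain.
#'
#' @seealso [burstSearch()], [thresholdBursts()], [applyAggregateFilter()]
#' @export
setClass("BurstSet",
  slots = c(bursts = "data.frame", params = "list", provenance = "character"),
  prototype = prototype(bursts = data.frame(), params = list(),
                        provenance = character(0))
)

.burst_core_cols <- c("start_us", "end_us", "duration_ms",
                      "n_DexDem", "n_DexAem", "n_AexDem", "n_AexAem",
                      "E_star", "S")

setValidity("BurstSet", function(object) {
  b <- object@bursts
  if (nrow(b) == 0) return(TRUE)
  missing <- setdiff(.burst_core_cols, names(b))
  if (length(missing))
    return(paste("missing burst columns:", paste(missing, collapse = ", ")))
  if (is.unsorted(b$start_us))
    return("bursts must be ordered by start_us")
  if (any(b$end_us < b$start_us))
    return("burst end_us must be >= start_us")
  TRUE
})

#' MixtureResult: Gaussian decomposition of an E* histogram
#'
#' Result of fitting a 1-3 component Gaussian sum to a binned apparent-FRET
#' histogram. Component means are apparent FRET values of conformational
#' states; weights (component areas normalized to one) are state abundances.
#' Components are stored sorted by ascending mean so that, for a three-state
#' ATPase site, they map onto open / intermediate / closed.
#'
#' @slot components data.frame with columns \code{mean}, \code{sigma},
#'   \code{amplitude}, \code{weight}, sorted by ascending mean.
#' @slot nComponents integer(1), number of fitted components.
#' @slot goodness numeric(1), reduced chi-square of the fit on the histogram.
#' @slot allGoodness numeric, reduced chi-square for every model order tried
#'   (named), populated by [selectModel()].
#' @slot converged logical(1), FALSE flags a degenerate or failed fit.
#' @slot binWidth numeric(1), E* histogram bin width used.
#'
#' @seealso [fitMixture()], [selectModel()], [statePopulations()]
#' @export
setClass("MixtureResult",
  slots = c(components = "data.frame", nComponents = "integer",
            goodness = "numeric", allGoodness = "numeric",
            converged = "logical", binWidth = "numeric"),
  prototype = prototype(components = data.frame(), nComponents = 0L,
                        goodness = NA_real_, allGoodness = numeric(0),
                        converged = TRUE, binWidth = 0.02)
)

setValidity("MixtureResult", function(object) {
  cmp <- object@components
  if (nrow(cmp) == 0) return(TRUE)
  if (!all(c("mean", "sigma", "weight") %in% names(cmp)))
    return("components need columns mean, sigma, weight")
  if (is.unsorted(cmp$mean)) return("components must be sorted by mean")
  if (abs(sum(cmp$weight) - 1) > 1e-6)
    return("component weights must sum to 1")
  TRUE
})

#' DurationHistogram: binned burst-duration counts
#'
#' Histogram of burst durations with bin size Delta (microseconds); bin i is
#' centered at t = i * Delta and collects bursts with duration in
#' (i*Delta - Delta/2, i*Delta + Delta/2]. The exponential tail of this
#' histogram carries the relative diffusion constant of the molecules.
#'
#' @slot deltaUs numeric(1), bin size in microseconds.
#' @slot tMs numeric, bin centers in milliseconds (i * Delta).
#' @slot counts numeric, burst counts per bin.
#'
#' @seealso [burstDurationHistogram()], [estimateD()]
#' @export
setClass("DurationHistogram",
  slots = c(deltaUs = "numeric", tMs = "numeric", counts = "numeric"))

setValidity("DurationHistogram", function(object) {
  if (length(object@tMs) != length(object@counts))
    return("tMs and counts must have equal length")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (length(object@tMs) > 1 && any(diff(object@tMs) <= 0))
    return("bin centers must be strictly increasing")
  TRUE
})

#' DiffusionEstimate: log-slope estimate of the relative diffusion constant
#'
#' The relative diffusion constant D (reciprocal milliseconds) is the
#' negated slope of an ordinary least-squares line fitted to log counts of
#' the burst-duration histogram over the tail window [t1, t2]. The overall
#' proportionality constant of the tail never enters the slope and is not
#' estimated.
#'
#' @slot DHat numeric(1), estimate in ms^-1.
#' @slot ci95 numeric(2), 95\% confidence interval from the regression slope
#'   standard error.
#' @slot t1Ms,t2Ms numeric(1), fit range in milliseconds.
#' @slot k integer(1), number of (nonzero) bins used.
#' @slot se numeric(1), standard error of the slope.
#'
#' @seealso [estimateD()]
#' @export
setClass("DiffusionEstimate",
  slots = c(DHat = "numeric", ci95 = "numeric", t1Ms = "numeric",
            t2Ms = "numeric", k = "integer", se = "numeric"))

#' BoundFractionEstimate: slow-component fraction of a duration mixture
#'
#' Fraction A of molecules in the slow-diffusing (ribosome-bound, rate D1)
#' component of a two-exponential burst-duration mixture, the remainder
#' 1 - A diffusing freely at rate D2. Estimated by matching the measured
#' log-slope of the histogram tail to the log-slope functional of the
#' analytic mixture tail.
#'
#' @slot AHat numeric(1), estimated bound fraction in [0, 1].
#' @slot D1,D2 numeric(1), bound and free diffusion rates (ms^-1) used.
#' @slot slopeMeasured numeric(1), measured log-slope magnitude (ms^-1).
#' @slot clamped logical(1), TRUE if no root existed in [0, 1] and the
#'   estimate was clamped to the nearest endpoint.
#' @slot n integer(1), number of bursts behind the histogram (NA if unknown).
#'
#' @seealso [estimateBoundFraction()], [mixtureTail()]
#' @export
setClass("BoundFractionEstimate",
  slots = c(AHat = "numeric", D1 = "numeric", D2 = "numeric",
            slopeMeasured = "numeric", clamped = "logical", n = "integer"))

#' FilterReport: outcome of the aggregate-burst correlation filter
#'
#' Per-burst statistics and summary of the hypothesis test that removes
#' bursts generated by fluorescent aggregates (runs of correlated high-E*
#' bursts). \code{pHatPrime} estimates the dataset-wide probability of a
#' burst exceeding the E* threshold; bursts whose local neighbor estimate
#' exceeds the acceptance bound while themselves being high-E* are removed.
#'
#' @slot pHatPrime numeric(1), fraction of bursts with E* > e (NA for an
#'   empty input).
#' @slot removedIds integer, row indices (in the input set) removed.
#' @slot removedFraction numeric(1).
#' @slot Ti integer, per-burst neighbor sums.
#' @slot pHatI numeric, per-burst neighbor-fraction estimates Ti / (2n).
#' @slot params list with elements \code{n}, \code{e}, \code{w}.
#'
#' @seealso [applyAggregateFilter()], [nullRemovalFraction()]
#' @export
setClass("FilterReport",
  slots = c(pHatPrime = "numeric", removedIds = "integer",
            removedFraction = "numeric", Ti = "integer", pHatI = "numeric",
            params = "list"))

setMethod("show", "PhotonStream", function(object) {
  n <- length(object@timestamps)
  cat("PhotonStream with", n, "photons\n")
  if (n) {
    cat(sprintf("  span: %.3f s, alternation period: %g us\n",
                diff(range(object@timestamps)) / 1e6,
                object@alternationPeriodUs))
    cat(sprintf("  channels: D=%d A=%d | excitation: Dex=%d Aex=%d\n",
                sum(object@channel == "D"), sum(object@channel == "A"),
                sum(object@excitation == "Dex"),
                sum(object@excitation == "Aex")))
  }
  if (nrow(object@groundTruth))
    cat("  ground truth:", nrow(object@groundTruth), "transits\n")
  invisible(object)
})

setMethod("show", "BurstSet", function(object) {
  cat("BurstSet with", nrow(object@bursts), "bursts\n")
  if (nrow(object@bursts)) {
    tot <- with(object@bursts, n_DexDem + n_DexAem + n_AexDem + n_AexAem)
    cat(sprintf("  photons/burst: median %d [%d, %d]\n",
                as.integer(stats::median(tot)), min(tot), max(tot)))
    es <- object@bursts$E_star
    cat(sprintf("  E*: mean %.3f (defined for %d bursts)\n",
                mean(es, na.rm = TRUE), sum(!is.na(es))))
  }
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " | "), "\n")
  invisible(object)
})

setMethod("show", "MixtureResult", function(object) {
  cat(sprintf("MixtureResult: %d component(s), reduced chi-square %.3g\n",
              object@nComponents, object@goodness))
  if (nrow(object@components)) {
    cmp <- object@components
    for (i in seq_len(nrow(cmp)))
      cat(sprintf("  mean %.3f  sigma %.3f  weight %.3f\n",
                  cmp$mean[i], cmp$sigma[i], cmp$weight[i]))
  }
  if (!object@converged) cat("  [flagged: fit did not converge cleanly]\n")
  invisible(object)
})

setMethod("show", "DiffusionEstimate", function(object) {
  cat(sprintf("DiffusionEstimate: D = %.3f ms^-1 [95%% CI %.3f, %.3f], %d bins in [%g, %g] ms\n",
              object@DHat, object@ci95[1], object@ci95[2], object@k,
              object@t1Ms, object@t2Ms))
  invisible(object)
})

setMethod("show", "BoundFractionEstimate", function(object) {
  cat(sprintf("BoundFractionEstimate: A = %.3f (D1 = %.2f, D2 = %.2f ms^-1)%s\n",
              object@AHat, object@D1, object@D2,
              if (object@clamped) " [clamped]" else ""))
  invisible(object)
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: p-hat' = %.4f, removed %d bursts (%.2f%%)\n",
              object@pHatPrime, length(object@removedIds),
              100 * object@removedFraction))
  invisible(object)
})

setMethod("show", "DurationHistogram", function(object) {
  cat(sprintf("DurationHistogram: %d bins of %g us, %d bursts\n",
              length(object@counts), object@deltaUs,
              as.integer(sum(object@counts))))
  invisible(object)
})
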