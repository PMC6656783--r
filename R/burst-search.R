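# Sliding-window burst detection and per-burst E*/S computation.

# Number of photons of `ts` (sorted) inside [t - T/2, t + T/2] for every t,
# via two binary searches; inclusive at both window ends.
.window_counts <- function(t, ts, T) {
  findInterval(t + T / 2, ts) - findInterval(t - T / 2, ts, left.open = TRUE)
}

# Maximal runs of TRUE in `qual` with at least L members; returns a matrix
# of (first, last) indices.
.qualified_runs <- function(qual, L) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= L
  cbind(first = starts[keep], last = ends[keep])
}

# Pairwise intersection of two sorted sets of disjoint intervals.
.intersect_intervals <- function(a, b) {
  if (!nrow(a) || !nrow(b))
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("start", "end"))))
  out <- matrix(numeric(0), 0, 2)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a[i, 1], b[j, 1]); e <- min(a[i, 2], b[j, 2])
    if (s <= e) out <- rbind(out, c(s, e))
    if (a[i, 2] < b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  colnames(out) <- c("start", "end")
  out
}

# Tally photons of a stream into burst intervals (inclusive bounds) and
# build the burst data.frame.
.tally_bursts <- function(stream, intervals) {
  ts <- stream@timestamps
  cat4 <- paste0(stream@excitation,
                 ifelse(stream@channel == "D", "Dem", "Aem"))
  cums <- lapply(c("DexDem", "DexAem", "AexDem", "AexAem"),
                 function(k) cumsum(cat4 == k))
  names(cums) <- c("DexDem", "DexAem", "AexDem", "AexAem")
  lo <- findInterval(intervals[, 1], ts, left.open = TRUE)  # photons before
  hi <- findInterval(intervals[, 2], ts)                    # photons <= end
  cnt <- function(k) {
    cc <- c(0, cums[[k]])
    as.integer(cc[hi + 1] - cc[lo + 1])
  }
  b <- data.frame(
    start_us = intervals[, 1], end_us = intervals[, 2],
    duration_ms = (intervals[, 2] - intervals[, 1]) / 1000,
    n_DexDem = cnt("DexDem"), n_DexAem = cnt("DexAem"),
    n_AexDem = cnt("AexDem"), n_AexAem = cnt("AexAem"))
  es <- computeES(b$n_DexDem, b$n_DexAem, b$n_AexAem)
  b$E_star <- es$E_star
  b$S <- es$S
  b
}

#' Sliding-window burst search
#'
#' Detects single-molecule bursts in a sorted photon stream. A photon is
#' burst-qualified when at least \code{M} photons of the tested stream
#' (including itself) fall within a centered window of \code{T}
#' microseconds around it; maximal runs of qualified photons containing at
#' least \code{L} photons become bursts.
#'
#' In \code{"all-photon"} mode the criterion is evaluated on the full
#' stream. In \code{"dual-color"} mode (the default, which selects
#' doubly-labelled molecules) it is evaluated independently on the
#' donor-excitation and the acceptor-excitation photon streams, and burst
#' intervals are the intersections of the per-stream qualified intervals.
#' Per-burst photon counts are tallied over all photons inside the burst
#' interval, split by (excitation period, detection channel), and E* and S
#' are computed.
#'
#' @param stream a \linkS4class{PhotonStream}.
#' @param L minimum photons per qualified run (default 25).
#' @param M neighbor count (default 15).
#' @param T neighbor window in microseconds (default 500).
#' @param mode \code{"dual-color"} or \code{"all-photon"}.
#' @return a \linkS4class{BurstSet} (empty for an empty stream).
#' @examples
#' sp <- simSpecies("x", fret_e = 0.5, diffusion_rate_D = 1,
#'                  brightness_dex = 300, brightness_aex = 200, fraction = 1)
#' ps <- simulatePhotonStream(simConfig(sp, duration_s = 2, seed = 3))
#' burstSearch(ps)
#' @export
burstSearch <- function(stream, L = 25, M = 15, T = 500,
                        mode = c("dual-color", "all-photon")) {
  stopifnot(is(stream, "PhotonStream"))
  mode <- match.arg(mode)
  if (L < 1 || M < 1 || T <= 0) stop("need L >= 1, M >= 1, T > 0")
  ts <- stream@timestamps
  if (length(ts) > 1 && is.unsorted(ts)) stop("stream is not sorted")
  params <- list(L = L, M = M, T = T, mode = mode)
  empty <- new("BurstSet", bursts = data.frame(), params = params,
               provenance = sprintf("burstSearch(%s)", mode))
  if (!length(ts)) return(empty)
  if (mode == "all-photon") {
    qual <- .window_counts(ts, ts, T) >= M
    runs <- .qualified_runs(qual, L)
    if (!nrow(runs)) return(empty)
    intervals <- cbind(ts[runs[, 1]], ts[runs[, 2]])
  } else {
    ivs <- lapply(c("Dex", "Aex"), function(ph) {
      sub <- ts[stream@excitation == ph]
      qual <- .window_counts(sub, sub, T) >= M
      runs <- .qualified_runs(qual, L)
      cbind(start = sub[runs[, 1]], end = sub[runs[, 2]])
    })
    intervals <- .intersect_intervals(ivs[[1]], ivs[[2]])
    if (!nrow(intervals)) return(empty)
  }
  b <- .tally_bursts(stream, intervals)
  new("BurstSet", bursts = b, params = params,
      provenance = sprintf("burstSearch(%s, L=%d, M=%d, T=%g)",
                           mode, L, M, T))
}

#' Threshold bursts by total photon count
#'
#' Keeps bursts whose total photon count (all four excitation/channel
#' streams) is strictly greater than \code{min_total_photons}; the default
#' 250 selects intense single-molecule bursts.
#'
#' @param bset a \linkS4class{BurstSet}.
#' @param min_total_photons strict lower bound (default 250).
#' @return the thresholded \linkS4class{BurstSet}.
#' @export
thresholdBursts <- function(bset, min_total_photons = 250) {
  stopifnot(is(bset, "BurstSet"))
  if (!nrow(bset@bursts)) return(bset)
  keep <- totalPhotons(bset) > min_total_photons
  out <- bset[keep]
  out@params <- c(bset@params, list(min_total_photons = min_total_photons))
  out@provenance <- c(bset@provenance,
                      sprintf("thresholdBursts(> %g)", min_total_photons))
  out
}

#' Apparent FRET efficiency and stoichiometry from photon counts
#'
#' E* is the sensitized acceptor emission normalized to the total
#' fluorescence during donor excitation:
#' \code{n_DexAem / (n_DexDem + n_DexAem)}. S is the donor-excitation
#' fluorescence over the total fluorescence:
#' \code{(n_DexDem + n_DexAem) / (n_DexDem + n_DexAem + n_AexAem)}.
#' Both are uncorrected (no leakage, direct-excitation or gamma
#' correction) and are \code{NA} where the denominator is zero.
#' Acceptor-emission photons during donor excitation of the acceptor
#' (\code{n_AexDem}) never enter either quantity.
#'
#' @param n_DexDem,n_DexAem,n_AexAem photon counts (vectorized).
#' @return data.frame with columns \code{E_star} and \code{S}.
#' @examples
#' computeES(50, 50, 100)   # E* = 0.5, S = 0.5
#' computeES(60, 40, 0)     # donor-only signature: S = 1
#' @export
computeES <- function(n_DexDem, n_DexAem, n_AexAem) {
  dex <- n_DexDem + n_DexAem
  tot <- dex + n_AexAem
  data.frame(E_star = ifelse(dex > 0, n_DexAem / dex, NA_real_),
             S = ifelse(tot > 0, dex / tot, NA_real_))
}

#' Select doubly-labelled species by stoichiometry
#'
#' Keeps bursts with \code{s_min <= S <= s_max}. Intermediate S values
#' select donor-acceptor molecules; donor-only bursts sit at S near 1 and
#' acceptor-only at S near 0. Bursts with undefined S are dropped.
#'
#' @param bset a \linkS4class{BurstSet}.
#' @param s_min,s_max stoichiometry window, \code{0 <= s_min < s_max <= 1}.
#' @return the selected \linkS4class{BurstSet}.
#' @export
selectSpecies <- function(bset, s_min = 0.3, s_max = 0.8) {
  stopifnot(is(bset, "BurstSet"))
  if (!(s_min >= 0 && s_min < s_max && s_max <= 1))
    stop("need 0 <= s_min < s_max <= 1")
  if (!nrow(bset@bursts)) return(bset)
  s <- Sratio(bset)
  out <- bset[!is.na(s) & s >= s_min & s <= s_max]
  out@params <- c(bset@params, list(s_min = s_min, s_max = s_max))
  out@provenance <- c(bset@provenance,
                      sprintf("selectSpecies([%g, %g])", s_min, s_max))
  out
}

#' Two-dimensional E*-S histogram
#'
#' Bins bursts with defined E* and S into the 2D ALEX histogram used for
#' species selection.
#'
#' @param bset a \linkS4class{BurstSet}.
#' @param e_bins,s_bins monotone bin edges covering [0, 1].
#' @return a list with \code{counts} (matrix, E* rows by S columns),
#'   \code{e_bins}, \code{s_bins}.
#' @export
esHistogram <- function(bset, e_bins = seq(0, 1, by = 0.02),
                        s_bins = seq(0, 1, by = 0.02)) {
  stopifnot(is(bset, "BurstSet"))
  if (is.unsorted(e_bins, strictly = TRUE) ||
      is.unsorted(s_bins, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  e <- Estar(bset); s <- Sratio(bset)
  ok <- !is.na(e) & !is.na(s)
  ce <- cut(e[ok], e_bins, include.lowest = TRUE)
  cs <- cut(s[ok], s_bins, include.lowest = TRUE)
  list(counts = table(E = ce, S = cs), e_bins = e_bins, s_bins = s_bins)
}
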