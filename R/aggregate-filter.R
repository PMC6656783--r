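# Burst-correlation hypothesis test removing fluorescent-aggregate bursts.
#
# A large fluorescent aggregate crossing the excitation volume produces a
# run of consecutive bursts with unrealistically high apparent FRET. The
# filter models the high-E indicator of each burst as Bernoulli(p') under
# the null (uncorrelated bursts) and removes a high-E burst when the
# high-E fraction among its 2n temporal neighbors is incompatible with p'.

#' Flag high-FRET bursts
#'
#' Bernoulli indicator per burst: \code{X_i = 1} when \code{E*_i > e},
#' else 0. A burst with E* exactly equal to \code{e}, or undefined E*,
#' gets 0.
#'
#' @param bset a \linkS4class{BurstSet} in temporal order, or a numeric
#'   vector of E* values.
#' @param e threshold (default 0.9).
#' @return integer vector of 0/1 indicators.
#' @export
flagHighFret <- function(bset, e = 0.9) {
  es <- if (is(bset, "BurstSet")) Estar(bset) else bset
  as.integer(!is.na(es) & es > e)
}

#' Neighbor statistic of the aggregate filter
#'
#' For burst \code{i}, \code{T_i} is the number of high-FRET bursts among
#' its \code{n} predecessors and \code{n} successors (the burst itself
#' excluded); \code{p_hat_i = T_i / (2n)}. Neighbors outside the dataset
#' boundaries count as 0, which makes the test conservative at the edges.
#'
#' @param X 0/1 indicator vector (see [flagHighFret()]).
#' @param i burst index (1-based) or vector of indices; default all bursts.
#' @param n neighbor half-width (default 3).
#' @return data.frame with columns \code{Ti} and \code{p_hat_i}.
#' @examples
#' neighborStatistic(rep(1L, 7), i = 4, n = 3)  # interior: Ti = 6
#' neighborStatistic(rep(1L, 7), i = 1, n = 3)  # edge: Ti = 3
#' @export
neighborStatistic <- function(X, i = seq_along(X), n = 3) {
  if (n < 1) stop("n must be >= 1")
  if (any(i < 1 | i > length(X))) stop("index out of range")
  Xp <- c(rep(0L, n), as.integer(X), rep(0L, n))
  cs <- c(0L, cumsum(Xp))
  # sum over [i-n, i+n] in padded coordinates, minus the center
  ip <- i + n
  Ti <- (cs[ip + n + 1] - cs[ip - n]) - Xp[ip]
  data.frame(Ti = as.integer(Ti), p_hat_i = Ti / (2 * n))
}

#' Apply the aggregate-burst correlation filter
#'
#' Estimates \code{p_hat'} (the fraction of bursts with E* > e) once from
#' the full input set, computes the neighbor statistic for every burst, and
#' removes burst \code{i} exactly when \code{X_i = 1} and
#' \code{p_hat_i > p_hat' + w * sqrt(p_hat' (1 - p_hat'))} (strict
#' rejection; the acceptance region is closed at the bound). Survivors keep
#' their order and their E* values.
#'
#' @param bset a \linkS4class{BurstSet} in temporal order.
#' @param n neighbor half-width (default 3).
#' @param e E* threshold (default 0.9).
#' @param w critical-region width multiplier (default 1; sensible values
#'   0.5-2, larger w removes less).
#' @return list with elements \code{bursts} (the filtered
#'   \linkS4class{BurstSet}) and \code{report} (a
#'   \linkS4class{FilterReport}).
#' @export
applyAggregateFilter <- function(bset, n = 3, e = 0.9, w = 1) {
  stopifnot(is(bset, "BurstSet"))
  if (n < 1 || e <= 0 || e >= 1 || w <= 0)
    stop("need n >= 1, 0 < e < 1, w > 0")
  params <- list(n = n, e = e, w = w)
  nb <- nrow(bset@bursts)
  if (nb == 0) {
    rep0 <- new("FilterReport", pHatPrime = NA_real_,
                removedIds = integer(0), removedFraction = 0,
                Ti = integer(0), pHatI = numeric(0), params = params)
    return(list(bursts = bset, report = rep0))
  }
  X <- flagHighFret(bset, e)
  p_hat_prime <- mean(X)
  stat <- neighborStatistic(X, n = n)
  bound <- p_hat_prime + w * sqrt(p_hat_prime * (1 - p_hat_prime))
  removed <- which(X == 1L & stat$p_hat_i > bound)
  out <- bset[setdiff(seq_len(nb), removed)]
  out@params <- c(bset@params, params)
  out@provenance <- c(bset@provenance,
                      sprintf("aggregateFilter(n=%d, e=%g, w=%g)", n, e, w))
  report <- new("FilterReport", pHatPrime = p_hat_prime,
                removedIds = as.integer(removed),
                removedFraction = length(removed) / nb,
                Ti = stat$Ti, pHatI = stat$p_hat_i, params = params)
  list(bursts = out, report = report)
}

#' Expected null removal fraction of the aggregate filter
#'
#' Closed-form false-positive rate of the filter on uncorrelated bursts:
#' under the null every indicator is Bernoulli(p'), the interior neighbor
#' sum is Binomial(2n, p'), and a burst is removed when it is itself
#' high-FRET and its neighbor sum strictly exceeds
#' \code{2n (p' + w sqrt(p'(1 - p')))}. The returned value is
#' \code{p' * P[Binomial(2n, p') > 2n (p' + w sqrt(p'(1-p')))]}, matching
#' the strict rejection rule of [applyAggregateFilter()] for interior
#' bursts (edge bursts are removed less often, so the Monte-Carlo fraction
#' sits slightly below this for finite datasets).
#'
#' @param p_prime probability of a high-FRET burst under the null, [0, 1].
#' @param n neighbor half-width (default 3).
#' @param w width multiplier (default 1).
#' @return expected removed fraction.
#' @examples
#' nullRemovalFraction(0.3, n = 3, w = 0.5)  # ~0.0211
#' @export
nullRemovalFraction <- function(p_prime, n = 3, w = 1) {
  if (p_prime < 0 || p_prime > 1) stop("p_prime must be in [0, 1]")
  bound <- 2 * n * (p_prime + w * sqrt(p_prime * (1 - p_prime)))
  # strict inequality: T > bound  <=>  T >= floor(bound) + 1
  p_prime * pbinom(floor(bound), 2 * n, p_prime, lower.tail = FALSE)
}
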