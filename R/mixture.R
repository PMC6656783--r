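# Gaussian-mixture decomposition of apparent-FRET histograms.
#
# Conformational states of a FRET-labelled ATP site appear as
# (shot-noise-broadened) Gaussian peaks in the 1-D E* histogram. The
# histogram is fitted with a sum of 1-3 Gaussians by weighted least
# squares; peak means are the state E* values, normalized component areas
# their abundances. Widths are constrained to a band calibrated on static
# standards; the default band [0.03, 0.10] in E* units is a package
# convention.

.gauss_sum <- function(x, mu, sigma, amp) {
  y <- numeric(length(x))
  for (j in seq_along(mu))
    y <- y + amp[j] * exp(-(x - mu[j])^2 / (2 * sigma[j]^2))
  y
}

.fit_one_start <- function(x, y, wts, mu0, sigma0, sigma_bounds) {
  k <- length(mu0)
  # optimize on a unit-normalized histogram so that means, widths and
  # amplitudes are comparably scaled for L-BFGS-B
  ymax <- max(y)
  yn <- y / ymax
  mkobj <- function(w) {
    w <- w / sum(w * yn^2)  # unit-scale objective for stable line search
    function(p) {
      mu <- p[1:k]; sg <- p[k + 1:k]; am <- p[2 * k + 1:k]
      sum(w * (yn - .gauss_sum(x, mu, sg, am))^2)
    }
  }
  # start amplitudes at the local histogram height; with Poisson weights a
  # grossly overpredicting start is costlier than the zero model, whose
  # basin the optimizer must not fall into
  amp0 <- vapply(mu0, function(m) max(yn[which.min(abs(x - m))], 0.05),
                 numeric(1))
  lower <- c(rep(0, k), rep(sigma_bounds[1], k), rep(0, k))
  upper <- c(rep(1, k), rep(sigma_bounds[2], k), rep(10, k))
  ctrl <- list(maxit = 2000, factr = 1e4)
  res <- tryCatch({
    # stage 1: unweighted fit locates the peaks; stage 2: Poisson-weighted
    # (chi-square) fit from there
    r1 <- optim(c(mu0, sigma0, amp0), mkobj(rep(1, length(y))),
                method = "L-BFGS-B", lower = lower, upper = upper,
                control = ctrl)
    objw <- mkobj(wts * ymax^2)
    r2 <- optim(r1$par, objw, method = "L-BFGS-B", lower = lower,
                upper = upper, control = ctrl)
    # restart until stationary; an abnormal line-search stop at a point a
    # restart cannot improve is numerical convergence
    for (i in 1:3) {
      if (r2$convergence == 0) break
      r3 <- optim(r2$par, objw, method = "L-BFGS-B", lower = lower,
                  upper = upper, control = ctrl)
      if (r3$value >= r2$value * (1 - 1e-10)) {
        r2$convergence <- 0L
        break
      }
      r2 <- r3
    }
    r2
  }, error = function(e) NULL)
  if (!is.null(res)) {
    res$par[2 * k + 1:k] <- res$par[2 * k + 1:k] * ymax
    p <- res$par
    res$value <- sum(wts * (y - .gauss_sum(x, p[1:k], p[k + 1:k],
                                           p[2 * k + 1:k]))^2)
  }
  res
}

#' Fit a k-component Gaussian mixture to an E* histogram
#'
#' Bins the E* values on [0, 1] with the given bin width and fits a sum of
#' \code{k} Gaussians by weighted least squares (weights are inverse
#' Poisson variances, \code{1/max(count, 1)}). Means are free in [0, 1],
#' widths are constrained to \code{sigma_bounds}, amplitudes are
#' non-negative. Initialization uses a fixed grid of data quantiles, so
#' the fit is deterministic for given data.
#'
#' @param e_values numeric E* values in [0, 1], at least 50.
#' @param k number of components, 1-3.
#' @param sigma_bounds numeric(2), allowed standard-deviation band in E*
#'   units (default \code{c(0.03, 0.10)}).
#' @param bin_width E* histogram bin width (default 0.02).
#' @return a \linkS4class{MixtureResult}; component weights are component
#'   areas (amplitude x sigma) normalized to 1 and components are sorted by
#'   ascending mean.
#' @examples
#' set.seed(1)
#' e <- pmin(pmax(rnorm(2000, 0.6, 0.05), 0), 1)
#' fitMixture(e, k = 1)
#' @export
fitMixture <- function(e_values, k, sigma_bounds = c(0.03, 0.10),
                       bin_width = 0.02) {
  e_values <- e_values[!is.na(e_values)]
  if (length(e_values) < 50) stop("need at least 50 E* values")
  if (any(e_values < 0 | e_values > 1)) stop("E* values must lie in [0, 1]")
  if (!(k %in% 1:3)) stop("k must be 1, 2 or 3")
  if (sigma_bounds[1] > sigma_bounds[2] || sigma_bounds[1] <= 0)
    stop("invalid sigma_bounds")
  if (stats::sd(e_values) < 1e-12)
    stop("degenerate input: all E* values identical")
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- graphics::hist(e_values, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  wts <- 1 / pmax(y, 1)
  # deterministic multi-start: means seeded on data quantiles and on the
  # k tallest well-separated histogram bins (quantiles alone can miss a
  # minor peak far from the bulk of the data)
  probs <- switch(k,
    list(0.5),
    list(c(0.25, 0.75), c(0.10, 0.60), c(0.40, 0.90)),
    list(c(0.15, 0.50, 0.85), c(0.10, 0.40, 0.70), c(0.30, 0.60, 0.90)))
  starts <- lapply(probs, function(p)
    as.numeric(quantile(e_values, p, names = FALSE)))
  peaks <- numeric(0)
  for (i in order(y, decreasing = TRUE)) {
    if (y[i] == 0) break
    if (!length(peaks) || min(abs(x[i] - peaks)) > 0.1)
      peaks <- c(peaks, x[i])
    if (length(peaks) == k) break
  }
  if (length(peaks) == k) starts <- c(starts, list(sort(peaks)))
  sigma0 <- rep(mean(sigma_bounds), k)
  best <- NULL
  for (mu0 in starts) {
    res <- .fit_one_start(x, y, wts, mu0, sigma0, sigma_bounds)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    return(new("MixtureResult", components = data.frame(),
               nComponents = as.integer(k), goodness = NA_real_,
               converged = FALSE, binWidth = bin_width))
  p <- best$par
  mu <- p[1:k]; sg <- p[k + 1:k]; am <- p[2 * k + 1:k]
  area <- am * sg
  if (sum(area) <= 0)
    return(new("MixtureResult", components = data.frame(),
               nComponents = as.integer(k), goodness = NA_real_,
               converged = FALSE, binWidth = bin_width))
  wgt <- area / sum(area)
  o <- order(mu)
  cmp <- data.frame(mean = mu[o], sigma = sg[o], amplitude = am[o],
                    weight = wgt[o])
  dof <- max(length(y) - 3 * k, 1)
  new("MixtureResult", components = cmp, nComponents = as.integer(k),
      goodness = best$value / dof,
      allGoodness = setNames(best$value / dof, as.character(k)),
      converged = best$convergence == 0, binWidth = bin_width)
}

#' Select the minimal number of mixture components
#'
#' Fits 1, 2 and 3 components and returns the smallest model that fits the
#' data. A model order k is accepted when its reduced chi-square is already
#' adequate (below \code{adequate_chisq}: the fit is statistically
#' consistent with the histogram, so extra components would only chase
#' noise), or when adding one more component no longer improves the reduced
#' chi-square by at least \code{criterion_threshold} (relative
#' improvement). A larger model is also rejected when degenerate (any
#' component weight below 1\%, a vanishing-population artifact). The
#' goodness of all model orders is kept in the \code{allGoodness} slot of
#' the result.
#'
#' @param e_values numeric E* values in [0, 1].
#' @param sigma_bounds,bin_width as in [fitMixture()].
#' @param criterion_threshold minimal relative reduced-chi-square
#'   improvement that justifies one more component (default 0.1).
#' @param adequate_chisq reduced chi-square below which a model already
#'   fits (default 1.5, about two standard deviations of a reduced
#'   chi-square with the typical number of histogram bins).
#' @return a \linkS4class{MixtureResult}.
#' @export
selectModel <- function(e_values, sigma_bounds = c(0.03, 0.10),
                        criterion_threshold = 0.1, bin_width = 0.02,
                        adequate_chisq = 1.5) {
  fits <- lapply(1:3, function(k)
    tryCatch(fitMixture(e_values, k, sigma_bounds, bin_width),
             error = function(e) NULL))
  good <- vapply(fits, function(f)
    if (is.null(f) || !f@converged) NA_real_ else f@goodness, numeric(1))
  degenerate <- vapply(fits, function(f)
    is.null(f) || !nrow(f@components) || any(f@components$weight < 0.01),
    logical(1))
  choice <- 3L
  for (k in 1:2) {
    if (is.na(good[k])) next
    if (good[k] <= adequate_chisq) {
      choice <- k
      break
    }
    nxt <- good[k + 1]
    improvement <- if (is.na(nxt)) 0 else (good[k] - nxt) / good[k]
    if (improvement < criterion_threshold || degenerate[k + 1]) {
      choice <- k
      break
    }
  }
  out <- fits[[choice]]
  if (is.null(out)) stop("no model order could be fitted")
  out@allGoodness <- setNames(good, c("1", "2", "3"))
  out
}

#' Conformational-state populations from a mixture fit
#'
#' Converts component weights to percentages. With exactly three
#' components the states are labelled \code{open}, \code{intermediate} and
#' \code{closed} by ascending mean E* (a shorter inter-probe distance, a
#' more closed site, gives higher FRET); with fewer components the states
#' are reported by their mean only.
#'
#' @param result a \linkS4class{MixtureResult}.
#' @return named numeric vector of percentages summing to 100.
#' @export
statePopulations <- function(result) {
  stopifnot(is(result, "MixtureResult"))
  cmp <- result@components
  if (!nrow(cmp)) stop("empty mixture result")
  pct <- 100 * cmp$weight / sum(cmp$weight)
  names(pct) <- if (nrow(cmp) == 3)
    c("open", "intermediate", "closed")
  else sprintf("E*=%.2f", cmp$mean)
  pct
}
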