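# Binding-kinetics fits and arithmetic: K_D from a titration, k_off from a
# dissociation time course, k_on = k_off / K_D, and the mean association
# time 1/(k_on * c) at a given ligand concentration.

#' Fit a dissociation constant to titration data
#'
#' Least-squares fit of the hyperbolic binding isotherm
#' f(c) = c / (K_D + c) to (concentration, bound fraction) pairs. Assumes
#' free ligand is approximately total ligand (receptor in trace amounts).
#' With per-point observation counts \code{n}, points are weighted by
#' inverse binomial variance.
#'
#' @param concentrations molar concentrations (>= 4 points; should span
#'   both sides of half-saturation for a well-constrained fit).
#' @param bound_fractions values in [0, 1], same length.
#' @param n optional per-point observation counts for binomial weights.
#' @return list with \code{kd} (molar), \code{se}, \code{ci95}
#'   (numeric(2)), \code{spanning} (logical: data bracket
#'   half-saturation), and the \code{fit} object.
#' @examples
#' cc <- c(1, 5, 20, 80, 320) * 1e-9
#' fitKd(cc, cc / (20e-9 + cc))$kd   # 2e-08
#' @export
fitKd <- function(concentrations, bound_fractions, n = NULL) {
  if (length(concentrations) < 4)
    stop("need at least 4 titration points")
  if (length(concentrations) != length(bound_fractions))
    stop("length mismatch")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  d <- data.frame(c = concentrations, f = bound_fractions)
  w <- if (is.null(n)) rep(1, nrow(d)) else {
    v <- pmax(d$f * (1 - d$f), 1e-4) / n
    1 / v
  }
  start <- list(kd = max(stats::median(d$c), min(d$c[d$c > 0])))
  fit <- minpack.lm::nlsLM(f ~ c / (kd + c), data = d, start = start,
                           weights = w, lower = c(kd = 1e-15),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  kd <- unname(coef(fit)["kd"])
  se <- summary(fit)$coefficients["kd", "Std. Error"]
  ci <- kd + c(-1, 1) * stats::qt(0.975, length(d$c) - 1) * se
  spanning <- any(bound_fractions < 0.5) && any(bound_fractions > 0.5)
  if (!spanning)
    warning("titration does not span half-saturation; K_D is weakly ",
            "constrained (wide CI)")
  list(kd = kd, se = se, ci95 = ci, spanning = spanning, fit = fit)
}

#' Fit a dissociation rate to a time course
#'
#' Least-squares fit of f(t) = f0 * exp(-k_off * t) to (time, bound
#' fraction) pairs. Times are in minutes, so k_off is per minute. Data
#' with no decreasing trend yield \code{koff = 0} with a flag.
#'
#' @param times minutes (>= 4 points).
#' @param bound_fractions values in [0, 1].
#' @param n optional per-point counts for binomial weights.
#' @return list with \code{koff} (per minute), \code{f0}, \code{se},
#'   \code{ci95}, \code{flat} (TRUE when the data do not decay) and the
#'   \code{fit} object (NULL when flat).
#' @export
fitDissociationRate <- function(times, bound_fractions, n = NULL) {
  if (length(times) < 4) stop("need at least 4 time points")
  if (length(times) != length(bound_fractions)) stop("length mismatch")
  if (any(times < 0)) stop("times must be >= 0")
  d <- data.frame(t = times, f = bound_fractions)
  slope <- coef(lm(f ~ t, data = d))[2]
  if (slope >= -1e-9)  # no decreasing trend: nothing to fit
    return(list(koff = 0, f0 = mean(d$f), se = NA_real_,
                ci95 = c(0, 0), flat = TRUE, fit = NULL))
  w <- if (is.null(n)) rep(1, nrow(d)) else {
    v <- pmax(d$f * (1 - d$f), 1e-4) / n
    1 / v
  }
  k0 <- max(-slope / max(mean(d$f), 1e-3), 1e-4)
  fit <- minpack.lm::nlsLM(f ~ f0 * exp(-koff * t), data = d,
                           start = list(f0 = max(d$f), koff = k0),
                           weights = w,
                           lower = c(f0 = 0, koff = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  koff <- unname(coef(fit)["koff"])
  se <- summary(fit)$coefficients["koff", "Std. Error"]
  ci <- koff + c(-1, 1) * stats::qt(0.975, length(d$t) - 2) * se
  list(koff = koff, f0 = unname(coef(fit)["f0"]), se = se, ci95 = ci,
       flat = FALSE, fit = fit)
}

#' Association rate from dissociation rate and dissociation constant
#'
#' k_on = k_off / K_D with k_off converted from per minute to per second:
#' \code{kon = (koff / 60) / kd}.
#'
#' @param koff dissociation rate, per minute (>= 0).
#' @param kd dissociation constant, molar (> 0).
#' @return k_on in M^-1 s^-1.
#' @examples
#' associationRate(0.5, 20e-9)  # ~4.2e5 M^-1 s^-1
#' @export
associationRate <- function(koff, kd) {
  if (koff < 0) stop("koff must be >= 0")
  if (kd <= 0) stop("kd must be > 0")
  (koff / 60) / kd
}

#' Mean association time at a given ligand concentration
#'
#' Pseudo-first-order association: tau = 1 / (k_on * c).
#'
#' @param kon association rate, M^-1 s^-1 (> 0).
#' @param conc ligand concentration, molar (> 0).
#' @return mean time to association, seconds.
#' @examples
#' meanAssociationTime(4e5, 1e-6)  # 2.5 s
#' @export
meanAssociationTime <- function(kon, conc) {
  if (kon <= 0 || conc <= 0) stop("kon and conc must be > 0")
  1 / (kon * conc)
}
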