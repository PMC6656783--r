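# Steady-state fluorescence anisotropy arithmetic.
#
# Anisotropy of the labelled protein validates that the dyes rotate freely
# (low r), i.e. that apparent FRET changes report distance, not dye
# sticking. Intensities are background-corrected by the caller.

#' Polarization sensitivity correction factor
#'
#' G = I_HV / I_HH from measurements under horizontal excitation, where the
#' two emission components are equally polarized and any remaining
#' difference is instrumental.
#'
#' @param I_HV,I_HH intensities with horizontal excitation and vertical /
#'   horizontal emission polarizer (\code{I_HH > 0}).
#' @return the G factor.
#' @examples
#' gFactor(0.65, 1)  # typical green-dye value
#' @export
gFactor <- function(I_HV, I_HH) {
  if (any(I_HH <= 0)) stop("I_HH must be > 0")
  I_HV / I_HH
}

#' Steady-state fluorescence anisotropy
#'
#' r = (I_VV - G I_VH) / (I_VV + 2 G I_VH) from the vertical-excitation
#' intensity components; invariant under common scaling of the
#' intensities.
#'
#' @param I_VV,I_VH intensities with vertical excitation and vertical /
#'   horizontal emission polarizer (>= 0).
#' @param G instrument factor from [gFactor()] (> 0).
#' @return anisotropy r.
#' @examples
#' anisotropy(2, 1, 1)  # 0.25
#' @export
anisotropy <- function(I_VV, I_VH, G) {
  if (any(G <= 0)) stop("G must be > 0")
  den <- I_VV + 2 * G * I_VH
  if (any(den <= 0)) stop("denominator I_VV + 2 G I_VH must be > 0")
  (I_VV - G * I_VH) / den
}
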