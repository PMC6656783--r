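#' Accessors for PhotonStream and BurstSet
#'
#' Slot access for the core containers. \code{timestamps}, \code{channel}
#' and \code{excitation} return the per-photon vectors of a
#' \linkS4class{PhotonStream}; \code{groundTruth} its transit table.
#' \code{bursts} returns the burst data.frame of a \linkS4class{BurstSet};
#' \code{Estar} and \code{Sratio} its apparent FRET efficiency and
#' stoichiometry vectors; \code{totalPhotons} the per-burst photon totals.
#'
#' @param x the object.
#' @return vectors or data.frames as described.
#' @name accessors
NULL

#' @rdname accessors
#' @export
timestamps <- function(x) x@timestamps

#' @rdname accessors
#' @export
channel <- function(x) x@channel

#' @rdname accessors
#' @export
excitation <- function(x) x@excitation

#' @rdname accessors
#' @export
alternationPeriod <- function(x) x@alternationPeriodUs

#' @rdname accessors
#' @export
groundTruth <- function(x) x@groundTruth

#' @rdname accessors
#' @export
bursts <- function(x) x@bursts

#' @rdname accessors
#' @export
Estar <- function(x) x@bursts$E_star

#' @rdname accessors
#' @export
Sratio <- function(x) x@bursts$S

#' @rdname accessors
#' @export
totalPhotons <- function(x)
  with(x@bursts, n_DexDem + n_DexAem + n_AexDem + n_AexAem)

#' @rdname accessors
#' @export
components <- function(x) x@components
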