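#' Number of photons or bursts in an object
#'
#' \code{length} of a \linkS4class{PhotonStream} is its photon count; of a
#' \linkS4class{BurstSet}, its burst count.
#'
#' @param x a PhotonStream or BurstSet.
#' @return integer(1).
#' @name length-methods
#' @aliases length,PhotonStream-method length,BurstSet-method
NULL

#' @rdname length-methods
#' @export
setMethod("length", "PhotonStream", function(x) length(x@timestamps))

#' @rdname length-methods
#' @export
setMethod("length", "BurstSet", function(x) nrow(x@bursts))

#' Subset a BurstSet by burst index
#'
#' @param x a \linkS4class{BurstSet}.
#' @param i integer or logical index over bursts.
#' @param j,...,drop ignored.
#' @return a BurstSet containing the selected bursts, order preserved.
#' @export
setMethod("[", "BurstSet", function(x, i, j, ..., drop = FALSE) {
  b <- x@bursts[i, , drop = FALSE]
  b <- b[order(b$start_us), , drop = FALSE]
  rownames(b) <- NULL
  initialize(x, bursts = b)
})
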