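# Plain-text interchange formats: a photon-stream CSV dialect
# (timestamp_us, channel, excitation), a ground-truth sidecar CSV, and the
# burst-table CSV.

#' Write / read a photon stream as CSV
#'
#' The photon CSV dialect has columns \code{timestamp_us} (integer
#' microseconds), \code{channel} (\code{D}/\code{A}) and \code{excitation}
#' (\code{Dex}/\code{Aex}). Ground truth, when present, goes to a sidecar
#' CSV with columns \code{burst_start_us}, \code{burst_end_us},
#' \code{species}, \code{fret_e}, \code{is_aggregate}.
#'
#' @param stream a \linkS4class{PhotonStream}.
#' @param path CSV file path.
#' @param ground_truth_path optional sidecar path for the transit table.
#' @return \code{writePhotonCSV}: \code{path}, invisibly.
#' @export
writePhotonCSV <- function(stream, path, ground_truth_path = NULL) {
  stopifnot(is(stream, "PhotonStream"))
  write.csv(data.frame(timestamp_us = stream@timestamps,
                       channel = stream@channel,
                       excitation = stream@excitation),
            path, row.names = FALSE, quote = FALSE)
  if (!is.null(ground_truth_path) && nrow(stream@groundTruth)) {
    gt <- stream@groundTruth
    write.csv(data.frame(burst_start_us = gt$start_us,
                         burst_end_us = gt$end_us,
                         species = gt$species,
                         fret_e = gt$fret_e,
                         is_aggregate = gt$is_aggregate),
              ground_truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname writePhotonCSV
#' @param alternation_period_us laser alternation period of the recording.
#' @return \code{readPhotonCSV}: a \linkS4class{PhotonStream}.
#' @export
readPhotonCSV <- function(path, alternation_period_us = 50,
                          ground_truth_path = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_us", "channel", "excitation")
  if (!all(need %in% names(d)))
    stop("photon CSV needs columns: ", paste(need, collapse = ", "))
  gt <- if (!is.null(ground_truth_path) && file.exists(ground_truth_path)) {
    g <- read.csv(ground_truth_path, stringsAsFactors = FALSE)
    data.frame(start_us = g$burst_start_us, end_us = g$burst_end_us,
               species = g$species,
               fret_e = if ("fret_e" %in% names(g)) g$fret_e else NA_real_,
               is_aggregate = g$is_aggregate, stringsAsFactors = FALSE)
  } else data.frame()
  o <- order(d$timestamp_us)
  new("PhotonStream", timestamps = as.numeric(d$timestamp_us[o]),
      channel = d$channel[o], excitation = d$excitation[o],
      alternationPeriodUs = alternation_period_us, groundTruth = gt)
}

#' Write / read a burst table as CSV
#'
#' Columns: \code{burst_id}, \code{start_us}, \code{end_us},
#' \code{duration_ms}, the four photon counts, \code{E_star}, \code{S},
#' plus any extra provenance columns present (e.g. \code{species}).
#'
#' @param bset a \linkS4class{BurstSet}.
#' @param path CSV file path.
#' @return \code{writeBurstCSV}: \code{path}, invisibly;
#'   \code{readBurstCSV}: a \linkS4class{BurstSet}.
#' @export
writeBurstCSV <- function(bset, path) {
  stopifnot(is(bset, "BurstSet"))
  b <- bset@bursts
  out <- cbind(burst_id = seq_len(nrow(b)), b)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBurstCSV
#' @export
readBurstCSV <- function(path) {
  b <- read.csv(path, stringsAsFactors = FALSE)
  b$burst_id <- NULL
  if (!all(c("E_star", "S") %in% names(b)) &&
      all(c("n_DexDem", "n_DexAem", "n_AexAem") %in% names(b))) {
    es <- computeES(b$n_DexDem, b$n_DexAem, b$n_AexAem)
    b$E_star <- es$E_star
    b$S <- es$S
  }
  if (!"duration_ms" %in% names(b) &&
      all(c("start_us", "end_us") %in% names(b)))
    b$duration_ms <- (b$end_us - b$start_us) / 1000
  b <- b[order(b$start_us), , drop = FALSE]
  rownames(b) <- NULL
  new("BurstSet", bursts = b, params = list(source = path),
      provenance = paste("read from", path))
}
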