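#' Mean heartbeat duration
#'
#' Arithmetic mean of successive trigger differences; all cycles are used.
#'
#' @param physio a \linkS4class{PhysioRecord} with at least 2 triggers.
#' @return mean RR, ms.
#' @examples
#' meanRR(new("PhysioRecord", triggerTimes = c(0, 900, 1900)))  # 950
#' @export
meanRR <- function(physio) {
  tt <- triggerTimes(physio)
  if (length(tt) < 2) stop("at least 2 triggers are required for a mean RR")
  mean(diff(tt))
}

#' Retrospective cardiac binning of readouts
#'
#' Sorts readouts into non-overlapping cardiac phases: a readout at time t
#' whose preceding trigger is tau falls into bin
#' \code{floor((t - tau)/binWidthMs)}. The number of bins is the mean
#' heartbeat duration divided by the bin width (floored); readouts that land
#' beyond the last bin (residual late-cycle data) or precede the first
#' trigger are discarded, keeping all bins duration-homogeneous.
#'
#' @param timestamps sorted readout times, ms.
#' @param physio a \linkS4class{PhysioRecord}.
#' @param binWidthMs cardiac bin width, ms (study default 80; sweep values
#'   40/80/160/240).
#' @return a \linkS4class{BinAssignment}.
#' @export
assignBins <- function(timestamps, physio, binWidthMs = 80) {
  .assertScalar(binWidthMs, "binWidthMs", positive = TRUE)
  if (is.unsorted(timestamps)) stop("timestamps must be sorted")
  mrr <- meanRR(physio)
  nB <- floor(mrr / binWidthMs)
  if (nB < 1)
    stop("bin width >= mean RR: zero bins")
  tt <- triggerTimes(physio)
  idx <- findInterval(timestamps, tt)
  offset <- timestamps - tt[pmax(idx, 1L)]
  bin <- as.integer(floor(offset / binWidthMs))
  bin[idx < 1L] <- NA_integer_          # before the first trigger
  bin[!is.na(bin) & bin >= nB] <- NA_integer_  # residual late-cycle readouts
  new("BinAssignment", bin = bin, nBins = as.integer(nB),
      binWidthMs = binWidthMs, meanRrMs = mrr)
}

#' Export a bin assignment for audit
#'
#' @param assignment a \linkS4class{BinAssignment}.
#' @param timestamps the readout times the assignment refers to, ms.
#' @param file optional CSV path; if NULL the data.frame is returned only.
#' @return data.frame (readout_index, time_ms, bin) with NA for discarded
#'   readouts.
#' @export
binAssignmentTable <- function(assignment, timestamps, file = NULL) {
  df <- data.frame(readout_index = seq_along(assignment@bin),
                   time_ms = timestamps, bin = assignment@bin)
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' Group raw k-space by cardiac bin
#'
#' Splits a continuous acquisition into the per-bin data and coordinate
#' lists consumed by the encoding operator and the reconstruction.
#'
#' @param raw a \linkS4class{RawKSpace}.
#' @param assignment a \linkS4class{BinAssignment} for its readouts.
#' @return list with \code{data} (per-bin M_b x coils complex matrices) and
#'   \code{coords} (per-bin M_b x 3 k coordinates).
#' @export
binKSpace <- function(raw, assignment) {
  stopifnot(length(assignment@bin) == dim(raw@data)[1])
  S <- dim(raw@data)[2]
  C <- dim(raw@data)[3]
  dataL <- vector("list", assignment@nBins)
  coordL <- vector("list", assignment@nBins)
  for (p in seq_len(assignment@nBins)) {
    rows <- which(!is.na(assignment@bin) & assignment@bin == (p - 1L))
    if (!length(rows))
      stop("empty cardiac bin: ", p - 1L)
    y <- matrix(0i, nrow = length(rows) * S, ncol = C)
    for (cc in seq_len(C))
      y[, cc] <- as.vector(t(raw@data[rows, , cc]))
    dataL[[p]] <- y
    coordL[[p]] <- trajectoryCoords(raw@trajectory, rows)
  }
  list(data = dataL, coords = coordL)
}
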