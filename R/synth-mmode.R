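#' Simulate an M-mode ultrasound wall trace
#'
#' Generates upper/lower outer-wall boundary positions at 250 frames per
#' second: \code{centre -/+ (D(t)/2 + IMT)} plus a shared (common-mode)
#' linear transducer drift and independent Gaussian noise per boundary.
#' D(t) follows the waveform at the cycle fraction of each sample given the
#' trigger record (linear interpolation on the periodic phase grid). The
#' lumen ground truth (dS, dD) is carried on the object.
#'
#' @param waveform a \linkS4class{DiameterWaveform}.
#' @param nBeats number of heartbeats to cover (>= 1; protocol uses 5).
#' @param driftMmPerS shared linear drift of both boundaries, mm/s.
#' @param noiseSdMm independent boundary noise SD, mm.
#' @param imtMm intima-media thickness added outside the lumen on each side
#'   (delineation follows the outer wall), mm.
#' @param physio optional \linkS4class{PhysioRecord}; default is a constant
#'   RR record at the waveform's RR.
#' @param seed integer seed.
#' @param fps frame rate (default 250).
#' @param centreMm transducer-line position of the vessel centre, mm.
#' @return an \linkS4class{MModeTrace}.
#' @examples
#' wf <- makeDiameterWaveform(5.5, 6.4, 960, 0.45, 240)
#' tr <- simulateMmode(wf, nBeats = 5)
#' length(tr@timeS)  # 1200 = 4.8 s x 250 fps
#' @export
simulateMmode <- function(waveform, nBeats = 5L, driftMmPerS = 0,
                          noiseSdMm = 0, imtMm = 0.6, physio = NULL,
                          seed = 1L, fps = 250, centreMm = 15) {
  nBeats <- .assertCount(nBeats, "nBeats")
  rr <- waveform@rrMs
  durS <- nBeats * rr / 1000
  n <- round(durS * fps)
  t <- (seq_len(n) - 1) / fps
  if (is.null(physio))
    physio <- new("PhysioRecord",
                  triggerTimes = seq(0, by = rr, length.out = nBeats + 1L))
  frac <- .cycleFraction(t * 1000, physio)
  d <- waveformAt(waveform, frac, method = "linear")
  half <- d / 2 + imtMm
  drift <- driftMmPerS * t
  noise <- withr::with_seed(seed, {
    matrix(stats::rnorm(2L * n, 0, noiseSdMm), ncol = 2)
  })
  upper <- centreMm - half + drift + if (noiseSdMm > 0) noise[, 1] else 0
  lower <- centreMm + half + drift + if (noiseSdMm > 0) noise[, 2] else 0
  bad <- lower <= upper
  if (any(bad))
    stop("boundary noise large enough to cross the boundaries")
  new("MModeTrace", timeS = t, upperMm = upper, lowerMm = lower,
      resolutionMm = 0.1, imtMm = imtMm, fps = fps,
      groundTruth = list(dS = dS(waveform), dD = dD(waveform),
                         rdc = waveformRdc(waveform)))
}
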