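#' Ground-truth cardiac diameter waveform
#'
#' Builds one cycle of lumen diameter on a uniform phase grid
#' \code{u_r = r/nPhases}: a raised-cosine systolic bump (upstroke and
#' windkessel-type decay spanning \code{systolicFraction} of the cycle,
#' centred at \code{peakPhase}) on a flat diastolic baseline. After sampling,
#' the bump is rescaled so that \code{min(diameters) == dD} and
#' \code{max(diameters) == dS} hold exactly on the grid.
#'
#' The default peak phase of 0.4 places the systolic peak ~0.4 RR after the
#' pulse-oximeter trigger and the diastolic baseline in the late cycle, as in
#' a distension waveform referenced to a peripheral pulse trigger.
#'
#' @param dD,dS diastolic and systolic diameter, mm (0 < dD <= dS).
#' @param rrMs cycle length, ms.
#' @param systolicFraction fraction of the cycle occupied by the systolic
#'   bump, in (0, 1).
#' @param nPhases number of grid points over the cycle.
#' @param peakPhase position of the systolic peak as a fraction of the cycle.
#' @return a \linkS4class{DiameterWaveform}.
#' @examples
#' wf <- makeDiameterWaveform(5.5, 6.4, 960, 0.35, 12)
#' range(diameters(wf))  # exactly 5.5 6.4
#' @export
makeDiameterWaveform <- function(dD, dS, rrMs = 960, systolicFraction = 0.45,
                                 nPhases = 24L, peakPhase = 0.4) {
  .assertScalar(dD, "dD", positive = TRUE)
  .assertScalar(dS, "dS", positive = TRUE)
  if (dS < dD) stop("dS must be >= dD")
  .assertScalar(rrMs, "rrMs", positive = TRUE)
  if (systolicFraction <= 0 || systolicFraction >= 1)
    stop("systolicFraction must lie in (0, 1)")
  nPhases <- .assertCount(nPhases, "nPhases")
  u <- (seq_len(nPhases) - 1) / nPhases
  # distance from the peak along the cycle, periodic
  dist <- abs(u - peakPhase)
  dist <- pmin(dist, 1 - dist)
  bump <- ifelse(dist <= systolicFraction / 2,
                 0.5 * (1 + cos(2 * pi * dist / systolicFraction)), 0)
  if (dS > dD && max(bump) > 0) bump <- bump / max(bump)  # pin max exactly
  d <- dD + (dS - dD) * bump
  new("DiameterWaveform", phaseTimes = u * rrMs, diameters = d, rrMs = rrMs,
      systolicFraction = systolicFraction, peakPhase = peakPhase)
}

#' Evaluate a waveform at arbitrary cycle fractions
#'
#' Linear interpolation on the periodic phase grid (used by the M-mode
#' synthesizer); \code{method = "nearest"} snaps to the nearest grid phase
#' (used by the k-space simulator so the phantom is rendered at a bounded
#' number of distinct diameters).
#'
#' @param waveform a \linkS4class{DiameterWaveform}.
#' @param frac cycle fractions (any real; wrapped into [0, 1)).
#' @param method "linear" or "nearest".
#' @return diameters, mm.
#' @export
waveformAt <- function(waveform, frac, method = c("linear", "nearest")) {
  method <- match.arg(method)
  n <- length(waveform@diameters)
  frac <- frac - floor(frac)
  pos <- frac * n
  if (method == "nearest") {
    idx <- (round(pos) %% n) + 1
    return(waveform@diameters[idx])
  }
  i0 <- floor(pos)
  w <- pos - i0
  d <- waveform@diameters
  d[(i0 %% n) + 1] * (1 - w) + d[((i0 + 1) %% n) + 1] * w
}

#' Relative diameter change of a waveform
#'
#' (max - min)/min x 100, the ground-truth strain index carried alongside
#' generated data.
#'
#' @param waveform a \linkS4class{DiameterWaveform}.
#' @return RDC in percent.
#' @export
waveformRdc <- function(waveform) {
  d <- waveform@diameters
  (max(d) - min(d)) / min(d) * 100
}
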