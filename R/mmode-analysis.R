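#' Diameter evolution from M-mode boundary traces
#'
#' Interpolates the two delineated boundaries onto the uniform frame grid,
#' subtracts them, and removes the least-squares linear trend while
#' preserving the mean (slope-only removal): absolute diameters are needed
#' downstream for the stiffness formulas. A common-mode transducer drift
#' cancels exactly in the subtraction; an independent residual trend is
#' removed here.
#'
#' @param trace an \linkS4class{MModeTrace} (boundaries may be on irregular
#'   time points; they are linearly interpolated to the uniform grid).
#' @return a \linkS4class{DiameterTrace}.
#' @export
diameterFromBoundaries <- function(trace) {
  t0 <- trace@timeS
  tg <- seq(min(t0), max(t0), by = 1 / trace@fps)
  up <- if (isTRUE(all.equal(t0, tg))) trace@upperMm
        else stats::approx(t0, trace@upperMm, xout = tg, rule = 2)$y
  lo <- if (isTRUE(all.equal(t0, tg))) trace@lowerMm
        else stats::approx(t0, trace@lowerMm, xout = tg, rule = 2)$y
  d <- lo - up
  if (any(d <= 0)) stop("lower boundary at/above the upper one")
  tc <- tg - mean(tg)
  slope <- sum(tc * d) / sum(tc^2)
  new("DiameterTrace", timeS = tg, diameterMm = d - slope * tc,
      slopeRemoved = slope)
}

#' Automatic multiscale-based peak (and trough) detection
#'
#' AMPD: for window scales k = 1 .. ceil(n/2) - 1, sample i is a local
#' maximum at scale k if it exceeds both x[i-k] and x[i+k]. The global scale
#' is the one with the most maxima (arg min of the row-wise sum of the
#' non-maximum indicator); peaks are the samples that are maxima at every
#' scale up to the global one. Troughs are the peaks of the negated trace.
#' Plateau ties are broken toward the earlier sample (strict comparison on
#' the left neighbour, non-strict on the right), so exactly flat summits
#' yield their leftmost sample. Comparisons that would cross the record
#' boundary use symmetric (half-point) reflection padding, so beats close to
#' the edges of a short record are still detected; the first and last sample
#' themselves are never reported as extrema.
#'
#' @param trace a \linkS4class{DiameterTrace} or numeric vector.
#' @return list(peaks, troughs) of 1-based sample indices (empty, with a
#'   warning, for monotone traces).
#' @export
ampdPeaks <- function(trace) {
  x <- if (is(trace, "DiameterTrace")) trace@diameterMm else as.numeric(trace)
  list(peaks = .ampd(x), troughs = .ampd(-x))
}

.ampd <- function(x) {
  n <- length(x)
  L <- as.integer(ceiling(n / 2) - 1)
  if (L < 1 || n < 3) {
    warning("trace too short for peak detection")
    return(integer(0))
  }
  # symmetric (half-point) reflection padding: xp[L + i] = x[i]
  xp <- c(rev(x[seq_len(L)]), x, rev(x[(n - L + 1):n]))
  gam <- integer(L)
  m <- matrix(FALSE, nrow = L, ncol = n)
  idx <- L + seq_len(n)
  for (k in seq_len(L)) {
    ok <- xp[idx] > xp[idx - k] & xp[idx] >= xp[idx + k]
    m[k, ] <- ok
    # scale selection uses the canonical (unpadded) count: positions whose
    # window crosses the record boundary do not count as maxima
    valid <- ok
    valid[seq_len(min(k, n))] <- FALSE
    if (k < n) valid[(n - k + 1):n] <- FALSE
    gam[k] <- sum(valid)
  }
  if (all(gam == 0)) {
    warning("no local maxima found (monotone trace?)")
    return(integer(0))
  }
  lambda <- which.max(gam)  # scale with most maxima = min of non-max count
  pk <- which(colSums(m[seq_len(lambda), , drop = FALSE]) == lambda)
  pk <- setdiff(pk, c(1L, n))  # boundary samples are never extrema
  if (!length(pk)) warning("no interior extrema found (monotone trace?)")
  pk
}

#' Systolic/diastolic diameters from five beats
#'
#' Uses the first five detected systolic peaks; each diastolic trough value
#' is the minimum of the (detrended) diameter between consecutive peaks
#' (the segment before the first peak supplies the first trough). The five
#' peak and trough diameters are averaged and corrected by subtracting the
#' intima-media thickness twice (the delineation follows the outer wall).
#'
#' @param trace a \linkS4class{DiameterTrace}.
#' @param peaks detected systolic peaks (see \code{\link{ampdPeaks}}); at
#'   least 5 required.
#' @param troughs detected diastolic troughs; at least 5 required when
#'   supplied. NULL (default) derives them by the pairing rule -- AMPD
#'   trough detection legitimately returns nothing on an exactly flat
#'   diastolic baseline, where any plateau sample is an equally good trough.
#' @param imtMm intima-media thickness, mm.
#' @return a \linkS4class{BeatExtrema}.
#' @export
beatsToDiameters <- function(trace, peaks, troughs = NULL, imtMm = 0) {
  if (length(peaks) < 5)
    stop("need at least 5 systolic peaks and 5 diastolic troughs")
  if (!is.null(troughs) && length(troughs) < 5)
    stop("need at least 5 systolic peaks and 5 diastolic troughs")
  x <- trace@diameterMm
  pk <- sort(peaks)[1:5]
  segStart <- c(1L, pk[1:4])
  trIdx <- integer(5)
  for (j in 1:5) {
    seg <- segStart[j]:pk[j]
    trIdx[j] <- seg[which.min(x[seg])]
  }
  dSv <- mean(x[pk]) - 2 * imtMm
  dDv <- mean(x[trIdx]) - 2 * imtMm
  if (dDv <= 0) stop("diastolic diameter non-positive after IMT correction")
  new("BeatExtrema", peaks = as.integer(pk), troughs = trIdx,
      dS = dSv, dD = dDv, imtMm = imtMm)
}

#' Full M-mode measurement pipeline
#'
#' Boundary interpolation and subtraction, linear detrending, multiscale
#' peak/trough detection, five-beat averaging and 2 x IMT correction.
#'
#' @param trace an \linkS4class{MModeTrace}.
#' @param imtMm intima-media thickness; defaults to the value stored on the
#'   trace.
#' @return a \linkS4class{BeatExtrema}.
#' @export
measureMmode <- function(trace, imtMm = NULL) {
  if (is.null(imtMm)) imtMm <- trace@imtMm
  dt <- diameterFromBoundaries(trace)
  ex <- suppressWarnings(ampdPeaks(dt))
  beatsToDiameters(dt, ex$peaks,
                   if (length(ex$troughs) >= 5) ex$troughs else NULL,
                   imtMm)
}
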