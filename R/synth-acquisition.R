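#' Simulate a pulse-oximeter trigger record
#'
#' Triggers start at time 0 and advance by RR intervals drawn from a normal
#' distribution truncated at +/- 3 SD. Reproducible under the seed.
#'
#' @param durationMs record length, ms (triggers generated up to this time).
#' @param meanRrMs,sdRrMs RR interval mean and SD, ms.
#' @param seed integer seed.
#' @return a \linkS4class{PhysioRecord}.
#' @examples
#' triggerTimes(simulatePhysio(10000, 1000, 0, 1))  # 0, 1000, ..., 9000
#' @export
simulatePhysio <- function(durationMs, meanRrMs, sdRrMs = 0, seed = 1L) {
  .assertScalar(durationMs, "durationMs", positive = TRUE)
  .assertScalar(meanRrMs, "meanRrMs", positive = TRUE)
  if (sdRrMs < 0) stop("sdRrMs must be >= 0")
  if (meanRrMs - 3 * sdRrMs <= 200)
    stop("RR variability too large: truncated RR could fall at/below 200 ms")
  nMax <- ceiling(durationMs / max(meanRrMs - 3 * sdRrMs, 201)) + 2L
  rr <- withr::with_seed(seed, {
    r <- stats::rnorm(nMax, meanRrMs, sdRrMs)
    pmin(pmax(r, meanRrMs - 3 * sdRrMs), meanRrMs + 3 * sdRrMs)
  })
  tt <- c(0, cumsum(rr))
  tt <- tt[tt < durationMs]
  new("PhysioRecord", triggerTimes = tt)
}

# Cardiac-cycle fraction for arbitrary times given a trigger record.
# Times beyond the last trigger use the mean RR; times before the first
# trigger use a virtual preceding cycle of mean RR length.
.cycleFraction <- function(t, physio) {
  tt <- physio@triggerTimes
  if (length(tt) < 2) stop("physio record needs at least 2 triggers")
  mrr <- mean(diff(tt))
  idx <- findInterval(t, tt)
  prevTrig <- ifelse(idx >= 1, tt[pmax(idx, 1)], tt[1] - mrr)
  rr <- ifelse(idx >= 1 & idx < length(tt), tt[pmin(idx + 1, length(tt))] -
                 tt[pmax(idx, 1)], mrr)
  (t - prevTrig) / rr
}

#' Simulate the continuous free-running radial acquisition
#'
#' Readout i is acquired at \eqn{t_i = (i-1) TR} from the phantom rendered
#' at the cardiac phase \eqn{(t_i - \tau)/RR} (fraction of the current cycle,
#' snapped to the waveform grid), where \eqn{\tau} is the preceding trigger.
#' Sample values are the non-uniform Fourier transform of (coil map x
#' phantom) at that readout's spoke coordinates, plus independent complex
#' Gaussian noise. The forward model is the same gridding NUFFT used in
#' reconstruction by default; \code{mode = "dft"} uses exact direct
#' summation (small grids; oracle tests and non-inverse-crime experiments).
#'
#' @param waveform a \linkS4class{DiameterWaveform} (ground truth).
#' @param spec a \code{\link{phantomSpec}}.
#' @param trajectory a discretized \linkS4class{RadialTrajectory}; its
#'   readout count is the number of acquired readouts.
#' @param coilMaps complex array N^3 x C (see \code{\link{makeCoilMaps}}).
#' @param trMs repetition time, ms.
#' @param noiseSd absolute SD of the complex noise per component; or use
#'   \code{noiseRel} to set it relative to the RMS of the noiseless data.
#' @param noiseRel optional relative noise level (overrides noiseSd).
#' @param physio a \linkS4class{PhysioRecord} covering the scan.
#' @param seed integer seed (noise).
#' @param mode forward model, "nufft" or "dft".
#' @param osf,width gridding parameters.
#' @return a \linkS4class{RawKSpace} carrying the ground truth.
#' @export
simulateAcquisition <- function(waveform, spec, trajectory, coilMaps,
                                trMs = 5.97, noiseSd = 0, noiseRel = NULL,
                                physio, seed = 1L,
                                mode = c("nufft", "dft"),
                                osf = 1.25, width = 6L) {
  mode <- match.arg(mode)
  if (!length(trajectory@samples))
    stop("trajectory has no samples; call radialSamples() first")
  R <- nrow(trajectory@directions)
  S <- dim(trajectory@samples)[2]
  C <- dim(coilMaps)[4]
  N <- dim(coilMaps)[1]
  if (N != spec$gridSize) stop("coilMaps grid does not match phantom grid")
  t <- (seq_len(R) - 1) * trMs
  tt <- physio@triggerTimes
  if (length(tt) >= 2 && max(t) > max(tt) + 2 * mean(diff(tt)))
    stop("acquisition is longer than the physiological record")
  frac <- .cycleFraction(t, physio)
  nP <- length(waveform@diameters)
  phaseIdx <- (round((frac - floor(frac)) * nP) %% nP) + 1L
  plan <- if (mode == "nufft") nufftPlan(N, osf = osf, width = width) else NULL
  data <- array(0i, dim = c(R, S, C))
  for (p in sort(unique(phaseIdx))) {
    rows <- which(phaseIdx == p)
    img <- renderPhantom(spec, waveform@diameters[p])
    k <- trajectoryCoords(trajectory, rows)
    for (cc in seq_len(C)) {
      cx <- img * coilMaps[, , , cc]
      y <- if (mode == "nufft") nufftForward(cx, plan, k)
           else nudftForward(cx, N, k)
      data[rows, , cc] <- matrix(y, nrow = length(rows), ncol = S,
                                 byrow = TRUE)
    }
  }
  if (!is.null(noiseRel)) {
    .assertScalar(noiseRel, "noiseRel")
    noiseSd <- noiseRel * sqrt(mean(abs(data)^2))
  }
  if (noiseSd > 0) {
    data <- data + withr::with_seed(seed, {
      array(complex(real = stats::rnorm(length(data), 0, noiseSd),
                    imaginary = stats::rnorm(length(data), 0, noiseSd)),
            dim = dim(data))
    })
  }
  new("RawKSpace", data = data, timestamps = t, trajectory = trajectory,
      coilMaps = coilMaps, trMs = trMs, noiseSd = noiseSd, physio = physio,
      voxelMm = spec$voxelMm,
      groundTruth = list(waveform = waveform, dS = dS(waveform),
                         dD = dD(waveform), rdc = waveformRdc(waveform),
                         phantomSpec = spec))
}

#' Simulate paired brachial pressure readings
#'
#' Pre-scan and post-scan systolic/diastolic readings are the true values
#' plus Gaussian noise; the returned pair is their mean, as in the
#' measurement protocol.
#'
#' @param truePs,truePd true pressures, mmHg (truePs > truePd).
#' @param sdMmHg reading noise SD, mmHg.
#' @param seed integer seed.
#' @return a \linkS4class{PressurePair}.
#' @export
simulatePressures <- function(truePs, truePd, sdMmHg = 0, seed = 1L) {
  if (truePs <= truePd) stop("truePs must exceed truePd")
  p <- withr::with_seed(seed, {
    c(mean(truePs + stats::rnorm(2, 0, sdMmHg)),
      mean(truePd + stats::rnorm(2, 0, sdMmHg)))
  })
  if (p[1] <= p[2])
    stop("averaged systolic pressure fell at/below the diastolic one")
  new("PressurePair", pS = p[1], pD = p[2])
}
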