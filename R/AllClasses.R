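#' @import methods
NULL

#' Segmented 3D radial phyllotaxis trajectory
#'
#' Holds the readout directions (acquisition order) and, once discretized,
#' the per-sample k-space coordinates of a segmented golden-angle
#' top-to-bottom spiral-phyllotaxis trajectory. Coordinates are normalized
#' so that |k| <= 0.5 (cycles per voxel spacing); physical units only enter
#' at I/O time through the field of view.
#'
#' @slot directions numeric matrix, one unit 3-vector per readout, rows in
#'   acquisition order.
#' @slot samples numeric array readouts x samples x 3, each spoke spanning
#'   \code{[-kMax, kMax]} along its direction; empty until
#'   \code{\link{radialSamples}} is applied.
#' @slot kMax maximum sampled spatial frequency, in (0, 0.5].
#' @slot nSegments,readoutsPerSegment segmentation of the acquisition.
#' @export
setClass("RadialTrajectory",
  representation(directions = "matrix", samples = "array", kMax = "numeric",
                 nSegments = "integer", readoutsPerSegment = "integer"),
  prototype(samples = array(numeric(0), dim = c(0, 0, 3))))

setValidity("RadialTrajectory", function(object) {
  msg <- character()
  d <- object@directions
  if (ncol(d) != 3L) msg <- c(msg, "directions must have 3 columns")
  nrm <- sqrt(rowSums(d^2))
  if (length(nrm) && max(abs(nrm - 1)) > 1e-12)
    msg <- c(msg, "directions must be unit vectors (tolerance 1e-12)")
  if (length(object@kMax) != 1L || object@kMax <= 0 || object@kMax > 0.5)
    msg <- c(msg, "kMax must lie in (0, 0.5]")
  if (length(object@samples) > 0) {
    s <- object@samples
    if (dim(s)[1] != nrow(d)) msg <- c(msg, "samples/readout count mismatch")
    r <- sqrt(s[, , 1]^2 + s[, , 2]^2 + s[, , 3]^2)
    if (max(r) > object@kMax + 1e-12)
      msg <- c(msg, "sample radius exceeds kMax")
  }
  if (length(msg)) msg else TRUE
})

#' Pulse-oximeter trigger record
#'
#' Cardiac trigger times, in ms from the start of the acquisition, as
#' recorded by the scanner's pulse oximeter and used for retrospective
#' cardiac binning.
#'
#' @slot triggerTimes strictly increasing trigger times (ms); successive
#'   differences (RR intervals) must exceed 200 ms.
#' @export
setClass("PhysioRecord", representation(triggerTimes = "numeric"))

setValidity("PhysioRecord", function(object) {
  tt <- object@triggerTimes
  if (length(tt) >= 2) {
    rr <- diff(tt)
    if (any(rr <= 0)) return("trigger times must be strictly increasing")
    if (any(rr <= 200)) return("RR intervals must exceed 200 ms")
  }
  TRUE
})

#' Continuously acquired raw radial k-space
#'
#' The y, F-sampling-locations and C of the reconstruction problem: complex
#' multi-coil radial samples with per-readout timestamps, the trajectory they
#' were acquired on, the coil sensitivity maps, and the physiological record
#' used for retrospective binning. Produced by \code{\link{simulateAcquisition}}.
#'
#' @slot data complex array readouts x samples x coils.
#' @slot timestamps per-readout acquisition times, ms; readout i is acquired
#'   at (i-1) * trMs.
#' @slot trajectory a \linkS4class{RadialTrajectory} with samples.
#' @slot coilMaps complex array nx x ny x nz x coils of sensitivities.
#' @slot trMs repetition time in ms (protocol default 5.97).
#' @slot noiseSd standard deviation of the additive complex Gaussian noise
#'   (per real/imaginary component).
#' @slot physio a \linkS4class{PhysioRecord}.
#' @slot voxelMm isotropic voxel size of the underlying phantom grid (mm).
#' @slot groundTruth list carrying the generating truth (waveform, true
#'   systolic/diastolic diameters) so downstream stages are parameter-recovery
#'   experiments.
#' @export
setClass("RawKSpace",
  representation(data = "array", timestamps = "numeric",
                 trajectory = "RadialTrajectory", coilMaps = "array",
                 trMs = "numeric", noiseSd = "numeric",
                 physio = "PhysioRecord", voxelMm = "numeric",
                 groundTruth = "list"))

setValidity("RawKSpace", function(object) {
  msg <- character()
  dm <- dim(object@data)
  if (length(dm) != 3L) msg <- c(msg, "data must be readouts x samples x coils")
  tr <- object@trajectory
  if (length(tr@samples) && !identical(dm[1:2], dim(tr@samples)[1:2]))
    msg <- c(msg, "data shape inconsistent with trajectory")
  if (length(object@timestamps) != dm[1])
    msg <- c(msg, "one timestamp per readout required")
  expected <- (seq_len(dm[1]) - 1) * object@trMs
  if (dm[1] > 0 && max(abs(object@timestamps - expected)) > 1e-9)
    msg <- c(msg, "timestamps must equal readout index times trMs")
  cm <- dim(object@coilMaps)
  if (length(cm) != 4L || cm[4] != dm[3])
    msg <- c(msg, "coilMaps must be nx x ny x nz x coils matching data")
  if (length(msg)) msg else TRUE
})

#' Retrospective cardiac bin assignment
#'
#' Maps each readout to a cardiac bin (or NA for discarded readouts:
#' pre-trigger readouts and residual late-cycle readouts beyond
#' nBins * binWidthMs).
#'
#' @slot bin integer per readout, in 0..(nBins-1), NA if discarded.
#' @slot nBins floor(mean RR / bin width), at least 1.
#' @slot binWidthMs,meanRrMs the bin width and mean heartbeat duration (ms).
#' @export
setClass("BinAssignment",
  representation(bin = "integer", nBins = "integer", binWidthMs = "numeric",
                 meanRrMs = "numeric"))

setValidity("BinAssignment", function(object) {
  msg <- character()
  if (object@nBins < 1L) msg <- c(msg, "nBins must be >= 1")
  b <- object@bin[!is.na(object@bin)]
  if (length(b) && (min(b) < 0L || max(b) >= object@nBins))
    msg <- c(msg, "bin indices must lie in 0..(nBins-1)")
  if (object@nBins != floor(object@meanRrMs / object@binWidthMs))
    msg <- c(msg, "nBins must equal floor(meanRrMs / binWidthMs)")
  if (length(msg)) msg else TRUE
})

#' Cardiac-resolved 4D image
#'
#' The reconstructed (or rendered) 3D + cardiac-phase image. Voxel values are
#' kept complex internally after reconstruction; magnitude is taken for
#' analysis and export.
#'
#' @slot data array nx x ny x nz x phases (complex or numeric).
#' @slot voxelMm isotropic voxel size, mm.
#' @slot binWidthMs temporal width of one cardiac phase, ms.
#' @slot objective per-iteration values of the reconstruction objective
#'   (empty if not reconstructed / not logged).
#' @slot lambda cardiac regularization weight used (NA if not applicable).
#' @export
setClass("Image4D",
  representation(data = "array", voxelMm = "numeric", binWidthMs = "numeric",
                 objective = "numeric", lambda = "numeric"),
  prototype(objective = numeric(0), lambda = NA_real_))

setValidity("Image4D", function(object) {
  if (length(dim(object@data)) != 4L)
    return("data must be a 4D array (x, y, z, phase)")
  if (length(object@voxelMm) != 1L ||
      (!is.na(object@voxelMm) && object@voxelMm <= 0))
    return("voxelMm must be a positive scalar (or NA)")
  TRUE
})

#' Ground-truth cardiac diameter waveform
#'
#' One cardiac cycle of lumen diameter on a uniform phase grid: a
#' raised-cosine systolic bump (upstroke and decay over
#' \code{systolicFraction} of the cycle) on a flat diastolic baseline, with
#' min and max pinned exactly to the requested diastolic/systolic diameters.
#'
#' @slot phaseTimes uniform grid of times within one cycle, ms.
#' @slot diameters diameters at those phases, mm.
#' @slot rrMs cycle length, ms.
#' @slot systolicFraction,peakPhase shape parameters (fractions of the cycle).
#' @export
setClass("DiameterWaveform",
  representation(phaseTimes = "numeric", diameters = "numeric",
                 rrMs = "numeric", systolicFraction = "numeric",
                 peakPhase = "numeric"))

setValidity("DiameterWaveform", function(object) {
  if (length(object@phaseTimes) != length(object@diameters))
    return("phaseTimes and diameters must have equal length")
  if (any(object@diameters <= 0)) return("diameters must be positive")
  TRUE
})

#' Synthetic M-mode ultrasound wall trace
#'
#' Time-resolved upper and lower lumen-wall boundary positions emulating an
#' M-mode acquisition at 250 frames per second and 0.1 mm resolution,
#' delineated at the outer wall (hence the downstream 2 x IMT correction).
#'
#' @slot timeS sample times, s (uniform, 1/fps spacing).
#' @slot upperMm,lowerMm boundary positions, mm (lower > upper everywhere).
#' @slot resolutionMm spatial resolution of the emulated system, mm.
#' @slot imtMm intima-media thickness used during synthesis, mm.
#' @slot fps frame rate, per second.
#' @slot groundTruth list(dS, dD) lumen truth carried for recovery tests.
#' @export
setClass("MModeTrace",
  representation(timeS = "numeric", upperMm = "numeric", lowerMm = "numeric",
                 resolutionMm = "numeric", imtMm = "numeric", fps = "numeric",
                 groundTruth = "list"))

setValidity("MModeTrace", function(object) {
  n <- length(object@timeS)
  if (length(object@upperMm) != n || length(object@lowerMm) != n)
    return("timeS, upperMm, lowerMm must have equal length")
  if (any(object@lowerMm <= object@upperMm))
    return("lower boundary must lie below (greater mm than) the upper one")
  if (n >= 2) {
    dt <- diff(object@timeS)
    if (max(abs(dt - 1 / object@fps)) > 1e-9)
      return("sampling interval must equal 1/fps")
  }
  TRUE
})

#' Detrended diameter evolution from an M-mode trace
#'
#' @slot timeS uniform time grid, s.
#' @slot diameterMm boundary-subtracted, linearly detrended diameter, mm
#'   (mean preserved).
#' @slot slopeRemoved the least-squares trend slope that was removed, mm/s.
#' @export
setClass("DiameterTrace",
  representation(timeS = "numeric", diameterMm = "numeric",
                 slopeRemoved = "numeric"))

#' Per-phase lumen diameters for one vessel
#'
#' Effective diameters D = 2 sqrt(A/pi) per cardiac phase (averaged across
#' the analyzed slices), with the systolic/diastolic extrema.
#'
#' @slot diameters per-phase diameters, mm (across-slice mean).
#' @slot dS,dD systolic / diastolic diameter, mm: per-slice max/min over
#'   phases, then averaged across slices.
#' @slot vessel label ("LC", "RC" or other).
#' @slot slices z indices analyzed.
#' @export
setClass("DiameterSeries",
  representation(diameters = "numeric", dS = "numeric", dD = "numeric",
                 vessel = "character", slices = "integer"))

setValidity("DiameterSeries", function(object) {
  if (object@dS < object@dD) return("dS must be >= dD")
  if (object@dD <= 0) return("diameters must be positive")
  TRUE
})

#' Systolic/diastolic extrema from an M-mode diameter trace
#'
#' @slot peaks,troughs sample indices of the five beats used.
#' @slot dS,dD means of the five systolic peaks / diastolic troughs after
#'   subtracting twice the intima-media thickness, mm.
#' @slot imtMm intima-media thickness used in the correction, mm.
#' @export
setClass("BeatExtrema",
  representation(peaks = "integer", troughs = "integer", dS = "numeric",
                 dD = "numeric", imtMm = "numeric"))

setValidity("BeatExtrema", function(object) {
  if (object@dS <= object@dD) return("dS must exceed dD")
  TRUE
})

#' Paired brachial pressures
#'
#' Systolic/diastolic brachial pressures, each the mean of a pre-scan and a
#' post-scan reading.
#'
#' @slot pS,pD systolic and diastolic pressure, mmHg, pS > pD > 0.
#' @export
setClass("PressurePair", representation(pS = "numeric", pD = "numeric"))

setValidity("PressurePair", function(object) {
  if (object@pD <= 0 || object@pS <= object@pD)
    return("need pS > pD > 0")
  TRUE
})

#' Carotid stiffness panel
#'
#' The five stiffness-related metrics for one vessel (or the left/right
#' average): relative diameter change RDC (%), stiffness index beta (-),
#' arterial compliance AC (mm^2/kPa), one-point local pulse wave velocity
#' PWV (m/s) and pressure-strain elastic modulus E (kPa), together with the
#' pressures and blood density used.
#'
#' @slot rdc,beta,ac,pwv,emod the metrics (units above).
#' @slot side "LC", "RC" or "average".
#' @slot pressures the \linkS4class{PressurePair} used.
#' @slot rho blood density, kg/m^3 (default 1050).
#' @export
setClass("StiffnessPanel",
  representation(rdc = "numeric", beta = "numeric", ac = "numeric",
                 pwv = "numeric", emod = "numeric", side = "character",
                 pressures = "PressurePair", rho = "numeric"))

setValidity("StiffnessPanel", function(object) {
  if (object@rdc < 0) return("rdc must be >= 0")
  TRUE
})

#' Reconstruction configuration
#'
#' Parameters of the compressed-sensing reconstruction: the cardiac
#' regularization weight lambda (interpreted on data scaled so that the
#' density-compensated adjoint image has unit maximum magnitude), the number
#' of ADMM iterations, the ADMM penalty (default 10 * lambda, i.e. 0.1 at the
#' default lambda = 0.01), and the inner conjugate-gradient solver settings.
#'
#' @slot lambda cardiac regularization weight (>= 0, default 0.01).
#' @slot nIters ADMM iterations (default 10).
#' @slot penalty ADMM penalty rho (NA = 10 * lambda).
#' @slot innerIters,innerTol inner CG iteration cap and relative-residual
#'   tolerance.
#' @slot dcInit use density-compensated adjoint as initialization.
#' @slot logObjective log the objective value per ADMM iteration.
#' @export
setClass("ReconConfig",
  representation(lambda = "numeric", nIters = "integer", penalty = "numeric",
                 innerIters = "integer", innerTol = "numeric",
                 dcInit = "logical", logObjective = "logical"),
  prototype(lambda = 0.01, nIters = 10L, penalty = NA_real_,
            innerIters = 10L, innerTol = 1e-6, dcInit = TRUE,
            logObjective = TRUE))

setValidity("ReconConfig", function(object) {
  if (object@lambda < 0) return("lambda must be >= 0")
  if (object@nIters < 1L) return("nIters must be >= 1")
  TRUE
})
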