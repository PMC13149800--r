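#' Systolic and diastolic diameter accessors
#'
#' @param object an object carrying a systolic/diastolic diameter pair
#'   (\linkS4class{DiameterSeries}, \linkS4class{BeatExtrema},
#'   \linkS4class{DiameterWaveform}).
#' @return numeric scalar, mm.
#' @export
setGeneric("dS", function(object) standardGeneric("dS"))

#' @rdname dS
#' @export
setGeneric("dD", function(object) standardGeneric("dD"))

#' Per-phase diameters
#'
#' @param object a \linkS4class{DiameterSeries} or
#'   \linkS4class{DiameterWaveform}.
#' @return numeric vector of diameters, mm.
#' @export
setGeneric("diameters", function(object) standardGeneric("diameters"))

#' Trigger times of a physiological record
#'
#' @param object a \linkS4class{PhysioRecord} or \linkS4class{RawKSpace}.
#' @return numeric vector, ms.
#' @export
setGeneric("triggerTimes", function(object) standardGeneric("triggerTimes"))

#' Number of cardiac bins
#'
#' @param object a \linkS4class{BinAssignment} or \linkS4class{Image4D}.
#' @return integer.
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' Stiffness metrics as a named vector
#'
#' @param object a \linkS4class{StiffnessPanel}.
#' @return named numeric vector (rdc, beta, ac, pwv, emod).
#' @export
setGeneric("stiffnessMetrics",
           function(object) standardGeneric("stiffnessMetrics"))

#' @describeIn dS systolic diameter of a measured series
setMethod("dS", "DiameterSeries", function(object) object@dS)
#' @describeIn dS diastolic diameter of a measured series
setMethod("dD", "DiameterSeries", function(object) object@dD)
#' @describeIn dS systolic diameter from M-mode beat extrema
setMethod("dS", "BeatExtrema", function(object) object@dS)
#' @describeIn dS diastolic diameter from M-mode beat extrema
setMethod("dD", "BeatExtrema", function(object) object@dD)
#' @describeIn dS true systolic diameter of a waveform
setMethod("dS", "DiameterWaveform", function(object) max(object@diameters))
#' @describeIn dS true diastolic diameter of a waveform
setMethod("dD", "DiameterWaveform", function(object) min(object@diameters))

#' @describeIn diameters per-phase diameters of a measured series
setMethod("diameters", "DiameterSeries", function(object) object@diameters)
#' @describeIn diameters the waveform's diameter grid
setMethod("diameters", "DiameterWaveform", function(object) object@diameters)

#' @describeIn triggerTimes triggers of a physiological record
setMethod("triggerTimes", "PhysioRecord", function(object) object@triggerTimes)
#' @describeIn triggerTimes triggers carried by a raw acquisition
setMethod("triggerTimes", "RawKSpace",
          function(object) object@physio@triggerTimes)

#' @describeIn nBins bins of an assignment
setMethod("nBins", "BinAssignment", function(object) object@nBins)
#' @describeIn nBins cardiac phases of a 4D image
setMethod("nBins", "Image4D", function(object) dim(object@data)[4L])

#' @describeIn stiffnessMetrics the five metrics of a panel
setMethod("stiffnessMetrics", "StiffnessPanel", function(object) {
  c(rdc = object@rdc, beta = object@beta, ac = object@ac,
    pwv = object@pwv, emod = object@emod)
})

setMethod("show", "RadialTrajectory", function(object) {
  cat("RadialTrajectory:", nrow(object@directions), "readouts (",
      object@nSegments, "segments x", object@readoutsPerSegment,
      "), kMax =", object@kMax, "\n")
  if (length(object@samples))
    cat("  ", dim(object@samples)[2], "samples per spoke\n")
})

setMethod("show", "RawKSpace", function(object) {
  dm <- dim(object@data)
  cat("RawKSpace:", dm[1], "readouts x", dm[2], "samples x", dm[3],
      "coils; TR =", object@trMs, "ms;",
      length(object@physio@triggerTimes), "triggers\n")
})

setMethod("show", "Image4D", function(object) {
  dm <- dim(object@data)
  cat("Image4D:", paste(dm[1:3], collapse = " x "), "voxels x", dm[4],
      "cardiac phases; voxel", object@voxelMm, "mm; bin width",
      object@binWidthMs, "ms\n")
})

setMethod("show", "DiameterSeries", function(object) {
  cat(sprintf("DiameterSeries [%s]: %d phases; Ds = %.3f mm, Dd = %.3f mm\n",
              object@vessel, length(object@diameters), object@dS, object@dD))
})

setMethod("show", "MModeTrace", function(object) {
  cat(sprintf("MModeTrace: %d samples at %g fps (%.2f s), IMT %.2f mm\n",
              length(object@timeS), object@fps,
              diff(range(object@timeS)), object@imtMm))
})

setMethod("show", "StiffnessPanel", function(object) {
  cat(sprintf("StiffnessPanel [%s]  (Ps/Pd = %g/%g mmHg, rho = %g kg/m^3)\n",
              object@side, object@pressures@pS, object@pressures@pD,
              object@rho))
  cat(sprintf("  RDC %.3f %% | beta %.3f | AC %.3f mm^2/kPa | PWV %.3f m/s | E %.2f kPa\n",
              object@rdc, object@beta, object@ac, object@pwv, object@emod))
})

setMethod("show", "BinAssignment", function(object) {
  cat(sprintf("BinAssignment: %d bins of %g ms (mean RR %.1f ms); %d/%d readouts retained\n",
              object@nBins, object@binWidthMs, object@meanRrMs,
              sum(!is.na(object@bin)), length(object@bin)))
})
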