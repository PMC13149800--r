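#' Write / read a 4D image as NIfTI
#'
#' Magnitude export: the voxel size goes into the spatial pixdim fields and
#' the cardiac bin width (in seconds) into the time-per-volume field.
#'
#' @param image an \linkS4class{Image4D}.
#' @param file NIfTI path (.nii or .nii.gz).
#' @return (write) the file path, invisibly; (read) an
#'   \linkS4class{Image4D} with magnitude data.
#' @export
writeImage4D <- function(image, file) {
  arr <- abs(image@data)
  pix <- c(rep(image@voxelMm, 3),
           if (is.na(image@binWidthMs)) 1 else image@binWidthMs / 1000)
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- pix[seq_len(length(dim(arr)))]
  RNifti::writeNifti(nii, file)
  invisible(file)
}

#' @rdname writeImage4D
#' @export
readImage4D <- function(file) {
  nii <- RNifti::readNifti(file)
  pix <- RNifti::pixdim(nii)
  arr <- array(as.numeric(nii), dim = dim(nii))
  if (length(dim(arr)) == 3L) arr <- array(arr, dim = c(dim(arr), 1L))
  binW <- if (length(pix) >= 4) pix[4] * 1000 else NA_real_
  new("Image4D", data = arr, voxelMm = pix[1], binWidthMs = binW,
      lambda = NA_real_)
}

#' Write / read an M-mode trace as CSV
#'
#' Columns: time_s, upper_mm, lower_mm (header included).
#'
#' @param trace an \linkS4class{MModeTrace}.
#' @param file CSV path.
#' @param imtMm,fps metadata to attach when reading (the CSV stores only the
#'   boundaries).
#' @return (write) the path, invisibly; (read) an \linkS4class{MModeTrace}.
#' @export
writeMModeTrace <- function(trace, file) {
  utils::write.csv(data.frame(time_s = trace@timeS,
                              upper_mm = trace@upperMm,
                              lower_mm = trace@lowerMm),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMModeTrace
#' @export
readMModeTrace <- function(file, imtMm = 0, fps = NULL) {
  df <- utils::read.csv(file)
  if (is.null(fps)) fps <- round(1 / stats::median(diff(df$time_s)))
  new("MModeTrace", timeS = df$time_s, upperMm = df$upper_mm,
      lowerMm = df$lower_mm, resolutionMm = 0.1, imtMm = imtMm, fps = fps,
      groundTruth = list())
}

#' Write / read a pressure pair as CSV
#'
#' @param pressures a \linkS4class{PressurePair}.
#' @param file CSV path (columns p_s, p_d).
#' @return (write) the path, invisibly; (read) a
#'   \linkS4class{PressurePair}.
#' @export
writePressures <- function(pressures, file) {
  utils::write.csv(data.frame(p_s = pressures@pS, p_d = pressures@pD),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname writePressures
#' @export
readPressures <- function(file) {
  df <- utils::read.csv(file)
  new("PressurePair", pS = df$p_s[1], pD = df$p_d[1])
}

#' Save / load a raw k-space container
#'
#' Run-time serialization of the full \linkS4class{RawKSpace} object
#' (k-space, timestamps, trajectory, triggers, coil maps, ground truth and
#' acquisition attributes).
#'
#' @param raw a \linkS4class{RawKSpace}.
#' @param file path (.rds).
#' @return (save) the path, invisibly; (load) the object.
#' @export
saveRawKSpace <- function(raw, file) {
  saveRDS(raw, file)
  invisible(file)
}

#' @rdname saveRawKSpace
#' @export
loadRawKSpace <- function(file) readRDS(file)
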