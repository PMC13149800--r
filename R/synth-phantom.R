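#' Phantom geometry and intensities
#'
#' Describes the neck-like digital phantom: two bright axial cylinders
#' (lumina) with a surrounding wall annulus in a darker background,
#' emulating inflow contrast (unsaturated inflowing blood is brighter than
#' stationary tissue). Coordinates are in mm with voxel centres at
#' \code{index * voxelMm}, 0-based.
#'
#' @param gridSize voxels per axis (cubic grid).
#' @param voxelMm isotropic voxel size, mm (default 0.6 as in the MR
#'   protocol).
#' @param vesselCentersMm matrix n x 2 of in-plane (x, y) cylinder axis
#'   positions, mm. Default: two vessels (LC, RC) symmetric about the grid
#'   centre.
#' @param wallThicknessMm wall annulus thickness, mm.
#' @param intensities named vector with components \code{lumen},
#'   \code{wall}, \code{background}; lumen must be brightest (default
#'   10/3/1, a 10:1 lumen:background contrast).
#' @param backgroundRoi integer vector (x0, x1, y0, y1, z0, z1), 1-based
#'   voxel box away from the vessels used for aSNR noise estimation.
#' @return a phantom specification (list).
#' @export
phantomSpec <- function(gridSize = 64L, voxelMm = 0.6,
                        vesselCentersMm = NULL, wallThicknessMm = 0.9,
                        intensities = c(lumen = 10, wall = 3, background = 1),
                        backgroundRoi = NULL) {
  gridSize <- .assertCount(gridSize, "gridSize")
  .assertScalar(voxelMm, "voxelMm", positive = TRUE)
  fov <- (gridSize - 1) * voxelMm
  if (is.null(vesselCentersMm)) {
    off <- fov / 4.6
    vesselCentersMm <- rbind(LC = c(fov / 2 - off, fov / 2),
                             RC = c(fov / 2 + off, fov / 2))
  }
  vesselCentersMm <- rbind(vesselCentersMm)
  if (ncol(vesselCentersMm) != 2L)
    stop("vesselCentersMm must have two columns (x, y in mm)")
  if (!all(c("lumen", "wall", "background") %in% names(intensities)))
    stop("intensities must name lumen, wall, background")
  if (intensities["lumen"] <= max(intensities["wall"],
                                  intensities["background"]))
    stop("lumen intensity must be the brightest")
  if (is.null(backgroundRoi)) {
    n8 <- max(2L, gridSize %/% 8L)
    backgroundRoi <- c(1L, n8, 1L, n8, 1L, gridSize)
  }
  list(gridSize = gridSize, voxelMm = voxelMm,
       vesselCentersMm = vesselCentersMm,
       wallThicknessMm = wallThicknessMm, intensities = intensities,
       backgroundRoi = backgroundRoi)
}

# Supersampled in-plane occupancy of a disk over the pixel grid.
# Returns a gridSize x gridSize matrix of occupancy fractions in [0, 1].
.diskOccupancy <- function(gridSize, voxelMm, cx, cy, radiusMm, ss = 4L) {
  occ <- matrix(0, gridSize, gridSize)
  if (radiusMm <= 0) return(occ)
  # bounding box of affected pixels
  i0 <- max(0L, floor((cx - radiusMm) / voxelMm) - 1L)
  i1 <- min(gridSize - 1L, ceiling((cx + radiusMm) / voxelMm) + 1L)
  j0 <- max(0L, floor((cy - radiusMm) / voxelMm) - 1L)
  j1 <- min(gridSize - 1L, ceiling((cy + radiusMm) / voxelMm) + 1L)
  sub <- ((seq_len(ss) - 0.5) / ss - 0.5) * voxelMm
  ii <- i0:i1; jj <- j0:j1
  # sub-voxel x and y offsets for all sub-samples of all pixels in the box
  px <- outer(ii * voxelMm, sub, "+")   # |ii| x ss
  py <- outer(jj * voxelMm, sub, "+")
  dx2 <- (px - cx)^2                     # |ii| x ss
  dy2 <- (py - cy)^2
  r2 <- radiusMm^2
  # occupancy(i, j) = mean over ss^2 sub-samples of (dx2 + dy2 <= r2)
  for (a in seq_len(ss)) {
    inx <- dx2[, a]
    for (b in seq_len(ss)) {
      occ[ii + 1L, jj + 1L] <- occ[ii + 1L, jj + 1L] +
        (outer(inx, dy2[, b], "+") <= r2)
    }
  }
  occ[ii + 1L, jj + 1L] <- occ[ii + 1L, jj + 1L] / (ss * ss)
  occ
}

#' Render the pulsating-vessel phantom at a given diameter
#'
#' Renders the two axial cylinders with supersampled partial-volume edges
#' (each voxel's value is the sub-voxel occupancy-weighted mix of
#' lumen/wall/background at \code{ss} x \code{ss} in-plane supersampling;
#' the cylinders are z-invariant). Deterministic.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param diameterMm lumen diameter(s), mm; recycled across vessels.
#' @param ss supersampling factor per in-plane axis (>= 4 recommended).
#' @return numeric 3D array gridSize^3.
#' @export
renderPhantom <- function(spec, diameterMm, ss = 4L) {
  n <- spec$gridSize
  v <- spec$voxelMm
  centers <- spec$vesselCentersMm
  nv <- nrow(centers)
  diameterMm <- rep_len(diameterMm, nv)
  if (any(diameterMm <= 0)) stop("diameterMm must be positive")
  fov <- (n - 1) * v
  outer_r <- diameterMm / 2 + spec$wallThicknessMm
  if (any(centers[, 1] - outer_r < 0 | centers[, 1] + outer_r > fov |
          centers[, 2] - outer_r < 0 | centers[, 2] + outer_r > fov))
    stop("vessel exits the grid at this diameter")
  ints <- spec$intensities
  slice <- matrix(ints[["background"]], n, n)
  for (k in seq_len(nv)) {
    occL <- .diskOccupancy(n, v, centers[k, 1], centers[k, 2],
                           diameterMm[k] / 2, ss)
    occO <- .diskOccupancy(n, v, centers[k, 1], centers[k, 2],
                           outer_r[k], ss)
    occW <- occO - occL
    slice <- slice + occL * (ints[["lumen"]] - ints[["background"]]) +
      occW * (ints[["wall"]] - ints[["background"]])
  }
  array(slice, dim = c(n, n, n))
}

#' Ground-truth lumen mask of the phantom
#'
#' Voxels whose centre lies inside a lumen at the given diameter; used for
#' aSNR lumen averaging and sweep bookkeeping.
#'
#' @inheritParams renderPhantom
#' @return logical 3D array.
#' @export
phantomLumenMask <- function(spec, diameterMm) {
  n <- spec$gridSize
  v <- spec$voxelMm
  centers <- spec$vesselCentersMm
  diameterMm <- rep_len(diameterMm, nrow(centers))
  xy <- (seq_len(n) - 1) * v
  m <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((xy - centers[k, 1])^2, (xy - centers[k, 2])^2, "+")
    m <- m | (d2 <= (diameterMm[k] / 2)^2)
  }
  array(m, dim = c(n, n, n))
}

#' Smooth synthetic coil sensitivity maps
#'
#' Gaussian-profile sensitivities centred on the lateral faces of the
#' volume, with a gentle per-coil linear phase, normalized so the
#' sum-of-squares magnitude is 1 everywhere (hence also in the vessel
#' region).
#'
#' @param gridSize voxels per axis.
#' @param nCoils number of coils (4-8 typical here).
#' @return complex array gridSize^3 x nCoils.
#' @export
makeCoilMaps <- function(gridSize, nCoils = 4L) {
  n <- .assertCount(gridSize, "gridSize")
  nCoils <- .assertCount(nCoils, "nCoils")
  g <- (seq_len(n) - 1) / (n - 1)  # 0..1
  ang <- 2 * pi * (seq_len(nCoils) - 1) / nCoils
  sigma <- 0.7
  maps <- array(0i, dim = c(n, n, n, nCoils))
  for (cc in seq_len(nCoils)) {
    cx <- 0.5 + 0.6 * cos(ang[cc])
    cy <- 0.5 + 0.6 * sin(ang[cc])
    mag2d <- exp(-(outer((g - cx)^2, (g - cy)^2, "+")) / (2 * sigma^2))
    ph2d <- 0.5 * (outer(g - 0.5, rep(0, n), "+") * cos(ang[cc]) +
                   outer(rep(0, n), g - 0.5, "+") * sin(ang[cc]))
    s2d <- mag2d * exp(1i * ph2d)
    maps[, , , cc] <- array(rep(s2d, n), dim = c(n, n, n))
  }
  sos <- sqrt(apply(abs(maps)^2, 1:3, sum))
  for (cc in seq_len(nCoils)) maps[, , , cc] <- maps[, , , cc] / sos
  maps
}
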