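#' Full-width-at-half-maximum crossings of a 1D profile
#'
#' The half level is \code{min + 0.5 * (max - min)} of the profile (half the
#' signal range). Scanning inward from each end, the first sub-sample
#' (linearly interpolated) upward crossing of the half level is returned, so
#' the pair is the outermost crossing pair bracketing the peak.
#'
#' @param profile intensity samples (>= 5).
#' @param positions sample positions, mm (strictly increasing).
#' @return c(left, right) crossing positions, mm.
#' @examples
#' fwhmCrossings(c(0, 0, 10, 10, 10, 0, 0), 0:6)  # 1.5 4.5
#' @export
fwhmCrossings <- function(profile, positions = seq_along(profile) - 1) {
  if (length(profile) < 5) stop("profile needs at least 5 samples")
  if (length(profile) != length(positions))
    stop("profile and positions must match")
  rng <- range(profile)
  if (diff(rng) == 0) stop("flat profile: no half-maximum crossing")
  half <- rng[1] + 0.5 * diff(rng)
  n <- length(profile)
  cross <- function(i, j) {
    positions[i] + (half - profile[i]) / (profile[j] - profile[i]) *
      (positions[j] - positions[i])
  }
  li <- which(profile >= half)[1]
  if (is.na(li) || li == 1L)
    stop("no half-maximum crossing on the left side")
  ri <- rev(which(profile >= half))[1]
  if (ri == n)
    stop("no half-maximum crossing on the right side")
  c(cross(li - 1L, li), cross(ri + 1L, ri))
}

# Vectorized bilinear interpolation of a matrix at fractional 0-based
# indices; out-of-range queries clamp to the border.
.bilinear <- function(mat, x, y) {
  nr <- nrow(mat); nc <- ncol(mat)
  x <- pmin(pmax(x, 0), nr - 1)
  y <- pmin(pmax(y, 0), nc - 1)
  x0 <- pmin(floor(x), nr - 2); y0 <- pmin(floor(y), nc - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0 + 1, y0 + 1)
  mat[i00] * (1 - fx) * (1 - fy) +
    mat[cbind(x0 + 2, y0 + 1)] * fx * (1 - fy) +
    mat[cbind(x0 + 1, y0 + 2)] * (1 - fx) * fy +
    mat[cbind(x0 + 2, y0 + 2)] * fx * fy
}

#' Semi-automatic FWHM lumen contour in one slice
#'
#' Casts equally spaced rays from the lumen centre; along each ray
#' (sampled by bilinear interpolation at 0.1-voxel steps out to
#' \code{maxRadiusMm}) the half level is min + half the range of that ray's
#' profile, and the vertex is the first sub-sample crossing below the half
#' level outward of the profile's peak. The centre is then iterated to the
#' contour centroid (at most \code{maxIter} times, stopping when the shift
#' falls below 0.1 voxel).
#'
#' @param sliceImage 2D magnitude image (matrix, x by y).
#' @param roiCenterMm c(x, y) starting centre inside the lumen, mm.
#' @param voxelMm voxel size, mm.
#' @param nRays number of rays (default 64).
#' @param maxRadiusMm ray length / ROI radius, mm.
#' @param maxIter centroid iterations.
#' @return list with \code{vertices} (nRays x 2, mm), \code{center} (mm),
#'   \code{converged}.
#' @export
extractContour <- function(sliceImage, roiCenterMm, voxelMm, nRays = 64L,
                           maxRadiusMm = 6, maxIter = 10L) {
  nRays <- .assertCount(nRays, "nRays")
  ang <- 2 * pi * (seq_len(nRays) - 1) / nRays
  step <- 0.1 * voxelMm
  r <- seq(0, maxRadiusMm, by = step)
  center <- roiCenterMm
  converged <- FALSE
  vertices <- NULL
  for (iter in seq_len(maxIter)) {
    vr <- numeric(nRays)
    failed <- integer(0)
    for (a in seq_len(nRays)) {
      px <- (center[1] + r * cos(ang[a])) / voxelMm
      py <- (center[2] + r * sin(ang[a])) / voxelMm
      prof <- .bilinear(sliceImage, px, py)
      rng <- range(prof)
      if (diff(rng) == 0) { failed <- c(failed, a); next }
      half <- rng[1] + 0.5 * diff(rng)
      # the lumen peak lies in the inner part of the ray; a bright artifact
      # or neighbouring structure near the ray end must not hijack the peak
      pk <- which.max(prof[seq_len(ceiling(length(prof) / 2))])
      below <- which(prof < half)
      below <- below[below > pk]
      if (!length(below)) { failed <- c(failed, a); next }
      i <- below[1]
      # linear interpolation between samples i-1 (>= half) and i (< half)
      frac <- (prof[i - 1] - half) / (prof[i - 1] - prof[i])
      vr[a] <- r[i - 1] + frac * step
    }
    if (length(failed))
      stop("FWHM crossing failed for ray angle(s) ",
           paste(round(ang[failed] * 180 / pi, 1), collapse = ", "),
           " degrees")
    vertices <- cbind(center[1] + vr * cos(ang),
                      center[2] + vr * sin(ang))
    newCenter <- colMeans(vertices)
    shift <- sqrt(sum((newCenter - center)^2))
    center <- newCenter
    if (shift < 0.1 * voxelMm) { converged <- TRUE; break }
  }
  if (!converged)
    warning("contour centroid did not converge; last estimate used")
  list(vertices = vertices, center = center, converged = converged)
}

#' Polygon area by fan triangulation
#'
#' Area as the sum of triangles fanned from the vertex centroid; for the
#' star-shaped contours produced here this equals the shoelace value.
#'
#' @param vertices n x 2 matrix of polygon vertices (ordered), n >= 3.
#' @return area (squared input units).
#' @examples
#' polygonArea(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygonArea <- function(vertices) {
  if (is.list(vertices) && !is.null(vertices$vertices))
    vertices <- vertices$vertices
  if (nrow(vertices) < 3) stop("a polygon needs at least 3 vertices")
  c0 <- colMeans(vertices)
  x <- vertices[, 1] - c0[1]
  y <- vertices[, 2] - c0[2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  # sum of signed fan-triangle areas (centroid, v_i, v_{i+1})
  abs(sum(x * yn - xn * y)) / 2
}

#' Effective diameter from a cross-sectional area
#'
#' \eqn{D = 2\sqrt{A/\pi}}, the diameter of the circle with the same area.
#'
#' @param areaMm2 area, mm^2 (> 0).
#' @return diameter, mm.
#' @export
effectiveDiameter <- function(areaMm2) {
  if (any(areaMm2 <= 0)) stop("area must be positive")
  2 * sqrt(areaMm2 / pi)
}

#' Per-phase lumen diameters from a 4D image
#'
#' For every analyzed slice and cardiac phase the lumen is contoured
#' (\code{\link{extractContour}}), triangulated to an area and converted to
#' the effective diameter. Systolic/diastolic diameters are the per-slice
#' maximum/minimum over phases, then averaged across slices (the
#' alternative, extrema of the across-slice mean curve, is available via
#' \code{extremaMode}). The reported per-phase series is the across-slice
#' mean. No intima-media correction is applied: the lumen signal is
#' targeted directly.
#'
#' @param image an \linkS4class{Image4D} (magnitude is taken).
#' @param roiCenterMm c(x, y) in-plane centre, mm.
#' @param slices 1-based z indices (default: 3 slices around the volume
#'   centre).
#' @param vessel label for the result.
#' @param extremaMode "per-slice" (default) or "mean-curve".
#' @param ... passed to \code{\link{extractContour}}.
#' @return a \linkS4class{DiameterSeries}.
#' @export
diameterSeries <- function(image, roiCenterMm, slices = NULL,
                           vessel = "LC", extremaMode = c("per-slice",
                                                          "mean-curve"),
                           ...) {
  extremaMode <- match.arg(extremaMode)
  arr <- abs(image@data)
  nz <- dim(arr)[3]
  P <- dim(arr)[4]
  if (is.null(slices)) {
    mid <- ceiling(nz / 2)
    slices <- unique(pmin(pmax(mid + (-1:1), 1L), nz))
  }
  d <- matrix(NA_real_, nrow = length(slices), ncol = P)
  for (si in seq_along(slices)) {
    for (p in seq_len(P)) {
      ct <- tryCatch(
        extractContour(arr[, , slices[si], p], roiCenterMm,
                       image@voxelMm, ...),
        error = function(e)
          stop(sprintf("contour failed at slice %d, phase %d: %s",
                       slices[si], p, conditionMessage(e)), call. = FALSE))
      d[si, p] <- effectiveDiameter(polygonArea(ct$vertices))
    }
  }
  if (extremaMode == "per-slice") {
    dSv <- mean(apply(d, 1, max))
    dDv <- mean(apply(d, 1, min))
  } else {
    curve <- colMeans(d)
    dSv <- max(curve); dDv <- min(curve)
  }
  new("DiameterSeries", diameters = colMeans(d), dS = dSv, dD = dDv,
      vessel = vessel, slices = as.integer(slices))
}
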