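#' Generate spiral-phyllotaxis readout directions
#'
#' Builds the segmented 3D golden-angle top-to-bottom spiral-phyllotaxis
#' direction set. The full pattern places its total of M x N spokes on the
#' spherical spiral with polar angle
#' \eqn{\theta_n = (\pi/2) \sqrt{n/(MN-1)}} (top-to-bottom from the +z pole)
#' and azimuth \eqn{\phi_n = n \gamma} (golden angle
#' \eqn{\gamma = 137.50776405^\circ}), and assigns them to M segments by
#' interleaving: readout j of segment s is global spoke n = s + jM. Each
#' segment is therefore a smooth pole-to-equator path, consecutive segments
#' are rotated about the main axis by exactly the golden angle
#' (azimuth(s, j) - azimuth(s-1, j) = \eqn{\gamma}), and the union of all
#' segments covers the hemisphere quasi-uniformly. Full k-space coverage
#' comes from each spoke spanning -kMax..+kMax.
#'
#' The construction is fully deterministic: regenerating with the same
#' parameters is bit-identical.
#'
#' @param nSegments number of segments (interleaves), >= 1.
#' @param readoutsPerSegment readouts per segment, >= 1 (the protocol's
#'   interleave length; default 22).
#' @param kMax maximum spatial frequency in (0, 0.5] (cycles per voxel
#'   spacing).
#' @return a \linkS4class{RadialTrajectory} with directions only (apply
#'   \code{\link{radialSamples}} to discretize the spokes).
#' @examples
#' tr <- phyllotaxisDirections(4, 6)
#' nrow(tr@directions)  # 24
#' @export
phyllotaxisDirections <- function(nSegments, readoutsPerSegment = 22L,
                                  kMax = 0.5) {
  nSegments <- .assertCount(nSegments, "nSegments")
  readoutsPerSegment <- .assertCount(readoutsPerSegment, "readoutsPerSegment")
  .assertScalar(kMax, "kMax", positive = TRUE)
  if (kMax > 0.5) stop("kMax must be <= 0.5")
  N <- readoutsPerSegment
  M <- nSegments
  total <- M * N
  j <- seq_len(N) - 1
  ga <- GOLDEN_ANGLE_DEG * pi / 180
  dirs <- matrix(0, nrow = total, ncol = 3)
  for (s in seq_len(M) - 1L) {
    n <- s + j * M  # interleaved global spoke index
    theta <- if (total == 1L) 0 else (pi / 2) * sqrt(n / (total - 1))
    phi <- n * ga
    rows <- s * N + seq_len(N)
    dirs[rows, 1] <- sin(theta) * cos(phi)
    dirs[rows, 2] <- sin(theta) * sin(phi)
    dirs[rows, 3] <- cos(theta)
  }
  # guard against rounding drift in the unit norm
  dirs <- dirs / sqrt(rowSums(dirs^2))
  new("RadialTrajectory", directions = dirs, kMax = kMax,
      nSegments = nSegments, readoutsPerSegment = readoutsPerSegment)
}

#' Discretize spokes into k-space sample coordinates
#'
#' Each spoke spans \code{[-kMax, +kMax]} symmetrically along its direction
#' with uniform spacing; for an odd number of samples the middle sample sits
#' exactly at the k-space origin.
#'
#' @param trajectory a \linkS4class{RadialTrajectory} (directions required).
#' @param samplesPerReadout samples per spoke, >= 2.
#' @return the trajectory with the \code{samples} array filled
#'   (readouts x samples x 3).
#' @examples
#' tr <- radialSamples(phyllotaxisDirections(1, 1), 3)
#' tr@samples[1, , 3]  # -0.5, 0, 0.5 for the polar spoke
#' @export
radialSamples <- function(trajectory, samplesPerReadout) {
  stopifnot(is(trajectory, "RadialTrajectory"))
  samplesPerReadout <- .assertCount(samplesPerReadout, "samplesPerReadout")
  if (samplesPerReadout < 2L)
    stop("samplesPerReadout must be >= 2")
  kMax <- trajectory@kMax
  radii <- seq(-kMax, kMax, length.out = samplesPerReadout)
  d <- trajectory@directions
  R <- nrow(d)
  samples <- array(0, dim = c(R, samplesPerReadout, 3))
  for (ax in 1:3)
    samples[, , ax] <- outer(d[, ax], radii)
  initialize(trajectory, samples = samples)
}

#' Flatten trajectory samples to an M x 3 coordinate matrix
#'
#' Utility used by the encoding operator and the simulator: rows are ordered
#' readout-major (all samples of readout 1, then readout 2, ...).
#'
#' @param trajectory a discretized \linkS4class{RadialTrajectory}.
#' @param readouts optional readout indices to keep (1-based).
#' @return numeric matrix M x 3 of k coordinates in cycles per voxel spacing.
#' @export
trajectoryCoords <- function(trajectory, readouts = NULL) {
  s <- trajectory@samples
  if (!length(s)) stop("trajectory has no samples; call radialSamples() first")
  if (!is.null(readouts)) s <- s[readouts, , , drop = FALSE]
  dm <- dim(s)
  # readout-major flattening: transpose so sample index varies fastest
  m <- matrix(0, nrow = dm[1] * dm[2], ncol = 3)
  for (ax in 1:3)
    m[, ax] <- as.vector(t(s[, , ax]))
  m
}
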