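#' @useDynLib freerunMRA, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Plan a gridding non-uniform Fourier transform
#'
#' Precomputes the oversampled grid size, Kaiser-Bessel kernel shape
#' parameter (Beatty's minimum-aliasing choice) and the deapodization
#' profile for a cubic image grid. The forward operator evaluates
#' \deqn{y_m = \sum_n x(n) e^{-2\pi i k_m \cdot (n - N/2)}}
#' at off-grid locations k (cycles per voxel spacing, |k| <= 0.5); the
#' adjoint is its exact conjugate transpose because spreading and
#' interpolation share the same real kernel.
#'
#' @param N image grid side (even).
#' @param osf oversampling factor (grid is rounded up to an even size).
#' @param width kernel width in oversampled grid cells.
#' @return a plan list used by \code{\link{nufftForward}} /
#'   \code{\link{nufftAdjoint}}.
#' @export
nufftPlan <- function(N, osf = 1.25, width = 6L) {
  N <- .assertCount(N, "N")
  if (N %% 2L != 0L) stop("N must be even")
  width <- .assertCount(width, "width")
  G <- 2L * as.integer(ceiling(osf * N / 2))
  sigma <- G / N
  beta <- pi * sqrt((width / sigma)^2 * (sigma - 0.5)^2 - 0.8)
  # deapodization = continuous Fourier transform of the kernel at the image
  # frequencies f = (n - N/2)/G, computed by Simpson quadrature
  nq <- 2001L
  u <- seq(-width / 2, width / 2, length.out = nq)
  t <- 1 - (2 * u / width)^2
  cu <- ifelse(t > 0, besselI(beta * sqrt(pmax(t, 0)), 0), 1)
  wq <- rep(c(2, 4), length.out = nq); wq[1] <- 1; wq[nq] <- 1
  h <- u[2] - u[1]
  f <- ((seq_len(N) - 1) - N / 2) / G
  apod <- vapply(f, function(ff)
    sum(wq * cu * cos(2 * pi * ff * u)) * h / 3, numeric(1))
  ia <- 1 / apod
  invApod3 <- array(outer(outer(ia, ia), ia), dim = c(N, N, N))
  # linear indices placing the centered N-cube into the wrapped G-cube
  # (image voxel n, centered coordinate n - N/2, stored at (n - N/2) mod G)
  ax <- (((seq_len(N) - 1) - N / 2) %% G) + 1
  padIdx <- as.vector(outer(outer(ax, (ax - 1) * G, "+"),
                            (ax - 1) * G * G, "+"))
  list(N = N, G = G, width = width, beta = beta, apod = apod,
       invApod3 = invApod3, padIdx = padIdx)
}

#' Apply the forward gridding NUFFT
#'
#' @param x complex (or numeric) 3D array N^3.
#' @param plan a \code{\link{nufftPlan}}.
#' @param k numeric matrix M x 3 of sample locations, cycles per voxel
#'   spacing.
#' @return complex vector of M k-space samples.
#' @export
nufftForward <- function(x, plan, k) {
  N <- plan$N; G <- plan$G
  stopifnot(identical(dim(x), c(N, N, N)))
  pad <- complex(length.out = G^3)
  pad[plan$padIdx] <- x * plan$invApod3
  dim(pad) <- c(G, G, G)
  Xc <- stats::fft(pad)
  dim(Xc) <- NULL
  kb_interp3(Xc, G, k * G, plan$width, plan$beta)
}

#' Apply the adjoint gridding NUFFT
#'
#' Exact conjugate transpose of \code{\link{nufftForward}}.
#'
#' @param y complex vector of M samples.
#' @param plan a \code{\link{nufftPlan}}.
#' @param k numeric matrix M x 3 matching \code{y}.
#' @return complex 3D array N^3.
#' @export
nufftAdjoint <- function(y, plan, k) {
  N <- plan$N; G <- plan$G
  grid <- kb_spread3(as.complex(y), G, k * G, plan$width, plan$beta)
  dim(grid) <- c(G, G, G)
  img <- stats::fft(grid, inverse = TRUE)
  array(img[plan$padIdx], dim = c(N, N, N)) * plan$invApod3
}

#' Exact non-uniform DFT (direct summation)
#'
#' Brute-force evaluation of the same transform as
#' \code{\link{nufftForward}}; O(M N^3), intended for small grids (forward
#' model oracle and "honest", non-inverse-crime simulation).
#'
#' @inheritParams nufftForward
#' @param N grid side.
#' @return complex vector of M samples.
#' @export
nudftForward <- function(x, N, k) {
  stopifnot(identical(dim(x), c(N, N, N)))
  dft_forward3(as.complex(as.vector(x)), N, k)
}

#' @rdname nudftForward
#' @param y complex vector of samples.
#' @export
nudftAdjoint <- function(y, N, k) {
  array(dft_adjoint3(as.complex(y), N, k), dim = c(N, N, N))
}

#' Build the per-bin multi-coil encoding operator
#'
#' Packages the sampling locations of every cardiac bin together with the
#' coil sensitivities and the gridding plan into the encoding operator FC of
#' the reconstruction problem: the forward applies coil weighting then the
#' non-uniform Fourier transform at that bin's locations; the adjoint is the
#' exact conjugate transpose (gridding plus conjugate coil combination).
#'
#' @param coords list with one M_b x 3 coordinate matrix per bin.
#' @param coilMaps complex array N x N x N x C.
#' @param osf,width gridding parameters (see \code{\link{nufftPlan}}).
#' @param mode "nufft" (gridding) or "dft" (exact direct summation; small
#'   grids only).
#' @return an encoding operator (list) for \code{\link{encodingForward}} /
#'   \code{\link{encodingAdjoint}}.
#' @export
encodingOperator <- function(coords, coilMaps, osf = 1.25, width = 6L,
                             mode = c("nufft", "dft")) {
  mode <- match.arg(mode)
  if (!is.list(coords)) coords <- list(coords)
  if (any(vapply(coords, nrow, 1L) == 0L)) {
    empty <- which(vapply(coords, nrow, 1L) == 0L)
    stop("empty cardiac bin(s): ", paste(empty, collapse = ", "))
  }
  dm <- dim(coilMaps)
  if (length(dm) != 4L || length(unique(dm[1:3])) != 1L)
    stop("coilMaps must be a cubic N x N x N x C array")
  N <- dm[1]
  plan <- if (mode == "nufft") nufftPlan(N, osf = osf, width = width) else NULL
  list(coords = coords, coilMaps = coilMaps, N = N, nCoils = dm[4],
       nBins = length(coords), plan = plan, mode = mode)
}

#' Forward / adjoint application of the encoding operator
#'
#' @param x4 complex array N x N x N x nBins.
#' @param op an \code{\link{encodingOperator}}.
#' @return \code{encodingForward}: list with one M_b x C complex matrix per
#'   bin; \code{encodingAdjoint}: complex array N x N x N x nBins.
#' @export
encodingForward <- function(x4, op) {
  N <- op$N
  if (length(dim(x4)) == 3L) x4 <- array(x4, dim = c(dim(x4), 1L))
  stopifnot(dim(x4)[4] == op$nBins)
  lapply(seq_len(op$nBins), function(p) {
    xp <- x4[, , , p]
    k <- op$coords[[p]]
    y <- matrix(0i, nrow = nrow(k), ncol = op$nCoils)
    for (cc in seq_len(op$nCoils)) {
      cx <- xp * op$coilMaps[, , , cc]
      y[, cc] <- if (op$mode == "nufft") nufftForward(cx, op$plan, k)
                 else nudftForward(cx, N, k)
    }
    y
  })
}

#' @rdname encodingForward
#' @param ylist list of per-bin M_b x C complex matrices.
#' @export
encodingAdjoint <- function(ylist, op) {
  N <- op$N
  out <- array(0i, dim = c(N, N, N, op$nBins))
  for (p in seq_len(op$nBins)) {
    k <- op$coords[[p]]
    acc <- array(0i, dim = c(N, N, N))
    for (cc in seq_len(op$nCoils)) {
      b <- if (op$mode == "nufft") nufftAdjoint(ylist[[p]][, cc], op$plan, k)
           else nudftAdjoint(ylist[[p]][, cc], N, k)
      acc <- acc + Conj(op$coilMaps[, , , cc]) * b
    }
    out[, , , p] <- acc
  }
  out
}
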