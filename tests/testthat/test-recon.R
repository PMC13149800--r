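# Compressed-sensing reconstruction behaviour on small problems.

reconSetup <- function(N = 16L, nSeg = 90L, perSeg = 5L, noiseSd = 0,
                       seed = 3) {
  spec <- phantomSpec(N, voxelMm = 0.6,
                      vesselCentersMm = rbind(LC = c(4.5, 4.5)),
                      wallThicknessMm = 0.6)
  traj <- radialSamples(phyllotaxisDirections(nSeg, perSeg), N)
  wf <- makeDiameterWaveform(3.0, 3.6, 960, 0.45, 8L)
  raw <- simulateAcquisition(wf, spec, traj, makeCoilMaps(N, 2L),
                             noiseSd = noiseSd, physio = constantPhysio(5, 960),
                             seed = seed, mode = "dft")
  list(spec = spec, wf = wf, raw = raw)
}

test_that("lambda = 0 with dense spokes reaches the noiseless truth (least-squares limit)", {
  # A sharp cylinder keeps a few percent of its energy in the Cartesian
  # k-space corners that radial spokes never visit, so exact recovery is
  # tested on an effectively band-limited object (Gaussian blobs, spectrum
  # ~ exp(-2 pi^2 sigma^2 k^2), negligible beyond |k| = 0.5).
  N <- 16L
  g <- seq_len(N) - 1
  blob <- function(cx, cy, cz, s, a) {
    d2 <- outer(outer((g - cx)^2, (g - cy)^2, "+"), (g - cz)^2, "+")
    a * exp(-d2 / (2 * s^2))
  }
  truth <- blob(7, 8, 7.5, 2.0, 10) + blob(10.5, 6, 8, 1.8, 6)
  # dense radial sampling (above the ~ pi/2 N^2 spoke count), uniform coil
  traj <- radialSamples(phyllotaxisDirections(90L, 5L), N)
  k <- trajectoryCoords(traj)
  coils <- array(1 + 0i, dim = c(N, N, N, 1))
  y <- nudftForward(truth + 0i, N, k)
  binned <- list(data = list(matrix(y, ncol = 1)), coords = list(k))
  op <- encodingOperator(binned$coords, coils)
  img <- admmReconstruct(binned, op,
                         reconConfig(lambda = 0, innerIters = 150L,
                                     innerTol = 1e-12))
  rel <- sqrt(sum((abs(img@data[, , , 1]) - truth)^2)) / sqrt(sum(truth^2))
  expect_lt(rel, 0.01)
})

test_that("the objective is non-increasing after the second ADMM iteration", {
  s <- reconSetup(noiseSd = 30, seed = 9)
  ba <- assignBins(s$raw@timestamps, s$raw@physio, 240)
  binned <- binKSpace(s$raw, ba)
  op <- encodingOperator(binned$coords, s$raw@coilMaps)
  img <- admmReconstruct(binned, op,
                         reconConfig(lambda = 0.01, nIters = 8L,
                                     innerIters = 6L))
  obj <- img@objective
  expect_length(obj, 8L)
  expect_true(all(diff(obj[-1]) <= 1e-9 * obj[1]))
})

test_that("a very large lambda flattens the cardiac phases", {
  s <- reconSetup(noiseSd = 0)
  ba <- assignBins(s$raw@timestamps, s$raw@physio, 240)
  binned <- binKSpace(s$raw, ba)
  op <- encodingOperator(binned$coords, s$raw@coilMaps)
  img <- admmReconstruct(binned, op,
                         reconConfig(lambda = 1e6, nIters = 12L,
                                     innerIters = 10L,
                                     logObjective = FALSE))
  a <- img@data
  m <- mean(abs(a))
  P <- dim(a)[4]
  for (p in 2:P)
    expect_lt(max(abs(a[, , , p] - a[, , , 1])) / m, 0.01)
})

test_that("reconstruction errors are informative", {
  s <- reconSetup()
  ba <- assignBins(s$raw@timestamps, s$raw@physio, 240)
  binned <- binKSpace(s$raw, ba)
  op <- encodingOperator(binned$coords, s$raw@coilMaps)
  binned$data[[1]][3, 1] <- NaN + 0i
  expect_error(admmReconstruct(binned, op, reconConfig()), "NaN")
})

test_that("aSNR is the lumen mean over background SD, scale invariant", {
  withr::with_seed(13, {
    img <- array(rnorm(20^3, 0, 1), dim = c(20, 20, 20))
  })
  lumen <- array(FALSE, dim = c(20, 20, 20)); lumen[8:12, 8:12, ] <- TRUE
  bg <- array(FALSE, dim = c(20, 20, 20)); bg[1:4, 1:4, ] <- TRUE
  img[lumen] <- 10
  a <- computeAsnr(img, lumen, bg)
  expect_equal(a, mean(abs(img[lumen])) / stats::sd(abs(img[bg])),
               tolerance = 1e-12)
  expect_equal(computeAsnr(5 * img, lumen, bg), a, tolerance = 1e-12)
  # Monte-Carlo magnitude: lumen 10 over unit-SD noise background.
  # |N(0,1)| has SD ~ sqrt(1 - 2/pi); aSNR ~ 10 / that
  withr::with_seed(14, {
    big <- array(rnorm(40^3), dim = c(40, 40, 40))
  })
  lum2 <- array(FALSE, dim = c(40, 40, 40)); lum2[18:22, 18:22, ] <- TRUE
  bg2 <- array(FALSE, dim = c(40, 40, 40)); bg2[1:10, 1:10, 1:10] <- TRUE
  big[lum2] <- 10
  expect_equal(computeAsnr(big, lum2, bg2), 10 / sqrt(1 - 2 / pi),
               tolerance = 0.05 * 10 / sqrt(1 - 2 / pi))
  expect_error(computeAsnr(img, lumen & FALSE, bg), "non-empty")
  expect_error(computeAsnr(img, lumen, lumen), "disjoint")
})
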