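# M-mode analysis: interpolation/subtraction/detrend, AMPD, beat averaging.

symWaveform <- function() {
  # sampled-value-symmetric configuration: peak centred between the two
  # middle grid samples so the discrete LS slope of the periodic part is 0
  makeDiameterWaveform(5.5, 6.4, 960, 0.45, 240L, peakPhase = 119.5 / 240)
}

test_that("boundary subtraction and mean-preserving detrend behave as specified", {
  n <- 500
  t <- (0:(n - 1)) / 250
  tr <- new("MModeTrace", timeS = t, upperMm = rep(2, n),
            lowerMm = rep(8, n), resolutionMm = 0.1, imtMm = 0,
            fps = 250, groundTruth = list())
  dt <- diameterFromBoundaries(tr)
  expect_equal(dt@diameterMm, rep(6, n), tolerance = 1e-12)
  # adding a pure linear trend to the diameter is removed exactly,
  # mean preserved
  base <- 6 + 0.5 * sin(2 * pi * t / 2)
  tr2 <- new("MModeTrace", timeS = t, upperMm = rep(0, n),
             lowerMm = base + 0.31 * t, resolutionMm = 0.1, imtMm = 0,
             fps = 250, groundTruth = list())
  tr3 <- new("MModeTrace", timeS = t, upperMm = rep(0, n),
             lowerMm = base, resolutionMm = 0.1, imtMm = 0,
             fps = 250, groundTruth = list())
  d2 <- diameterFromBoundaries(tr2)
  d3 <- diameterFromBoundaries(tr3)
  # construct-and-subtract oracle: mean-preserving (slope-only) detrending
  # recovers the drift-free waveform up to the constant drift mean b*mean(t)
  expect_lt(max(abs(d2@diameterMm -
                      (d3@diameterMm + 0.31 * mean(t)))), 1e-9)
  expect_equal(mean(d2@diameterMm), mean(base + 0.31 * t),
               tolerance = 1e-9)
  # idempotence: the output's own LS slope is zero
  tc <- t - mean(t)
  expect_lt(abs(sum(tc * d2@diameterMm) / sum(tc^2)), 1e-9)
  # boundary crossing is an error
  trBad <- new("MModeTrace", timeS = t, upperMm = rep(2, n),
               lowerMm = rep(8, n), resolutionMm = 0.1, imtMm = 0,
               fps = 250, groundTruth = list())
  trBad@lowerMm[5] <- 1.9
  expect_error(diameterFromBoundaries(trBad), "at/above")
})

test_that("AMPD finds sine extrema exactly and respects negation symmetry", {
  t <- (0:1199) / 240
  x <- sin(2 * pi * t)
  found <- ampdPeaks(x)
  analyticPeaks <- 0.25 + 0:4
  analyticTroughs <- 0.75 + 0:4
  expect_length(found$peaks, 5)
  expect_length(found$troughs, 5)
  expect_true(all(abs(t[found$peaks] - analyticPeaks) <= 1 / 240 + 1e-12))
  expect_true(all(abs(t[found$troughs] - analyticTroughs) <= 1 / 240 + 1e-12))
  neg <- ampdPeaks(-x)
  expect_identical(neg$peaks, found$troughs)
  expect_identical(neg$troughs, found$peaks)
  expect_warning(ampdPeaks(seq_len(100) * 0.1), "monotone")
})

test_that("AMPD agrees with an independent brute-force oracle on seeded noisy sines", {
  t <- (0:1199) / 240
  for (seed in c(11L, 42L)) {
    x <- sin(2 * pi * t) +
      withr::with_seed(seed, rnorm(1200, 0, 0.02))
    mine <- ampdPeaks(x)
    oracle <- ampdOracle(x)
    expect_length(mine$peaks, 5)
    expect_length(mine$troughs, 5)
    # the unpadded oracle cannot see beats within its global scale of the
    # record edges; every peak it does find must be matched within 2 samples
    expect_gte(length(oracle), 3)
    expect_true(all(vapply(oracle, function(p)
      min(abs(mine$peaks - p)) <= 2, logical(1))))
  }
})

test_that("beat averaging applies the 2 x IMT correction", {
  # synthetic trace with constant peak/trough levels
  n <- 1200
  x <- rep(c(rep(7, 120), rep(8, 120)), 5)
  dt <- new("DiameterTrace", timeS = (0:(n - 1)) / 250, diameterMm = x,
            slopeRemoved = 0)
  peaks <- 120 + 60 + 240 * (0:4)
  troughs <- 60 + 240 * (0:4)
  be <- beatsToDiameters(dt, peaks, troughs, imtMm = 0.5)
  expect_equal(be@dS, 7.0)  # 8 - 2*0.5
  expect_equal(be@dD, 6.0)  # 7 - 2*0.5
  be0 <- beatsToDiameters(dt, peaks, troughs, imtMm = 0)
  expect_equal(c(be0@dS, be0@dD), c(8, 7))
  expect_error(beatsToDiameters(dt, peaks[1:4], troughs, 0), "at least 5")
  expect_error(beatsToDiameters(dt, peaks, troughs[1:3], 0), "at least 5")
})

test_that("noiseless five-beat traces recover the lumen truth exactly for any drift", {
  wf <- symWaveform()
  for (drift in c(-0.5, 0, 0.25, 0.8)) {
    tr <- simulateMmode(wf, 5, driftMmPerS = drift, noiseSdMm = 0,
                        imtMm = 0.6, seed = 1)
    be <- measureMmode(tr)
    expect_equal(be@dS, 6.4, tolerance = 1e-6)
    expect_equal(be@dD, 5.5, tolerance = 1e-6)
  }
})

test_that("M-mode RDC is invariant to drift and transducer offset", {
  wf <- symWaveform()
  rdcOf <- function(be) (be@dS - be@dD) / be@dD * 100
  tr1 <- simulateMmode(wf, 5, 0, 0, imtMm = 0.6, seed = 1, centreMm = 15)
  tr2 <- simulateMmode(wf, 5, 0.6, 0, imtMm = 0.6, seed = 1, centreMm = 40)
  expect_equal(rdcOf(measureMmode(tr1)), rdcOf(measureMmode(tr2)),
               tolerance = 1e-9)
  expect_equal(rdcOf(measureMmode(tr1)), (6.4 - 5.5) / 5.5 * 100,
               tolerance = 1e-6)
})
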