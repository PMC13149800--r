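test_that("diameter waveform pins its extremes exactly", {
  wf <- makeDiameterWaveform(5.5, 6.4, 960, 0.35, 12)
  expect_identical(min(diameters(wf)), 5.5)
  expect_identical(max(diameters(wf)), 6.4)
  expect_equal(dD(wf), 5.5)
  expect_equal(dS(wf), 6.4)
  # constant waveform when dD == dS
  wfc <- makeDiameterWaveform(6, 6, 960, 0.35, 12)
  expect_true(all(diameters(wfc) == 6))
  expect_error(makeDiameterWaveform(6.4, 5.5, 960, 0.35, 12), "dS must be")
})

test_that("waveform RDC matches direct arithmetic", {
  wf <- makeDiameterWaveform(5.5, 6.4, 960, 0.35, 12)
  expect_equal(waveformRdc(wf), (6.4 - 5.5) / 5.5 * 100, tolerance = 1e-12)
})

test_that("waveform is periodic with a flat diastolic baseline", {
  wf <- makeDiameterWaveform(5.5, 6.4, 960, 0.45, 48, peakPhase = 0.4)
  d <- diameters(wf)
  expect_equal(d[1], d[length(d)], tolerance = 1e-9)  # both in flat diastole
  expect_gt(sum(d == 5.5), 10)  # flat baseline occupies the off-bump cycle
})

test_that("rendered phantom has exact interior intensities and partial-volume edges", {
  spec <- phantomSpec(48L, voxelMm = 0.6)
  img <- renderPhantom(spec, 5.5)
  ctr <- spec$vesselCentersMm[1, ]
  ci <- round(ctr / 0.6) + 1
  expect_equal(img[ci[1], ci[2], 10], 10)      # deep lumen voxel
  expect_equal(img[3, 3, 5], 1)                # far background voxel
  expect_identical(img[, , 1], img[, , 48])    # z-invariant cylinders
  # edge-voxel occupancy is monotone in diameter
  vals <- sapply(c(5.2, 5.5, 5.8, 6.1), function(D)
    renderPhantom(spec, D)[ci[1] + 5, ci[2], 1])
  expect_true(all(diff(vals) >= 0))
  expect_error(renderPhantom(spec, 40), "exits the grid")
})

test_that("FWHM contour of a rendered cylinder recovers its diameter", {
  spec <- phantomSpec(48L, voxelMm = 0.6)
  img <- renderPhantom(spec, 5.5)
  ct <- extractContour(img[, , 24], spec$vesselCentersMm[1, ], 0.6,
                       maxRadiusMm = 5.5)
  d <- effectiveDiameter(polygonArea(ct$vertices))
  expect_lt(abs(d - 5.5), 0.3)
})

test_that("simulated physio is reproducible and has the expected rate", {
  ph <- simulatePhysio(10000, 1000, 0, 1)
  expect_equal(triggerTimes(ph), seq(0, 9000, by = 1000))
  a <- simulatePhysio(60000, 960, 40, 7)
  b <- simulatePhysio(60000, 960, 40, 7)
  expect_identical(triggerTimes(a), triggerTimes(b))
  long <- simulatePhysio(600000, 960, 40, 7)
  expect_lt(abs(mean(diff(triggerTimes(long))) - 960) / 960, 0.02)
  expect_error(simulatePhysio(10000, 400, 80, 1), "200 ms")
})

test_that("pressure pairs average pre/post readings", {
  p <- simulatePressures(113, 63, 0, 1)
  expect_equal(c(p@pS, p@pD), c(113, 63))
  expect_error(simulatePressures(80, 90, 0, 1), "exceed")
  # averaging two readings shrinks the SD by sqrt(2) (Monte Carlo)
  reps <- vapply(1:2000, function(s)
    simulatePressures(113, 63, 4, s)@pS, numeric(1))
  expect_equal(stats::sd(reps), 4 / sqrt(2), tolerance = 0.1)
})

test_that("M-mode synthesis has the protocol geometry", {
  wf <- makeDiameterWaveform(5.5, 6.4, 960, 0.45, 240)
  tr <- simulateMmode(wf, 5, 0, 0, imtMm = 0)
  expect_equal(length(tr@timeS), 1200)          # 4.8 s x 250 fps
  expect_equal(unique(round(diff(tr@timeS), 10)), 1 / 250)
  # lower - upper reproduces D(t) exactly without drift/noise/IMT
  frac <- ((tr@timeS * 1000) %% 960) / 960
  expect_equal(tr@lowerMm - tr@upperMm, waveformAt(wf, frac),
               tolerance = 1e-9)
  # a shared drift is common-mode: the difference is unchanged
  trd <- simulateMmode(wf, 5, 0.4, 0, imtMm = 0)
  expect_equal(trd@lowerMm - trd@upperMm, tr@lowerMm - tr@upperMm,
               tolerance = 1e-9)
  # IMT enters both boundaries
  tri <- simulateMmode(wf, 5, 0, 0, imtMm = 0.6)
  expect_equal(tri@lowerMm - tri@upperMm,
               (tr@lowerMm - tr@upperMm) + 1.2, tolerance = 1e-9)
})
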