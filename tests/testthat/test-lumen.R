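test_that("FWHM crossings follow linear interpolation at half the range", {
  # plateau profile: half level 5, crossings at 1.5 and 4.5 (hand oracle)
  cr <- fwhmCrossings(c(0, 0, 10, 10, 10, 0, 0), 0:6)
  expect_equal(cr, c(1.5, 4.5), tolerance = 1e-12)
  expect_equal(diff(cr), 3.0, tolerance = 1e-12)
  # symmetric triangular profile: width is half the base (similar triangles)
  prof <- c(0, 2.5, 5, 7.5, 10, 7.5, 5, 2.5, 0)
  cr2 <- fwhmCrossings(prof, 0:8)
  expect_equal(diff(cr2), 4, tolerance = 1e-12)
  expect_equal(mean(cr2), 4, tolerance = 1e-12)
  expect_error(fwhmCrossings(rep(5, 7), 0:6), "flat profile")
  expect_error(fwhmCrossings(c(10, 9, 5, 2, 0), 0:4), "left side")
})

test_that("contour vertices of an analytic disk lie on the circle", {
  img <- diskSlice(24L, 0.6, c(7.2, 7.2), 3.0)
  ct <- extractContour(img, c(7.2, 7.2), 0.6, nRays = 64L, maxRadiusMm = 6)
  expect_equal(nrow(ct$vertices), 64L)
  radii <- sqrt(rowSums(sweep(ct$vertices, 2, ct$center)^2))
  expect_true(all(abs(radii - 3.0) < 0.3))
  # off-centre seed converges to the same contour (centroid fixed point)
  ct2 <- extractContour(img, c(6.3, 7.9), 0.6, nRays = 64L, maxRadiusMm = 6)
  expect_equal(ct2$center, ct$center, tolerance = 0.05)
  expect_equal(effectiveDiameter(polygonArea(ct2$vertices)),
               effectiveDiameter(polygonArea(ct$vertices)),
               tolerance = 0.05)
})

test_that("polygon area matches closed forms", {
  expect_equal(polygonArea(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(polygonArea(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  ang <- 2 * pi * (0:63) / 64
  hex <- cbind(3 * cos(ang), 3 * sin(ang))
  expect_equal(polygonArea(hex), 0.5 * 64 * 9 * sin(2 * pi / 64),
               tolerance = 1e-9)
  expect_error(polygonArea(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("effective diameter inverts the circle area formula", {
  expect_equal(effectiveDiameter(pi), 2)
  expect_equal(effectiveDiameter(28.2477), 5.9975, tolerance = 1e-4)
  r <- c(0.5, 1.7, 3.2)
  expect_equal(effectiveDiameter(pi * r^2), 2 * r, tolerance = 1e-12)
  expect_error(effectiveDiameter(0), "positive")
})

test_that("diameter series recovers a rendered pulsating movie and slice averaging", {
  spec <- phantomSpec(32L, voxelMm = 0.6,
                      vesselCentersMm = rbind(LC = c(9.3, 9.3)))
  wf <- makeDiameterWaveform(5.5, 6.4, 960, 0.45, 6L)
  arr <- array(0, dim = c(32, 32, 32, 6))
  for (p in 1:6) arr[, , , p] <- renderPhantom(spec, wf@diameters[p])
  img <- new("Image4D", data = arr, voxelMm = 0.6, binWidthMs = 160)
  ds <- diameterSeries(img, c(9.3, 9.3), slices = c(10L, 16L, 22L),
                       vessel = "LC", maxRadiusMm = 5.6)
  expect_lt(abs(dS(ds) - 6.4), 0.3)
  expect_lt(abs(dD(ds) - 5.5), 0.3)
  # identical slices equal the single-slice result
  ds1 <- diameterSeries(img, c(9.3, 9.3), slices = 16L, vessel = "LC",
                        maxRadiusMm = 5.6)
  expect_equal(diameters(ds), diameters(ds1), tolerance = 1e-9)
  # static movie: dS == dD
  arrS <- array(rep(renderPhantom(spec, 5.8), 3), dim = c(32, 32, 32, 3))
  imgS <- new("Image4D", data = arrS, voxelMm = 0.6, binWidthMs = 320)
  dsS <- diameterSeries(imgS, c(9.3, 9.3), slices = 16L, maxRadiusMm = 5.6)
  expect_equal(dS(dsS), dD(dsS), tolerance = 1e-12)
})

test_that("contour area is invariant to intensity scaling and whole-voxel shifts", {
  spec <- phantomSpec(32L, voxelMm = 0.6,
                      vesselCentersMm = rbind(LC = c(9.3, 9.3)))
  img <- renderPhantom(spec, 5.5)[, , 16]
  a1 <- polygonArea(extractContour(img, c(9.3, 9.3), 0.6,
                                   maxRadiusMm = 5.6)$vertices)
  a2 <- polygonArea(extractContour(7.3 * img, c(9.3, 9.3), 0.6,
                                   maxRadiusMm = 5.6)$vertices)
  expect_equal(a1, a2, tolerance = 1e-9)
  spec2 <- phantomSpec(32L, voxelMm = 0.6,
                       vesselCentersMm = rbind(LC = c(9.3 + 1.2, 9.3)))
  img2 <- renderPhantom(spec2, 5.5)[, , 16]
  a3 <- polygonArea(extractContour(img2, c(10.5, 9.3), 0.6,
                                   maxRadiusMm = 5.6)$vertices)
  expect_equal(a3, a1, tolerance = 1e-6)
})

test_that("estimated diameter scales with the phantom diameter", {
  spec <- phantomSpec(32L, voxelMm = 0.6,
                      vesselCentersMm = rbind(LC = c(9.3, 9.3)))
  dEst <- vapply(c(4.4, 5.0, 5.6, 6.2), function(D) {
    img <- renderPhantom(spec, D)[, , 16]
    effectiveDiameter(polygonArea(
      extractContour(img, c(9.3, 9.3), 0.6, maxRadiusMm = 5.8)$vertices))
  }, numeric(1))
  expect_true(all(diff(dEst) > 0))
  expect_true(all(abs(dEst - c(4.4, 5.0, 5.6, 6.2)) < 0.3))
})
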