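# Linear-operator correctness: NUFFT pair, encoding operator, temporal
# difference, soft threshold.

randomComplexArray <- function(dims, seed) {
  withr::with_seed(seed, {
    array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))),
          dim = dims)
  })
}

test_that("gridding NUFFT matches the exact DFT and is exactly adjoint", {
  N <- 16L
  x <- randomComplexArray(c(N, N, N), 1)
  k <- withr::with_seed(2, matrix(runif(3 * 300, -0.5, 0.5), ncol = 3))
  plan <- nufftPlan(N, 1.25, 6L)
  y <- nufftForward(x, plan, k)
  yExact <- nudftForward(x, N, k)
  expect_lt(max(abs(y - yExact)) / max(abs(yExact)), 5e-3)
  yr <- randomComplexArray(300, 3)
  lhs <- sum(Conj(yr) * y)
  rhs <- sum(Conj(nufftAdjoint(yr, plan, k)) * x)
  expect_lt(abs(lhs - rhs) / (sqrt(sum(abs(x)^2)) * sqrt(sum(abs(yr)^2))),
            1e-12)
})

test_that("zero image gives zero samples; impulse gives flat magnitudes", {
  N <- 16L
  k <- withr::with_seed(4, matrix(runif(3 * 50, -0.5, 0.5), ncol = 3))
  z <- array(0i, dim = c(N, N, N))
  expect_true(all(nudftForward(z, N, k) == 0))
  imp <- z; imp[5, 9, 12] <- 3 + 0i
  mag <- abs(nudftForward(imp, N, k))
  expect_equal(max(mag) - min(mag), 0, tolerance = 1e-10)
  expect_equal(mag[1], 3, tolerance = 1e-10)
})

test_that("multi-coil encoding operator passes the dot-product test on a 24^3 x 4 problem", {
  N <- 24L
  traj <- radialSamples(phyllotaxisDirections(8L, 12L), 24L)
  coords <- lapply(0:3, function(p)
    trajectoryCoords(traj, p * 24 + 1:24))
  coils <- makeCoilMaps(N, 4L)
  op <- encodingOperator(coords, coils)
  x <- randomComplexArray(c(N, N, N, 4L), 5)
  y <- lapply(1:4, function(p) randomComplexArray(c(24L * 24L, 4L), 5 + p))
  fx <- encodingForward(x, op)
  aty <- encodingAdjoint(y, op)
  lhs <- sum(vapply(1:4, function(p) sum(Conj(y[[p]]) * fx[[p]]),
                    complex(1)))
  rhs <- sum(Conj(aty) * x)
  nx <- sqrt(sum(abs(x)^2))
  ny <- sqrt(sum(vapply(y, function(m) sum(abs(m)^2), numeric(1))))
  expect_lt(abs(lhs - rhs) / (nx * ny), 1e-6)
  expect_error(encodingOperator(list(coords[[1]], coords[[2]][0, ]), coils),
               "empty cardiac bin")
})

test_that("temporal difference is periodic, telescoping and exactly adjoint", {
  x <- randomComplexArray(c(3, 3, 3, 4), 7)
  d <- temporalDiff(x)
  # periodic forward difference, checked slot-wise
  expect_equal(d[, , , 4], x[, , , 1] - x[, , , 4])
  expect_equal(d[, , , 2], x[, , , 3] - x[, , , 2])
  # telescoping: the phase sum vanishes voxel-wise
  expect_lt(max(abs(apply(d, 1:3, sum))), 1e-12)
  # phase-constant movie maps to zero
  xc <- array(rep(x[, , , 1], 4), dim = dim(x))
  expect_true(all(temporalDiff(xc) == 0))
  # adjoint against the explicit matrix transpose on a 4-phase scalar series
  D <- rbind(c(-1, 1, 0, 0), c(0, -1, 1, 0), c(0, 0, -1, 1), c(1, 0, 0, -1))
  v <- withr::with_seed(8, complex(real = rnorm(4), imaginary = rnorm(4)))
  w <- array(v, dim = c(1, 1, 1, 4))
  expect_equal(as.vector(temporalDiff(w)), as.vector(D %*% v),
               tolerance = 1e-15)
  expect_equal(as.vector(temporalDiffAdjoint(w)),
               as.vector(t(D) %*% v), tolerance = 1e-15)
  # dot-product adjointness on the full array
  z <- randomComplexArray(dim(x), 9)
  lhs <- sum(Conj(z) * temporalDiff(x))
  rhs <- sum(Conj(temporalDiffAdjoint(z)) * x)
  expect_lt(abs(lhs - rhs) / (sqrt(sum(abs(x)^2)) * sqrt(sum(abs(z)^2))),
            1e-12)
  expect_error(temporalDiff(array(0i, dim = c(2, 2, 2, 1))), "2 phases")
})

test_that("soft threshold obeys the closed-form shrinkage with phase preserved", {
  z <- withr::with_seed(10, complex(real = rnorm(500), imaginary = rnorm(500)))
  for (t in c(0, 0.3, 1.5)) {
    s <- softThreshold(z, t)
    expect_equal(abs(s), pmax(abs(z) - t, 0), tolerance = 1e-12)
    keep <- abs(z) > t
    expect_equal(Arg(s[keep]), Arg(z[keep]), tolerance = 1e-12)
  }
  expect_identical(softThreshold(0 + 0i, 1), 0 + 0i)
})
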