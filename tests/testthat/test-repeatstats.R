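test_that("ICC(2,1) matches definitional cases", {
  m <- cbind(c(4, 5, 6, 7), c(4, 5, 6, 7))
  r <- icc21(m)
  expect_equal(r$icc, 1, tolerance = 1e-12)
  # constant shift with large between-subject variance: absolute agreement
  # penalizes the shift, ICC < 1
  m2 <- cbind(c(4, 5, 6, 7), c(4, 5, 6, 7) + 1)
  expect_lt(icc21(m2)$icc, 1)
  expect_gt(icc21(m2)$icc, 0)
  expect_error(icc21(matrix(3, 4, 2)), "zero total variance")
  expect_error(icc21(m[1:2, ]), "at least 3")
})

test_that("ICC(2,1) matches the brute-force two-way ANOVA oracle on 100 seeded matrices", {
  for (seed in 1:100) {
    m <- withr::with_seed(seed, {
      subj <- rnorm(14, 6, 0.5)
      cbind(subj + rnorm(14, 0, 0.2), subj + rnorm(14, 0.05, 0.2))
    })
    expect_equal(icc21(m)$icc, iccOracle(m), tolerance = 1e-10)
  }
})

test_that("ICC is invariant to constant shifts and subject relabeling", {
  m <- withr::with_seed(5, {
    subj <- rnorm(12, 6, 0.5)
    cbind(subj + rnorm(12, 0, 0.15), subj + rnorm(12, 0, 0.15))
  })
  base <- icc21(m)$icc
  expect_equal(icc21(m + 3.7)$icc, base, tolerance = 1e-12)
  perm <- withr::with_seed(6, sample(12))
  expect_equal(icc21(m[perm, ])$icc, base, tolerance = 1e-12)
  ci <- icc21(m)$ci
  expect_lte(ci[1], base)
  expect_gte(ci[2], base)
})

test_that("test-retest CV is the RMS within-subject CV", {
  expect_equal(cvTestRetest(cbind(c(10, 12), c(10, 12))), 0)
  # single subject (10, 11): sd 0.7071, mean 10.5 -> 6.734 %
  expect_equal(cvTestRetest(matrix(c(10, 11), 1)), 6.734, tolerance = 1e-3)
  m <- withr::with_seed(7, matrix(runif(20, 5, 7), 10))
  expect_equal(cvTestRetest(3 * m), cvTestRetest(m), tolerance = 1e-12)
  expect_error(cvTestRetest(matrix(c(-1, 1), 1)), "positive")
})

test_that("Bland-Altman agrees with closed forms", {
  a <- c(1, 2, 3, 4)
  expect_equal(blandAltman(a, a)$bias, 0)
  expect_equal(blandAltman(a, a)$loa, c(0, 0))
  ba <- blandAltman(a + 1, a)
  expect_equal(ba$bias, 1)
  expect_equal(ba$loa, c(1, 1))
  # seeded Gaussian differences: bias ~ 0.5, LoA width ~ 3.92 sd
  d <- withr::with_seed(8, rnorm(10000, 0.5, 1))
  ba2 <- blandAltman(d, rep(0, 10000))
  expect_equal(ba2$bias, 0.5, tolerance = 0.05)
  expect_equal(diff(ba2$loa), 2 * 1.96, tolerance = 0.1)
  expect_error(blandAltman(1:3, 1:4), "equal length")
})

test_that("regression matches the normal-equation oracle", {
  a <- c(1, 2, 3, 4, 5)
  r1 <- regressionPearson(a, a)
  expect_equal(c(r1$slope, r1$intercept, r1$r), c(1, 0, 1),
               tolerance = 1e-12)
  r2 <- regressionPearson(a, -2 * a + 3)
  expect_equal(c(r2$slope, r2$intercept, r2$r), c(-2, 3, -1),
               tolerance = 1e-12)
  withr::with_seed(9, {
    x <- rnorm(50)
    y <- 1.3 * x - 0.4 + rnorm(50, 0, 0.3)
  })
  fit <- regressionPearson(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_error(regressionPearson(rep(1, 5), 1:5), "zero variance")
})

test_that("the paired comparison gates on Shapiro-Wilk normality", {
  withr::with_seed(10, {
    a <- rnorm(20, 5, 1)
    shift <- rnorm(20, 3, 0.2)
  })
  res <- pairedCompare(a, a - shift)
  expect_equal(res$test, "paired t-test")
  expect_lt(res$p, 0.001)
  # exactly constant differences degrade gracefully to the signed-rank test
  expect_warning(resC <- pairedCompare(a, a - 3), "constant")
  expect_equal(resC$test, "wilcoxon signed-rank")
  expect_lt(resC$p, 0.01)
  # heavy-tailed differences select Wilcoxon
  withr::with_seed(11, {
    b <- rnorm(30)
    d <- rcauchy(30)
  })
  res2 <- pairedCompare(b + d, b)
  expect_equal(res2$test, "wilcoxon signed-rank")
  expect_lte(res2$shapiroP, 0.05)
  expect_warning(res3 <- pairedCompare(a, a), "zero")
  expect_equal(res3$p, 1)
})
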