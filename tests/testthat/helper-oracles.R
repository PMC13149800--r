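# Shared fixtures and independent oracles used across the suite.

constantPhysio <- function(nBeats, rrMs = 960) {
  new("PhysioRecord", triggerTimes = seq(0, by = rrMs,
                                         length.out = nBeats + 1L))
}

# Brute-force non-uniform DFT oracle (pure R, vectorized over voxels):
# y_m = sum_n x(n) exp(-2 pi i k_m . (n - N/2))
bruteDft <- function(x, k) {
  N <- dim(x)[1]
  nidx <- as.matrix(expand.grid(0:(N - 1), 0:(N - 1), 0:(N - 1))) - N / 2
  xv <- as.vector(x)
  vapply(seq_len(nrow(k)), function(m) {
    s <- sum(xv * exp(-2i * pi * (nidx %*% k[m, ])))
    s
  }, complex(1))
}

# Minimal independent AMPD re-implementation (direct double loop over the
# definition; no padding, strict/non-strict tie-break as documented).
ampdOracle <- function(x) {
  n <- length(x)
  L <- as.integer(ceiling(n / 2) - 1)
  cnt <- integer(L)
  isMax <- matrix(FALSE, L, n)
  for (k in seq_len(L)) {
    for (i in seq_len(n)) {
      lo <- i - k; hi <- i + k
      if (lo < 1 || hi > n) next
      if (x[i] > x[lo] && x[i] >= x[hi]) {
        isMax[k, i] <- TRUE
        cnt[k] <- cnt[k] + 1L
      }
    }
  }
  lambda <- which.max(cnt)
  pk <- integer(0)
  for (i in seq_len(n))
    if (all(isMax[seq_len(lambda), i])) pk <- c(pk, i)
  setdiff(pk, c(1L, n))
}

# ICC(2,1) oracle: mean squares from a brute-force two-way ANOVA via aov(),
# plugged into the published formula.
iccOracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   sess = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Analytic partial-volume disk image (2D) for contour tests.
diskSlice <- function(N, voxelMm, centerMm, radiusMm, hi = 10, lo = 1,
                      ss = 8L) {
  img <- matrix(lo, N, N)
  sub <- ((seq_len(ss) - 0.5) / ss - 0.5) * voxelMm
  for (i in seq_len(N)) for (j in seq_len(N)) {
    px <- (i - 1) * voxelMm + sub
    py <- (j - 1) * voxelMm + sub
    occ <- mean(outer((px - centerMm[1])^2, (py - centerMm[2])^2, "+") <=
                  radiusMm^2)
    if (occ > 0) img[i, j] <- lo + occ * (hi - lo)
  }
  img
}
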