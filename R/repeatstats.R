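#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with the mean squares computed directly from the row/column/grand means
#' of the n x k measurement matrix. The 95\% confidence interval uses the
#' exact F-distribution bounds of the same two-way model
#' (McGraw-Wong A,1 form with a Satterthwaite denominator df).
#'
#' @param m numeric matrix n subjects x k sessions (typically k = 2,
#'   scan-rescan), no missing cells, n >= 3.
#' @param alpha CI level (default 0.05 for a 95\% CI).
#' @return list(icc, ci = c(low, high)).
#' @export
icc21 <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 subjects")
  if (anyNA(m)) stop("missing cells are not supported")
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  sst <- sum((m - grand)^2)
  if (sst == 0) stop("zero total variance: ICC undefined")
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # F-based CI (two-way random, absolute agreement, single measures)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci = c(lower, upper))
}

#' Test-retest coefficient of variation
#'
#' Root-mean-square over subjects of the within-subject coefficient of
#' variation (SD of the repeated measurements over the subject mean), in
#' percent -- the standard test-retest CV convention.
#'
#' @param m numeric matrix n subjects x k sessions, all subject means > 0.
#' @return CV in percent.
#' @examples
#' cvTestRetest(matrix(c(10, 11), nrow = 1))  # 6.734
#' @export
cvTestRetest <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  if (any(mu <= 0)) stop("subject means must be positive")
  s <- apply(m, 1, stats::sd)
  sqrt(mean((s / mu)^2)) * 100
}

#' Bland-Altman agreement analysis
#'
#' Differences d = a - b: bias = mean(d), limits of agreement =
#' bias +/- 1.96 x SD(d) (sample SD).
#'
#' @param a,b paired measurements (equal length >= 2).
#' @return list(bias, loa = c(low, high), sd).
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  list(bias = mean(d), loa = mean(d) + c(-1.96, 1.96) * s, sd = s)
}

#' Ordinary least-squares regression with Pearson correlation
#'
#' Fits b ~ a by OLS and reports the slope, intercept and Pearson r.
#'
#' @param a,b paired measurements (n >= 3, var(a) > 0).
#' @return list(slope, intercept, r).
#' @export
regressionPearson <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::var(a) == 0) stop("zero variance in the predictor")
  fit <- stats::lm(b ~ a)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(a, b))
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk on the paired differences decides the test: a two-sided
#' paired Student t-test when the differences look normal (p > alpha), a
#' two-sided Wilcoxon signed-rank test otherwise. Degenerate all-zero
#' differences return p = 1 with a warning.
#'
#' @param a,b paired measurements (equal length >= 4).
#' @param alpha normality gate level (default 0.05).
#' @return list(test, p, shapiroP).
#' @export
pairedCompare <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 4) stop("need at least 4 pairs")
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1")
    return(list(test = "paired t-test", p = 1, shapiroP = NA_real_))
  }
  if (stats::sd(d) == 0) {
    # constant non-zero differences: normality cannot be assessed and the
    # t statistic is undefined; fall back to the signed-rank test
    warning("constant paired differences; using the signed-rank test")
    return(list(
      test = "wilcoxon signed-rank",
      p = suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value),
      shapiroP = NA_real_))
  }
  sw <- stats::shapiro.test(d)$p.value
  if (sw > alpha) {
    list(test = "paired t-test",
         p = stats::t.test(a, b, paired = TRUE)$p.value, shapiroP = sw)
  } else {
    list(test = "wilcoxon signed-rank",
         p = suppressWarnings(
           stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value),
         shapiroP = sw)
  }
}
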