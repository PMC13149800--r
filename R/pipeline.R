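# Orchestration: end-to-end experiments, scan-rescan subjects, cohorts and
# the bin-width / regularization sweeps.

#' Experiment configuration
#'
#' Collects every parameter of a simulated examination: phantom geometry,
#' ground-truth waveform, trajectory and acquisition settings, binning and
#' reconstruction parameters, M-mode and pressure noise, and the cohort
#' noise model. Defaults are the desk-scale study conditions: 64^3 grid at
#' 0.6 mm, TR 5.97 ms, ~150 s scan, RR 960 +/- 40 ms, diameters 5.5-6.4 mm,
#' 80 ms bins, lambda 0.01 with 10 ADMM iterations, pressures 113/63 mmHg.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return a validated configuration list (class "ExperimentConfig").
#' @export
experimentConfig <- function(...) {
  cfg <- list(
    # phantom
    gridSize = 64L, voxelMm = 0.6, vesselCentersMm = NULL,
    wallThicknessMm = 0.9,
    intensities = c(lumen = 10, wall = 3, background = 1),
    # ground-truth waveform
    dD = 5.5, dS = 6.4, rrMs = 960, sdRrMs = 40,
    systolicFraction = 0.45, peakPhase = 0.4, nPhasesWave = 24L,
    # acquisition
    # k-space noise is specified relative to the RMS of the noiseless data,
    # which is dominated by the k-space centre; 0.01 leaves a high-spatial-
    # frequency SNR of order 5 and reconstructed aSNR in the low tens
    scanS = 150, trMs = 5.97, readoutsPerSegment = 22L,
    samplesPerReadout = NULL, nCoils = 4L, noiseRel = 0.01,
    osf = 1.25, gridWidth = 5L, forwardMode = "nufft",
    # binning + reconstruction (warm-started inner CG: a few iterations per
    # ADMM step suffice and keep desk-scale runs tractable)
    binWidthMs = 80, lambda = 0.01, nAdmm = 10L, innerIters = 4L,
    innerTol = 1e-6,
    # M-mode arm
    nBeats = 5L, driftMmPerS = 0.1, mmodeNoiseSdMm = 0.05, imtMm = 0.6,
    mmodeNPhases = 240L,
    # pressures
    truePs = 113, truePd = 63, pressureSdMmHg = 4,
    # cohort noise model (measurement level)
    nSubjects = 14L, popDdMean = 5.5, popDdSd = 0.5, popRdcMean = 16.4,
    popRdcSd = 2.0, mraSdMm = 0.11, usSdMm = 0.25,
    rho = 1050, slices = NULL)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown configuration field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (is.null(cfg$samplesPerReadout)) cfg$samplesPerReadout <- cfg$gridSize
  structure(cfg, class = "ExperimentConfig")
}

# independent sub-seeds derived reproducibly from a master seed
.deriveSeeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.configPhantom <- function(cfg) {
  phantomSpec(gridSize = cfg$gridSize, voxelMm = cfg$voxelMm,
              vesselCentersMm = cfg$vesselCentersMm,
              wallThicknessMm = cfg$wallThicknessMm,
              intensities = cfg$intensities)
}

.configWaveform <- function(cfg, nPhases = NULL) {
  makeDiameterWaveform(cfg$dD, cfg$dS, cfg$rrMs, cfg$systolicFraction,
                       if (is.null(nPhases)) cfg$nPhasesWave else nPhases,
                       cfg$peakPhase)
}

#' Simulate one free-running MRA acquisition from a configuration
#'
#' @param cfg an \code{\link{experimentConfig}}.
#' @param seed integer seed (physiology and k-space noise).
#' @return a \linkS4class{RawKSpace}.
#' @export
simulateScan <- function(cfg, seed = 1L) {
  seeds <- .deriveSeeds(seed, 2)
  nReadouts <- ceiling(cfg$scanS * 1000 / cfg$trMs)
  nSeg <- ceiling(nReadouts / cfg$readoutsPerSegment)
  traj <- radialSamples(
    phyllotaxisDirections(nSeg, cfg$readoutsPerSegment),
    cfg$samplesPerReadout)
  physio <- simulatePhysio(cfg$scanS * 1000 + 2 * cfg$rrMs, cfg$rrMs,
                           cfg$sdRrMs, seeds[1])
  wf <- .configWaveform(cfg)
  coils <- makeCoilMaps(cfg$gridSize, cfg$nCoils)
  simulateAcquisition(wf, .configPhantom(cfg), traj, coils,
                      trMs = cfg$trMs, noiseRel = cfg$noiseRel,
                      physio = physio, seed = seeds[2],
                      mode = cfg$forwardMode, osf = cfg$osf,
                      width = cfg$gridWidth)
}

#' Bin and reconstruct a raw acquisition
#'
#' @param raw a \linkS4class{RawKSpace}.
#' @param binWidthMs cardiac bin width, ms.
#' @param config a \linkS4class{ReconConfig}.
#' @param osf,width gridding parameters.
#' @return an \linkS4class{Image4D}.
#' @export
reconstructRaw <- function(raw, binWidthMs = 80, config = reconConfig(),
                           osf = 1.25, width = 6L) {
  assign <- assignBins(raw@timestamps, raw@physio, binWidthMs)
  binned <- binKSpace(raw, assign)
  op <- encodingOperator(binned$coords, raw@coilMaps, osf = osf,
                         width = width)
  admmReconstruct(binned, op, config, voxelMm = raw@voxelMm,
                  binWidthMs = binWidthMs)
}

# measure both vessels of a reconstructed image
.measureVessels <- function(image, cfg) {
  spec <- .configPhantom(cfg)
  centers <- spec$vesselCentersMm
  labels <- rownames(centers)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(centers)))
  out <- lapply(seq_len(nrow(centers)), function(i)
    diameterSeries(image, centers[i, ], slices = cfg$slices,
                   vessel = labels[i],
                   maxRadiusMm = cfg$dS / 2 + cfg$wallThicknessMm + 1.5))
  names(out) <- labels
  out
}

#' Run one scan-rescan subject through both modalities
#'
#' Imaging mode simulates two full MRA acquisitions (independent
#' physiological jitter and noise) and two M-mode traces from the same
#' subject truth, reconstructs and measures them, and derives stiffness
#' panels per side plus their average for each modality and session.
#' Measurement mode replaces the imaging chain by the diameter-level noise
#' model (truth + Gaussian measurement error, SDs \code{mraSdMm} /
#' \code{usSdMm}), which is the desk-scale model used for cohort statistics.
#'
#' @param cfg an \code{\link{experimentConfig}}.
#' @param seed integer seed; everything downstream is deterministic given
#'   (cfg, seed).
#' @param mode "imaging" or "measurement".
#' @return list with per-modality, per-session measurements and stiffness
#'   panels.
#' @export
runSubject <- function(cfg, seed = 1L, mode = c("imaging", "measurement")) {
  mode <- match.arg(mode)
  seeds <- .deriveSeeds(seed, 8)
  wfUs <- .configWaveform(cfg, nPhases = cfg$mmodeNPhases)
  pressures <- list(
    mra = simulatePressures(cfg$truePs, cfg$truePd, cfg$pressureSdMmHg,
                            seeds[5]),
    us = simulatePressures(cfg$truePs, cfg$truePd, cfg$pressureSdMmHg,
                           seeds[6]))
  mra <- vector("list", 2); us <- vector("list", 2)
  if (mode == "imaging") {
    rc <- reconConfig(lambda = cfg$lambda, nIters = cfg$nAdmm,
                      innerIters = cfg$innerIters, innerTol = cfg$innerTol)
    for (s in 1:2) {
      raw <- simulateScan(cfg, seeds[s])
      img <- reconstructRaw(raw, cfg$binWidthMs, rc, osf = cfg$osf,
                            width = cfg$gridWidth)
      mra[[s]] <- .measureVessels(img, cfg)
      trL <- simulateMmode(wfUs, cfg$nBeats, cfg$driftMmPerS,
                           cfg$mmodeNoiseSdMm, cfg$imtMm,
                           seed = seeds[2 + s])
      trR <- simulateMmode(wfUs, cfg$nBeats, cfg$driftMmPerS,
                           cfg$mmodeNoiseSdMm, cfg$imtMm,
                           seed = seeds[6 + s])
      us[[s]] <- list(LC = measureMmode(trL), RC = measureMmode(trR))
    }
  } else {
    dTrue <- c(dS = cfg$dS, dD = cfg$dD)
    noise <- withr::with_seed(seeds[1], {
      list(mra = stats::rnorm(8, 0, cfg$mraSdMm),
           us = stats::rnorm(8, 0, cfg$usSdMm))
    })
    shape <- function(e) list(
      LC = list(dS = unname(dTrue["dS"]) + e[1],
                dD = unname(dTrue["dD"]) + e[2]),
      RC = list(dS = unname(dTrue["dS"]) + e[3],
                dD = unname(dTrue["dD"]) + e[4]))
    mra <- list(shape(noise$mra[1:4]), shape(noise$mra[5:8]))
    us <- list(shape(noise$us[1:4]), shape(noise$us[5:8]))
  }
  getDs <- function(x) if (is(x, "DiameterSeries") || is(x, "BeatExtrema"))
    c(dS(x), dD(x)) else c(x$dS, x$dD)
  panelFor <- function(sv, pp) {
    sides <- lapply(names(sv), function(nm) {
      d <- getDs(sv[[nm]])
      stiffnessPanel(d[1], d[2], pp, rho = cfg$rho, side = nm)
    })
    names(sides) <- names(sv)
    sides$average <- averageSides(sides[[1]], sides[[2]])
    sides
  }
  panels <- list(
    mra = lapply(mra, panelFor, pp = pressures$mra),
    us = lapply(us, panelFor, pp = pressures$us))
  list(mra = mra, us = us, pressures = pressures, panels = panels,
       truth = list(dS = cfg$dS, dD = cfg$dD,
                    rdc = (cfg$dS - cfg$dD) / cfg$dD * 100))
}

#' Run a synthetic scan-rescan cohort
#'
#' Draws per-subject, per-side diameter truths from the population model,
#' simulates scan-rescan measurements for both modalities (measurement-level
#' noise by default), and assembles Table-1-style repeatability (ICC(2,1),
#' CV; systolic and diastolic diameters pooled per side) and intermodality
#' agreement (Bland-Altman, regression, normality-gated paired test on the
#' session means).
#'
#' @param cfg an \code{\link{experimentConfig}}.
#' @param seed integer seed.
#' @param mode "measurement" (default) or "imaging" (full chain per subject;
#'   heavy).
#' @return list(measurements, repeatability, agreement, panels).
#' @export
runCohort <- function(cfg, seed = 1L, mode = c("measurement", "imaging")) {
  mode <- match.arg(mode)
  n <- cfg$nSubjects
  if (n < 3) stop("need at least 3 subjects")
  seeds <- .deriveSeeds(seed, n + 1L)
  truths <- withr::with_seed(seeds[n + 1L], {
    data.frame(
      subject = rep(seq_len(n), each = 2),
      side = rep(c("LC", "RC"), n),
      dD = stats::rnorm(2 * n, cfg$popDdMean, cfg$popDdSd),
      rdc = stats::rnorm(2 * n, cfg$popRdcMean, cfg$popRdcSd))
  })
  truths$dS <- truths$dD * (1 + truths$rdc / 100)
  rows <- list()
  panels <- list()
  for (i in seq_len(n)) {
    ti <- truths[truths$subject == i, ]
    ci <- cfg
    pressures <- simulatePressures(cfg$truePs, cfg$truePd,
                                   cfg$pressureSdMmHg, seeds[i])
    if (mode == "measurement") {
      noise <- withr::with_seed(seeds[i], {
        list(mra = stats::rnorm(8, 0, cfg$mraSdMm),
             us = stats::rnorm(8, 0, cfg$usSdMm))
      })
      meas <- list()
      for (modality in c("mra", "us")) {
        e <- noise[[modality]]
        idx <- 0L
        for (session in 1:2) for (sd_ in c("LC", "RC")) {
          tr <- ti[ti$side == sd_, ]
          idx <- idx + 1L
          dSm <- tr$dS + e[2 * idx - 1]
          dDm <- tr$dD + e[2 * idx]
          rows[[length(rows) + 1L]] <- data.frame(
            subject = i, modality = modality, session = session,
            side = sd_, d_s = dSm, d_d = dDm)
        }
      }
    } else {
      ci$dD <- mean(ti$dD); ci$dS <- mean(ti$dS)
      res <- runSubject(ci, seeds[i], mode = "imaging")
      for (modality in c("mra", "us")) {
        sess <- res[[modality]]
        for (session in 1:2) for (sd_ in c("LC", "RC")) {
          x <- sess[[session]][[sd_]]
          rows[[length(rows) + 1L]] <- data.frame(
            subject = i, modality = modality, session = session,
            side = sd_, d_s = dS(x), d_d = dD(x))
        }
      }
    }
    # stiffness panels from session-1 measurements
    last8 <- do.call(rbind, utils::tail(rows, 8))
    for (modality in c("mra", "us")) {
      m1 <- last8[last8$modality == modality & last8$session == 1, ]
      ps <- lapply(c("LC", "RC"), function(sd_) {
        r <- m1[m1$side == sd_, ]
        # noisy measurements keep their ordering by construction here, but
        # guard against a crossed pair by taking the order statistics
        stiffnessPanel(max(r$d_s, r$d_d), min(r$d_s, r$d_d),
                       pressures, rho = cfg$rho, side = sd_)
      })
      avg <- averageSides(ps[[1]], ps[[2]])
      tb <- panelTable(c(ps, list(avg)))
      tb$subject <- i; tb$modality <- modality
      panels[[length(panels) + 1L]] <- tb
    }
  }
  meas <- do.call(rbind, rows)
  repeatability <- do.call(rbind, lapply(c("mra", "us"), function(modality) {
    do.call(rbind, lapply(c("LC", "RC"), function(sd_) {
      sub <- meas[meas$modality == modality & meas$side == sd_, ]
      # pool systolic and diastolic rows: one row per subject x metric
      m1 <- .pairMatrix(sub)
      icc <- icc21(m1)
      data.frame(modality = modality, side = sd_, icc = icc$icc,
                 ci_low = icc$ci[1], ci_high = icc$ci[2],
                 cv_percent = cvTestRetest(m1))
    }))
  }))
  agg <- stats::aggregate(cbind(d_s, d_d) ~ subject + modality + side,
                          data = meas, FUN = mean)
  agreement <- do.call(rbind, lapply(c("d_s", "d_d"), function(metric) {
    a <- agg[agg$modality == "mra", metric]
    b <- agg[agg$modality == "us", metric]
    ba <- blandAltman(a, b)
    rg <- regressionPearson(a, b)
    pc <- pairedCompare(a, b)
    data.frame(metric = metric, bias = ba$bias, loa_low = ba$loa[1],
               loa_high = ba$loa[2], slope = rg$slope,
               intercept = rg$intercept, r = rg$r, test = pc$test,
               p = pc$p)
  }))
  list(measurements = meas, repeatability = repeatability,
       agreement = agreement, panels = do.call(rbind, panels))
}

# subject x session matrix pooling d_s and d_d rows (one unit per
# subject x metric)
.pairMatrix <- function(sub) {
  s1 <- sub[sub$session == 1, ]
  s2 <- sub[sub$session == 2, ]
  s1 <- s1[order(s1$subject), ]
  s2 <- s2[order(s2$subject), ]
  rbind(cbind(s1$d_s, s2$d_s), cbind(s1$d_d, s2$d_d))
}

#' Bin-width sweep
#'
#' Reconstructs the same raw acquisition at several cardiac bin widths and
#' measures the systolic/diastolic diameters each time; wider bins average
#' more motion states, which overestimates the diastolic diameter while the
#' systolic estimate stays comparatively stable.
#'
#' @param raw a \linkS4class{RawKSpace} (carrying its ground truth).
#' @param cfg the \code{\link{experimentConfig}} used to simulate it.
#' @param widths bin widths to test, ms.
#' @return data.frame(width_ms, d_s, d_d, mse) where mse is the mean squared
#'   error of (d_s, d_d) against the ground truth.
#' @export
binWidthSweep <- function(raw, cfg, widths = c(40, 80, 160, 240)) {
  rc <- reconConfig(lambda = cfg$lambda, nIters = cfg$nAdmm,
                    innerIters = cfg$innerIters, innerTol = cfg$innerTol,
                    logObjective = FALSE)
  mrr <- meanRR(raw@physio)
  out <- lapply(widths, function(w) {
    if (w >= mrr) {
      warning(sprintf("bin width %g ms >= mean RR %.0f ms: skipped", w, mrr))
      return(NULL)
    }
    img <- reconstructRaw(raw, w, rc, osf = cfg$osf, width = cfg$gridWidth)
    meas <- .measureVessels(img, cfg)[[1]]
    mse <- mean(c((dS(meas) - raw@groundTruth$dS)^2,
                  (dD(meas) - raw@groundTruth$dD)^2))
    data.frame(width_ms = w, d_s = dS(meas), d_d = dD(meas), mse = mse)
  })
  do.call(rbind, out)
}

#' Cardiac regularization weight sweep
#'
#' Reconstructs identical binned data at several lambda values, reporting
#' the diameter mean squared error against the ground truth and the
#' apparent SNR of the first cardiac phase (lumen mean over background SD).
#'
#' @param raw a \linkS4class{RawKSpace}.
#' @param cfg the \code{\link{experimentConfig}} used to simulate it.
#' @param lambdas regularization weights (>= 0; include 0 as the baseline).
#' @return data.frame(lambda, mse, asnr).
#' @export
lambdaSweep <- function(raw, cfg, lambdas = c(0, 0.005, 0.01, 0.05)) {
  spec <- .configPhantom(cfg)
  lumen <- phantomLumenMask(spec, raw@groundTruth$dD * 0.8)
  roi <- spec$backgroundRoi
  bg <- array(FALSE, dim = rep(cfg$gridSize, 3))
  bg[roi[1]:roi[2], roi[3]:roi[4], roi[5]:roi[6]] <- TRUE
  out <- lapply(lambdas, function(lam) {
    # the lambda = 0 baseline collapses to a single CG solve; give it the
    # same total iteration budget as the ADMM runs so all points of the
    # sweep are equally converged
    inner <- if (lam == 0) cfg$innerIters * cfg$nAdmm else cfg$innerIters
    rc <- reconConfig(lambda = lam, nIters = cfg$nAdmm,
                      innerIters = inner, innerTol = cfg$innerTol,
                      logObjective = FALSE)
    img <- reconstructRaw(raw, cfg$binWidthMs, rc, osf = cfg$osf,
                          width = cfg$gridWidth)
    # at very low lambda on noisy data the contour can legitimately fail;
    # report NA for the diameter error and keep the image-quality metric
    mse <- tryCatch({
      meas <- .measureVessels(img, cfg)[[1]]
      mean(c((dS(meas) - raw@groundTruth$dS)^2,
             (dD(meas) - raw@groundTruth$dD)^2))
    }, error = function(e) {
      warning(sprintf("diameter measurement failed at lambda = %g: %s",
                      lam, conditionMessage(e)))
      NA_real_
    })
    asnr <- computeAsnr(img@data[, , , 1], lumen, bg)
    data.frame(lambda = lam, mse = mse, asnr = asnr)
  })
  do.call(rbind, out)
}
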