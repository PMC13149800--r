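# freerunMRA

Simulation and analysis of **free-running 4D carotid MR angiography** for
arterial stiffness quantification, with a parallel synthetic **M-mode
ultrasound** arm — the full chain from continuously acquired radial k-space
to the five carotid stiffness metrics and scan–rescan repeatability
statistics, built for synthetic data with known ground truth so that every
stage is a parameter-recovery experiment.

## Who this is for

Researchers developing or validating dynamic vessel-imaging pipelines:
retrospective cardiac binning of ungated acquisitions, compressed-sensing
reconstruction with temporal regularization, sub-voxel lumen diameter
measurement, and test–retest study statistics — without access to scanner
raw data.

## What it computes

A free-running gradient-echo acquisition samples k-space continuously along
a segmented 3D golden-angle **spiral-phyllotaxis** trajectory (spoke *n* at
polar angle θₙ = (π/2)√(n/(N−1)), azimuth n·137.508°, interleaved across
segments). Pulse-oximeter triggers sort readouts into non-overlapping
cardiac bins of 80 ms (bins per cycle = mean RR / width), and the 4D image
is reconstructed by ADMM as

```
x̂ = argmin_x ‖F C x − y‖₂² + λc ‖∇c x‖₁ ,      λc = 0.01, 10 iterations
```

with `F` a Kaiser–Bessel gridding NUFFT, `C` the coil sensitivities and
`∇c` the periodic temporal finite difference. Lumen contours are found per
slice and phase by full-width-at-half-maximum ray casting; the effective
diameter is D = 2√(A/π) with A from fan triangulation, and Dₛ/D_d are the
per-slice extrema averaged over three slices. The M-mode arm interpolates
and subtracts the two wall boundaries, detrends linearly, finds the five
beats by automatic multiscale peak detection (AMPD), and subtracts twice
the intima–media thickness. Both arms feed the stiffness panel

```
RDC = (Ds − Dd)/Dd · 100 (%)          β   = ln(Ps/Pd) / ((Ds − Dd)/Dd)
AC  = π(Ds² − Dd²)/(4(Ps − Pd))       PWV = sqrt(β·Ps/(2ρ))      (ρ = 1050 kg/m³)
E   = (Ps − Pd) / ((Ds − Dd)/Dd)
```

and scan–rescan cohorts are summarized by ICC(2,1) with exact F confidence
bounds, test–retest CV, Bland–Altman limits of agreement, OLS regression
with Pearson r, and Shapiro–Wilk-gated paired tests.

## Worked example

```r
library(freerunMRA)

# stiffness panel from a young-cohort diameter/pressure quadruple
p <- stiffnessPanel(6.4, 5.5, new("PressurePair", pS = 113, pD = 63))
p
#> StiffnessPanel [LC]  (Ps/Pd = 113/63 mmHg, rho = 1050 kg/m^3)
#>   RDC 16.364 % | beta 3.570 | AC 1.262 mm^2/kPa | PWV 5.061 m/s | E 40.74 kPa
```

RDC 16.4% says the lumen distends by a sixth of its diastolic diameter each
beat; β ≈ 3.6, AC ≈ 1.26 mm²/kPa, PWV ≈ 5 m/s and E ≈ 41 kPa are the
magnitudes expected for a compliant young carotid.

A complete synthetic examination (simulate → bin → reconstruct → measure;
about 8 minutes at the default 64³ / 0.6 mm / 2.5-min-scan configuration):

```r
cfg <- experimentConfig()                   # study conditions
raw <- simulateScan(cfg, seed = 11)         # continuous multi-coil k-space
img <- reconstructRaw(raw, cfg$binWidthMs,  # 12 bins of 80 ms at RR 960
                      reconConfig(lambda = 0.01, nIters = 10,
                                  innerIters = 4, logObjective = FALSE),
                      width = cfg$gridWidth)
spec <- phantomSpec(cfg$gridSize, cfg$voxelMm)
diameterSeries(img, spec$vesselCentersMm["LC", ], maxRadiusMm = 5.6)
#> DiameterSeries [LC]: 12 phases; Ds = 6.449 mm, Dd = 5.667 mm
```

against a ground truth of Dₛ = 6.4 mm, D_d = 5.5 mm: the systolic diameter
is recovered to 0.05 mm and the diastolic one to 0.17 mm (the diastolic
estimate carries the half-maximum contour's outward bias, well inside the
half-voxel tolerance), giving an RDC of 13.8% against the true 16.4%.
`simulateMmode()`/`measureMmode()` provide the ultrasound arm, and
`runCohort()` assembles repeatability and intermodality-agreement tables
for a synthetic scan–rescan cohort.

The methods vignette
(`vignettes/carotid-stiffness-freerun-mra.Rmd`) documents the models,
every tunable parameter, the numerical conventions, and what the synthetic
data do and do not emulate.

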