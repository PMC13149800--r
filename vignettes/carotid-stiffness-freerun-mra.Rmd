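---
title: "Free-running 4D carotid MRA: models, simulation and stiffness analysis"
author: "freerunMRA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-running 4D carotid MRA: models, simulation and stiffness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Carotid artery stiffness is clinically assessed with M-mode ultrasound: the
vessel walls are tracked over a few heartbeats, the systolic and diastolic
lumen diameters $D_s$ and $D_d$ are extracted, and together with the brachial
pressure pair $(P_s, P_d)$ they yield a small panel of stiffness metrics. A
free-running (continuously acquired, ungated) 3D radial MR angiography
sequence can measure the same diameter change in an isotropic 3D volume: the
readouts are sorted retrospectively into cardiac bins using pulse-oximeter
triggers and reconstructed into a cardiac-resolved 4D image by compressed
sensing, after which the lumen is contoured in each phase.

`freerunMRA` implements this entire analysis chain as a tested, reusable
pipeline operating on synthetic data with known ground truth, so that every
stage is a parameter-recovery experiment:

1. **trajectory** — segmented 3D golden-angle top-to-bottom spiral-phyllotaxis
   spoke directions and their discretized k-space coordinates;
2. **synthesis** — a pulsating two-vessel neck phantom, multi-coil radial
   k-space acquisition at TR 5.97 ms, pulse-oximeter triggers with RR
   variability, parallel M-mode wall traces at 250 fps, and paired pressures;
3. **binning** — non-overlapping cardiac phases of (by default) 80 ms;
4. **reconstruction** — ADMM solution of the temporally
   total-variation-regularized least-squares problem;
5. **lumen measurement** — FWHM contouring, fan-triangulated area,
   $D = 2\sqrt{A/\pi}$, three-slice averaging;
6. **M-mode analysis** — boundary interpolation, subtraction, linear
   detrending, multiscale peak detection, five-beat averaging, $2\times$IMT
   correction;
7. **stiffness** — RDC, $\beta$, AC, one-point PWV, $E$;
8. **statistics** — ICC(2,1) with exact F confidence bounds, test-retest CV,
   Bland-Altman, OLS regression with Pearson $r$, Shapiro-Wilk-gated paired
   tests.

# Reconstruction model

The cardiac-resolved image $\hat{x}$ solves

$$\hat{x} = \arg\min_x \; \lVert FCx - y \rVert_2^2
          + \lambda_c \lVert \nabla_c x \rVert_1,$$

where $F$ evaluates the non-uniform Fourier transform at each bin's spoke
coordinates, $C$ applies the coil sensitivities, and $\nabla_c$ is the
first-order finite difference along the (cyclic) cardiac dimension. The
solver is ADMM on the splitting $z = \nabla_c x$: the x-update solves the
normal equations by warm-started conjugate gradients, the z-update is
complex soft-thresholding at $\lambda_c/\rho$, followed by dual ascent.

Numerical conventions that the published form of the problem leaves open,
fixed here:

* **Operator.** $F$ is a Kaiser-Bessel gridding NUFFT (oversampling 1.25,
  kernel width 6 by default; width 5 in the desk-scale experiment
  configurations) with numerically integrated deapodization. Spreading and
  interpolation share the same real kernel, so the adjoint is exact to
  machine precision regardless of kernel accuracy; forward accuracy against
  the exact direct-summation transform is of order $10^{-4}$ relative at the
  defaults. An exact $O(MN^3)$ direct-summation mode exists for small grids
  and serves as the oracle surface and as an "honest" (non-inverse-crime)
  simulation mode.
* **Normalization of $\lambda_c$.** A bare $\lambda_c = 0.01$ is meaningless
  without a scaling convention. Here the fidelity is density-compensation
  weighted, the weighted operator is normalized to unit Rayleigh gain on the
  density-compensated adjoint image, and the data are scaled so that this
  initial image has unit maximum magnitude. Under this convention (the one
  used by the reference k-t sparse SENSE implementations) the $\ell_1$ term
  is commensurate with the fidelity, and the weighted normal operator is
  well conditioned, so a few warm-started CG iterations per ADMM step
  suffice (the desk-scale default is 4, capped at the configured maximum
  with relative tolerance $10^{-6}$).
* **Penalty.** $\rho = 10\,\lambda_c$ (i.e. $0.1$ at the default
  $\lambda_c = 0.01$), configurable. $\lambda_c = 0$ short-circuits to plain
  (weighted) CG least squares; this is the least-squares limit used in the
  solver-exactness test.
* **Boundary.** $\nabla_c$ is periodic: the cardiac dimension is a cycle, so
  the phase sum of the differences telescopes to zero.
* **Initialization.** Density-compensated adjoint with its amplitude
  calibrated by a least-squares line fit (the gridding adjoint is not
  normalized); radial weights $w \propto |k|^2$ floored at the innermost
  percentile.
* **Output.** The complex image is retained internally; analysis and NIfTI
  export use the magnitude. An optional per-iteration objective log (in the
  normalized units in which $\lambda_c$ is defined) supports convergence
  checks. No patch-based post-denoising is applied; a no-op hook would sit
  after reconstruction and is intentionally out of scope.

A note on the least-squares limit: radial spokes never visit the Cartesian
corners of k-space, and a sharp-edged cylinder keeps a few percent of its
energy there, so "exact" recovery at $\lambda_c = 0$ is only meaningful for
effectively band-limited objects. The corresponding test therefore uses
Gaussian blobs whose spectrum is negligible beyond the sampled ball.

# Trajectory

The full pattern places its $MN$ spokes on the spherical spiral
$\theta_n = (\pi/2)\sqrt{n/(MN-1)}$, $\phi_n = n\gamma$ with the golden angle
$\gamma = 137.50776405^\circ$, and assigns readout $j$ of segment $s$ to
global spoke $n = s + jM$. Each segment is then a smooth pole-to-equator
(top-to-bottom) path, consecutive segments are rotated about the main axis by
exactly one golden angle, and the union covers the hemisphere quasi-uniformly
— the interleaved assignment matters: giving every segment the *same* polar
ladder would concentrate all spokes on $N$ rings and visibly starve the
interior of k-space. Spokes span $[-k_{max}, +k_{max}]$ symmetrically, so a
hemisphere of directions covers the full sphere. Coordinates are kept in
normalized units ($|k| \le 0.5$ cycles per voxel spacing); physical units
enter only at I/O. The interleave length (readouts per segment) is not a
published protocol parameter; the default is 22 and it is freely
configurable.

# The synthetic examination

The generator emulates, with known ground truth carried on every object:

* **Geometry.** Two bright axial cylinders (lumen:wall:background
  10:3:1 by default — the in-vivo inflow contrast ratio is not published, so
  10:1 is a free parameter, not a claim) in a $64^3$ grid of 0.6 mm voxels.
  Partial-volume edges are rendered by $\ge 4\times$ in-plane supersampling.
* **Pulsation.** One cycle of lumen diameter on a uniform phase grid: a
  raised-cosine systolic bump on a flat diastolic baseline, rescaled after
  sampling so the grid minimum and maximum equal $D_d$ and $D_s$ exactly
  (defaults 5.5 and 6.4 mm, the magnitudes of a young healthy cohort). The
  systolic fraction defaults to 0.45 (fast upstroke plus windkessel-type
  decay) and the peak sits at 0.4 of the cycle, i.e. ~380 ms after the
  pulse trigger at RR 960 ms, leaving the diastolic baseline in the late
  cycle as in a distension waveform referenced to a peripheral pulse
  trigger. Cardiac phase during simulation is the *fraction* of the current
  RR interval, while binning uses millisecond offsets (as the scanner must),
  so with RR variability the reconstruction is tested against a slightly
  mismatched truth — deliberately, as in vivo.
* **Acquisition.** Readout $i$ at $t_i = (i-1)\,\mathrm{TR}$ (TR 5.97 ms)
  samples the exact Fourier transform of (coil map $\times$ phantom rendered
  at that readout's phase, snapped to the waveform grid so the number of
  distinct renders is bounded), plus independent complex Gaussian noise.
  The noise level is specified relative to the RMS of the noiseless data;
  since that RMS is dominated by the k-space centre, the default of 1%
  leaves a high-spatial-frequency k-space SNR of order 5 and a
  reconstructed apparent SNR in the low tens — the regime of the in-vivo
  images.
  Four to eight smooth Gaussian-profile coils with sum-of-squares magnitude
  one stand in for the head-neck array. The default forward model is the
  same gridding operator used in reconstruction (an inverse-crime
  convenience appropriate for parameter-recovery tests); the exact DFT mode
  decouples the two for accuracy tests.
* **Physiology.** Triggers at cumulative RR intervals drawn from a normal
  distribution truncated at $\pm 3$ SD (defaults 960 $\pm$ 40 ms).
* **M-mode.** Outer-wall boundary positions at 250 fps:
  $\mathrm{centre} \mp (D(t)/2 + \mathrm{IMT})$ plus shared linear drift and
  independent Gaussian noise per boundary (IMT default 0.6 mm).
* **Pressures.** Pre- and post-scan readings (truth + Gaussian noise,
  defaults 113/63 mmHg $\pm$ 4) averaged into one pair per examination.

What the generator does **not** emulate: MR signal physics (relaxation,
flip-angle saturation, flow profiles and inflow-dependent intensity
gradients), respiration and swallowing, B0/B1 inhomogeneity, speckle or
echo-tracking physics in ultrasound, and observer variability beyond
additive noise. Passing the recovery tests therefore demonstrates that the
*algorithms* recover what they are defined to recover under controlled
conditions — not that the method is validated on patients.

# Lumen measurement

Per slice and cardiac phase, 64 rays are cast from the lumen centre, each
sampled by bilinear interpolation at 0.1-voxel steps. The half level is
min + half the range *of that ray's profile* (robust to intensity shading;
the published description fixes no normalization window), and the vertex is
the first sub-sample crossing below the half level outward of the ray's
peak — the innermost outward crossing, which keeps the second vessel from
confusing long rays. The centre is iterated to the contour centroid (at most
10 times, stopping below 0.1 voxel). The contour area is the fan
triangulation from the centroid (equal to the shoelace value for these
star-shaped contours), the effective diameter is $2\sqrt{A/\pi}$, and
$D_s/D_d$ are the per-slice extrema over phases, averaged across three
slices (computing extrema first and averaging second follows the published
order of operations; the mean-curve alternative is available behind a flag).
No IMT correction is applied to MRA diameters: the lumen signal is targeted
directly. Voxel centres sit at `index * voxelMm`, 0-based — fixed so NIfTI
round-trips are unambiguous.

Half-the-range contouring of a blurred bright disk lands slightly outside
the true edge when the wall is brighter than the far background (the
crossing sits at ~64% of the lumen-wall transition); at 0.6 mm voxels this
bias stays within the half-voxel tolerance and largely cancels in the
relative diameter change.

# M-mode analysis

Boundaries are linearly interpolated to the uniform frame grid and
subtracted; a shared transducer drift is common-mode and cancels exactly in
the subtraction. The least-squares linear trend of the difference is then
removed *slope-only*, preserving the mean — absolute diameters feed the
stiffness formulas, so zero-centred detrending would destroy them. Two
consequences worth knowing:

* Removing the slope about the record mean maps $D(t) + bt$ to
  $D(t) + b\bar{t}$: an independent trend on the *diameter* (as opposed to a
  common-mode boundary drift) leaves its constant mean behind. That is
  inherent to slope-only detrending.
* A finite record of a periodic waveform generally has a small nonzero LS
  slope of its own, so detrending distorts peak/trough values at the
  $10^{-3}$ mm level unless the sampled waveform is symmetric within the
  record. The machine-exactness tests use the symmetric configuration (peak
  centred mid-cycle at the half-sample phase, constant RR, waveform grid
  matched to the frame rate); the default asymmetric configuration is the
  realistic one and its detrend bias is far below the measurement noise.

Peaks are detected by automatic multiscale-based peak detection (AMPD): a
local-maxima scalogram over window scales, the global scale with the most
maxima, and peaks = samples that are maxima at every scale up to it. Two
practical refinements: plateau ties break toward the earlier sample (strict
left, non-strict right — exactly flat noiseless summits would otherwise
vanish), and comparisons crossing the record boundary use symmetric
reflection padding so that beats close to the edges of a five-beat record
survive, while the global scale is still chosen from the canonical unpadded
count and the first/last samples are never reported. Troughs for the beat
averages come from the deterministic pairing rule — each trough is the
minimum between consecutive peaks (the segment before the first peak
supplies the first) — because AMPD legitimately finds no strict extrema on
an exactly flat diastolic plateau. $D_s$ and $D_d$ are the means over the
first five beats, each reduced by twice the IMT (the delineation follows
the outer wall).

# Stiffness metrics

With diameters in mm, pressures in mmHg, and blood density
$\rho = 1050\ \mathrm{kg/m^3}$:

$$\mathrm{RDC} = \frac{D_s - D_d}{D_d} \cdot 100\ (\%) \qquad
\beta = \frac{\ln(P_s/P_d)}{(D_s - D_d)/D_d} \qquad
\mathrm{AC} = \frac{\pi (D_s^2 - D_d^2)}{4 (P_s - P_d)}\ (\mathrm{mm^2/kPa})$$

$$\mathrm{PWV} = \sqrt{\frac{\beta P_s}{2 \rho}}\ (\mathrm{m/s}) \qquad
E = \frac{P_s - P_d}{(D_s - D_d)/D_d}\ (\mathrm{kPa})$$

with $1\ \mathrm{mmHg} = 133.322\ \mathrm{Pa}$ applied inside AC, PWV and
$E$; $\beta$ takes the pressures as a unit-free ratio. These conversions are
what place the outputs at the physiological magnitudes (AC near
1 mm²/kPa, PWV near 5 m/s, $E$ near 40 kPa for the young-cohort worked
example). Zero strain makes $\beta$ and $E$ undefined and is an error. The
left/right "average" is the metric-level mean of the two side panels, not
the panel of mean diameters — the two differ slightly because the metrics
are nonlinear in the diameters; metric-level averaging matches a results
table whose average column summarizes per-side metrics.

# Repeatability and agreement statistics

ICC(2,1) is the two-way random-effects, absolute-agreement, single-
measurement form, computed from explicit mean squares, with the 95% CI from
the exact F-distribution bounds of the same model (Satterthwaite denominator
df) rather than a bootstrap. The test-retest CV is the RMS over subjects of
(within-subject SD / subject mean), the standard convention where none is
published. Bland-Altman uses bias $\pm 1.96\,$SD of the paired differences
(sample SD); regression is OLS with Pearson $r$. Paired comparisons are
gated by Shapiro-Wilk on the differences at $\alpha = 0.05$: Student's
paired t when normal-looking, Wilcoxon signed-rank otherwise (and also when
the differences are exactly constant, where neither Shapiro-Wilk nor the t
statistic exists). No multiple-testing correction is applied.

The scan-rescan cohort model draws per-subject, per-side truths
($D_d \sim N(5.5, 0.5)$ mm, RDC $\sim N(16.4, 2.0)$ %) and adds
measurement noise per scan with SD 0.11 mm (MRA) and 0.25 mm (ultrasound) —
back-computed from test-retest CVs near 1.8% and 4.2% at ~6 mm diameters.
Repeatability tables pool systolic and diastolic diameters per side (one row
per subject $\times$ metric). The cohort runs at the diameter level
("measurement" mode) by default; the full imaging chain for hundreds of
cohort replicates is not a desk-scale computation, and the property of
interest — the ICC/CV ordering between a lower-noise and a higher-noise
modality — lives entirely at the measurement level. `runSubject` exposes the
full "imaging" mode for single subjects.

# Sweep experiments

Two configuration sweeps re-enact the protocol-optimization experiments at
desk scale ($32^3$ grid, single vessel, ~45 s simulated scans):

* **Bin width** (40/80/160/240 ms, one reconstruction per width on identical
  raw data). Wider bins average more motion states. The diastolic
  overestimation that drives the published choice of 80 ms requires a
  waveform that decays through diastole and RR variability (late-cycle
  offsets smear across phases); the sweep configuration therefore uses
  systolic fraction 0.95 (brief flat foot only) with RR SD 50 ms. Under
  those conditions the estimated diastolic diameter grows with the bin
  width while the systolic estimate varies less, and a static phantom is
  width-independent.
* **Regularization weight** ($\lambda_c \in \{0, 0.005, 0.01, 0.05\}$ on
  identical noisy data), reporting diameter MSE against truth and the
  apparent SNR (lumen mean over background-box SD) of the first phase;
  stronger temporal regularization smooths noise, so aSNR does not decrease
  with $\lambda_c$. At very small $\lambda_c$ on noisy data the FWHM
  contour can legitimately fail; the sweep then reports NA for the diameter
  error and keeps the image-quality metric.

# Problem sizes and runtimes

The package's study conditions are deliberately desk-scale: $64^3$ voxels at
0.6 mm (a 38.4 mm field of view around the vessels) with ~2 minutes of
simulated scanning for the headline parameter-recovery experiment, $32^3$
for the sweeps, and $16^3$-$24^3$ for operator and solver tests. These sizes
were chosen so the full suite and the acceptance run complete on a single
CPU in tens of minutes while leaving every algorithmic property intact; the
in-vivo protocol's 160 mm field of view and half-hour reconstructions
exercise no additional code path.

# Known limitations

* The forward simulation defaults to the same NUFFT used in reconstruction
  (inverse crime); honest-accuracy experiments must opt into the exact DFT
  mode, which is only tractable on small grids.
* The phantom has no flow-dependent contrast, so the inflow-related
  systolic/diastolic intensity asymmetry discussed for the in-vivo method
  — a suspected source of RDC overestimation — cannot be reproduced here.
* FWHM contouring assumes a bright, roughly convex lumen; plaques,
  bifurcations and wall imaging are out of scope.
* The M-mode noise model is white per frame; because the beat averages take
  peak and trough extrema, frame noise biases the systolic diameter up and
  the diastolic one down and so overstates the ultrasound RDC. Real manual
  delineation error is smoother than white noise, so this is a conservative
  noise model for the ultrasound arm, not a statement about M-mode itself.
* ICC confidence bounds assume the two-way normal model; heavy-tailed
  measurement noise is not covered.
* The raw-data container is serialized as RDS at run time; an HDF5 layout
  would be preferable for interoperability but is not available in this
  R dependency set.
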