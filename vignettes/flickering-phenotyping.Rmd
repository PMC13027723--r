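---
title: "Mechanical phenotyping of red blood cells from contour flickering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanical phenotyping of red blood cells from contour flickering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcflicker)
```

## The measurement problem

Healthy red blood cells flicker: their membrane–cytoskeleton envelope
undergoes nanometer-scale thermal (and active) undulations that are visible
as fluctuations of the equatorial contour in video microscopy. The
statistics of these fluctuations carry mechanical information — a stiffer or
more tense envelope fluctuates less, a more dissipative one relaxes more
slowly. `rbcflicker` implements a desk-scale version of a
computational-microscopy workflow that extracts this information from two
complementary acquisitions:

1. **Cell fields** (bright-field, ~0.1 µm/px): hundreds of suspended cells
   imaged once. Each accepted cell yields a smooth polar contour
   $R(\theta) = R_0 + h(\theta)$, shape descriptors, and an instantaneous
   fluctuation amplitude. Treating the population as an ensemble proxy for
   the temporal fluctuations of a single cell (the *ergodic approximation*),
   the low-order Fourier modes of $h$ yield an effective lateral tension.
2. **High-speed videos** (2000 fps, 50 nm/px): a single cell tracked for
   thousands of frames. Each of the $N$ angular stations of the contour
   yields a time series $h(\theta_j, t)$, analysed as an overdamped Langevin
   coordinate to give per-cell viscoelastic descriptors.

A hemolysis readout (Harboe spectrophotometry with blank-propagated
detection limits) gates the measurements — flickering phenotypes are only
interpretable in a sub-hemolytic regime — and a nonparametric statistical
layer summarizes and compares conditions.

No donor imagery ships with the package. Instead a synthetic-data module
generates every input class with known ground truth, which is what the test
suite and the acceptance script exercise end to end.

## Models and estimators

### Contours and morphometry

Every cell outline is a star-shaped curve sampled on the uniform grid
$\theta_j = 2\pi j/N$. From the resampled polygon the package computes area
$A$ (shoelace), perimeter $P$, equivalent radius $R_{eq} = \sqrt{A/\pi}$,
angular mean radius $R_0$, circularity $C = 4\pi A/P^2$, its linear variant
$C_{lin} = 2\pi R_{eq}/P$ (so $C_{lin}^2 = C$ identically), form factor
$F = P^2/A$ (hence $F \cdot C = 4\pi$ identically), and elongation $E = a/b$
from the inertia-equivalent ellipse, i.e. the eigen-decomposition of the
second central area moments of the filled polygon with $a = 2\sqrt{\lambda_1}$,
$b = 2\sqrt{\lambda_2}$. Both circularity conventions appear in the
morphometric literature; both are reported, and the acceptance filter uses
the standard $C$. The instantaneous fluctuation amplitude is
$\Delta = \langle h^2(\theta)\rangle_\theta^{1/2}$ (population divisor $N$).

### Ensemble ("ergodic") tension

With the forward Fourier convention $h_n = \frac1N \sum_j h(\theta_j)
e^{-in\theta_j}$, a tension-dominated Helfrich-like membrane has equatorial
mode powers falling off inversely with the mode index, and the operational
tension estimate is

$$\sigma_{eff} = \frac{k_B T}{2\pi\, n\, \langle |h_n|^2\rangle},$$

evaluated at a low mode ($n = 3$ by default) or averaged over the band
$n \in \{2,3,4\}$, on the arithmetic per-mode mean over cells. The absolute
scale of $\sigma_{eff}$ depends on this convention, which is therefore
stamped into every spectrum object (`convention_id`); the estimator is a
*comparative* descriptor under a fixed pipeline, not an absolute material
constant. Band averaging is used in the round-trip validations because the
per-mode power of an $M$-cell ensemble has relative error $\sim 1/\sqrt{M}$,
and the three-mode band cuts it by $\sqrt3$ without changing the estimand.

### Time-resolved descriptors

Each angular station's series (time mean removed) is treated as an
overdamped harmonic coordinate:

* **effective rigidity** $k_{eff} = k_BT / \langle h^2\rangle_t$
  (equipartition; divisor $T$),
* **Einstein diffusivity** $D$ from the initial slope of the mean squared
  displacement, $\mathrm{MSD}(\tau) = 2D\tau$, fit through the origin over
  the first 10 lags (5 ms at 2000 fps — far inside the linear regime for
  relaxation rates of tens per second; configurable),
* **friction** $\gamma = k_BT/D$ (Einstein relation; $\gamma D = k_BT$ holds
  exactly by construction),
* **relaxation frequency** $\omega_c = k_{eff} D / k_BT = k_{eff}/\gamma$,
  with $\tau_c = 1/\omega_c$,
* **volatility**: the standard deviation across moving-window standard
  deviations (0.5 s windows every 0.25 s), a non-stationarity marker that is
  offset-invariant and scales linearly with amplitude.

Angles are analysed independently and aggregated per cell by the **median**
(the aggregator is not dictated by the underlying theory; the median is
robust to dead angles, which are dropped and counted — a cell with more than
half its angles degenerate is flagged unusable). $\gamma$, $\omega_c$,
$\tau_c$ are derived *after* aggregation so the identities hold exactly on
every record.

### Hemolysis gating

The Harboe readout is $H = c_1 A'_{415} - c_2 A'_{380} - c_3 A'_{450}$ on
blank-corrected absorbances, with the standard weights
$(167.2, 83.6, 83.6)$ as configurable defaults. Hemolysis is
$100 \cdot H_{sample}/H_{lysis}$, so the weights cancel in the ratio. The
limit of detection propagates the per-wavelength blank standard deviations
(3 replicates × 5 reads) through the combination by root-sum-square and
multiplies by the conventional 3.3; sub-LOD values (including small
negatives) are reported as-is with a `below_lod` flag rather than clipped,
because sub-LOD fluctuations are uninterpretable, not zero.

### Statistical layer

Kruskal–Wallis across groups, two-sided Mann–Whitney U for planned pairs
(exact permutation null when both groups have ≤ 8 observations and no ties,
normal approximation with tie correction otherwise), summaries as median and
IQR (linear-interpolation quartiles, `quantile` type 7), and the fixed label
map `***`/`**`/`*` at 0.001/0.01/0.05 with a *trend* band on
$0.05 \le p < 0.1$ (lower bound inclusive). No multiplicity correction by
default, matching a within-run reporting scheme; Holm adjustment is a flag.
All reporting is within-condition, within-run: nothing the package emits is
population-level inference. The rigidity–frequency plane
($\omega_c$ vs $k_{eff}$ with a descriptive OLS line) preserves rigidity
ordering by construction since $\omega_c \propto k_{eff}$ at fixed $D$.

## Segmentation: choices that matter

* **Otsu** is implemented as an exhaustive scan over the 256-bin histogram
  maximizing between-class variance, ties broken toward the lowest
  threshold; the dark class (bright-field rims) is strictly below the
  threshold. Tests verify exact bin agreement with an independent
  brute-force oracle.
* **Connectivity** is 8-way (diagonally touching rims are one candidate).
* **Acceptance filters** run in a fixed order — border clearance, focus,
  solidity, circularity, radius window — and log the *first* failing reason,
  so rejection reasons are deterministic. Accepted components are reported
  in raster order of their centroids.
* **Focus** is operationalized as rim contrast,
  $(I_{bg} - I_{min})/I_{bg}$ on the globally normalized frame, with
  default threshold 0.45. After min–max normalization the deepest in-focus
  rims span most of the unit range, so any Otsu-detectable component has
  contrast above ~0.25; a mid-contrast rejection point is the smallest
  value that actually separates defocused rims from sharp ones. (A much
  lower threshold can never fire on a normalized frame.)
* **Aggregates** are components whose convex-hull solidity (computed from
  the raw boundary pixel chain — smoothing would erase the tell-tale
  waists) falls below 0.9, or whose boundary is not star-convex about the
  centroid. No splitting is attempted; aggregates are discarded.
* **Contour smoothing** interprets "high-degree periodic interpolation" as
  periodic trigonometric least squares: boundary samples are bin-averaged
  in angle (suppressing the ~0.3 px pixelation jitter the fit must not
  chase), fit with the configured number of harmonics (12 for fields, 18
  for videos), and the degree is raised until the residual RMS is ≤ 0.25 px.
  The Fourier basis is the natural periodic smoother for polar contours and
  feeds directly into the mode analysis; the residual bound makes the
  contract testable without fixing knot counts.
* **Sub-pixel refinement**: the binarization boundary sits on the outer
  flank of the rim trough, so radii are refined by localizing the intensity
  minimum along a dense fan of rays (local quadratic least squares over a
  ±1 px neighborhood of the profile minimum — a 3-point parabola sits below
  bilinear-interpolation artifacts). The refined contour follows the rim's
  optical center; on rendered fixtures this recovers planted radii to
  ~0.05 px and removes rigid drift to below 0.1 px.
* **Video denoising** uses a milder blur (σ = 1 px) than field preprocessing
  (σ = 2 px): sub-pixel rim localization degrades once the kernel approaches
  the angular arc spacing of the contour samples.

## The synthetic-data module

The generators define the conditions under which the pipeline is validated:

* **Scenes**: cells are dark annular rims (radial Gaussian troughs, depth
  0.6, width 0.45 µm) on a bright background with additive Gaussian noise
  (sd 0.01 of full scale). The nine-cell demonstration scene plants five
  defect-free cells (radii 7.2–7.6 µm, small mode-3 perturbations) and one
  each of: border-touching, fused L-shaped triad (aggregate), wide shallow
  rim (defocused), and an area-matched 2:1 ellipse (elongated). Planted
  radii sit inside the 7–8 µm acceptance window of the reference protocol;
  the window itself is configuration, not code. An axis ratio of 2 is used
  for the elongated defect because a 1.5 ellipse has $C \approx 0.94$ and
  would *pass* the 0.9 circularity filter. The aggregate is a triad because
  the convex-hull solidity of any connected *pair* of rendered rims stays
  above 0.9 — the overlapping troughs fill the waist — while the L-triad's
  empty corner drops it to ~0.87.
* **Dynamics**: stationary Ornstein–Uhlenbeck series via the exact discrete
  update $h_{k+1} = h_k e^{-\omega\Delta t} + \xi\sqrt{(k_BT/k_0)(1 -
  e^{-2\omega\Delta t})}$ from a stationary draw (no Euler bias), defaults
  $k_0 = 2\times10^{-6}$ N/m, $\gamma_0 = 10^{-7}$ kg/s (so $\omega_0 =
  20\,s^{-1}$, rms ≈ 46 nm at 37 °C — the scale of healthy-cell flicker).
  Per-angle series are independent by default, mirroring the per-angle
  analysis. For *optical* round trips a band-limited variant superposes
  modes 2–8 with per-mode OU coefficients sharing one relaxation rate: each
  angle is then still exactly OU, but the field is smooth in angle. This
  matters: an angularly white field has piecewise-linear corners that no
  smooth-contour tracker can represent, so it is not a fair rendering
  fixture, while real membrane fields are mode-limited anyway.
* **Static ensembles**: real contours with independent mode amplitudes
  drawn so that $E|h_n|^2 = k_BT/(2\pi n \sigma_0)$ on the band, zero
  elsewhere; no $n=0$ component, so $h$ has exactly zero angular mean.
* **Absorbance records**: 3 blank replicates × 5 reads plus sample and
  lysis-reference triplets built so the blank-corrected Harboe value equals
  the planted fraction of the lysis reference before noise.
* **Video rendering** is fixture plumbing, not optics: no point-spread
  function, no interior pallor, no 3-D shape. Passing round trips show the
  *pipeline* is faithful, not that the renderer models the instrument.

All generators are pure functions of their spec (same seed, bit-identical
output).

## Problem sizes and tolerances in the shipped validations

The test and acceptance runs use scaled-down sizes chosen to keep the
statistical contracts meaningful: 640 px scenes at 0.206 µm/px (nine cells),
OU recovery on 20 cells × 64 angles × 6000 frames at 2000 fps (median
relative errors: $k_{eff}$ ≤ 10%, $D$ ≤ 15%, $\omega_c$ ≤ 20%), tension
round trips at $M = 300$ cells within 10% (with mean error shrinking over
$M \in \{30, 300, 3000\}$), rendered-video tracking at 48–64 angles and a
few hundred frames, and 50–100 seeded replicates for the coverage-style
checks (ergodic-vs-temporal CI overlap, volatility discrimination, null
calibration of the report stage). Record lengths are kept at
$\omega_0 T \gtrsim 30$; shorter records bias the equipartition variance
low (the time mean absorbs the slow wander), which is a property of the
estimator, not a defect of the generator.

## Known limitations

* The bending modulus is never estimated; the analysis is restricted to the
  tension-dominated low-mode regime, and $\sigma_{eff}$ is comparative.
* Descriptors are *effective* quantities under an equilibrium, overdamped
  model; active (ATP-driven) contributions are not decomposed and no
  frequency-domain or memory-kernel inference is attempted.
* The renderer's idealized rims mean segmentation robustness to real
  optical artifacts (halos, debris, uneven illumination) is untested here.
* Aggregate handling discards fused components rather than splitting them.
* The equivalent-radius acceptance window follows the reference protocol's
  stated 7–8 µm; for other optics it should be reconfigured, and the
  package treats it purely as configuration.
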