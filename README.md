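# rbcflicker

Mechanical phenotyping of red blood cells (RBCs) from bright-field imagery:
contour-based morphometry of cell fields, ensemble ("ergodic") flickering
spectroscopy yielding an effective lateral membrane tension, and
high-speed time-resolved flickering yielding per-cell viscoelastic
descriptors, together with the Harboe hemolysis readout that gates the
measurements and a nonparametric reporting layer.

It is aimed at membrane-biophysics and hemorheology groups who image
suspended erythrocytes and want a deterministic, testable pipeline from raw
TIFF frames to per-cell descriptor tables — plus a synthetic-data module
with known ground truth, so every stage can be validated without donor
imagery.

## What it computes

Cell outlines are star-shaped polar contours R(θ) = R0 + h(θ) on a uniform
angular grid. From these:

* **Morphometry** — area A, perimeter P, equivalent radius R_eq = √(A/π),
  circularity C = 4πA/P² (and C_lin = 2πR_eq/P with C_lin² = C), form
  factor F = P²/A, elongation E = a/b from the inertia-equivalent ellipse,
  and the fluctuation amplitude Δ = ⟨h²⟩^½. Candidate cells pass border,
  focus, solidity (aggregate), circularity (> 0.9) and equivalent-radius
  (7–8 µm) filters; the accepted/detected ratio is the normocyte fraction.
* **Ensemble tension** — with h_n the (1/N-normalized) Fourier modes of h,
  the tension-dominated spectrum gives the operational estimate
  σ_eff = k_BT / (2π n ⟨|h_n|²⟩) at low modes (n = 3, or the band {2,3,4}),
  averaging |h_n|² over the cell population in place of time (the ergodic
  approximation). σ_eff is a comparative descriptor under a fixed pipeline.
* **Time-resolved descriptors** — per angular station of a tracked video:
  effective rigidity k_eff = k_BT/⟨h²⟩_t (equipartition), Einstein
  diffusivity D from the initial MSD slope (MSD = 2Dτ), friction
  γ = k_BT/D, relaxation frequency ω_c = k_eff D/k_BT (τ_c = 1/ω_c), and a
  moving-window volatility (non-stationarity marker); per-cell aggregation
  by the median across angles.
* **Hemolysis** — blank-corrected Harboe readout
  H = 167.2·A415′ − 83.6·A380′ − 83.6·A450′, percent of full hypotonic
  lysis, and a per-condition limit of detection (3.3 × blank sd propagated
  through the combination).
* **Statistics** — Kruskal–Wallis + planned Mann–Whitney pairs (exact for
  n ≤ 8 without ties), median/IQR summaries, significance labels with a
  trend band (0.05 ≤ p < 0.1), and the ω_c-vs-k_eff mechanical plane.

## Worked example

Simulate a nine-cell bright-field scene with planted defects, run the
morphometry workflow, then estimate a tension and a per-cell dynamics
record from synthetic ground truth:

```r
library(rbcflicker)

out <- tempfile(); run_simulate("field", out, seed = 1)
cfg <- run_config(pixel_size_um = 0.206)
res <- run_morpho(file.path(out, "field.tif"), file.path(out, "morpho"),
                  cfg, condition = "vehicle")
#> [morpho] field: 9 detected, 5 accepted, 4 rejected
round(res$cells[, c("Req_um", "C", "E", "delta_nm")], 3)
#>   Req_um     C     E delta_nm
#> 1  7.588 1.000 1.000   41.876
#> 2  7.388 1.000 1.000   42.353
#> 3  7.188 1.000 1.000   41.804
#> 4  7.388 0.999 1.001   69.627
#> 5  7.388 1.000 1.000   42.136
res$fields$normocyte_fraction
#> [1] 0.5555556

es  <- ensemble_spec(n_cells = 300, tension_true = 5e-7, seed = 1)
avg <- ensemble_spectrum(lapply(generate_static_ensemble(es)$contours,
                                mode_spectrum))
effective_tension(avg, thermal_context(), 2:4)
#> Effective lateral tension: 4.69e-07 N/m (mode 2,3,4, 300 cells, T = 310.15 K)

dyn <- generate_angle_dynamics(ou_spec(seed = 1))   # truth: k0 = 2e-6 N/m
cell_summary(dyn$field, thermal_context())
#> Per-cell flickering descriptors:
#>     cell_id condition     k_eff         D     gamma omega_c   tau_c volatility
#> 1 synthetic      <NA> 2.076e-06 4.093e-14 1.046e-07   19.84 0.05041  7.872e-09
#>   n_angles_used usable
#> 1            64   TRUE
```

The five accepted cells are exactly the five defect-free plants (the
border-touching, aggregated, defocused and elongated plants are rejected
with those reasons, giving the 5/9 normocyte fraction); the recovered
tension is within a few percent of the planted 5e-7 N/m, and the dynamics
record recovers the planted stiffness (2e-6 N/m) and relaxation rate
(20 s⁻¹), with γ·D = k_BT holding exactly.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/rbcflick.R` with subcommands `simulate`, `morpho`, `flicker`,
`hemolysis` and `report`.

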