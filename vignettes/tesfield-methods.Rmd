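---
title: "Modelling tES-induced electric fields over the adult lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tES-induced electric fields over the adult lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Transcranial electrical stimulation (tES) injects a weak current (here
±2 mA) through a pair of scalp electrodes; the therapeutic agent is the
electric field this induces in the cortex. Head anatomy changes continuously
through adult life — grey matter atrophies, ventricles expand, the skull and
scalp change thickness, CSF accumulates — so the same stimulation dose
produces systematically different cortical fields at different ages.
`tesfield` provides the full computational chain needed to study that
dependence in a controlled setting: a synthetic aging cohort of layered
spherical head phantoms, a finite-element forward solver, an analytic
oracle validating the solver, field outcome metrics, anatomical predictors,
and the statistical layer (decade summaries, t-tests, stepwise regression,
trend-shape classification).

Two claims motivate the design of the default experiment:

1. cortical field amplitude over the adult lifespan is not monotone in age
   but **U-shaped** — declining to a minimum around the eighth decade and
   rebounding in the oldest group; and
2. **local** anatomy (scalp, skull and CSF thickness directly under the
   electrodes) explains more of the between-subject amplitude variance than
   **global** anatomy (relative tissue volumes).

Both are qualitative, property-style claims, and the test suite asserts
exactly those properties on synthetic cohorts.

## The volume-conduction model

At tES frequencies the field is quasi-static: the potential solves the
conduction equation

$$\nabla \cdot (\sigma \nabla \varphi) = 0$$

inside the head, with Neumann boundary conditions describing the injected
current and $E = -\nabla\varphi$. Tissues are assigned fixed conductivities
(S/m): scalp 0.465, skull 0.01, CSF 1.654, grey matter 0.275, white matter
0.126, with electrode pad 29.4 and saline gel 1.0; ventricles are treated as
CSF-filled. We deliberately keep conductivity age-independent: the point of
the model is to isolate the effect of *anatomy* on the field.

The solver uses linear (P1) tetrahedral elements with element-constant
fields, the standard choice in tES modelling, so the stiffness matrix is

$$K_{ij} = \sum_e V_e \, (\nabla \lambda_i)^\top \sigma_e (\nabla \lambda_j),$$

assembled sparse and factorized once per head (supernodal Cholesky after
pinning one node; the potential is recentred to the mean-zero gauge, which
avoids introducing reference-electrode semantics the problem does not have).
The solver contract is a relative residual below `rel_tol` (default 1e-10,
far below discretization error); the factorization is reused across all
montages of a subject. Optional synthetic white-matter anisotropy is
available via `tensorize_wm()`: tangential principal axes with ratio
$\rho = \sigma_t/\sigma_r$ and the geometric mean of the eigenvalues pinned
to the scalar value (volume-normalized mapping). The cohort default is
isotropic ($\rho = 1$), matching the fixed-conductivity design.

### Electrode models

A 5 × 5 cm pad cannot be isometrically mapped onto a sphere, so pads are
represented as spherical caps of equal area (25 cm²); area, not shape, is
what the injected current density depends on. Two models are provided:

* `PATCH_NEUMANN` (default): uniform inward current density
  $j = I/A_\text{cap}$ over the cap's boundary facets, each cap normalized
  by its own realized (meshed) area so the anode and cathode fluxes balance
  exactly — a requirement for Neumann solvability.
* `EXTRUDED_PAD`: explicit 5 mm gel + 2 mm pad element layers extruded over
  the cap, with the current injected on the outer pad surface. Because
  $\sigma_\text{pad} \gg \sigma_\text{gel} \gg \sigma_\text{scalp}$, the pad
  is nearly equipotential (measured potential spread ~2% of the total drop).
  The two models produce the same field pattern (grey-matter magnitude
  correlation 0.998), but the equipotential pad redistributes current toward
  the cap rim and yields a grey-matter peak about 16% below the
  uniform-density patch — a genuine electrode-model difference, stable
  across mesh resolutions, that users comparing absolute amplitudes should
  be aware of.

Electrode directions come from the 10-10 system, generated from its
geometric construction (midline positions at 18° steps of the nasion–inion
arc, the 10% ring at 72° inclination, lateral positions as great-circle arc
midpoints) and shipped as a versioned CSV asset. The four montages are
F3-F4, F3-P3, P3-P4 and Fp1-P4. On a perfect sphere P3-P4 is the
front–back mirror image of F3-F4, so their field magnitudes coincide — a
geometric degeneracy of the phantom, not of real heads.

## The analytic oracle

A multilayer concentric sphere with isotropic layers admits a closed-form
solution: per Legendre degree $l$ the radial part is
$A r^l + B r^{-(l+1)}$ in each layer, with $\varphi$ and
$\sigma\,\partial_r \varphi$ continuous across interfaces, and the cap
current density expanded through the cap integral identity
$\int_{\text{cap}} P_l = (P_{l-1} - P_{l+1})/(2l+1)$ evaluated at
$\cos\alpha$. The coefficients propagate across layers by a 2 × 2 transfer
recursion; to keep the recursion well-conditioned at $L = 100$ each layer's
solution is normalized to its own radii ($A_k (r/R_k)^l +
B_k (R_{k+1}/r)^{l+1}$), so every power stays in $[0, 1]$ inside its layer.

The oracle is self-checked (interface continuity residuals below 1e-10,
gradients against central finite differences, homogeneous reduction to the
single-sphere closed form) and serves as the FEM's independent referee: on
the default five-layer phantom (radii 92/86/80/78/60 mm) the relative
volume-weighted L2 error of $|E|$ over brain tissue is ~3.4% at the default
resolution (~1.0 × 10⁵ tets) and decreases monotonically under refinement
(4.0% → 3.4% → 2.3% at 5.5 × 10⁴ → 1.0 × 10⁵ → 4.2 × 10⁵ tets). The error is
angular-resolution limited beyond that: reaching 2% requires a
subdivision-5 geodesic surface (~1.3 × 10⁶ tets), which we document rather
than exercise routinely.

## The synthetic aging cohort

The phantom generator replaces MRI segmentation. Each subject is a layered
sphere (scalp, skull, CSF, GM shell, WM core, optional ventricle core)
whose layer thicknesses are piecewise-linear functions of age plus Gaussian
between-subject noise, truncated at 0.5 mm so no layer degenerates. The
default trajectory *shapes* encode the qualitative adult-lifespan picture:

| quantity  | shape                                     | knots (age, mm) | SD (mm) |
|-----------|-------------------------------------------|-----------------|---------|
| scalp     | stable to 60, declining after             | (18, 6.0) (60, 6.0) (80, 5.75) (88, 5.1) | 0.3 |
| skull     | inverted U, maximum at 60                 | (18, 5.5) (60, 7.0) (80, 6.8) (88, 5.8)  | 0.4 |
| CSF       | non-decreasing after 20                   | (18, 2.0) (20, 2.0) (80, 4.0) (88, 4.6)  | 0.3 |
| GM shell  | declining                                 | (18, 19.0) (50, 17.8) (70, 17.2) (88, 16.2) | 0.5 |
| ventricle | growing, steeper after 60                 | (18, 10) (60, 13) (88, 18)               | 1.0 |

Slopes are free parameters (the source trends are graphical); the defaults
were chosen once so that the *electrode-to-cortex distance* — the sum of
scalp, skull and CSF thickness — rises until about 60, plateaus through the
seventh decade and falls after 80, with a late-life amplitude rebound of a
few percent, the magnitude reported for real cohorts. Under these defaults
the noise-free amplitude profile has its minimum in the 71–80 decade and a
+4% rebound in the oldest bin, comfortably outside the n = 20 group-mean
noise (SE ≈ 0.005 V/m).

Ages are sampled uniformly within each decade bin (the least-assumptive
choice given only group counts), per-subject seeds derive from the master
seed by counter (order-independent determinism), and the default group
sizes reproduce an 8-bin design; a 7/49/76/79/73/72/84/36 configuration
reproduces a 476-subject cohort.

What the phantom does *not* emulate: gyrification (so focality values are
phantom-scale, not head-scale), the cerebellum (no spherical analog; its
relative-volume predictor is therefore absent from the regressions), skull
foramina, azimuthal anatomy variation (anode- and cathode-side thicknesses
are identical per subject, so one of each collinear pair is dropped in the
regressions), and subject-specific WM tensors. Passing cohort tests
therefore demonstrate that the *pipeline* recovers the qualitative
anatomy-driven trends from data that contain them, not that real heads
behave like spheres.

Regions of interest are geometric analogs preserving the property that
matters (location relative to the electrodes): an anterior-inferior cone
(ventromedial-prefrontal analog), a posterior-superior cone
(posterior-parietal analog), both 25° half-angle in GM, and a deep 10 mm
ball on the left at 0.55 of the GM radius (hippocampal analog).

## Outcome metrics and predictors

* `peak99` — the volume-weighted 99th percentile of $|E|$ over grey matter,
  a robust proxy for the peak that ignores isolated numerical extremes.
  Percentiles are volume-weighted by default because element-count
  percentiles would overweight finely meshed regions; a `count` switch
  exists for sensitivity analysis. The same 99th-percentile convention is
  applied within ROIs (which are small and artifact-sensitive), along with
  the volume-weighted ROI mean.
* `focality75` — the grey-matter volume whose $|E|$ strictly exceeds the
  volume-weighted 75th percentile, in cm³. Under this percentile-threshold
  definition the focality of a continuous field is essentially a quarter of
  the GM volume, so its age trend tracks GM volume; the invariant
  `focality75 ≤ 25% · GM volume + one element volume` holds by
  construction. (A fraction-of-peak threshold would give much smaller
  absolute volumes; we implement the percentile contract and note the
  ambiguity.)
* Global predictors — relative tissue volumes per the ratio
  tissue volume / TIV, with TIV defined as the inner-skull contents
  (CSF + GM + WM + ventricle), so the four relative volumes partition 1.
  TIV has no universal definition; this one makes the partition exact.
* Local predictors — scalp, skull and CSF thickness under each electrode,
  measured by casting a ray from the scalp point under the electrode center
  toward the head center and intersecting the tissue-interface facets; the
  electrode-to-cortex distance is their sum by definition. On exact layered
  spheres the ray-cast values equal the generating thicknesses, which the
  tests exploit as a two-implementation cross-check.

## Statistical layer

Decade bins follow the integer part of age (18–20, 21–30, …, 81–88; a
boundary age such as 21.0 joins the bin whose printed range starts at 21).
Group summaries are mean ± SE with normal 95% intervals. Two-sample t-tests
are pooled-variance by default (Welch by flag) with fixed conventions for
degenerate zero-variance inputs. No multiple-testing correction is applied
anywhere; α = 0.05 throughout — matching the analysis design this package
reproduces.

The regression layer z-scores outcome and predictors, drops linearly
dependent columns by pivoted QR (tolerance 1e-10, recorded per fit), fits
OLS with intercept, and removes the least significant predictor while any
p > α, refitting each step. "Standardized coefficients" is interpreted as
coefficients of the z-scored fit. The procedure is fully deterministic,
including tie-breaks (largest p, then column order); its trace records each
elimination, and all predictors may be eliminated (an empty model is a
valid outcome). A planted-model simulation (n = 80, 10 predictors, 3
active at standardized 0.5, unit noise, 200 seeds) retains every active
predictor in ≥ 90% of runs and each inactive in ≤ 10%.

Trend shapes are classified strictly (relative tolerance 1e-9): U-shaped
means the minimum sits at an interior (or penultimate) decade with both
endpoints above it; applied to the published per-decade F3-F4 amplitude
means, the classifier returns U-shaped with the dip in the 71–80 decade.

## Numerical choices and degenerate inputs

* Meshes are built by radially stacking a geodesic sphere into prisms and
  splitting each prism with the monotone-staircase rule keyed on global
  vertex indices, which makes adjacent prisms conforming by construction;
  the innermost gap closes with a tetrahedral fan. Inverted elements are
  repaired by a node swap at construction/read time.
* Every layer receives at least one radial element (`ceiling(thickness/h)`
  sublayers), so thin noisy layers never vanish; the WM core is radially
  coarsened (default 3×) where the field varies slowly.
* Electrode caps must contain ≥ 20 boundary facets, otherwise placement
  errors out as under-resolved; overlapping caps are rejected.
* The solver refuses unbalanced loads (net injected current must vanish)
  and reports non-convergence with diagnostics instead of returning a bad
  field.
* MSH interchange is fixed at ASCII v2.2 (the widest-read dialect); v4
  files are rejected explicitly rather than partially parsed.

## Problem sizes used in the shipped checks

The validation suite runs the oracle comparison at 5.5 × 10⁴ / 1.0 × 10⁵ /
4.2 × 10⁵ tets, the cohort reproduction at 8 bins × 20 subjects × 4
montages at the smoke resolution (~6 × 10⁴ tets per head; one stiffness
factorization per subject reused across its four montage solves), the
planted-regression study at 200 seeds, and the t-test calibration at 2000
null replicates. These sizes were chosen so the full chain — including the
end-to-end cohort — completes on a single CPU in minutes while leaving the
qualitative claims decisively outside noise.

## Known limitations

Spherical geometry degenerates some contrasts (montage mirror pairs
coincide; anode/cathode thickness predictors are exactly collinear);
focality follows the percentile-threshold contract discussed above; the
oracle assumes isotropic layers, so anisotropic runs are checked by
conservation and limit properties rather than against the series; and the
cohort findings are reproductions of qualitative shapes under a generator
that encodes those shapes' anatomical drivers — they validate the method
chain, not the anatomy itself.
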