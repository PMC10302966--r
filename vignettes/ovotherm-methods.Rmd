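---
title: "Models and methods behind ovotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ovotherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ovotherm` measures egg freshness from active thermography of the blunt
end. This vignette explains the physical and statistical models the
package implements, the conventions and tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The physical picture

The egg's air cell grows as the egg ages; its height (ACH) is a standard
freshness indicator alongside the Haugh unit (HU). After a short hot-air
pulse on the blunt end, the shell above the air cell warms faster than the
shell above albumen: the air pocket beneath has a thermal conductivity
roughly 25 times lower and a volumetric heat capacity three to four orders
of magnitude lower, so the jet's heat accumulates in the thin shell skin
instead of diffusing inward. A thermal camera therefore sees a hot
elliptical patch whose geometry encodes the air cell.

## Egg and air-cell geometry

The egg profile is the curve
\(x^2/a^2 + y^2/(b + x\tan\theta)^2 = 1\), rotated about its long axis;
`a` and `b` are the long- and short-axis radii (defaults 28.435 mm and
21.89 mm) and \(\theta\) the shape angle (10°). The blunt end sits at
`x = +a`, where the profile is widest.

The blunt crown is modeled as the sphere through the blunt tip and the
equatorial circle, `R = (a² + b²)/(2a)` (`blunt_crown_radius()`); between
equator and tip this sphere lies inside the egg solid, which keeps the
spherical-cap air cell inside the egg at every height used here. The
membrane is a chord circle of radius `Ra` at perpendicular distance
`R − h` from the sphere center, tilted by `α` against the equatorial
plane; `h` is the ACH measured perpendicular to the membrane, so
`h = R − √(R² − Ra²)`.

Orthogonal projection onto the equatorial plane maps the membrane circle
to an ellipse with long semi-axis `Ra` (the in-plane direction is
preserved) and short semi-axis `Rb = Ra cos α`; the ellipse center sits at
`√(R² − Ra²)·sin α` from the egg axis. Writing `xB` for the horizontal
coordinate of the projected membrane endpoint on the tilt side, the
distance from sphere center to membrane plane is
\(D = R_a\,(x_B - R_b)/\sqrt{R_a^2 - R_b^2}\), and

\[h = \sqrt{D^2 + R_a^2} - D .\]

The crown radius cancels — the ACH is recoverable from the projected
ellipse alone. This inversion was derived symbolically from the chord
construction and is validated in the test suite against an explicit 3D
point-cloud oracle (`aircell_oracle_construct()`); the round trip
`estimate_ach(forward_project(cell))` reproduces `h` to better than
10⁻⁶ mm across tilts of 1–60°. When `Ra − Rb < 10⁻⁶·Ra` the division is
degenerate (horizontal membrane) and the spherical-cap formula is used
instead, which requires `R` explicitly; the package then demands it
rather than guessing.

All angles are degrees at the API surface and radians internally.

## The conduction simulator

`simulate_conduction()` integrates axisymmetric transient conduction
\(\rho c\,\partial T/\partial t = \nabla\!\cdot\!(k\nabla T)\) with
backward-Euler (unconditionally stable) time stepping on a structured
finite-volume grid, factorizing the constant system matrix once per run.
Convective (Robin) boundaries couple the jet patch to the hot air and the
rest of the surface to ambient. Radiation and internal flow are neglected
and properties are temperature-independent; shell, air cell and albumen
use fixed `k`, `c`, `ρ` values (`egg_material_properties()`).

Conventions and defaults that matter:

- **Jet coupling.** The jet's convective coefficient is not derivable
  from the imaging setup, so it is a configuration parameter:
  `h_jet = 60 W/(m²K)` (typical for mild air impingement) over a polar cap
  of 60° from the blunt tip, `h_ambient = 5 W/(m²K)` and ambient at the
  10 °C initial temperature elsewhere. Absolute temperature differences
  therefore carry the uncertainty of `h_jet`; orderings, onset behavior
  and contrasts are the robust outputs.
- **Geometry representation.** The egg cross-section is rasterized on a
  uniform grid (default 0.5 mm; 0.25 mm for quantitative work). Because
  the 0.35 mm shell is thinner than practical cells, each cell is
  subsampled 4×4: per-cell heat capacity is the exact sub-cell material
  mix (partial boundary cells donate their mass to the nearest solid
  cell, conserving total thermal mass), directional effective
  conductivities use series/parallel homogenization, and the convective
  boundary applies the true revolved surface area per boundary cell
  rather than staircase face areas. These choices are what make probe
  temperatures converge under grid halving (≤1% at 2 s for probes placed
  away from material interfaces; a probe inside the one-cell
  neighbourhood of the shell/air kink remains first-order and should not
  be used for convergence claims).
- **Air cell under the shell.** The air cap is cut from the crown sphere
  of the shell's *inner* surface (profile shrunk by the shell thickness),
  so the shell band always covers it; the rasterized cap volume matches
  the analytic `πh²(3Rᵢ − h)/3` within a fraction of a percent.
- **Tilted cells.** A tilted membrane breaks axisymmetry. The map
  rasterizes the tilt-plane cross-section and the solver still treats
  `|x|` as the cylindrical radius — a deliberate approximation adequate
  for qualitative tilted-cell comparisons, not for quantitative 3D
  fields.
- **Verification.** The solver is checked against the 1D semi-infinite
  convective-boundary solution (erfc form) on a homogeneous slab
  (≤2% of the excitation range; measured ~0.02%), the maximum principle,
  equilibrium and steady-state limits, and grid-convergence of probe
  temperatures.

Simulated fields reproduce the mechanism: air-cell-backed surface heats
faster than albumen-backed surface, the contrast grows over the 10 s
window, appears within tenths of a second at the default jet, and
strengthens with `h_jet`.

## Synthetic thermal video

`render_thermal_video()` renders what the camera pipeline consumes:
pseudo-colored 8-bit RGB frames of the blunt end viewed pole-on, with
exact ground truth. The temperature-to-color mapping is a fixed
piecewise-linear palette (blue → cyan → green → yellow → orange → red)
over a fixed 0–50 °C display range; the numeric stops are part of the
package contract (`thermal_colormap()`), which makes the "blue = egg" and
"red = hot" heuristics of the extraction route well-posed. The scene has
a cool egg body (10 °C) against a warmer background (28 °C), a warm halo
band decaying outside the silhouette (peak 33 °C), and during heating an
elliptical hot region at the projected membrane position whose edge
temperature (40 °C) maps safely above the red-segmentation threshold
(~36.8 °C on the canonical palette) with a steep sub-pixel skirt outside,
so the segmented region equals the geometric ellipse to rasterization
accuracy. The heating schedule is three-phase — unheated frames, a linear
amplitude ramp while heating, exponential decay while cooling — so the
maximum-area frame is the heating-stop frame, as the extraction logic
assumes. All randomness (sensor noise) flows from one scene seed.

What it does *not* emulate: radiometric camera response, auto-scaling
palettes, fixed-pattern noise, egg motion, specular reflections, halo
asymmetries, or shell-color/cleanliness effects. Passing tests on
synthetic video therefore demonstrate the correctness of the geometry and
of the extraction chain, not robustness to real-camera artifacts — the
RGB thresholds (`hot_rgb_thresholds()`: `R ≥ 180`,
`R − max(G,B) ≥ 40`) are exposed precisely because real palettes differ.

`sample_feature_table()` draws labeled per-grade Gaussian clusters in
λ1- or λ2-shaped feature space; `separation` scales the distance between
class means (6 gives a Bayes error well under 1%, 0 gives
indistinguishable classes), and `structure = "radial"` places grades on
concentric rings — separable by an RBF kernel but not a linear one. HU
values are drawn per grade consistently with the grading cutoffs.

## Feature extraction

**Edge route (λ1).** On an unheated reference frame (default: the first),
the B channel is binarized with Otsu's threshold — the cool egg is the
most-blue region — the largest 8-connected component is kept, Canny edge
points are extracted (Gaussian blur σ 1.4, gradient non-maximum
suppression, two-threshold hysteresis) and an algebraic (Kåsa)
least-squares circle gives `(x_egg, y_egg, r)`. Per frame, the RGB hot
thresholds applied inside the dilated egg disk (3 px) give the hot
region; the frame with the largest region is selected (ties to the
earliest), its mask boundary is fitted with the direct least-squares
conic method constrained to ellipses (Halir–Flusser formulation, solved
via the centered conic's 2×2 eigen decomposition), and `(x_cell, y_cell,
Lm, Ls, θc)` complete the eight-vector. `Lm`/`Ls` are full axis lengths;
`θc` is the major-axis angle to the image horizontal in (−90°, 90°],
reported but unstable when the ellipse is near-circular. Boundary pixel
centers sit about half a pixel inside the true contour, so the fitted
axes carry a +1 px compensation. Pixel coordinates are 1-based at pixel
centers, x rightward, y downward. On noise-free synthetic video every λ1
entry is recovered within 2% or 2 px, and horizontal flips transform the
vector exactly as the geometry dictates.

**Mask route (λ2).** From a 3-class label mask (0 background, 1 eggshell,
2 egg air cell; the egg domain is the union of 1 and 2, matching how the
labeling treats the whole egg as one region), the largest 8-connected
components give centroids, pixel-count areas and marching-squares
perimeters; an isolated pixel has perimeter `2√2` by that convention. The
pair statistics are the centroid distance `d`, the centroid-line angle
reduced to (−90°, 90°] (0 for coincident centroids), and the area and
perimeter ratios `PS`, `PC`. Texture comes from a gray-level
co-occurrence matrix over the egg-domain luminance (Rec. 601 weights),
with 8 gray levels by uniform quantization of the domain intensity range,
distance-1 offsets at 0°, 45°, 90° and 135°, symmetrized and pooled
before normalization — pooling removes orientation sensitivity, so
90°-rotations leave the texture features unchanged. Contrast,
correlation, entropy (log base 2; `0·log 0 = 0`) and angular second
moment follow the standard definitions; correlation is flagged `NA` when
a marginal variance vanishes (e.g. constant images, which give CON = 0,
ENT = 0, ASM = 1). Every statistic is tested against exhaustive
pixel/pair enumeration on ≤16×16 images. Frame selection takes the mask
with the most air-cell pixels within 50 frames of the heating stop —
"largest area" rather than "highest intensity", consistent with the edge
route's peak rule.

The mask route accepts masks from any segmenter; the package itself does
not train one. Its color-threshold segmenter and ground-truth masks both
satisfy the contract.

## Grading and classification

HU-to-grade cutoffs default to the USDA convention (AA ≥ 72, A ≥ 60,
B ≥ 31, else C), with boundaries belonging to the higher grade; they are
configurable because grading protocols differ. Features are min–max
normalized with parameters fitted on training rows only (test values may
leave [0, 1]); constant columns map to 0 with a warning. The five
classifiers use the field-standard implementations: Gaussian naive Bayes
and C-SVC SVM from `e1071` (one-vs-one multi-class; RBF kernel with
`C = 111.4305`, `γ = 0.5743` by default), `class::knn` (Euclidean,
`k = 3`, selectable by stratified 5-fold cross-validation with ties to
the smallest k), `rpart` trees, and `randomForest` with 100 trees and
minimum node size 5 — "5 leaf nodes" interpreted as the minimum leaf
size. All stochastic fits are seeded; KNN and naive Bayes predictions are
invariant to training-row order. Evaluation produces a per-grade
sample/correct table whose overall accuracy is `100·Σcorrect/Σn`;
`split_dataset()` stratifies by grade (0.75 reproduces a 3:1
train:validation split, 0.8 a 4:1 split).

On the separable synthetic benchmark both random forest and RBF-SVM hold
≥95% held-out accuracy across 20 seeded replicates, zero separation gives
chance-level (~25%) accuracy, and the radial benchmark orders RBF above
linear kernels. These establish that the pipeline's modeling layer is
wired correctly; they say nothing about accuracy on real eggs, which
depends on data the synthetic tables do not emulate.

## Problem sizes and interfaces

The shipped tests run the solver at 0.5 mm for property checks and
0.25 mm/0.125 mm for the convergence pair, render 220×180 px videos of
~20 frames, and use feature tables of 120–240 rows — sizes chosen so the
whole suite completes in well under a minute while every check remains
informative at its stated tolerance. The command-line wrapper
(`inst/exec/ovotherm`, or `ovotherm_run()` programmatically) exposes
synthesis, simulation, both extraction routes, training, evaluation,
grading and a `pipeline` smoke run; configurations are schema-validated
YAML (unknown keys rejected), frames are 8-bit PNG, masks grayscale PNG
with literal labels 0/1/2, feature tables CSV with 17-significant-digit
serialization so doubles round-trip bit-identically, and every run logs
the package version, seed and a configuration hash.

## Known limitations

- The tilted-cell simulation is an axisymmetric approximation of a 3D
  configuration.
- Absolute simulated temperature differences inherit the uncertainty of
  the convective coefficients; only orderings and trends are calibrated.
- The λ1 route assumes one egg per frame and a palette on which the egg
  is the most-blue region and the heated cell the most-red.
- Probe-based convergence statements exclude points within one grid cell
  of a material interface, where point sampling of the kinked temperature
  profile is first-order by nature.
- Classifier benchmarks are synthetic; hyperparameter defaults are taken
  as given, not re-tuned.
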