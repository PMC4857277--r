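---
title: "Reconstructing the necrotic-core backside and computing peak cap stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the necrotic-core backside and computing peak cap stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqrecon)
```

## The problem

Peak cap stress (PCS) — the maximum von Mises stress in the fibrous cap of a
coronary atherosclerotic plaque at systolic pressure — is a candidate marker
of rupture risk, and computing it requires the full cross-sectional geometry
of the plaque. Intravascular optical imaging resolves the lumen, the cap and
the *front* side of the necrotic core (NC), but the lipid-rich core
attenuates light so strongly that its backside is invisible. `plaqrecon`
implements a reconstruction of that hidden backside from quantities that are
measurable on the front side alone, and a 2D finite-element (FE) pipeline
that quantifies how much the reconstruction perturbs the PCS relative to the
ground-truth geometry.

All geometry lives in a 2D Cartesian frame in millimetres; contours are
simple counter-clockwise polygons; angles are radians, counter-clockwise
from +x, measured about the **lumen center**, which this package defines as
the area centroid of the lumen polygon (a definition chosen for robustness
on eccentric lumens; the center of the largest inscribed circle is a
plausible alternative that we did not adopt because it is less stable under
vertex noise).

## Morphometry

For each NC the package casts rays from the lumen center to every NC
boundary vertex and keeps the vertices that are the *first* intersection of
their ray — the front side. Vertices sharing a ray (for example across an
exactly radial end edge) are resolved in favour of the nearer one. The
angular extent of the retained vertices is the **NC angle**; measurement
rays are placed at 25% / 50% / 75% of that span (the ±sidecap and midcap
sites). Along each site ray we measure:

* `capT` — lumen boundary to NC front (cap thickness),
* `IMT` — lumen boundary to the outer media border (intima-media thickness),
* `NCt` — first to last NC-boundary intersection (NC thickness),
* `rNCt = NCt / IMT` — the relative NC thickness, the quantity that is
  modelled and transferred between plaques.

The minimum cap thickness is searched on a dense angular grid (0.25°
steps) over the front span, not only at polygon vertices.

## Estimating rNCt where it cannot be measured

Two estimators are provided. The **group average** uses the cohort median
of midcap rNCt and the median of the pooled ±sidecap rNCt (packaged
constants 0.40 / 0.35 from the published cohort; when refit on an input
cohort, the medians are computed leave-one-plaque-out so a plaque never
informs its own reconstruction). The **plaque-specific** model is a linear
relation per site,

rNCt = β₀ + β_angle · (NC angle [rad]) + β_IMT · (IMT [µm]) + β_capT · (capT [µm]),

fitted by generalized estimating equations (GEE) with Gaussian errors,
identity link and an exchangeable working correlation across cross-sections
of the same artery, with the robust sandwich covariance. The package stores
the coefficients on the natural scale and prints ×1000 for comparability
with the published table; `published_coefficients()` carries the published
fits. The link and working structure are not stated in the source
publication; Gaussian-identity-exchangeable is the natural reading of a
linear model "corrected for correlation amongst cross-sections within an
artery", and both are configurable. The model r² is the squared Pearson
correlation between fitted and observed rNCt. Predictions outside (0, 1)
are clamped to [0.01, 0.95] and flagged — a package policy, since the
source is silent on out-of-range predictions.

## Reconstruction

Given the front polyline and an rNCt estimate per site, reconstruction
proceeds in four steps:

1. **Back points.** On each site ray the estimated absolute thickness
   rNCt × IMT is laid off radially behind the front hit.
2. **Edge arcs.** NCs have rounded edges, so a circular arc of radius
   0.14 × NC angle [rad] (in mm — the published coefficient's unit is not
   printed; millimetres per radian is the only reading at coronary scale)
   and 30° extent is attached at each front end. Its center comes from the
   published circle construction: circle 1 sits on the edge vertex; its
   first crossing of the cap boundary is the center of circle 2; of the two
   intersections of circles 1 and 2, the one farthest from the lumen center
   is the arc center. The construction circles' radii are not published;
   they default to the final arc radius. If the circles fail to intersect,
   a quarter-arc about a radially offset center is used and flagged in the
   result's provenance.
3. **Polynomial closure.** In a local frame whose abscissa is the chord
   between the two arc free ends, the unique quartic through the five
   closure points (two arc ends, three back points) is sampled densely —
   degree 4 because five interpolation conditions determine it; the
   source says only "polynomial". If the assembled polygon self-intersects,
   a quadratic (exact at the arc ends, least squares through the back
   points) is tried; then a polar-frame quartic (radius versus angle,
   floored just behind the front) which is simple by construction; finally
   a Clipper repair that keeps the dominant piece when only corner slivers
   are cut off. Each fallback is recorded. A few extreme tail geometries
   (millimetre-thick caps over sliver cores) can still fail; the pipeline
   logs them in a failure table rather than dropping them silently.
4. **Media clipping.** The polygon is intersected with the outer intima
   border shrunk inward by 10 µm, so a reconstruction that would touch the
   media keeps a small clearance, and the result is flagged
   `clipped_to_media`.

Geometric agreement with ground truth is scored by the Dice-type similarity
index SI = 2·|A∩B| / (|A|+|B|) and the area mismatch ΔA% = |A_rec−A_GT| /
A_GT × 100 (asymmetric by definition — normalized by the ground truth).

## The synthetic cohort

The histology cohort behind the published numbers is not deposited, so the
package ships a generator that emulates its printed statistics: log-normal
marginals whose location/scale are solved from each feature's median and
IQR (minimum cap thickness 0.20 mm, IQR 0.09–0.40; NC angle 54°, 35–75;
midcap capT/IMT/NCt 0.30/1.05/0.46 mm; sidecap 0.31/1.03/0.36 mm), a
shared per-artery Gaussian latent effect giving within-artery correlation
ρ (default 0.3 — the source quantifies none, but the GEE needs clustered
data to be meaningful), and 1–2 NCs per section with the published 21/52
two-NC frequency. Cross-sections are built as radial profiles about the
lumen center: smooth angular splines through the three site values, an
elliptically tapered NC band (rounded ends), an optional narrow cap dip
that realizes the minimum-cap-thickness draw, and a 20 µm NC thickness
floor that keeps front and back polylines separated after feasibility
clamping. The generator reproduces the configured site values exactly (to
vertex discretization) on idealized specs and the cohort medians in
distribution.

What it does **not** emulate: imaging physics (speckle, attenuation),
segmentation error, non-star-shaped lumens or cores, longitudinal
correlation along an artery beyond the exchangeable latent effect, and the
exact empirical shape variety of 73 histology cores. Passing tests on this
cohort therefore demonstrate correctness and internal ordering of the
methods, not clinical-scale accuracy.

## Wall stress

The FE model is a true 2D plane-strain idealization of the cross-section —
the mechanical idealization a thin extruded slab with constrained faces
realizes, at desk-scale cost. Materials are nearly incompressible
neo-Hookean solids, W = C10(Ī₁−3) + (1/D1)(J−1)², with the published
constants (intima C10 = 166.7 kPa, media+adventitia 250, NC 1, all
D1 = 10⁻⁵ kPa⁻¹; buffer C10 = 10 kPa, D1 = 0.02 — where the buffer's
printed ν and D1 disagree, the C10/D1 pair is taken as authoritative).
A soft compressible buffer ring (thickness 50% of the mean adventitia
radius by default; the source gives none) surrounds the adventitia and its
outer edge is fixed, restraining rigid-body motion without stiffening the
wall.

**Meshing.** The mesh is a boundary-conforming structured polar grid: one
radial node column per angular station, snapped to every interface (lumen,
NC front/back, outer intima, media, adventitia, buffer edge), with fixed
layer counts per band — seven across the cap, honouring the published
resolution rule — and each quad split into four triangles about its
centroid. The criss-cross split is deliberate: its divergence-free
piecewise-linear subspace is rich enough that linear triangles do not
volumetrically lock at D1 = 10⁻⁵. The volumetric penalty still admits a
checkerboard hydrostatic mode on such patches, so reported stresses
patch-average the hydrostatic component over each quad; von Mises is purely
deviatoric and unaffected. Rays that cross an NC thinner than 20 µm treat
it as absent, so NC tips are approximated within one angular step. The
mesh is valid for star-shaped sections (every boundary crossed once per
ray), which both the generator and the reconstruction guarantee.

**Solution.** Follower pressure acts on the deformed lumen boundary
(consistent load stiffness included, making the tangent slightly
nonsymmetric; the sparse LU in Matrix handles it). Newton iteration with
backtracking line search and adaptive load stepping converges to a 10⁻⁸
relative residual. Verification: the homogeneous ring matches the Lamé
thick-wall solution within 2% at the default resolution, displacements halve
when all stiffnesses double at small load, and a rigid rotation of the whole
section leaves the von Mises field unchanged to discretization error.

**Prestress.** Because imaged (or pressure-fixed histological) geometry is
the configuration at ~100 mmHg, the unloaded configuration is recovered by
the backward-incremental fixed point X ← X − λ(x(X) − x*), with Aitken
adaptation of λ, convergence at a 1 µm maximum node mismatch, and an
accept-with-flag rule when the iteration stalls on a small residual floor
(below 10 µm) that a few thin-cap geometries exhibit. Systolic loading to
140 mmHg (100 mmHg = 13.332 kPa, 140 mmHg = 18.666 kPa) then starts from
the unloaded configuration. Every PCS records whether prestress was applied.

**PCS.** The peak von Mises stress is searched over the cap (intima
elements radially between lumen and NC front, within the NC angular span)
and the two shoulders (intima within 15° beyond either end of the span,
full intima depth — the wedge reading of the published region sketch).
Location shifts between ground-truth and reconstructed peaks are classified
as colocalized (below a 50 µm threshold — a declared surrogate for the
published visual inspection, sitting an order of magnitude above the
colocalized median distance reported there and an order below the shifted
ones), side-to-side, same-side, or lumen↔NC-front translocation; the
distance is straight-line Euclidean.

## Problem sizes and numerical defaults

Defaults were chosen once for desk-scale reproducibility: 512-vertex
contours for idealized fixtures and 192–256 for sampled cohorts; mesh
resolution `n_theta = 96` with 7/4/2/3/2/3 radial layers for single-section
studies, and a coarser 72-column, 3/1/2/1/2-layer variant for cohort sweeps;
the end-to-end comparison runs 30 sections with group-average and
oracle-rNCt stress solves and no prestress (the prestress round trip is
verified separately on fixtures). The test suite asserts the method
ordering the full-scale study reports — plaque-specific ≥ group-average in
median SI, and oracle-rNCt below group-average in median PCS error — rather
than its cohort-level numbers, which depend on the undeposited histology.

## Known limitations

* Star-shaped geometry is assumed throughout (visibility, meshing).
* Constant-strain triangles with a penalty formulation are first-order;
  absolute PCS values carry discretization error that cancels in the
  paired ground-truth/reconstruction comparisons the pipeline reports.
* The backside closure can fail on extreme tail geometries (~3% of sampled
  sections at default settings); failures are logged, never imputed.
* Anisotropy, fibre dispersion, residual stress beyond pressure prestress,
  3D effects and fluid–structure interaction are out of scope.
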