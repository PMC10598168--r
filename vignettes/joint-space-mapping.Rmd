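---
title: "Joint space mapping: models, parameters, and design choices"
author: "jsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint space mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsmap)
```

## The measurement problem

Joint space width (JSW) — the distance between two opposing subchondral
bone surfaces — is the standard imaging surrogate for cartilage thickness
and osteoarthritis severity. Measured at a handful of hand-picked
locations it hides most of the information a 3-D acquisition contains;
measured naively between segmented meshes it inherits every segmentation
error and is blurred by the scanner's point spread function (PSF), which
at weight-bearing CT resolutions (0.37 mm isotropic voxels) is on the
order of the joint space itself.

`jsmap` implements the alternative: *joint space mapping*. JSW is
estimated at every vertex of an articular surface patch directly from the
image intensities, by fitting a physical model of a blurred two-edge
profile along the surface normal, and the resulting per-vertex maps are
carried through registration to a template and into vertex-wise
statistics — Bland–Altman reproducibility and repeatability maps, and
statistical parametric mapping (SPM) of JSW against a covariate such as
joint angulation.

## The measurement chain

1. **Shadow casting** (`castShadow`). A vertex of the reference bone
   belongs to an articular patch if the ray along its outward normal hits
   the opposing bone within `tMax` (default 6 mm). This delimits the
   articulating region without any cartilage segmentation. Patches are the
   intersection of this shadow with a (possibly operator-drawn) perimeter
   mask, extracted as the largest edge-connected submesh
   (`patchSubmesh`).

2. **Profile extraction** (`extractProfile`). Intensities are sampled by
   trilinear interpolation along the normal ray at a uniform `step`
   (default 0.1 mm), from `back` (4 mm) behind the vertex to `forward`
   (`tMax` + 4 mm) beyond it; `mapJSW` clamps the window per vertex to the
   volume bounds.

3. **Blurred two-edge model fit** (`fitBlurModel`). The profile is
   modelled as
   $$y(t) = b + (A_1 - b)\,\Phi\!\left(\frac{e_1 - t}{s}\right)
              + (A_2 - b)\,\Phi\!\left(\frac{t - e_2}{s}\right),$$
   two Gaussian-blurred steps with common blur SD $s$, background $b$, and
   plateau intensities $A_1, A_2$; $\mathrm{JSW} = e_2 - e_1$. The fit is
   bounded Levenberg–Marquardt, parameterised by edge midpoint and
   non-negative half-width so $e_1 \le e_2$ holds by construction, with
   $s$ confined to `psfBounds` (default 0.2–1.5 mm). Initial values come
   from the extrema of a smoothed derivative of the profile. Because each
   cortical shell is finite, the profile is truncated at the two plateau
   peaks flanking the gap before fitting, so the far sides of the bones
   cannot distort the edge estimates. A profile with no second intensity
   rise is flagged `no_opposing_edge` and its vertex masked — this is what
   happens at patch margins, where the method is least reliable.

4. **Map assembly and smoothing** (`mapJSW`, `smoothField`). Failed fits
   are masked; the JSW field is then smoothed by iterated masked umbrella
   (1-ring) averaging, default 5 iterations at weight 0.5. Smoothing is
   applied on the native patch, before registration.

5. **Template transfer** (`icpRigid`, `transferField`). Point-to-point
   ICP with a Kabsch (SVD) update aligns each subject patch to the
   template; each template vertex then takes the barycentric
   interpolation of the field at its closest point on the registered
   source surface, masked beyond a 2 mm cutoff.

6. **Statistics** (`blandAltmanMap`, `spmFMap`, `pairedT`,
   `sagittalAngle`). Agreement between paired map sets is summarised
   vertex-wise as bias (mean difference) and 95 % limits of agreement
   (1.96 × the n−1 SD of differences). The angulation analysis fits, per
   vertex, JSW = β₀ + β₁·angle and tests β₁ with an F statistic (1, n−2),
   controlling the family-wise error rate by max-statistic permutation of
   the covariate.

## Why the background must be anchored for sub-voxel gaps

When the gap falls below the blur width the two edges overlap and the
intensity dip no longer reaches the true background. In that regime the
residual surface of the six-parameter fit has a nearly flat valley along
which the background level trades off against the gap width: widening the
estimated gap while raising the estimated background reproduces almost
the same dip. Under realistic noise the free-background fit therefore
lands anywhere along the valley, while fixing the background restores
sharp identifiability (the package's tests demonstrate both behaviours).
`mapJSW` consequently estimates the soft-tissue background once per
volume — the median intensity below the midpoint of the intensity range —
and anchors every profile fit with it (`background = "auto"`). The
standalone `fitBlurModel` defaults to a free background, which is the
right choice for well-separated edges and satisfies exact parameter
recovery on noiseless model data.

## The synthetic phantom cohort

No public weight-bearing CT dataset accompanies the methodology, so the
package ships a first-class generator whose defaults *are* the study
conditions it is validated under:

- **Geometry** (`makeJointPhantom`): a reference articular surface
  (parallel slab, spherical cap, or saddle; 20 mm extent, 1 mm mesh
  resolution) is offset along its vertex normals by a prescribed gap
  field g(u,v) and both surfaces are thickened into closed cortical
  bodies (2.5 mm shells). Offsetting along normals makes ground-truth
  correspondence exact by construction, so the statistics layer can be
  validated without confounding it with registration error.
- **Gap fields**: constant, linear ramp (default 1.9 → 2.9 mm,
  bracketing the range reported for ankle facets), radial bump, or
  arbitrary per-vertex values.
- **Imaging** (`rasterizeCT`): occupancy of the closed bodies is sampled
  on a 3× supersampled grid and box-averaged, so edge voxels carry
  partial-volume fractions as in a real reconstruction, then convolved
  with an isotropic Gaussian PSF (default σ = 0.5 mm, the order of the
  0.37 mm voxel) and degraded with i.i.d. Gaussian noise (default SD 20
  on a 0–1000 HU-like scale). Purely binary occupancy
  (`supersample = 1`) quantizes both bone edges to the voxel grid and
  biases JSW by up to half a voxel; partial volume removes that artefact
  and is the physically correct model. The scanner's true noise and PSF
  figures are not published, so these defaults are stated assumptions,
  exposed as parameters.
- **Cohorts** (`simulateCohort`): per subject, a smooth random gap
  modulation (SD 0.3 mm) plus an angulation effect
  `effectMap × (angle − mean angle)`; per visit, a fresh noise
  realisation and a small random pose change (≤ 2°, ≤ 0.5 mm); per
  operator, a jittered patch perimeter (`perturbPerimeter`, RMS 1 mm).
  Subject angles default to SD 9°. Sub-seeds are derived per (subject,
  visit, operator), so enlarging a cohort never changes earlier
  subjects' draws.

What the phantom does *not* emulate: trabecular texture, beam hardening
and metal artefacts, scanner-specific reconstruction kernels, true
anatomical shape variation, and non-rigid inter-subject correspondence.
Passing tests on these phantoms therefore demonstrates that the
measurement and statistics machinery is unbiased and calibrated under its
own model assumptions — not that the pipeline is robust to everything a
clinical WBCT can contain.

## Numerical and design choices

- **Vertex indexing** is 1-based in memory (the R idiom); PLY/OBJ/VTK
  files are read and written 0-based per those formats.
- **Smoothing operator**: iterated masked umbrella averaging was chosen
  for its fixed points (constants), mesh-resolution awareness and exact
  testability; weight 0 is the identity, and on a closed connected mesh
  iteration converges to a constant.
- **Patch means** use one-third face-area lumping (barycentric vertex
  areas), robust on irregular triangulations.
- **Ray direction** is the reference vertex normal, not the
  nearest-point direction — deterministic and faithful to the shadow
  geometry. Where several intersections exist the nearest positive hit
  wins.
- **Registration** is rigid only. Synthetic cohorts have exact
  correspondence, so rigid ICP plus closest-point transfer suffices to
  validate the statistics; non-rigid matching for real anatomy is an
  extension point, and the template for synthetic cohorts is simply the
  generating base mesh.
- **Bland–Altman patch summaries** reduce each subject's map to an
  area-weighted patch mean first and apply Bland–Altman to those scalars
  (the headline values); the area-weighted surface averages of the
  vertex-wise bias and LOA fields are also reported, since "surface
  averaged" agreement admits both readings.
- **SPM correction** is max-statistic permutation of the covariate with
  the observed statistic included in the null (p ≥ 1/(B+1) by
  construction; B defaults to 999, the pipeline demo uses 199). The
  permutation scheme is exactly testable for family-wise error control,
  which a random-field approximation is not.
- **Sagittal plane** for the landmark angle defaults to the plane
  orthogonal to the x axis (scanner left–right); configurable.
- **Pipeline configs** are plain YAML; runs write every artefact with an
  md5 checksum into a manifest, and deterministic stages reproduce their
  checksums on rerun.

## Problem sizes used in validation

The test-suite and acceptance phantoms use 20 mm patches at 1 mm mesh
resolution (441 vertices) rasterized at the full 0.37 mm study
resolution; the sharp-limit oracle comparison uses a 0.12 mm grid. SPM
calibration uses 500 null cohorts and 100 effect cohorts of 23 subjects ×
500 vertices at 199 permutations; Bland–Altman calibration uses 200
simulated two-visit cohorts. These sizes keep a full validation run in
the low tens of seconds on one CPU while leaving Monte-Carlo error well
below the tolerances being checked.

## Known limitations

- The blur model assumes a single gap along the ray; triple-edge
  configurations (e.g. a sesamoid in the space) are not modelled and
  will be masked or mis-fit.
- Background anchoring assumes a reasonably uniform soft-tissue level
  across the joint space; strong local intensity gradients (metal
  artefact, contrast agent) violate it.
- Rigid-only registration limits real-data use to joints where a
  subject-specific template is available.
- The angle-measurement operation expects landmarks already identified;
  no automatic landmarking is provided.
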