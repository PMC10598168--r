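# jsmap — 3-D joint space mapping from CT-like volumes

`jsmap` measures **joint space width (JSW)** — the distance between two
opposing subchondral bone surfaces, the standard imaging surrogate for
cartilage thickness in osteoarthritis — at *every vertex* of an articular
surface patch, directly from image intensities. It is aimed at
musculoskeletal imaging researchers working with weight-bearing CT (or
any isotropic CT-like reconstruction) who need sub-voxel JSW maps
together with honest error statistics: inter-operator reproducibility,
test–retest repeatability, and covariate effects across a surface.

## The method in brief

For a reference bone mesh with outward vertex normals:

1. **Shadow casting** — a vertex is articulating if the ray along its
   normal hits the opposing bone within `tMax`; the shadow delimits the
   joint space patch.
2. **Blurred two-edge profile model** — intensities sampled along the
   normal are fitted with

   y(t) = b + (A₁ − b)·Φ((e₁ − t)/s) + (A₂ − b)·Φ((t − e₂)/s),

   two Gaussian-blurred bone edges with common blur SD `s` (bounded by
   the scanner PSF), background `b` and plateaus `A₁, A₂`;
   **JSW = e₂ − e₁**. Fitting edge *positions* rather than thresholding
   segmented surfaces is what makes the measurement sub-voxel.
3. **Template transfer** — rigid ICP plus closest-point barycentric
   interpolation brings per-subject maps onto shared template vertices.
4. **Statistics** — vertex-wise Bland–Altman bias and 95 % limits of
   agreement (1.96 × SD of paired differences), and an F-test
   statistical parametric map of JSW against a covariate (e.g.
   plantarflexion angle) with max-statistic permutation control of the
   family-wise error rate.

A first-class synthetic module (`makeJointPhantom`, `rasterizeCT`,
`simulateCohort`) builds articulating phantoms with exactly known gap
fields, rasterizes them with partial-volume occupancy, PSF blur and
noise, and simulates multi-visit, multi-operator cohorts — so every
claim the package makes about accuracy and calibration is checked
against ground truth.

## Worked example

```r
library(jsmap)

## a synthetic ankle-like facet: ramp gap 1.9 -> 2.9 mm over 20 mm,
## imaged at 0.37 mm isotropic voxels with PSF 0.5 mm and noise SD 20
ph  <- makeJointPhantom(phantomSpec(gapField = list(type = "ramp", from = 1.9, to = 2.9)))
vol <- rasterizeCT(ph, spacing = 0.37, psfSigma = 0.5, noiseSd = 20, seed = 7)

## articular patch = the shadow of the opposing bone on the reference surface
patch <- patchSubmesh(ph$reference, castShadow(ph$reference, ph$opposing, tMax = 4), "facet")

## per-vertex JSW from the blurred two-edge profile model
map <- mapJSW(vol, patch, ph$opposing, params = list(tMax = 4, back = 3))
map
#> JSWMap on patch 'facet': 441/441 valid vertices
#>   JSW mean 2.427 mm, range [1.950, 2.907]

truth <- ScalarField(ph$gap[patch@parentIndex])
sprintf("patch mean %.3f mm (truth %.3f); RMSE %.3f mm",
        patchMean(map@field, patch), patchMean(truth, patch),
        sqrt(mean((fieldValues(map)[fieldMask(map)] -
                   truth@values[fieldMask(map)])^2)))
#> "patch mean 2.426 mm (truth 2.400); RMSE 0.033 mm"
```

The measured map recovers the true ramp with a per-vertex RMSE of
0.033 mm — an order of magnitude below the 0.37 mm voxel — and a patch
mean within 0.03 mm of truth. Repeatability of two simulated visits
(per-vertex noise SD 0.1 mm, 23 subjects):

```r
v1 <- simulateMeasuredFields(ph$gap, 23, noiseSd = 0.1, seed = 1)
v2 <- simulateMeasuredFields(ph$gap, 23, noiseSd = 0.1, seed = 2)
blandAltmanMap(v1, v2, patch = patchSubmesh(ph$reference, rep(TRUE, nVertices(ph$reference))))
#> BlandAltmanMap
#>   patch-mean bias 0.002 mm, LOA 0.012 mm
#>   surface-average bias 0.002 mm, LOA 0.275 mm
```

The surface-average vertex LOA sits at the closed-form value
1.96·√2·0.1 ≈ 0.277 mm, while patch-mean LOA is far tighter — averaging
over the patch before comparing visits is exactly why patch summaries
are more repeatable than any single vertex.

An end-to-end run (simulate → measure → register → stats → report) is one
call — `runPipeline(defaultRunConfig())` — or from a shell via
`Rscript inst/scripts/jsmap.R demo --out run1`. Every artefact lands in
the output directory with an md5-checksummed manifest.

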