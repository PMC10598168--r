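test_that("constant-gap phantom separates the surfaces by exactly the gap", {
  ph <- makeJointPhantom(phantomSpec(gapField = list(type = "constant",
                                                     value = 2)))
  patch <- patchSubmesh(ph$reference, rep(TRUE, nVertices(ph$reference)))
  d <- fieldValues(rayDistanceOracle(patch, ph$opposing, tMax = 6))
  ok <- is.finite(d)
  expect_true(all(ok))
  expect_true(all(abs(d[ok] - 2) < 0.1))  # resolution/10 tolerance
})

test_that("ramp gap field hits the analytic midline value", {
  ph <- makeJointPhantom(phantomSpec(extent = 20,
    gapField = list(type = "ramp", from = 1.9, to = 2.9)))
  v <- vertices(ph$reference)
  mid <- which(abs(v[, 1]) < 1e-9)
  expect_true(all(abs(ph$gap[mid] - 2.4) < 0.01))
  expect_equal(range(ph$gap), c(1.9, 2.9))
})

test_that("non-positive gap fields are rejected", {
  expect_error(makeJointPhantom(phantomSpec(
    gapField = list(type = "constant", value = -1))), "positive")
  expect_error(makeJointPhantom(phantomSpec(
    gapField = list(type = "ramp", from = -0.5, to = 1))), "positive")
})

test_that("all phantom geometries produce watertight bodies and exact truth", {
  for (geom in c("parallel-slabs", "ball-and-socket", "saddle")) {
    ph <- makeJointPhantom(phantomSpec(geometry = geom, extent = 12,
      gapField = list(type = "constant", value = 2.2)))
    patch <- patchSubmesh(ph$reference, rep(TRUE, nVertices(ph$reference)))
    d <- fieldValues(rayDistanceOracle(patch, ph$opposing, tMax = 6))
    ok <- is.finite(d)
    expect_gt(mean(ok), 0.95)
    expect_lt(max(abs(d[ok] - ph$gap[ok])), 1e-6)
  }
})

test_that("noiseless sharp rasterization reproduces plateau intensities", {
  ph <- makeJointPhantom(phantomSpec(extent = 10))
  vol <- rasterizeCT(ph, spacing = 0.37, psfSigma = 0, noiseSd = 0,
                     supersample = 1)
  # voxel centred well inside the reference slab
  p <- c(0, 0, -1.2)
  idx <- round((p - vol@origin) / vol@spacing) + 1
  expect_identical(vol@intensities[idx[1], idx[2], idx[3]], 1000)
  # and well inside the gap
  g <- c(0, 0, 1.0)
  idx <- round((g - vol@origin) / vol@spacing) + 1
  expect_identical(vol@intensities[idx[1], idx[2], idx[3]], 0)
})

test_that("a blurred slab face follows the analytic Gaussian step", {
  ph <- makeJointPhantom(phantomSpec(extent = 8,
    gapField = list(type = "constant", value = 3)))
  # well-resolved sampling so the PSF dominates the edge spread
  vol <- rasterizeCT(ph, spacing = 0.12, psfSigma = 0.5, noiseSd = 0,
                     supersample = 3)
  prof <- extractProfile(vol, c(0.1, 0.2, 0), c(0, 0, 1),
                         back = 1.4, forward = 1.4, step = 0.05)
  t <- prof@positions
  model <- 1000 * pnorm((0 - t) / 0.5)
  expect_lt(max(abs(prof@intensities - model)), 0.02 * 1000)
})

test_that("rasterization is bit-identical for the same seed", {
  ph <- makeJointPhantom(phantomSpec(extent = 8))
  v1 <- rasterizeCT(ph, noiseSd = 20, seed = 11)
  v2 <- rasterizeCT(ph, noiseSd = 20, seed = 11)
  v3 <- rasterizeCT(ph, noiseSd = 20, seed = 12)
  expect_identical(v1@intensities, v2@intensities)
  expect_false(identical(v1@intensities, v3@intensities))
})

test_that("bone voxel volume matches the analytic body volume within 2%", {
  # tilt the slabs so their faces are not grid-aligned: voxel-centre
  # quantization then averages out across columns instead of hitting a
  # single worst-case grid phase
  a <- 15 * pi / 180; b <- 10 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3) %*%
       matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  ph <- makeJointPhantom(phantomSpec(extent = 14,
    gapField = list(type = "constant", value = 2),
    pose = RigidTransform(R, c(0, 0, 0))))
  vol <- rasterizeCT(ph, spacing = 0.37, psfSigma = 0, noiseSd = 0)
  boneVox <- sum(vol@intensities > 500)   # midpoint threshold
  measured <- boneVox * vol@spacing^3
  analytic <- 2 * 14 * 14 * 2.5          # two extent^2 x thickness slabs
  expect_lt(abs(measured - analytic) / analytic, 0.02)
})

test_that("perturbPerimeter is a seeded, magnitude-0-identity boundary jitter", {
  mesh <- gridMesh(20, 1)
  mask <- rowSums(vertices(mesh)[, 1:2]^2) < 10^2   # disc of radius 10
  expect_identical(perturbPerimeter(mask, mesh, 0, seed = 5), mask)
  p1 <- perturbPerimeter(mask, mesh, 1, seed = 5)
  p2 <- perturbPerimeter(mask, mesh, 1, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1, perturbPerimeter(mask, mesh, 1, seed = 6)))
  # vertices farther than 2 mm (geodesically) from the boundary stay put
  r <- sqrt(rowSums(vertices(mesh)[, 1:2]^2))
  deep <- which(abs(r - 10) > 2)
  expect_gte(mean(p1[deep] == mask[deep]), 0.9)
})

test_that("cohort simulation is deterministic and honours its contracts", {
  spec <- cohortSpec(nSubjects = 3, visitNoiseSd = 0,
                     visitPoseJitter = c(0, 0), perimeterJitter = 0,
                     betweenSubjectSd = 0.1,
                     gapBase = phantomSpec(extent = 8), seed = 2L)
  co <- simulateCohort(spec)
  # zero visit noise and zero pose jitter: per-subject visit volumes identical
  byVisit <- split(seq_along(co@records),
                   vapply(co@records, function(r) r$subject, 1))
  for (recs in byVisit) {
    vis <- vapply(co@records[recs], function(r) r$visit, 1)
    vols <- vapply(co@records[recs], function(r) r$volumeIndex, 1)
    expect_identical(co@volumes[[vols[vis == 1][1]]]@intensities,
                     co@volumes[[vols[vis == 2][1]]]@intensities)
  }
  co2 <- simulateCohort(spec)
  expect_identical(co@groundTruth, co2@groundTruth)
  expect_identical(co@volumes[[1]]@intensities, co2@volumes[[1]]@intensities)
  expect_error(
    cohortSpec(nSubjects = 3, angleValues = c(1, 2)),
    "angleValues")
})

test_that("ground-truth gap regresses onto angle with the exact slope", {
  beta <- 0.02
  spec <- cohortSpec(nSubjects = 6, betweenSubjectSd = 0, effectMap = beta,
                     gapBase = phantomSpec(extent = 8), seed = 3L)
  co <- simulateCohort(spec, rasterize = FALSE)
  ang <- co@covariates$angle_deg
  for (vtx in c(1, 10, 25)) {
    fit <- lm(co@groundTruth[vtx, ] ~ ang)
    expect_equal(unname(coef(fit)[2]), beta, tolerance = 1e-6)
  }
  # effectMap = 0: no angle relationship by construction
  spec0 <- cohortSpec(nSubjects = 6, betweenSubjectSd = 0, effectMap = 0,
                      gapBase = phantomSpec(extent = 8), seed = 3L)
  co0 <- simulateCohort(spec0, rasterize = FALSE)
  expect_equal(stats::sd(co0@groundTruth[1, ]), 0)
})
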