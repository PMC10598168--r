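flatPair <- function(gap = 2, extent = 10, res = 1) {
  ref <- gridMesh(extent, res)
  opp <- gridMesh(extent, res)
  ov <- vertices(opp)
  ov[, 3] <- ov[, 3] + gap
  opp <- SurfaceMesh(ov, faces(opp))
  list(ref = ref, opp = opp)
}

test_that("castShadow flags exactly the overlapped vertices", {
  fp <- flatPair(gap = 2)
  flags <- castShadow(fp$ref, fp$opp, tMax = 10)
  # every interior vertex of two aligned parallel patches is covered
  v <- vertices(fp$ref)
  interior <- abs(v[, 1]) < 5 - 1e-9 & abs(v[, 2]) < 5 - 1e-9
  expect_true(all(flags[interior]))
  # gap beyond tMax: nothing flagged
  expect_false(any(castShadow(fp$ref, fp$opp, tMax = 1)))
  # monotone in tMax
  f3 <- castShadow(fp$ref, fp$opp, tMax = 3)
  f6 <- castShadow(fp$ref, fp$opp, tMax = 6)
  expect_true(all(!f3 | f6))
})

test_that("castShadow of a shifted patch matches brute-force intersection", {
  fp <- flatPair(gap = 2, extent = 10)
  ov <- vertices(fp$opp)
  ov[, 1] <- ov[, 1] + 5   # shift by half its width
  opp <- SurfaceMesh(ov, faces(fp$opp))
  flags <- castShadow(fp$ref, opp, tMax = 10)
  v <- vertices(fp$ref); n <- meshNormals(fp$ref)
  expected <- vapply(seq_len(nrow(v)), function(i) {
    t <- oracleRayMesh(v[i, ], n[i, ], opp, tMax = 10)
    !is.na(t) && t > 0
  }, TRUE)
  expect_identical(flags, expected)
  expect_gt(sum(flags), 0)
  expect_lt(sum(flags), nrow(v))
})

test_that("degenerate normals mark vertices invalid without global failure", {
  fp <- flatPair()
  nrm <- meshNormals(fp$ref)
  nrm[5, ] <- NaN
  ref <- new("SurfaceMesh", vertices = vertices(fp$ref),
             faces = faces(fp$ref), normals = nrm)
  flags <- castShadow(ref, fp$opp, tMax = 10)
  expect_false(flags[5])
  expect_true(any(flags))
})

test_that("extractProfile samples exactly in constant and linear volumes", {
  arr <- array(7.5, c(30, 30, 30))
  vol <- VoxelVolume(arr, spacing = 0.5, origin = c(0, 0, 0))
  pr <- extractProfile(vol, c(7, 7, 7), c(0, 0, 1), back = 3, forward = 4,
                       step = 0.1)
  expect_true(all(pr@intensities == 7.5))
  # linear gradient: trilinear interpolation is exact for linear fields
  zs <- (seq_len(30) - 1) * 0.5
  grad <- array(rep(2 * zs + 1, each = 900), c(30, 30, 30))
  volg <- VoxelVolume(grad, spacing = 0.5, origin = c(0, 0, 0))
  prg <- extractProfile(volg, c(7, 7, 7), c(0, 0, 1), back = 3, forward = 4,
                        step = 0.1)
  expect_equal(prg@intensities, 2 * (7 + prg@positions) + 1,
               tolerance = 1e-10)
  # out of bounds: error names the endpoint
  expect_error(
    extractProfile(vol, c(7, 7, 14), c(0, 0, 1), back = 3, forward = 4,
                   step = 0.1),
    "out of bounds")
})

test_that("fitBlurModel recovers generating parameters on noiseless data", {
  t <- seq(0, 8, by = 0.1)
  pr <- modelProfile(t, b = 0, A1 = 1000, A2 = 1000, e1 = 3, e2 = 5, s = 0.5)
  ft <- fitBlurModel(pr)
  expect_true(ft@converged)
  expect_equal(ft@jsw, 2, tolerance = 0.01)
  expect_equal(ft@e1, 3, tolerance = 0.01)
  expect_equal(ft@e2, 5, tolerance = 0.01)
  expect_equal(ft@s, 0.5, tolerance = 0.01)
  expect_equal(ft@b, 0, tolerance = 1)
  expect_lt(ft@rmsResidual, 1e-3)
})

test_that("sub-voxel gaps are identifiable under noise", {
  t <- seq(0, 8, by = 0.1)
  # with the background anchored (as mapJSW does from the volume) the
  # 0.3 mm gap is recovered well below the sampling step
  errs <- vapply(1:100, function(s) {
    pr <- modelProfile(t, 0, 1000, 1000, e1 = 3, e2 = 3.3, s = 0.5,
                       noiseSd = 20, seed = s)
    ft <- fitBlurModel(pr, background = 0)
    if (ft@converged) abs(ft@jsw - 0.3) else NA_real_
  }, 1)
  expect_gt(mean(!is.na(errs)), 0.9)
  expect_lte(median(errs, na.rm = TRUE), 0.10)
  # independent dense grid search over the edge pair agrees
  pr <- modelProfile(t, 0, 1000, 1000, e1 = 3, e2 = 3.3, s = 0.5,
                     noiseSd = 20, seed = 1)
  e <- oracleEdgeGridSearch(pr@positions, pr@intensities, b = 0, A1 = 1000,
                            A2 = 1000, s = 0.5, eGrid = seq(2, 5, by = 0.02))
  expect_lt(abs((e[2] - e[1]) - 0.3), 0.1)
})

test_that("profiles without an opposing bone are flagged", {
  t <- seq(0, 8, by = 0.1)
  # A2 = b: single falling edge only
  y <- 1000 * pnorm((3 - t) / 0.5)
  ft <- fitBlurModel(Profile(t, y))
  expect_false(ft@converged)
  expect_equal(ft@status, "no_opposing_edge")
})

test_that("rayDistanceOracle handles flat, tilted and disjoint cases", {
  fp <- flatPair(gap = 2)
  patch <- patchSubmesh(fp$ref, rep(TRUE, nVertices(fp$ref)))
  m <- rayDistanceOracle(patch, fp$opp, tMax = 6)
  ok <- fieldMask(m)
  expect_true(all(abs(fieldValues(m)[ok] - 2) < 1e-9))
  # 45 degree tilted opposing plane: distance = gap / cos(45) along normal
  th <- pi / 4
  R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  big <- gridMesh(40, 1)
  bv <- vertices(big) %*% t(R)
  bv[, 3] <- bv[, 3] + 2
  opp45 <- SurfaceMesh(bv, faces(big))
  m45 <- rayDistanceOracle(patch, opp45, tMax = 10)
  ok45 <- fieldMask(m45)
  v <- vertices(patch)[ok45, , drop = FALSE]
  expected <- 2 + v[, 2] * tan(th)   # ray-plane: z = 2 + tan(th) * y
  expect_equal(fieldValues(m45)[ok45], expected, tolerance = 1e-9)
  # non-overlapping surfaces: fully masked
  far <- SurfaceMesh(vertices(fp$opp) + matrix(c(100, 0, 0), nVertices(fp$opp),
                                               3, byrow = TRUE),
                     faces(fp$opp))
  expect_false(any(fieldMask(rayDistanceOracle(patch, far, tMax = 6))))
})

test_that("patch-mean error stays below the voxel size across gap widths", {
  for (gap in c(1.0, 1.5, 2.5, 3.0)) {
    ph <- makeJointPhantom(phantomSpec(extent = 10,
      gapField = list(type = "constant", value = gap)))
    vol <- rasterizeCT(ph, spacing = 0.37, psfSigma = 0.5, noiseSd = 20,
                       seed = round(100 * gap))
    patch <- patchSubmesh(ph$reference, rep(TRUE, nVertices(ph$reference)))
    m <- suppressWarnings(
      mapJSW(vol, patch, ph$opposing, params = list(tMax = 4, back = 3)))
    expect_lt(abs(patchMean(m@field, patch) - gap), 0.37)
  }
})

test_that("image-based JSW matches ground truth at study imaging settings", {
  ph <- makeJointPhantom(phantomSpec(gapField = list(type = "constant",
                                                     value = 2)))
  vol <- rasterizeCT(ph, spacing = 0.37, psfSigma = 0.5, noiseSd = 20,
                     seed = 1)
  patch <- patchSubmesh(ph$reference, rep(TRUE, nVertices(ph$reference)))
  m <- mapJSW(vol, patch, ph$opposing, params = list(tMax = 4, back = 3))
  expect_equal(patchMean(m@field, patch), 2, tolerance = 0.10)
})

test_that("JSW maps are invariant under a common rigid transform", {
  spec0 <- phantomSpec(extent = 10,
                       gapField = list(type = "constant", value = 2.2))
  th <- 20 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3) %*%
       matrix(c(1, 0, 0, 0, cos(0.3), sin(0.3), 0, -sin(0.3), cos(0.3)), 3, 3)
  pose <- RigidTransform(R, c(3, -1, 2))
  specT <- phantomSpec(extent = 10,
                       gapField = list(type = "constant", value = 2.2),
                       pose = pose)
  pm <- vapply(list(spec0, specT), function(sp) {
    ph <- makeJointPhantom(sp)
    vol <- rasterizeCT(ph, psfSigma = 0.5, noiseSd = 0)
    patch <- patchSubmesh(ph$reference, rep(TRUE, nVertices(ph$reference)))
    m <- mapJSW(vol, patch, ph$opposing, params = list(tMax = 4, back = 3))
    patchMean(m@field, patch)
  }, 1)
  expect_equal(pm[1], pm[2], tolerance = 0.05)
})

test_that("mapJSW warns when most profile fits fail", {
  fp <- flatPair(gap = 2, extent = 6)
  patch <- patchSubmesh(fp$ref, rep(TRUE, nVertices(fp$ref)))
  # an empty (boneless) volume supports no fits at all
  arr <- array(0, c(40, 40, 40))
  vol <- VoxelVolume(arr, spacing = 0.5, origin = c(-10, -10, -10))
  expect_warning(mapJSW(vol, patch, fp$opp,
                        params = list(tMax = 4, back = 3)),
                 "fits failed")
})
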