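curvedMesh <- function(extent = 16, res = 1) {
  gridMesh(extent, res, zfun = function(x, y) 0.05 * (x^2 - y^2))
}

knownTransform <- function(deg = 5, trans = c(1, 2, 0.5)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  RigidTransform(R, trans)
}

rotationAngleDeg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

test_that("icpRigid returns the identity for identical surfaces", {
  m <- curvedMesh()
  tr <- icpRigid(m, m)
  expect_lt(max(abs(tr@rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tr@translation)), 1e-6)
})

test_that("icpRigid recovers a known 5 degree / (1,2,0.5) mm transform", {
  target <- curvedMesh()
  known <- knownTransform()
  # source = target moved by the inverse, so the forward transform is known
  Rt <- t(known@rotation)
  src <- applyTransform(target,
                        RigidTransform(Rt, -as.numeric(Rt %*%
                                                         known@translation)))
  rec <- icpRigid(src, target, maxIter = 100, tol = 1e-7)
  rotErr <- rotationAngleDeg(t(rec@rotation) %*% known@rotation)
  expect_lt(rotErr, 0.5)
  expect_lt(sqrt(sum((rec@translation - known@translation)^2)), 0.05)
  # composing with the known inverse moves no vertex more than 0.1 mm
  back <- applyTransform(applyTransform(src, rec),
                         RigidTransform(Rt, -as.numeric(Rt %*%
                                                          known@translation)))
  disp <- sqrt(rowSums((vertices(back) - vertices(src))^2))
  expect_lt(max(disp), 0.1)
})

test_that("icpRigid fails on surfaces that cannot overlap", {
  flat <- gridMesh(10, 1)
  ball <- icosphere(2, radius = 4, center = c(30, 0, 0))
  expect_error(icpRigid(ball, flat), "registration failed")
})

test_that("transferField is exact when source and template coincide", {
  m <- curvedMesh(extent = 10)
  p <- patchSubmesh(m, rep(TRUE, nVertices(m)))
  set.seed(4)
  f <- ScalarField(rnorm(nVertices(m)))
  out <- suppressMessages(transferField(p, f, p, RigidTransform()))
  expect_equal(fieldValues(out), fieldValues(f))
  # fields linear over faces stay exact too
  lin <- ScalarField(2 + 0.3 * vertices(m)[, 1] - 0.1 * vertices(m)[, 2])
  outl <- suppressMessages(transferField(p, lin, p, RigidTransform()))
  expect_equal(fieldValues(outl), fieldValues(lin), tolerance = 1e-10)
})

test_that("template vertices far from the source are masked", {
  m <- gridMesh(10, 1)
  p <- patchSubmesh(m, rep(TRUE, nVertices(m)))
  far <- SurfaceMesh(vertices(m) + matrix(c(0, 0, 10), nVertices(m), 3,
                                          byrow = TRUE), faces(m))
  pf <- patchSubmesh(far, rep(TRUE, nVertices(far)))
  f <- ScalarField(rep(1, nVertices(m)))
  out <- suppressMessages(transferField(p, f, pf, RigidTransform()))
  expect_false(any(fieldMask(out)))
})

test_that("fields survive transfer across a deformed, registered cohort", {
  template <- curvedMesh(extent = 16)
  tp <- patchSubmesh(template, rep(TRUE, nVertices(template)))
  set.seed(9)
  cors <- vapply(1:5, function(s) {
    # subject surface: template + smooth random deformation, RMS 0.3 mm,
    # then a known rigid displacement
    n <- nVertices(template)
    d <- vapply(1:3, function(k) {
      h <- smoothField(ScalarField(rnorm(n)), template, iterations = 15,
                       weight = 0.9)@values
      h / stats::sd(h) * 0.3 / sqrt(3)
    }, numeric(n))
    sv <- vertices(template) + d
    subj <- SurfaceMesh(sv, faces(template))
    known <- knownTransform(deg = 3, trans = c(0.5, -1, 0.3))
    Rt <- t(known@rotation)
    subjMoved <- applyTransform(subj,
      RigidTransform(Rt, -as.numeric(Rt %*% known@translation)))
    sp <- patchSubmesh(subjMoved, rep(TRUE, nVertices(subjMoved)))
    # ground truth field indexed by the generator's exact correspondence
    truth <- 2 + 0.5 * sin(vertices(template)[, 1] / 3) +
      0.3 * cos(vertices(template)[, 2] / 4)
    tr <- icpRigid(sp@mesh, template)
    out <- suppressMessages(transferField(sp, ScalarField(truth), tp, tr))
    ok <- fieldMask(out)
    cor(fieldValues(out)[ok], truth[ok])
  }, 1)
  expect_true(all(cors >= 0.95))
})
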