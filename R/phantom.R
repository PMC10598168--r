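## Synthetic articulating joint phantoms: two cortical bodies separated by a
## known gap field, rasterized into CT-like isotropic volumes, and cohort
## simulation with visit, operator and angulation effects.

#' Create a PhantomSpec
#'
#' @param geometry "parallel-slabs", "ball-and-socket" or "saddle".
#' @param extent lateral extent of the articular region, mm (default 20).
#' @param gapField gap description; see \linkS4class{PhantomSpec}. Default is
#'   a constant 2 mm gap, inside the 1.9-2.9 mm range typical of ankle
#'   articular facets.
#' @param meshResolution target edge length, mm (default 1).
#' @param thickness cortical shell thickness per body, mm (default 2.5).
#' @param pose rigid transform applied to the articulating pair.
#' @export
phantomSpec <- function(geometry = "parallel-slabs", extent = 20,
                        gapField = list(type = "constant", value = 2),
                        meshResolution = 1, thickness = 2.5,
                        pose = RigidTransform()) {
  new("PhantomSpec", geometry = geometry, extent = extent,
      gapField = gapField, meshResolution = meshResolution,
      thickness = thickness, pose = pose)
}

evalGapField <- function(gapField, v) {
  x <- v[, 1]; y <- v[, 2]
  g <- switch(gapField$type,
    constant = rep(gapField$value, nrow(v)),
    ramp = {
      s <- (x - min(x)) / (max(x) - min(x))
      gapField$from + (gapField$to - gapField$from) * s
    },
    bump = {
      r2 <- x^2 + y^2
      gapField$base + gapField$amplitude * exp(-r2 / (2 * gapField$sigma^2))
    },
    custom = {
      if (length(gapField$values) != nrow(v))
        stop("custom gap field must have one value per reference vertex")
      gapField$values
    },
    stop("unknown gap field type: ", gapField$type))
  if (any(g <= 0)) stop("gap field must be strictly positive everywhere")
  g
}

referenceSurface <- function(spec) {
  ext <- spec@extent; res <- spec@meshResolution
  switch(spec@geometry,
    "parallel-slabs" = gridMesh(ext, res),
    "ball-and-socket" = {
      R <- ext  # cap of a sphere with radius = extent (mild curvature)
      gridMesh(ext, res, zfun = function(x, y) sqrt(R^2 - x^2 - y^2) - R)
    },
    "saddle" = gridMesh(ext, res,
                        zfun = function(x, y) (x^2 - y^2) / (2 * ext)))
}

## directed boundary edges of an open mesh, as they appear in faces
boundaryEdges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[key %in% names(which(table(key) == 1)), , drop = FALSE]
}

isClosed <- function(mesh) {
  nrow(mesh@faces) > 0 && nrow(boundaryEdges(mesh@faces)) == 0
}

## thicken an open surface into a watertight body by offsetting each vertex
## by `offset` (n x 3) and stitching the boundary
thickenSurface <- function(mesh, offset) {
  v <- mesh@vertices
  nV <- nrow(v)
  v2 <- v + offset
  f1 <- mesh@faces
  f2 <- mesh@faces[, c(1, 3, 2), drop = FALSE] + nV
  be <- boundaryEdges(f1)
  side <- rbind(cbind(be[, 1], be[, 2], be[, 2] + nV),
                cbind(be[, 1], be[, 2] + nV, be[, 1] + nV))
  allV <- rbind(v, v2)
  allF <- rbind(f1, f2, side)
  new("SurfaceMesh", vertices = allV,
      faces = matrix(as.integer(allF), ncol = 3),
      normals = vertexNormals(allV, allF))
}

#' Build an articulating joint phantom with a known gap field
#'
#' The opposing articular surface is the reference surface offset along its
#' vertex normals by the gap g(u, v); both surfaces are then thickened into
#' closed cortical bodies. Ground truth is g at each reference vertex, so
#' vertex-wise correspondence between truth and measurement is exact.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return list with elements \code{reference} (open articular SurfaceMesh
#'   with outward normals), \code{opposing} (closed opposing body),
#'   \code{referenceBody} (closed reference body), \code{truth}
#'   (\linkS4class{ScalarField} of gap in mm at reference vertices),
#'   \code{gap} (numeric vector), and \code{spec}.
#' @export
makeJointPhantom <- function(spec) {
  validObject(spec)
  ref <- referenceSurface(spec)
  g <- evalGapField(spec@gapField, ref@vertices)
  n <- ref@normals
  oppInner <- new("SurfaceMesh", vertices = ref@vertices + n * g,
                  faces = ref@faces[, c(1, 3, 2), drop = FALSE],
                  normals = -n)
  refBody <- thickenSurface(ref, -n * spec@thickness)
  oppBody <- thickenSurface(
    new("SurfaceMesh", vertices = oppInner@vertices, faces = ref@faces,
        normals = n),
    n * spec@thickness)
  idt <- max(abs(spec@pose@rotation - diag(3))) < 1e-12 &&
    max(abs(spec@pose@translation)) < 1e-12
  if (!idt) {
    ref <- applyTransform(ref, spec@pose)
    refBody <- applyTransform(refBody, spec@pose)
    oppBody <- applyTransform(oppBody, spec@pose)
  }
  list(reference = ref, opposing = oppBody, referenceBody = refBody,
       truth = ScalarField(g), gap = g, spec = spec)
}

## separable Gaussian blur of a 3-D array, sigma in voxels
gaussianBlur3D <- function(arr, sigmaVox) {
  if (sigmaVox <= 0) return(arr)
  r <- max(1L, ceiling(4 * sigmaVox))
  blur1 <- function(m) {
    # m: (dim being blurred) x rest
    n <- nrow(m)
    idx <- outer(seq_len(n), seq_len(n), "-")
    K <- exp(-idx^2 / (2 * sigmaVox^2))
    K[abs(idx) > r] <- 0
    K <- K / Matrix::rowSums(K)
    K %*% m
  }
  d <- dim(arr)
  a <- blur1(matrix(arr, d[1], d[2] * d[3]))
  arr <- array(a, d)
  arr <- aperm(arr, c(2, 1, 3))
  a <- blur1(matrix(arr, d[2], d[1] * d[3]))
  arr <- aperm(array(a, c(d[2], d[1], d[3])), c(2, 1, 3))
  arr <- aperm(arr, c(3, 2, 1))
  a <- blur1(matrix(arr, d[3], d[2] * d[1]))
  aperm(array(a, c(d[3], d[2], d[1])), c(3, 2, 1))
}

#' Rasterize a phantom pair into a CT-like voxel volume
#'
#' Binary occupancy of the two closed bodies sampled at voxel centres,
#' convolved with an isotropic Gaussian point spread function, plus i.i.d.
#' Gaussian noise. Deterministic given the seed.
#'
#' @param pair list as returned by \code{makeJointPhantom} (elements
#'   \code{referenceBody} and \code{opposing}), or a list of two closed
#'   SurfaceMeshes.
#' @param spacing isotropic voxel spacing, mm (default 0.37).
#' @param psfSigma Gaussian PSF standard deviation, mm (default 0.5).
#' @param noiseSd additive noise SD, intensity units (default 20).
#' @param boneIntensity,backgroundIntensity HU-like plateau values
#'   (defaults 1000 and 0).
#' @param seed integer RNG seed for the noise realisation.
#' @param margin field-of-view margin around the bodies, mm (>= 4).
#' @param supersample integer; occupancy is sampled on a grid this many
#'   times finer per axis and box-averaged, so edge voxels carry fractional
#'   (partial-volume) occupancy as in a real reconstruction. 1 = binary
#'   occupancy at voxel centres.
#' @return a \linkS4class{VoxelVolume}
#' @export
rasterizeCT <- function(pair, spacing = 0.37, psfSigma = 0.5, noiseSd = 20,
                        boneIntensity = 1000, backgroundIntensity = 0,
                        seed = 1, margin = 4, supersample = 3L) {
  stopifnot(spacing > 0, psfSigma >= 0, noiseSd >= 0, margin >= 4,
            supersample >= 1)
  bodies <- if (!is.null(pair$referenceBody))
    list(pair$referenceBody, pair$opposing)
  else pair[1:2]
  for (b in bodies)
    if (!isClosed(b)) stop("rasterization requires closed surfaces")
  allV <- do.call(rbind, lapply(bodies, function(b) b@vertices))
  lo <- apply(allV, 2, min) - margin
  hi <- apply(allV, 2, max) + margin
  nd <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  ss <- as.integer(supersample)
  ssSp <- spacing / ss
  ssLo <- lo - spacing / 2 + ssSp / 2   # sub-voxels tile each voxel
  ndF <- nd * ss
  occ <- integer(prod(ndF))
  for (b in bodies) {
    o <- cpp_voxelize(b@vertices, b@faces, ndF[1], ndF[2], ndF[3],
                      ssSp, ssLo[1], ssLo[2], ssLo[3])
    occ <- pmax(occ, o)
  }
  frac <- if (ss == 1) as.numeric(occ) else {
    a6 <- array(occ, c(ss, nd[1], ss, nd[2], ss, nd[3]))
    colMeans(matrix(aperm(a6, c(1, 3, 5, 2, 4, 6)), ss^3))
  }
  arr <- array(backgroundIntensity +
                 (boneIntensity - backgroundIntensity) * frac, nd)
  arr <- gaussianBlur3D(arr, psfSigma / spacing)
  if (noiseSd > 0) {
    set.seed(seed)
    arr <- arr + array(rnorm(length(arr), 0, noiseSd), nd)
  }
  VoxelVolume(arr, spacing = spacing, origin = lo)
}

## deterministic per-record sub-seed: adding subjects never changes
## earlier subjects' draws
subSeed <- function(base, i, v = 0, o = 0) {
  as.integer((as.numeric(base) * 7919 + i * 1000003 + v * 10007 + o * 101) %%
               2147483629)
}

#' Randomly erode/dilate a patch perimeter (operator simulation)
#'
#' A smooth random signed offset field with RMS amplitude \code{magnitude}
#' (mm) is added to the signed geodesic distance from the mask boundary;
#' vertices whose perturbed distance stays positive remain in the mask.
#' Interior vertices far from the boundary are unchanged.
#'
#' @param mask logical per-vertex flags. @param mesh host SurfaceMesh.
#' @param magnitude RMS boundary offset, mm (>= 0). @param seed integer.
#' @return perturbed logical mask
#' @export
perturbPerimeter <- function(mask, mesh, magnitude, seed = 1) {
  stopifnot(magnitude >= 0)
  if (is(mesh, "JointPatch")) mesh <- mesh@mesh
  if (magnitude == 0) return(mask)
  bnd <- maskBoundaryVertices(mask, mesh)
  if (!length(bnd)) return(mask)
  eg <- edgeLengthGraph(mesh)
  dmat <- igraph::distances(eg$graph, v = bnd, weights = eg$weights)
  d <- apply(dmat, 2, min)[seq_len(nrow(mesh@vertices))]
  phi <- ifelse(mask, d, -d)
  set.seed(seed)
  h <- rnorm(nrow(mesh@vertices))
  h <- smoothField(ScalarField(h), mesh, iterations = 20, weight = 0.9)@values
  h <- h / stats::sd(h) * magnitude
  (phi + h) > 0
}

#' Create a CohortSpec
#'
#' Defaults emulate the study design the package is validated against:
#' 23 subjects, two visits, two operators, per-subject plantarflexion
#' angles with SD 9 degrees, gaps in the 1.9-2.9 mm range at 0.37 mm
#' voxels.
#'
#' @param nSubjects number of subjects (default 23).
#' @param visits,operators counts (defaults 2 and 2).
#' @param gapBase shared \linkS4class{PhantomSpec}; default is a ramp gap
#'   from 1.9 to 2.9 mm across a 20 mm parallel-slab phantom.
#' @param betweenSubjectSd SD (mm) of smooth per-subject gap modulation
#'   (default 0.3).
#' @param visitNoiseSd image noise SD per visit (default 20).
#' @param visitPoseJitter c(max rotation deg, max translation mm)
#'   (default c(2, 0.5)).
#' @param angleValues per-subject angle (deg); default drawn with SD 9.
#' @param effectMap per-vertex slope (mm/deg) of gap on angle (default 0).
#' @param perimeterJitter operator boundary RMS offset, mm (default 1).
#' @param seed integer (default 1).
#' @export
cohortSpec <- function(nSubjects = 23, visits = 2, operators = 2,
                       gapBase = phantomSpec(
                         gapField = list(type = "ramp", from = 1.9, to = 2.9)),
                       betweenSubjectSd = 0.3, visitNoiseSd = 20,
                       visitPoseJitter = c(2, 0.5), angleValues = NULL,
                       effectMap = 0, perimeterJitter = 1, seed = 1L) {
  if (is.null(angleValues)) {
    set.seed(subSeed(seed, 0, 0, 7))
    angleValues <- rnorm(nSubjects, 0, 9)
  }
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      visits = as.integer(visits), operators = as.integer(operators),
      gapBase = gapBase, betweenSubjectSd = betweenSubjectSd,
      visitNoiseSd = visitNoiseSd, visitPoseJitter = visitPoseJitter,
      angleValues = angleValues, effectMap = effectMap,
      perimeterJitter = perimeterJitter, seed = as.integer(seed))
}

randomRigidJitter <- function(maxRotDeg, maxTransMm) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, -maxRotDeg, maxRotDeg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  RigidTransform(R, runif(3, -maxTransMm, maxTransMm))
}

#' Simulate a two-visit, two-operator joint phantom cohort
#'
#' Per subject: a smooth random gap modulation plus an angulation effect
#' \code{effectMap * (angle - mean(angle))}. Per visit: an independent noise
#' realisation and a small random pose change. Per operator: a jittered
#' patch perimeter. All ground truth (true gap per template vertex and
#' subject) is recorded on the shared template mesh. Reproducible given
#' the spec seed; sub-seeds are derived per (subject, visit, operator), so
#' adding subjects does not change earlier subjects' draws.
#'
#' @param spec a \linkS4class{CohortSpec}
#' @param rasterize logical; set FALSE to skip volume rasterization (the
#'   geometry, masks and ground truth are still generated).
#' @return a \linkS4class{CohortData}
#' @export
simulateCohort <- function(spec, rasterize = TRUE) {
  validObject(spec)
  base <- makeJointPhantom(spec@gapBase)
  template <- base$reference
  nV <- nrow(template@vertices)
  g0 <- base$gap
  eff <- rep(spec@effectMap, length.out = nV)
  ang <- spec@angleValues
  angC <- ang - mean(ang)
  set.seed(subSeed(spec@seed, 0, 0, 3))
  interval <- round(runif(spec@nSubjects, 40, 120))
  truth <- matrix(NA_real_, nV, spec@nSubjects)
  volumes <- list()
  records <- list()
  shadow0 <- castShadow(template, base$opposing, tMax = 6)
  for (i in seq_len(spec@nSubjects)) {
    gi <- g0
    if (spec@betweenSubjectSd > 0) {
      set.seed(subSeed(spec@seed, i, 0, 1))
      m <- rnorm(nV)
      m <- smoothField(ScalarField(m), template, iterations = 20,
                       weight = 0.9)@values
      m <- (m - mean(m)) / stats::sd(m) * spec@betweenSubjectSd
      gi <- gi + m
    }
    gi <- gi + eff * angC[i]
    gi <- pmax(gi, 0.2)
    truth[, i] <- gi
    subjSpec <- spec@gapBase
    subjSpec@gapField <- list(type = "custom", values = gi)
    phant <- makeJointPhantom(subjSpec)
    opMasks <- lapply(seq_len(spec@operators), function(o) {
      perturbPerimeter(shadow0, template, spec@perimeterJitter,
                       seed = subSeed(spec@seed, i, 0, 20 + o))
    })
    for (v in seq_len(spec@visits)) {
      set.seed(subSeed(spec@seed, i, v, 2))
      pose <- if (all(spec@visitPoseJitter == 0)) RigidTransform()
        else randomRigidJitter(spec@visitPoseJitter[1],
                               spec@visitPoseJitter[2])
      posed <- list(
        reference = applyTransform(phant$reference, pose),
        referenceBody = applyTransform(phant$referenceBody, pose),
        opposing = applyTransform(phant$opposing, pose))
      volIdx <- NA_integer_
      if (rasterize) {
        vol <- rasterizeCT(posed, noiseSd = spec@visitNoiseSd,
                           seed = subSeed(spec@seed, i, v, 5))
        volumes[[length(volumes) + 1]] <- vol
        volIdx <- length(volumes)
      }
      for (o in seq_len(spec@operators)) {
        records[[length(records) + 1]] <- list(
          subject = i, visit = v, operator = o, pose = pose,
          volumeIndex = volIdx, mask = opMasks[[o]],
          reference = posed$reference, opposing = posed$opposing)
      }
    }
  }
  new("CohortData", records = records, volumes = volumes,
      covariates = data.frame(subject = seq_len(spec@nSubjects),
                              angle_deg = ang, interval_days = interval),
      groundTruth = truth, template = template, spec = spec)
}

#' Field-level measurement simulation on a template
#'
#' Adds i.i.d. vertex noise to true per-subject fields — the cheap analogue
#' of measuring each subject's map through the full imaging chain, used for
#' calibrating the statistics layer at scale.
#'
#' @param truth numeric matrix (vertices x subjects) of true values, or a
#'   vector recycled across subjects.
#' @param nSubjects number of columns when `truth` is a vector.
#' @param noiseSd per-vertex measurement noise SD (mm).
#' @param seed integer.
#' @return numeric matrix (vertices x subjects)
#' @export
simulateMeasuredFields <- function(truth, nSubjects = NULL, noiseSd = 0.1,
                                   seed = 1) {
  if (is.null(dim(truth))) {
    stopifnot(!is.null(nSubjects))
    truth <- matrix(truth, length(truth), nSubjects)
  }
  set.seed(seed)
  truth + matrix(rnorm(length(truth), 0, noiseSd), nrow(truth))
}
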