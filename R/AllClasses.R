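#' @title Core S4 classes for joint space mapping
#' @name jsmap-classes
#' @description
#' The package represents an articular surface as a triangulated
#' \linkS4class{SurfaceMesh} in millimetres, per-vertex quantities (joint
#' space width, bias, limits of agreement, F statistics, p values) as
#' \linkS4class{ScalarField}s with a validity mask, an articular facet as a
#' \linkS4class{JointPatch} (connected submesh plus the map back to its
#' parent mesh), and a CT-like reconstruction as an isotropic
#' \linkS4class{VoxelVolume}.
NULL

#' SurfaceMesh: a triangulated surface in millimetres
#'
#' @slot vertices numeric matrix (n x 3), vertex positions in mm
#'   (right-handed frame).
#' @slot faces integer matrix (m x 3), 1-based vertex indices per triangle.
#' @slot normals numeric matrix (n x 3), per-vertex outward unit normals.
#'
#' @details Meshes need not be closed; non-manifold connectivity is
#' tolerated with a warning at construction. Connectivity used by patch
#' extraction and smoothing is defined through shared faces.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", normals = "matrix"))

setValidity("SurfaceMesh", function(object) {
  msgs <- character()
  v <- object@vertices; f <- object@faces; nrm <- object@normals
  if (ncol(v) != 3) msgs <- c(msgs, "vertices must be an n x 3 matrix")
  if (nrow(f) > 0 && ncol(f) != 3) msgs <- c(msgs, "faces must be an m x 3 matrix")
  if (nrow(f) > 0) {
    if (any(f < 1) || any(f > nrow(v)))
      msgs <- c(msgs, "face indices out of range")
    if (any(f != round(f))) msgs <- c(msgs, "face indices must be integers")
  }
  if (nrow(nrm) != nrow(v) || (nrow(nrm) > 0 && ncol(nrm) != 3))
    msgs <- c(msgs, "normals must match vertices in shape")
  if (nrow(nrm) > 0) {
    len <- sqrt(rowSums(nrm^2))
    bad <- is.finite(len) & abs(len - 1) > 1e-6
    if (any(bad))
      msgs <- c(msgs, sprintf("%d normals are not unit length", sum(bad)))
  }
  if (length(msgs)) msgs else TRUE
})

#' ScalarField: one value per mesh vertex with a validity mask
#'
#' @slot values numeric vector, one value per host-mesh vertex; units depend
#'   on role (mm for JSW/bias/LOA, dimensionless for F, probability for p).
#' @slot mask logical vector, TRUE where the value is valid.
#' @export
setClass("ScalarField",
  representation(values = "numeric", mask = "logical"))

setValidity("ScalarField", function(object) {
  msgs <- character()
  if (length(object@values) != length(object@mask))
    msgs <- c(msgs, "values and mask must have equal length")
  if (any(object@mask & !is.finite(object@values)))
    msgs <- c(msgs, "values must be finite wherever mask is TRUE")
  if (length(msgs)) msgs else TRUE
})

#' JointPatch: one articular facet as a connected submesh
#'
#' @slot mesh the patch \linkS4class{SurfaceMesh} (single connected component).
#' @slot parentIndex integer vector mapping each patch vertex to its vertex
#'   in the parent mesh (injective).
#' @slot label character; facet name, conventionally one of
#'   \code{"talonavicular"}, \code{"dome-medial"}, \code{"lateral-gutter"},
#'   \code{"posterior-subtalar"}, or free text.
#' @export
setClass("JointPatch",
  representation(mesh = "SurfaceMesh", parentIndex = "integer",
                 label = "character"))

setValidity("JointPatch", function(object) {
  msgs <- character()
  if (length(object@parentIndex) != nrow(object@mesh@vertices))
    msgs <- c(msgs, "parentIndex must have one entry per patch vertex")
  if (anyDuplicated(object@parentIndex))
    msgs <- c(msgs, "parentIndex must be injective")
  if (length(msgs)) msgs else TRUE
})

#' VoxelVolume: an isotropic intensity grid emulating a CT reconstruction
#'
#' @slot intensities numeric 3-D array (HU-like units).
#' @slot spacing numeric(1), isotropic voxel spacing in mm.
#' @slot origin numeric(3), world position (mm) of the centre of voxel
#'   \code{[1, 1, 1]}; axes are aligned with the phantom frame.
#' @export
setClass("VoxelVolume",
  representation(intensities = "array", spacing = "numeric",
                 origin = "numeric"))

setValidity("VoxelVolume", function(object) {
  msgs <- character()
  if (length(dim(object@intensities)) != 3)
    msgs <- c(msgs, "intensities must be a 3-D array")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    msgs <- c(msgs, "spacing must be a single positive number")
  if (length(object@origin) != 3)
    msgs <- c(msgs, "origin must be length 3")
  if (length(msgs)) msgs else TRUE
})

#' Profile: intensity samples along a measurement ray
#'
#' Coordinates are mm along the ray, 0 at the reference vertex, positive
#' toward the opposing bone; samples are trilinear interpolations of the
#' volume on a uniform grid.
#'
#' @slot positions numeric, strictly increasing uniform sample coordinates (mm).
#' @slot intensities numeric, interpolated intensities.
#' @export
setClass("Profile",
  representation(positions = "numeric", intensities = "numeric"))

setValidity("Profile", function(object) {
  msgs <- character()
  p <- object@positions
  if (length(p) < 20) msgs <- c(msgs, "profile needs at least 20 samples")
  if (length(p) >= 2) {
    d <- diff(p)
    if (any(d <= 0)) msgs <- c(msgs, "positions must be strictly increasing")
    if (max(d) - min(d) > 1e-8 * max(abs(p)))
      msgs <- c(msgs, "positions must be uniformly spaced")
  }
  if (length(object@intensities) != length(p))
    msgs <- c(msgs, "positions and intensities must have equal length")
  if (length(msgs)) msgs else TRUE
})

#' ProfileFit: the blurred two-edge model fitted to one profile
#'
#' Model: \eqn{y(t) = b + (A_1-b)\Phi((e_1-t)/s) + (A_2-b)\Phi((t-e_2)/s)},
#' with \eqn{\Phi} the standard normal CDF. JSW is \eqn{e_2-e_1}.
#'
#' @slot b background intensity. @slot A1 reference-bone plateau.
#' @slot A2 opposing-bone plateau. @slot e1 first (falling) edge, mm.
#' @slot e2 second (rising) edge, mm. @slot s blur SD, mm.
#' @slot jsw \code{e2 - e1}, mm. @slot rmsResidual RMS fit residual.
#' @slot converged logical. @slot status "ok", "no_opposing_edge" or
#'   "not_converged".
#' @export
setClass("ProfileFit",
  representation(b = "numeric", A1 = "numeric", A2 = "numeric",
                 e1 = "numeric", e2 = "numeric", s = "numeric",
                 jsw = "numeric", rmsResidual = "numeric",
                 converged = "logical", status = "character"))

setValidity("ProfileFit", function(object) {
  msgs <- character()
  if (object@converged) {
    if (object@e1 > object@e2 + 1e-9) msgs <- c(msgs, "e1 must not exceed e2")
    if (object@s <= 0) msgs <- c(msgs, "s must be positive")
    if (object@jsw < -1e-9) msgs <- c(msgs, "jsw must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' JSWMap: a joint space width field on a patch, with fit quality
#'
#' @slot field \linkS4class{ScalarField} of JSW in mm on the patch vertices.
#' @slot quality data.frame with per-vertex \code{rms_residual} and
#'   \code{converged}.
#' @slot patch the \linkS4class{JointPatch} the map lives on.
#' @export
setClass("JSWMap",
  representation(field = "ScalarField", quality = "data.frame",
                 patch = "JointPatch"))

#' RigidTransform: rotation plus translation, x -> R x + t
#'
#' @slot rotation 3 x 3 orthonormal matrix, det = +1.
#' @slot translation numeric(3), mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  msgs <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) msgs <- c(msgs, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msgs <- c(msgs, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-9)
      msgs <- c(msgs, "rotation determinant must be +1")
  }
  if (length(object@translation) != 3)
    msgs <- c(msgs, "translation must be length 3")
  if (length(msgs)) msgs else TRUE
})

#' BlandAltmanMap: vertex-wise agreement between two sets of maps
#'
#' @slot bias \linkS4class{ScalarField}, mean of paired differences (mm).
#' @slot loa \linkS4class{ScalarField}, 1.96 x SD of paired differences (mm).
#' @slot patchBias numeric(1), Bland-Altman bias of per-subject patch means.
#' @slot patchLoa numeric(1), 1.96 x SD of per-subject patch-mean differences.
#' @slot surfaceBias numeric(1), area-weighted surface average of the
#'   vertex-wise bias field (alternative summary).
#' @slot surfaceLoa numeric(1), area-weighted surface average of the
#'   vertex-wise LOA field (alternative summary).
#' @export
setClass("BlandAltmanMap",
  representation(bias = "ScalarField", loa = "ScalarField",
                 patchBias = "numeric", patchLoa = "numeric",
                 surfaceBias = "numeric", surfaceLoa = "numeric"))

#' SPMResult: vertex-wise F map with family-wise corrected p values
#'
#' @slot F \linkS4class{ScalarField}, F statistic of the covariate slope.
#' @slot pCorrected \linkS4class{ScalarField}, max-statistic permutation
#'   family-wise corrected p values in \code{[1/(B+1), 1]}.
#' @slot pUncorrected \linkS4class{ScalarField}, parametric per-vertex p.
#' @slot significant logical per vertex, \code{pCorrected < alpha}.
#' @slot nPermutations integer. @slot alpha numeric significance threshold.
#' @export
setClass("SPMResult",
  representation(F = "ScalarField", pCorrected = "ScalarField",
                 pUncorrected = "ScalarField", significant = "logical",
                 nPermutations = "integer", alpha = "numeric"))

#' TTestResult: a paired Student t test on differences
#'
#' @slot meanDiff mean difference (input units). @slot sdDiff SD (n-1).
#' @slot t the t statistic. @slot df degrees of freedom, n - 1.
#' @slot p two-sided p value.
#' @export
setClass("TTestResult",
  representation(meanDiff = "numeric", sdDiff = "numeric", t = "numeric",
                 df = "numeric", p = "numeric"))

setValidity("TTestResult", function(object) {
  if (object@p < 0 || object@p > 1) "p must lie in [0, 1]" else TRUE
})

#' PhantomSpec: parameters of a synthetic articulating joint phantom
#'
#' @slot geometry "parallel-slabs", "ball-and-socket" or "saddle".
#' @slot extent numeric(1), lateral extent of the articular region, mm.
#' @slot gapField list describing g(u, v) >= 0 in mm over the reference
#'   surface: \code{list(type = "constant", value = )},
#'   \code{list(type = "ramp", from = , to = )} (along x),
#'   \code{list(type = "bump", base = , amplitude = , sigma = )} (radial), or
#'   \code{list(type = "custom", values = )} (one value per reference vertex).
#' @slot meshResolution numeric(1), target edge length, mm.
#' @slot thickness numeric(1), cortical shell thickness of each body, mm.
#' @slot pose \linkS4class{RigidTransform} applied to the articulating pair.
#' @export
setClass("PhantomSpec",
  representation(geometry = "character", extent = "numeric",
                 gapField = "list", meshResolution = "numeric",
                 thickness = "numeric", pose = "RigidTransform"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (!object@geometry %in% c("parallel-slabs", "ball-and-socket", "saddle"))
    msgs <- c(msgs, "unknown geometry")
  if (object@meshResolution <= 0) msgs <- c(msgs, "meshResolution must be > 0")
  if (object@extent <= 0) msgs <- c(msgs, "extent must be > 0")
  if (object@thickness < 2) msgs <- c(msgs, "thickness must be >= 2 mm")
  if (length(msgs)) msgs else TRUE
})

#' CohortSpec: design of a simulated two-visit, two-operator cohort
#'
#' @slot nSubjects integer. @slot visits integer, default 2.
#' @slot operators integer, default 2.
#' @slot gapBase \linkS4class{PhantomSpec} shared by all subjects.
#' @slot betweenSubjectSd numeric, SD (mm) of the smooth random per-subject
#'   gap modulation.
#' @slot visitNoiseSd numeric, image noise SD (intensity units) per visit.
#' @slot visitPoseJitter numeric(2), max rotation (deg) and translation (mm)
#'   applied independently per visit.
#' @slot angleValues numeric, per-subject plantarflexion angle (deg).
#' @slot effectMap numeric, per-vertex slope (mm per deg) linking angle to
#'   true gap; a scalar is recycled.
#' @slot perimeterJitter numeric, RMS operator perimeter offset (mm).
#' @slot seed integer.
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", visits = "integer",
                 operators = "integer", gapBase = "PhantomSpec",
                 betweenSubjectSd = "numeric", visitNoiseSd = "numeric",
                 visitPoseJitter = "numeric", angleValues = "numeric",
                 effectMap = "numeric", perimeterJitter = "numeric",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nSubjects < 2) msgs <- c(msgs, "nSubjects must be >= 2")
  if (length(object@angleValues) != object@nSubjects)
    msgs <- c(msgs, "angleValues length must equal nSubjects")
  if (any(c(object@betweenSubjectSd, object@visitNoiseSd,
            object@perimeterJitter) < 0))
    msgs <- c(msgs, "all SDs must be >= 0")
  if (length(object@visitPoseJitter) != 2 || any(object@visitPoseJitter < 0))
    msgs <- c(msgs, "visitPoseJitter must be c(maxRotDeg, maxTransMm) >= 0")
  if (length(msgs)) msgs else TRUE
})

#' CohortData: a simulated cohort with ground truth on the template
#'
#' @slot records list; one element per (subject, visit, operator) with the
#'   phantom pair in visit pose, the volume index, and the operator patch mask.
#' @slot volumes list of \linkS4class{VoxelVolume}, one per (subject, visit).
#' @slot covariates data.frame: subject, angle_deg, interval_days.
#' @slot groundTruth numeric matrix (template vertices x subjects), true gap.
#' @slot template \linkS4class{SurfaceMesh}, the shared reference surface.
#' @slot spec the generating \linkS4class{CohortSpec}.
#' @export
setClass("CohortData",
  representation(records = "list", volumes = "list",
                 covariates = "data.frame", groundTruth = "matrix",
                 template = "SurfaceMesh", spec = "CohortSpec"))

#' TemplateAtlas: per-subject fields resampled onto template vertices
#'
#' @slot template \linkS4class{JointPatch}.
#' @slot fields numeric matrix (template vertices x maps), NA where masked.
#' @slot meta data.frame, one row per column of \code{fields}.
#' @export
setClass("TemplateAtlas",
  representation(template = "JointPatch", fields = "matrix",
                 meta = "data.frame"))

setValidity("TemplateAtlas", function(object) {
  if (nrow(object@fields) != nrow(object@template@mesh@vertices))
    "stacked fields must share the template vertex count"
  else TRUE
})
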