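#' @rdname jsmap-classes
#' @param x an object
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname jsmap-classes
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname jsmap-classes
#' @export
setGeneric("meshNormals", function(x) standardGeneric("meshNormals"))
#' @rdname jsmap-classes
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname jsmap-classes
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname jsmap-classes
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname jsmap-classes
#' @export
setGeneric("fieldMask", function(x) standardGeneric("fieldMask"))
#' @rdname jsmap-classes
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname jsmap-classes
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
setMethod("faces", "SurfaceMesh", function(x) x@faces)
setMethod("meshNormals", "SurfaceMesh", function(x) x@normals)
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))
setMethod("nFaces", "SurfaceMesh", function(x) nrow(x@faces))

setMethod("vertices", "JointPatch", function(x) x@mesh@vertices)
setMethod("faces", "JointPatch", function(x) x@mesh@faces)
setMethod("meshNormals", "JointPatch", function(x) x@mesh@normals)
setMethod("nVertices", "JointPatch", function(x) nrow(x@mesh@vertices))
setMethod("nFaces", "JointPatch", function(x) nrow(x@mesh@faces))

setMethod("fieldValues", "ScalarField", function(x) x@values)
setMethod("fieldMask", "ScalarField", function(x) x@mask)
setMethod("fieldValues", "JSWMap", function(x) x@field@values)
setMethod("fieldMask", "JSWMap", function(x) x@field@mask)

setMethod("voxelSpacing", "VoxelVolume", function(x) x@spacing)
setMethod("voxelOrigin", "VoxelVolume", function(x) x@origin)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  bb <- apply(object@vertices, 2, range)
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

setMethod("show", "ScalarField", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("ScalarField: %d vertices, %d valid\n",
              length(object@values), sum(object@mask)))
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
                min(v), max(v), mean(v)))
})

setMethod("show", "JointPatch", function(object) {
  cat(sprintf("JointPatch '%s': %d vertices, %d faces\n",
              object@label, nrow(object@mesh@vertices),
              nrow(object@mesh@faces)))
})

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels at %.3g mm\n",
              d[1], d[2], d[3], object@spacing))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, intensities [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "ProfileFit", function(object) {
  cat(sprintf(
    "ProfileFit [%s]: jsw = %.3f mm (e1 %.3f, e2 %.3f, s %.3f), rms %.3g\n",
    object@status, object@jsw, object@e1, object@e2, object@s,
    object@rmsResidual))
})

setMethod("show", "JSWMap", function(object) {
  ok <- object@field@mask
  cat(sprintf("JSWMap on patch '%s': %d/%d valid vertices\n",
              object@patch@label, sum(ok), length(ok)))
  if (any(ok))
    cat(sprintf("  JSW mean %.3f mm, range [%.3f, %.3f]\n",
                mean(object@field@values[ok]),
                min(object@field@values[ok]),
                max(object@field@values[ok])))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) *
    180 / pi
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "BlandAltmanMap", function(object) {
  cat("BlandAltmanMap\n")
  cat(sprintf("  patch-mean bias %.3f mm, LOA %.3f mm\n",
              object@patchBias, object@patchLoa))
  cat(sprintf("  surface-average bias %.3f mm, LOA %.3f mm\n",
              object@surfaceBias, object@surfaceLoa))
})

setMethod("show", "SPMResult", function(object) {
  ok <- object@F@mask
  cat(sprintf("SPMResult: %d valid vertices, %d permutations, alpha %.3g\n",
              sum(ok), object@nPermutations, object@alpha))
  cat(sprintf("  %d significant vertices (max F = %.3f)\n",
              sum(object@significant),
              if (any(ok)) max(object@F@values[ok]) else NA))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s, extent %.1f mm, resolution %.2f mm, gap '%s'\n",
              object@geometry, object@extent, object@meshResolution,
              object@gapField$type))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d subjects x %d visits x %d operators (seed %d)\n",
              object@nSubjects, object@visits, object@operators,
              object@seed))
})

setMethod("show", "CohortData", function(object) {
  cat(sprintf("CohortData: %d records, %d volumes, template %d vertices\n",
              length(object@records), length(object@volumes),
              nrow(object@template@vertices)))
})

setMethod("show", "TemplateAtlas", function(object) {
  cat(sprintf("TemplateAtlas: %d template vertices x %d stacked fields\n",
              nrow(object@fields), ncol(object@fields)))
})
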