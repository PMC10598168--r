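## Rigid template registration and field transfer.

kabsch <- function(x, y) {
  # rigid transform minimising ||R x + t - y||^2
  mx <- colMeans(x); my <- colMeans(y)
  H <- crossprod(sweep(x, 2, mx), sweep(y, 2, my))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(my - R %*% mx))
}

#' Iterative closest point rigid registration
#'
#' Point-to-point ICP with an SVD (Kabsch) update, initialised by centroid
#' alignment. Stops when the RMS closest-point distance changes by less
#' than \code{tol} or after \code{maxIter} iterations. Registration fails
#' with an error if the RMS increases for five consecutive iterations or
#' the final residual remains larger than 10 percent of the target
#' bounding-box diagonal (surfaces that do not overlap).
#'
#' @param source,target SurfaceMesh (or JointPatch) objects.
#' @param maxIter maximum iterations (default 50).
#' @param tol RMS change threshold, mm (default 1e-4).
#' @return a \linkS4class{RigidTransform} mapping source into target frame
#' @export
icpRigid <- function(source, target, maxIter = 50, tol = 1e-4) {
  if (is(source, "JointPatch")) source <- source@mesh
  if (is(target, "JointPatch")) target <- target@mesh
  x <- source@vertices
  R <- diag(3)
  t <- colMeans(target@vertices) - colMeans(x)
  diag_t <- sqrt(sum((apply(target@vertices, 2, max) -
                      apply(target@vertices, 2, min))^2))
  prevRms <- Inf
  up <- 0L
  rms <- NA_real_
  for (it in seq_len(maxIter)) {
    xt <- x %*% t(R) + matrix(t, nrow(x), 3, byrow = TRUE)
    cp <- cpp_closest_point(xt, target@vertices, target@faces)
    y <- cp[, 2:4, drop = FALSE]
    rms <- sqrt(mean(cp[, 5]^2))
    if (rms > prevRms + 1e-12) up <- up + 1L else up <- 0L
    if (up >= 5L)
      stop(sprintf(
        "registration failed: RMS increased 5 consecutive iterations (rms %.3f mm at iter %d)",
        rms, it))
    if (abs(prevRms - rms) < tol) break
    prevRms <- rms
    k <- kabsch(x, y)
    R <- k$R; t <- k$t
  }
  if (rms > 0.1 * diag_t)
    stop(sprintf(
      "registration failed: residual RMS %.3f mm exceeds 10%% of target extent (%.3f mm)",
      rms, diag_t))
  RigidTransform(R, t)
}

#' Transfer a scalar field from a subject patch onto template vertices
#'
#' Each template vertex takes the barycentric interpolation of the field at
#' its closest point on the transformed source patch; template vertices
#' farther than \code{cutoff} from the source surface, or supported by
#' masked source vertices, are masked.
#'
#' @param sourcePatch subject \linkS4class{JointPatch}.
#' @param field ScalarField on the source patch vertices.
#' @param templatePatch template \linkS4class{JointPatch} (or SurfaceMesh).
#' @param transform RigidTransform mapping source into the template frame.
#' @param cutoff masking distance, mm (default 2).
#' @return a \linkS4class{ScalarField} on template vertices
#' @export
transferField <- function(sourcePatch, field, templatePatch,
                          transform = RigidTransform(), cutoff = 2) {
  sm <- if (is(sourcePatch, "JointPatch")) sourcePatch@mesh else sourcePatch
  tm <- if (is(templatePatch, "JointPatch")) templatePatch@mesh
        else templatePatch
  stopifnot(length(field@values) == nrow(sm@vertices))
  sv <- applyTransform(sm, transform)
  cp <- cpp_closest_point(tm@vertices, sv@vertices, sv@faces)
  fIdx <- cp[, 1]
  tri <- sv@faces[fIdx, , drop = FALSE]
  bw <- cp[, 6:8, drop = FALSE]
  vals <- bw[, 1] * field@values[tri[, 1]] +
          bw[, 2] * field@values[tri[, 2]] +
          bw[, 3] * field@values[tri[, 3]]
  srcOk <- field@mask[tri[, 1]] & field@mask[tri[, 2]] & field@mask[tri[, 3]]
  ok <- cp[, 5] <= cutoff & srcOk & is.finite(vals)
  nMasked <- sum(!ok)
  if (nMasked > 0)
    message(sprintf("transferField: %d of %d template vertices masked",
                    nMasked, nrow(tm@vertices)))
  ScalarField(ifelse(ok, vals, NA_real_), mask = ok)
}

#' Stack per-subject fields into a template matrix
#'
#' @param fields list of ScalarFields sharing the template vertex count.
#' @return numeric matrix (vertices x fields), NA where masked
#' @export
stackFields <- function(fields) {
  n <- unique(vapply(fields, function(f) length(f@values), 1L))
  if (length(n) != 1)
    stop("stacked fields must share the template vertex count")
  out <- vapply(fields, function(f) ifelse(f@mask, f@values, NA_real_),
                numeric(n))
  matrix(out, nrow = n)
}
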