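## Measurement core: shadow casting, profile extraction, blurred two-edge
## model fitting for sub-voxel JSW, and per-vertex map assembly.

#' Cast the shadow of an opposing bone onto a reference surface
#'
#' A vertex is flagged iff the ray from it along its outward normal first
#' intersects the opposing surface at a distance in (0, tMax]. Vertices
#' with degenerate (non-finite) normals get an invalid flag rather than
#' failing globally.
#'
#' @param reference SurfaceMesh (or JointPatch) with outward normals.
#' @param opposing SurfaceMesh of the opposing bone.
#' @param tMax maximum gap considered, mm (default 6).
#' @return logical per-vertex flags
#' @export
castShadow <- function(reference, opposing, tMax = 6) {
  if (is(reference, "JointPatch")) reference <- reference@mesh
  d <- cpp_ray_mesh(reference@vertices, reference@normals,
                    opposing@vertices, opposing@faces, tMax)
  !is.na(d) & d > 0 & d <= tMax
}

#' Trilinear interpolation of a VoxelVolume at world points
#' @param volume a VoxelVolume. @param pts n x 3 world coordinates (mm).
#' @return numeric vector (NA outside the grid)
#' @keywords internal
trilinearSample <- function(volume, pts) {
  d <- dim(volume@intensities)
  p <- sweep(pts, 2, volume@origin) / volume@spacing + 1
  out <- rep(NA_real_, nrow(pts))
  eps <- 1e-9
  inb <- p[, 1] >= 1 - eps & p[, 1] <= d[1] + eps &
         p[, 2] >= 1 - eps & p[, 2] <= d[2] + eps &
         p[, 3] >= 1 - eps & p[, 3] <= d[3] + eps
  if (!any(inb)) return(out)
  q <- p[inb, , drop = FALSE]
  i0 <- pmin(pmax(floor(q), 1), matrix(d - 1, nrow(q), 3, byrow = TRUE))
  fr <- q - i0
  fr <- pmin(pmax(fr, 0), 1)
  arr <- volume@intensities
  lin <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  x0 <- i0[, 1]; y0 <- i0[, 2]; z0 <- i0[, 3]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  v000 <- lin(x0, y0, z0);     v100 <- lin(x0 + 1, y0, z0)
  v010 <- lin(x0, y0 + 1, z0); v110 <- lin(x0 + 1, y0 + 1, z0)
  v001 <- lin(x0, y0, z0 + 1); v101 <- lin(x0 + 1, y0, z0 + 1)
  v011 <- lin(x0, y0 + 1, z0 + 1); v111 <- lin(x0 + 1, y0 + 1, z0 + 1)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inb] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Extract an intensity profile along a ray
#'
#' Samples the volume by trilinear interpolation from \code{-back} to
#' \code{+forward} mm at a uniform step, with 0 at \code{start}.
#'
#' @param volume a VoxelVolume.
#' @param start numeric(3), the reference vertex (mm).
#' @param direction unit vector toward the opposing bone.
#' @param back,forward extent of the profile behind/ahead of start, mm.
#' @param step sample spacing, mm.
#' @return a \linkS4class{Profile}
#' @export
extractProfile <- function(volume, start, direction, back = 4, forward = 10,
                           step = 0.1) {
  stopifnot(step > 0)
  t <- seq(-back, forward, by = step)
  pts <- matrix(start, length(t), 3, byrow = TRUE) +
    outer(t, as.numeric(direction))
  d <- dim(volume@intensities)
  lo <- volume@origin
  hi <- volume@origin + (d - 1) * volume@spacing
  for (end in c(1, length(t))) {
    p <- pts[end, ]
    if (any(p < lo - 1e-9) || any(p > hi + 1e-9))
      stop(sprintf(
        "profile out of bounds: endpoint (%.2f, %.2f, %.2f) outside volume",
        p[1], p[2], p[3]))
  }
  y <- trilinearSample(volume, pts)
  if (anyNA(y)) stop("profile out of bounds: interior sample outside volume")
  Profile(t, y)
}

blurModelPredict <- function(par, t) {
  # par: b, A1, A2, m, w, s ; edges e1 = m - w, e2 = m + w
  b <- par[1]; A1 <- par[2]; A2 <- par[3]
  e1 <- par[4] - par[5]; e2 <- par[4] + par[5]; s <- par[6]
  b + (A1 - b) * pnorm((e1 - t) / s) + (A2 - b) * pnorm((t - e2) / s)
}

#' Fit the blurred two-edge profile model
#'
#' Model: \eqn{y(t) = b + (A_1-b)\Phi((e_1-t)/s) + (A_2-b)\Phi((t-e_2)/s)}
#' with the constraint \eqn{e_1 \le e_2} (parameterised by midpoint and
#' non-negative half-width) and \eqn{s} bounded to \code{psfBounds}.
#' JSW is \eqn{e_2 - e_1}. Initial values come from the extrema of a
#' smoothed derivative of the profile. A profile with no second intensity
#' rise is flagged \code{"no_opposing_edge"} (the vertex is masked out by
#' the caller, mirroring patch-margin unreliability).
#'
#' When the gap is below the blur width the two edges overlap and the
#' background level trades off against the gap width along a nearly flat
#' residual valley; supplying \code{background} (the known soft-tissue
#' intensity, e.g. estimated from the volume) anchors \eqn{b} and restores
#' identifiability of sub-voxel gaps.
#'
#' @param profile a \linkS4class{Profile}.
#' @param psfBounds numeric(2), allowed blur SD range in mm
#'   (default c(0.2, 1.5)).
#' @param background optional fixed background intensity \eqn{b}; NULL
#'   (default) fits \eqn{b} freely.
#' @return a \linkS4class{ProfileFit}
#' @export
fitBlurModel <- function(profile, psfBounds = c(0.2, 1.5),
                         background = NULL) {
  t <- profile@positions
  y <- profile@intensities
  n <- length(t)
  step <- t[2] - t[1]
  failFit <- function(status) {
    new("ProfileFit", b = NA_real_, A1 = NA_real_, A2 = NA_real_,
        e1 = NA_real_, e2 = NA_real_, s = NA_real_, jsw = NA_real_,
        rmsResidual = NA_real_, converged = FALSE, status = status)
  }
  # smoothed derivative for initialisation
  k <- max(3, min(9, 2 * floor(0.25 / step) + 1))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  dy <- diff(ys) / step
  # first strong falling edge = the reference bone surface; refine to the
  # local extremum inside its contiguous run of strong-gradient samples
  refineRun <- function(cand, d, pick) {
    i <- cand[1]
    run <- i
    j <- 2
    while (j <= length(cand) && cand[j] == cand[j - 1] + 1 &&
           cand[j - 1] >= i) { run <- c(run, cand[j]); j <- j + 1 }
    run[pick(d[run])]
  }
  fallCand <- which(dy <= 0.5 * min(dy))
  if (!length(fallCand) || min(dy) >= 0) return(failFit("no_reference_edge"))
  i1 <- refineRun(fallCand, dy, which.min)
  if (i1 >= n - 2) return(failFit("no_opposing_edge"))
  after <- (i1 + 1):(n - 1)
  posMax <- max(dy[after])
  if (posMax <= 0) return(failFit("no_opposing_edge"))
  riseCand <- after[dy[after] >= 0.5 * posMax]
  i2 <- refineRun(riseCand, dy, which.max)
  e1_0 <- (t[i1] + t[i1 + 1]) / 2
  e2_0 <- (t[i2] + t[i2 + 1]) / 2
  # truncate at the two plateau peaks so the finite cortical shells
  # (intensity falling again beyond either bone) do not distort the fit
  i3 <- i2 + which.max(ys[(i2 + 1):n])
  i0 <- which.max(ys[1:i1])
  tf <- t[i0:i3]; yf <- y[i0:i3]
  s0 <- min(max(0.5, psfBounds[1]), psfBounds[2])
  nf <- length(yf)
  A1_0 <- mean(yf[tf < e1_0 - 2 * s0])
  if (!is.finite(A1_0)) A1_0 <- mean(yf[seq_len(min(nf, max(2, round(n / 10))))])
  A2_0 <- mean(yf[tf > e2_0 + 2 * s0])
  if (!is.finite(A2_0)) A2_0 <- max(ys[(i2 + 1):i3])
  midIdx <- tf > e1_0 + s0 & tf < e2_0 - s0
  b_0 <- if (!is.null(background)) background
    else if (any(midIdx)) mean(yf[midIdx]) else min(ys[i1:i2])
  plateauRef <- A1_0 - b_0
  if (!is.finite(plateauRef) || !is.finite(A2_0))
    return(failFit("not_converged"))
  if (plateauRef <= 0) return(failFit("no_reference_edge"))
  if ((A2_0 - b_0) < 0.15 * plateauRef)
    return(failFit("no_opposing_edge"))
  t <- tf; y <- yf
  if (is.null(background)) {
    par0 <- c(b_0, A1_0, A2_0, (e1_0 + e2_0) / 2, max(0, (e2_0 - e1_0) / 2),
              s0)
    lower <- c(-Inf, -Inf, -Inf, t[1], 0, psfBounds[1])
    upper <- c(Inf, Inf, Inf, t[length(t)], (t[length(t)] - t[1]) / 2,
               psfBounds[2])
    resid <- function(p) y - blurModelPredict(p, t)
  } else {
    par0 <- c(A1_0, A2_0, (e1_0 + e2_0) / 2, max(0, (e2_0 - e1_0) / 2), s0)
    lower <- c(-Inf, -Inf, t[1], 0, psfBounds[1])
    upper <- c(Inf, Inf, t[length(t)], (t[length(t)] - t[1]) / 2,
               psfBounds[2])
    resid <- function(p) y - blurModelPredict(c(background, p), t)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failFit("not_converged"))
  p <- if (is.null(background)) fit$par else c(background, fit$par)
  conv <- fit$info %in% 1:4
  new("ProfileFit", b = p[1], A1 = p[2], A2 = p[3],
      e1 = p[4] - p[5], e2 = p[4] + p[5], s = p[6], jsw = 2 * p[5],
      rmsResidual = sqrt(mean(fit$fvec^2)),
      converged = conv, status = if (conv) "ok" else "not_converged")
}

#' Default measurement parameters for mapJSW
#' @keywords internal
jswParams <- function(params = list()) {
  def <- list(tMax = 6, back = 4, forward = NULL, step = 0.1,
              psfBounds = c(0.2, 1.5), smoothIterations = 5,
              smoothWeight = 0.5, background = "auto")
  def[names(params)] <- params
  if (is.null(def$forward)) def$forward <- def$tMax + 4
  def
}

#' Measure joint space width across a patch
#'
#' For every patch vertex inside the shadow of the opposing bone, an
#' intensity profile is extracted along the vertex normal and the blurred
#' two-edge model fitted; failed fits are masked. The JSW field is then
#' smoothed with masked umbrella averaging.
#'
#' @param volume the CT-like \linkS4class{VoxelVolume}.
#' @param patch the articular \linkS4class{JointPatch}.
#' @param opposing the opposing bone SurfaceMesh.
#' @param params list overriding defaults: tMax (6 mm), back (4 mm),
#'   forward (tMax + 4 mm), step (0.1 mm), psfBounds (c(0.2, 1.5) mm),
#'   smoothIterations (5), smoothWeight (0.5), background ("auto": the
#'   soft-tissue level estimated as the median sub-midpoint intensity of
#'   the volume, anchoring the profile fits; a number fixes it; NULL frees
#'   it per profile).
#' @return a \linkS4class{JSWMap}
#' @export
mapJSW <- function(volume, patch, opposing, params = list()) {
  p <- jswParams(params)
  if (identical(p$background, "auto")) {
    mid <- mean(range(volume@intensities))
    p$background <- stats::median(volume@intensities[volume@intensities < mid])
  }
  mesh <- patch@mesh
  shadow <- castShadow(mesh, opposing, p$tMax)
  nV <- nrow(mesh@vertices)
  vals <- rep(NA_real_, nV)
  rms <- rep(NA_real_, nV)
  conv <- rep(FALSE, nV)
  status <- rep("outside_shadow", nV)
  lo <- volume@origin
  hi <- volume@origin + (dim(volume@intensities) - 1) * volume@spacing
  raySpan <- function(o, d) {
    # parametric span of o + t d inside the volume box (slab method)
    t0 <- -Inf; t1 <- Inf
    for (k in 1:3) {
      if (abs(d[k]) < 1e-12) next
      a <- (lo[k] - o[k]) / d[k]; b <- (hi[k] - o[k]) / d[k]
      t0 <- max(t0, min(a, b)); t1 <- min(t1, max(a, b))
    }
    c(t0, t1)
  }
  for (i in which(shadow)) {
    span <- raySpan(mesh@vertices[i, ], mesh@normals[i, ])
    backI <- min(p$back, -span[1] - p$step)
    fwdI <- min(p$forward, span[2] - p$step)
    prof <- tryCatch(
      extractProfile(volume, mesh@vertices[i, ], mesh@normals[i, ],
                     back = backI, forward = fwdI, step = p$step),
      error = function(e) NULL)
    if (is.null(prof)) { status[i] <- "out_of_bounds"; next }
    fit <- fitBlurModel(prof, p$psfBounds, background = p$background)
    status[i] <- fit@status
    if (fit@converged && fit@status == "ok" &&
        fit@jsw >= 0 && fit@jsw <= p$tMax) {
      vals[i] <- fit@jsw
      rms[i] <- fit@rmsResidual
      conv[i] <- TRUE
    }
  }
  nShadow <- sum(shadow)
  nFail <- nShadow - sum(conv)
  if (nShadow > 0 && nFail > 0.5 * nShadow)
    warning(sprintf("mapJSW: %d of %d profile fits failed", nFail, nShadow))
  field <- ScalarField(vals, mask = conv)
  field <- smoothField(field, mesh, iterations = p$smoothIterations,
                       weight = p$smoothWeight)
  new("JSWMap", field = field,
      quality = data.frame(rms_residual = rms, converged = conv,
                           status = status),
      patch = patch)
}

#' Brute-force mesh-to-mesh JSW oracle
#'
#' JSW at each patch vertex is the distance to the first intersection of
#' the outward-normal ray with the opposing surface; no image is involved.
#' Used to validate image-based measurement.
#'
#' @param patch a JointPatch. @param opposing opposing SurfaceMesh.
#' @param tMax maximum distance, mm (default 6); farther vertices masked.
#' @return a \linkS4class{JSWMap}
#' @export
rayDistanceOracle <- function(patch, opposing, tMax = 6) {
  mesh <- patch@mesh
  d <- cpp_ray_mesh(mesh@vertices, mesh@normals,
                    opposing@vertices, opposing@faces, tMax)
  ok <- !is.na(d) & d > 0
  vals <- ifelse(ok, d, NA_real_)
  new("JSWMap", field = ScalarField(vals, mask = ok),
      quality = data.frame(rms_residual = ifelse(ok, 0, NA_real_),
                           converged = ok,
                           status = ifelse(ok, "ok", "no_intersection")),
      patch = patch)
}
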