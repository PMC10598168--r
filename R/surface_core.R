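#' Construct a SurfaceMesh
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of per-vertex unit normals; computed
#'   from area-weighted face normals when omitted.
#' @param checkManifold warn (not error) on non-manifold edges.
#' @return a \linkS4class{SurfaceMesh}
#' @export
SurfaceMesh <- function(vertices, faces, normals = NULL,
                        checkManifold = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (is.null(normals)) normals <- vertexNormals(vertices, faces)
  normals <- as.matrix(normals)
  storage.mode(normals) <- "double"
  if (checkManifold && nrow(faces) > 0) {
    e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    cnt <- table(key)
    if (any(cnt > 2))
      warning(sprintf("mesh is non-manifold: %d edges shared by > 2 faces",
                      sum(cnt > 2)))
  }
  new("SurfaceMesh", vertices = vertices, faces = faces, normals = normals)
}

#' Construct a ScalarField
#'
#' @param values numeric vector, one per host-mesh vertex.
#' @param mask logical validity flags; default: finite values.
#' @return a \linkS4class{ScalarField}
#' @export
ScalarField <- function(values, mask = NULL) {
  values <- as.numeric(values)
  if (is.null(mask)) mask <- is.finite(values)
  new("ScalarField", values = values, mask = as.logical(mask))
}

#' Construct a JointPatch directly (see also patchSubmesh)
#' @param mesh patch submesh. @param parentIndex map to parent vertices.
#' @param label facet label.
#' @export
JointPatch <- function(mesh, parentIndex, label = "patch") {
  new("JointPatch", mesh = mesh, parentIndex = as.integer(parentIndex),
      label = as.character(label))
}

#' Construct a VoxelVolume
#' @param intensities 3-D array. @param spacing isotropic spacing (mm).
#' @param origin world position (mm) of voxel [1,1,1] centre.
#' @export
VoxelVolume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  new("VoxelVolume", intensities = intensities,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Construct a Profile
#' @param positions uniform strictly increasing coordinates (mm).
#' @param intensities sampled intensities.
#' @export
Profile <- function(positions, intensities) {
  new("Profile", positions = as.numeric(positions),
      intensities = as.numeric(intensities))
}

#' Construct a RigidTransform (x -> R x + t)
#' @param rotation 3 x 3 orthonormal matrix. @param translation numeric(3) mm.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

## ---- mesh utilities ----

#' Per-face areas (mm^2)
#' @param mesh a SurfaceMesh (or vertex matrix with faces given)
#' @param faces optional face matrix when `mesh` is a vertex matrix
#' @export
faceAreas <- function(mesh, faces = NULL) {
  if (is(mesh, "SurfaceMesh")) { v <- mesh@vertices; f <- mesh@faces }
  else { v <- mesh; f <- faces }
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Lumped per-vertex areas: one third of incident face area
#' @param mesh a SurfaceMesh
#' @export
vertexAreas <- function(mesh) {
  fa <- faceAreas(mesh)
  w <- numeric(nrow(mesh@vertices))
  for (k in 1:3) {
    acc <- tapply(fa, mesh@faces[, k], sum)
    idx <- as.integer(names(acc))
    w[idx] <- w[idx] + acc
  }
  w / 3
}

#' Area-weighted per-vertex unit normals
#' @param vertices n x 3 matrix. @param faces m x 3 index matrix.
#' @export
vertexNormals <- function(vertices, faces) {
  n <- matrix(0, nrow(vertices), 3)
  if (nrow(faces) == 0) return(n)
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # area-weighted already
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fn[, d], faces[, k], sum)
      idx <- as.integer(names(acc))
      n[idx, d] <- n[idx, d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- NA_real_
  n / len
}

#' Sparse vertex adjacency (1-ring) from shared faces
#' @param mesh a SurfaceMesh
#' @return a sparse symmetric 0/1 Matrix
#' @export
vertexAdjacency <- function(mesh) {
  f <- mesh@faces
  i <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  n <- nrow(mesh@vertices)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  A@x[] <- 1  # collapse duplicate edges
  A
}

#' Vertices of a mask adjacent to a vertex outside it
#' @param mask logical per-vertex flags. @param mesh a SurfaceMesh.
#' @return integer vertex indices on the mask boundary
#' @export
maskBoundaryVertices <- function(mask, mesh) {
  A <- vertexAdjacency(mesh)
  outNbr <- as.vector(A %*% as.numeric(!mask))
  which(mask & outNbr > 0)
}

edgeLengthGraph <- function(mesh) {
  f <- mesh@faces
  e <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt(rowSums((mesh@vertices[e[, 1], , drop = FALSE] -
                       mesh@vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  list(graph = g, weights = len)
}

#' Apply a rigid transform to a mesh, patch, or point matrix
#' @param x SurfaceMesh, JointPatch, or n x 3 matrix
#' @param transform a RigidTransform
#' @export
applyTransform <- function(x, transform) {
  R <- transform@rotation; t <- transform@translation
  if (is(x, "SurfaceMesh")) {
    v <- x@vertices %*% t(R) + matrix(t, nrow(x@vertices), 3, byrow = TRUE)
    n <- x@normals %*% t(R)
    new("SurfaceMesh", vertices = v, faces = x@faces, normals = n)
  } else if (is(x, "JointPatch")) {
    new("JointPatch", mesh = applyTransform(x@mesh, transform),
        parentIndex = x@parentIndex, label = x@label)
  } else {
    x %*% t(R) + matrix(t, nrow(x), 3, byrow = TRUE)
  }
}

## ---- mesh generators ----

#' Regular grid mesh in the z = 0 plane, normals +z
#'
#' @param extent numeric(1) or (2): side length(s), mm; centred on origin.
#' @param resolution target edge length, mm.
#' @param zfun optional function(x, y) giving vertex heights.
#' @export
gridMesh <- function(extent, resolution = 1, zfun = NULL) {
  ext <- rep(extent, length.out = 2)
  nx <- max(2, round(ext[1] / resolution) + 1)
  ny <- max(2, round(ext[2] / resolution) + 1)
  xs <- seq(-ext[1] / 2, ext[1] / 2, length.out = nx)
  ys <- seq(-ext[2] / 2, ext[2] / 2, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  z <- if (is.null(zfun)) 0 else zfun(g$x, g$y)
  v <- cbind(g$x, g$y, z)
  idx <- function(i, j) (j - 1) * nx + i
  i <- rep(1:(nx - 1), ny - 1)
  j <- rep(1:(ny - 1), each = nx - 1)
  # counter-clockwise seen from +z
  f <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
             cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  SurfaceMesh(v, f)
}

#' Icosphere: subdivided icosahedron projected to a sphere
#' @param subdivisions subdivision depth (0 = icosahedron).
#' @param radius sphere radius, mm. @param center numeric(3), mm.
#' @export
icosphere <- function(subdivisions = 2, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    getMid <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c3 <- f[r, 3]
      ab <- getMid(a, b); bc <- getMid(b, c3); ca <- getMid(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v * radius + matrix(center, nrow(v), 3, byrow = TRUE)
  SurfaceMesh(v, f)
}

## ---- spec operations ----

#' Extract the largest connected patch induced by a vertex mask
#'
#' Faces are kept iff all three vertices are selected; connectivity is
#' through shared edges between kept faces; the largest component (by face
#' count) becomes the patch.
#'
#' @param mesh parent SurfaceMesh.
#' @param vertexMask logical per-vertex selection.
#' @param label facet label.
#' @return a \linkS4class{JointPatch} with parentIndex mapping back to `mesh`
#' @export
patchSubmesh <- function(mesh, vertexMask, label = "patch") {
  stopifnot(length(vertexMask) == nrow(mesh@vertices))
  keep <- vertexMask[mesh@faces[, 1]] & vertexMask[mesh@faces[, 2]] &
    vertexMask[mesh@faces[, 3]]
  if (!any(keep)) stop("empty patch: mask selects no complete face")
  f <- mesh@faces[keep, , drop = FALSE]
  # face adjacency through shared edges
  eKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- data.frame(
    key = c(eKey(f[, 1], f[, 2]), eKey(f[, 2], f[, 3]), eKey(f[, 3], f[, 1])),
    face = rep(seq_len(nrow(f)), 3))
  sp <- split(edges$face, edges$key)
  pairs <- do.call(rbind, lapply(sp[lengths(sp) >= 2], function(fs) {
    t(utils::combn(fs, 2))
  }))
  comp <- if (is.null(pairs) || nrow(f) == 1) {
    rep(1L, nrow(f))
  } else {
    g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(f) - max(pairs)))
    igraph::components(g)$membership[seq_len(nrow(f))]
  }
  best <- as.integer(names(which.max(table(comp))))
  f <- f[comp == best, , drop = FALSE]
  vids <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh@vertices))
  remap[vids] <- seq_along(vids)
  sub <- new("SurfaceMesh",
             vertices = mesh@vertices[vids, , drop = FALSE],
             faces = matrix(remap[f], ncol = 3),
             normals = mesh@normals[vids, , drop = FALSE])
  new("JointPatch", mesh = sub, parentIndex = as.integer(vids),
      label = as.character(label))
}

#' Iterated masked umbrella smoothing of a vertex field
#'
#' Each iteration replaces a valid vertex value by
#' \code{(1 - weight) * value + weight * mean(valid 1-ring neighbours)}.
#' Masked-out vertices neither change nor contribute to neighbour means;
#' the mask is unchanged.
#'
#' @param field a ScalarField hosted on `mesh`.
#' @param mesh the host SurfaceMesh (or JointPatch).
#' @param iterations number of smoothing passes (default 5).
#' @param weight blending weight in [0, 1] (default 0.5).
#' @return the smoothed \linkS4class{ScalarField}
#' @export
smoothField <- function(field, mesh, iterations = 5, weight = 0.5) {
  if (is(mesh, "JointPatch")) mesh <- mesh@mesh
  if (iterations < 0) stop("iterations must be >= 0")
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  stopifnot(length(field@values) == nrow(mesh@vertices))
  if (iterations == 0 || weight == 0) return(field)
  A <- vertexAdjacency(mesh)
  v <- field@values
  m <- as.numeric(field@mask)
  vals <- ifelse(field@mask, v, 0)
  for (it in seq_len(iterations)) {
    num <- as.vector(A %*% vals)
    den <- as.vector(A %*% m)
    nbrMean <- ifelse(den > 0, num / den, vals)
    upd <- (1 - weight) * vals + weight * nbrMean
    vals <- ifelse(field@mask, upd, vals)
  }
  out <- v
  out[field@mask] <- vals[field@mask]
  new("ScalarField", values = out, mask = field@mask)
}

#' Area-weighted mean of a field over a patch
#'
#' Each valid vertex is weighted by one third of its summed incident face
#' area on the patch submesh (barycentric lumping).
#'
#' @param field ScalarField on the patch vertices.
#' @param patch a JointPatch (or SurfaceMesh).
#' @return numeric(1)
#' @export
patchMean <- function(field, patch) {
  mesh <- if (is(patch, "JointPatch")) patch@mesh else patch
  stopifnot(length(field@values) == nrow(mesh@vertices))
  ok <- field@mask & is.finite(field@values)
  if (!any(ok)) stop("empty field: no valid vertices")
  w <- vertexAreas(mesh)
  sum(w[ok] * field@values[ok]) / sum(w[ok])
}
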