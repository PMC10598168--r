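## Mesh and volume I/O.
## PLY/OBJ are parsed here directly (no installed package reads them);
## vertex indices are 0-based on disk per both formats, 1-based in memory.

#' Read a PLY mesh (ASCII or binary little-endian)
#' @param path file path
#' @return a \linkS4class{SurfaceMesh}
#' @export
readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 200) stop("PLY header not terminated")
  }
  fmt <- grep("^format", header, value = TRUE)[1]
  ascii <- grepl("ascii", fmt)
  if (!ascii && !grepl("binary_little_endian", fmt))
    stop("unsupported PLY format: ", fmt)
  elLines <- grep("^element", header)
  nV <- nF <- 0L
  propTypes <- character()
  for (i in elLines) {
    parts <- strsplit(header[i], "\\s+")[[1]]
    if (parts[2] == "vertex") {
      nV <- as.integer(parts[3])
      j <- i + 1
      while (j <= length(header) && grepl("^property", header[j])) {
        propTypes <- c(propTypes, strsplit(header[j], "\\s+")[[1]][2])
        j <- j + 1
      }
    }
    if (parts[2] == "face") nF <- as.integer(parts[3])
  }
  if (ascii) {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    vtxt <- txt[seq_len(nV)]
    vmat <- do.call(rbind, lapply(strsplit(trimws(vtxt), "\\s+"), as.numeric))
    ftxt <- txt[nV + seq_len(nF)]
    fmat <- do.call(rbind, lapply(strsplit(trimws(ftxt), "\\s+"), function(x) {
      x <- as.integer(x)
      if (x[1] != 3) stop("only triangle faces supported")
      x[2:4] + 1L
    }))
  } else {
    sizes <- c(float = 4, float32 = 4, double = 8, float64 = 8,
               uchar = 1, uint8 = 1, char = 1, int8 = 1,
               short = 2, ushort = 2, int = 4, int32 = 4, uint = 4,
               uint32 = 4)
    np <- length(propTypes)
    vmat <- matrix(NA_real_, nV, np)
    for (i in seq_len(nV)) {
      for (p in seq_len(np)) {
        ty <- propTypes[p]
        vmat[i, p] <- if (ty %in% c("float", "float32"))
          readBin(con, "double", 1, size = 4, endian = "little")
        else if (ty %in% c("double", "float64"))
          readBin(con, "double", 1, size = 8, endian = "little")
        else readBin(con, "integer", 1, size = sizes[[ty]],
                     endian = "little")
      }
    }
    fmat <- matrix(0L, nF, 3)
    for (i in seq_len(nF)) {
      cnt <- readBin(con, "integer", 1, size = 1, signed = FALSE,
                     endian = "little")
      if (cnt != 3) stop("only triangle faces supported")
      fmat[i, ] <- readBin(con, "integer", 3, size = 4,
                           endian = "little") + 1L
    }
  }
  v <- vmat[, 1:3, drop = FALSE]
  nrm <- NULL
  if (ncol(vmat) >= 6 && all(c("nx", "ny", "nz") %in%
      sub("^property\\s+\\S+\\s+", "", grep("^property", header, value = TRUE)))) {
    propNames <- vapply(strsplit(grep("^property", header, value = TRUE),
                                 "\\s+"), function(x) x[3], "")
    ni <- match(c("nx", "ny", "nz"), propNames)
    if (!anyNA(ni)) nrm <- vmat[, ni, drop = FALSE]
  }
  SurfaceMesh(v, fmat, normals = nrm)
}

#' Write a mesh as ASCII PLY (with per-vertex normals)
#' @param mesh a SurfaceMesh. @param path output path.
#' @export
writePLY <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces; n <- mesh@normals
  n[!is.finite(n)] <- 0
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  vl <- apply(cbind(v, n), 1, function(r) paste(format(r, trim = TRUE),
                                                collapse = " "))
  fl <- apply(f - 1L, 1, function(r) paste(c(3, r), collapse = " "))
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Read a Wavefront OBJ mesh (triangles)
#' @param path file path
#' @export
readOBJ <- function(path) {
  txt <- readLines(path)
  vt <- txt[startsWith(txt, "v ")]
  ft <- txt[startsWith(txt, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vt)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", ft)), "\\s+"),
                             function(x) {
    if (length(x) != 3) stop("only triangle faces supported")
    as.integer(sub("/.*", "", x))
  }))
  SurfaceMesh(v, f)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a SurfaceMesh. @param path output path.
#' @export
writeOBJ <- function(mesh, path) {
  vl <- apply(mesh@vertices, 1, function(r)
    paste("v", paste(format(r, trim = TRUE), collapse = " ")))
  fl <- apply(mesh@faces, 1, function(r)
    paste("f", paste(r, collapse = " ")))
  writeLines(c(vl, fl), path)
  invisible(path)
}

#' Write a mesh with named per-vertex scalar arrays as legacy VTK PolyData
#'
#' @param mesh SurfaceMesh or JointPatch.
#' @param path output path (conventionally .vtk).
#' @param fields named list of ScalarFields or numeric vectors; masked
#'   vertices are written as NaN. Conventional names: "jsw", "bias", "loa",
#'   "F", "p_corrected", "true_gap".
#' @export
writeVTK <- function(mesh, path, fields = list()) {
  if (is(mesh, "JointPatch")) mesh <- mesh@mesh
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "jsmap surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(apply(v, 1, function(r)
    paste(format(r, trim = TRUE), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  writeLines(apply(f - 1L, 1, function(r)
    paste(c(3, r), collapse = " ")), con)
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(fields)) {
      x <- fields[[nm]]
      if (is(x, "ScalarField")) {
        vals <- ifelse(x@mask, x@values, NaN)
      } else vals <- as.numeric(x)
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(vals, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Write a VoxelVolume as NIfTI-1
#' @param volume a VoxelVolume. @param path output path (.nii or .nii.gz).
#' @export
writeVoxelVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@intensities)
  RNifti::pixdim(img) <- rep(volume@spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file into a VoxelVolume (isotropic grids only)
#' @param path file path. @param origin world position of voxel [1,1,1].
#' @export
readVoxelVolume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (max(pd) - min(pd) > 1e-6)
    stop("only isotropic volumes are supported")
  VoxelVolume(array(as.numeric(img), dim = dim(img)), spacing = pd[1],
              origin = origin)
}

#' Write a VoxelVolume as MetaImage (.mhd header + .raw data)
#' @param volume a VoxelVolume. @param path path to the .mhd header.
#' @export
writeMetaImage <- function(volume, path) {
  rawPath <- sub("\\.mhd$", ".raw", path)
  d <- dim(volume@intensities)
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
               sprintf("ElementSpacing = %g %g %g", volume@spacing,
                       volume@spacing, volume@spacing),
               sprintf("Offset = %g %g %g", volume@origin[1],
                       volume@origin[2], volume@origin[3]),
               "ElementType = MET_DOUBLE",
               sprintf("ElementDataFile = %s", basename(rawPath))), path)
  con <- file(rawPath, "wb")
  writeBin(as.vector(volume@intensities), con, size = 8, endian = "little")
  close(con)
  invisible(path)
}
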