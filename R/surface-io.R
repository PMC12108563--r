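#' Read and write STL surface files
#'
#' `write_stl` writes binary (default) or ASCII STL; `read_stl` detects the
#' format. STL stores a triangle soup, so reading re-welds identical vertex
#' coordinates into shared vertices.
#'
#' @param s a [tri_surface()].
#' @param path file path.
#' @param ascii write ASCII STL instead of binary.
#' @param name solid name recorded in the file.
#' @return `write_stl`: `path` invisibly; `read_stl`: a [tri_surface()].
#' @export
write_stl <- function(s, path, ascii = FALSE, name = "tmjfem") {
  stopifnot(inherits(s, "tri_surface"))
  v1 <- s$vertices[s$faces[, 1], , drop = FALSE]
  v2 <- s$vertices[s$faces[, 2], , drop = FALSE]
  v3 <- s$vertices[s$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  n <- nrow(s$faces)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("solid", name), con)
    for (i in seq_len(n)) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", v1[i, 1], v1[i, 2], v1[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", v2[i, 1], v2[i, 2], v2[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", v3[i, 1], v3[i, 2], v3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(paste("endsolid", name), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("binary stl", name)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    # interleave: normal, v1, v2, v3, attribute count per facet
    block <- t(cbind(nrm, v1, v2, v3))
    for (i in seq_len(n)) {
      writeBin(as.numeric(block[, i]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 80L)
  is_ascii <- grepl("^solid", rawToChar(head[1:5]))
  if (is_ascii) {
    close(con)
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    tris <- nums
  } else {
    n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    vals <- matrix(0, 9L, n)
    for (i in seq_len(n)) {
      rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)
      vals[, i] <- rec[4:12]
    }
    close(con)
    tris <- matrix(as.vector(vals), ncol = 3L, byrow = TRUE)
  }
  # weld identical coordinates
  key <- paste(tris[, 1], tris[, 2], tris[, 3])
  uk <- !duplicated(key)
  verts <- tris[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tri_surface(verts, matrix(idx, ncol = 3L, byrow = TRUE))
}

#' Write a surface as legacy VTK PolyData
#'
#' Optionally attaches one per-vertex scalar field (e.g. a deviation map)
#' as `POINT_DATA`.
#'
#' @param s a [tri_surface()].
#' @param path output file.
#' @param point_scalars optional numeric vector, one value per vertex.
#' @param scalar_name field name in the VTK file.
#' @return `path`, invisibly.
#' @export
write_surface_vtk <- function(s, path, point_scalars = NULL,
                              scalar_name = "deviation_mm") {
  stopifnot(inherits(s, "tri_surface"))
  nv <- nrow(s$vertices); nf <- nrow(s$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tmjfem surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(apply(s$vertices, 1L, function(r)
    sprintf("%.9g %.9g %.9g", r[1], r[2], r[3])), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(apply(s$faces - 1L, 1L, function(r)
    sprintf("3 %d %d %d", r[1], r[2], r[3])), con)
  if (!is.null(point_scalars)) {
    stopifnot(length(point_scalars) == nv)
    writeLines(c(sprintf("POINT_DATA %d", nv),
                 sprintf("SCALARS %s double 1", scalar_name),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", point_scalars), con)
  }
  invisible(path)
}
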