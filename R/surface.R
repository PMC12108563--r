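#' Triangulated surface
#'
#' Vertex coordinates in mm and triangle connectivity (1-based vertex index
#' triplets). Degenerate (zero-area) triangles are dropped at construction.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of vertex indices.
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (nrow(faces)) {
    a <- triangle_areas(vertices, faces)
    faces <- faces[a > 0, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface> %d vertices, %d triangles, area %.3f mm^2\n",
              nrow(x$vertices), nrow(x$faces), surface_area(x)))
  invisible(x)
}

triangle_areas <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - v1
  e2 <- vertices[faces[, 3], , drop = FALSE] - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Surface area and enclosed volume
#'
#' `enclosed_volume` integrates the divergence theorem over the triangles
#' (signed tetrahedra to the origin); it equals the enclosed volume for
#' closed, consistently outward-oriented surfaces.
#'
#' @param s a [tri_surface()].
#' @return Scalar mm^2 / mm^3.
#' @export
surface_area <- function(s) {
  stopifnot(inherits(s, "tri_surface"))
  if (!nrow(s$faces)) return(0)
  sum(triangle_areas(s$vertices, s$faces))
}

#' @rdname surface_area
#' @export
enclosed_volume <- function(s) {
  stopifnot(inherits(s, "tri_surface"))
  if (!nrow(s$faces)) return(0)
  v1 <- s$vertices[s$faces[, 1], , drop = FALSE]
  v2 <- s$vertices[s$faces[, 2], , drop = FALSE]
  v3 <- s$vertices[s$faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
        v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
        v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

#' Axis-aligned box surface
#'
#' @param lo,hi opposite box corners (mm).
#' @return A closed, outward-oriented [tri_surface()] with 12 triangles.
#' @export
box_surface <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: x fastest; faces as outward-oriented triangles
  f <- rbind(
    c(1, 7, 3), c(1, 5, 7),   # -x
    c(2, 4, 8), c(2, 8, 6),   # +x
    c(1, 2, 6), c(1, 6, 5),   # -y
    c(3, 8, 4), c(3, 7, 8),   # +y
    c(1, 4, 2), c(1, 3, 4),   # -z
    c(5, 6, 8), c(5, 8, 7))   # +z
  tri_surface(v, f)
}

#' Triangulated sphere (subdivided icosahedron)
#'
#' @param centre sphere centre (mm).
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-way triangle subdivisions (default 3).
#' @return A closed [tri_surface()].
#' @export
sphere_surface <- function(centre = c(0, 0, 0), radius = 1, subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    keys <- c(edge_key(f[, 1], f[, 2]), edge_key(f[, 2], f[, 3]),
              edge_key(f[, 3], f[, 1]))
    uk <- unique(keys)
    mid_id <- match(keys, uk) + nv
    ab <- mid_id[seq_len(nrow(f))]
    bc <- mid_id[nrow(f) + seq_len(nrow(f))]
    ca <- mid_id[2 * nrow(f) + seq_len(nrow(f))]
    pairs <- do.call(rbind, strsplit(uk, " "))
    mv <- (v[as.integer(pairs[, 1]), , drop = FALSE] +
             v[as.integer(pairs[, 2]), , drop = FALSE]) / 2
    mv <- mv / sqrt(rowSums(mv^2))
    v <- rbind(v, mv)
    f <- rbind(cbind(f[, 1], ab, ca), cbind(ab, f[, 2], bc),
               cbind(ca, bc, f[, 3]), cbind(ab, bc, ca))
  }
  tri_surface(sweep(v * radius, 2L, centre, "+"), f)
}

#' Concatenate surfaces into one triangle set
#'
#' @param ... `tri_surface` objects.
#' @return A [tri_surface()] with stacked vertices and faces.
#' @export
merge_surfaces <- function(...) {
  ss <- list(...)
  off <- 0L
  vs <- list(); fs <- list()
  for (s in ss) {
    stopifnot(inherits(s, "tri_surface"))
    vs[[length(vs) + 1L]] <- s$vertices
    fs[[length(fs) + 1L]] <- s$faces + off
    off <- off + nrow(s$vertices)
  }
  tri_surface(do.call(rbind, vs), do.call(rbind, fs))
}

#' Apply a rigid transform to a surface
#'
#' @param tr a [rigid_transform()].
#' @param s a [tri_surface()].
#' @return The transformed [tri_surface()].
#' @export
transform_surface <- function(tr, s) {
  stopifnot(inherits(s, "tri_surface"))
  tri_surface(apply_transform(tr, s$vertices), s$faces)
}

#' Extract the boundary surface of a voxel mask
#'
#' Emits the isosurface of the binary field at the 0.5 level under
#' nearest-neighbour interpolation: every voxel face separating a foreground
#' voxel from a background voxel inside the grid becomes two triangles,
#' oriented outward. Faces on the grid border have no neighbour and are
#' omitted, so masks that touch the border yield open surfaces; interior
#' masks yield closed, watertight surfaces.
#'
#' @param m a [mask()].
#' @param spacing,origin override geometry (defaults taken from the mask).
#' @return A [tri_surface()].
#' @export
extract_surface <- function(m, spacing = m$spacing, origin = m$origin) {
  stopifnot(inherits(m, "mask"))
  if (!any(m$data)) stop("cannot extract a surface from an empty mask")
  d <- dim(m$data)
  a <- m$data
  quads <- list()
  # for each axis/direction collect faces fg -> bg
  shift_cmp <- function(axis, dir) {
    # returns arr.ind of foreground voxels whose neighbour at +dir along
    # axis is background (neighbour inside grid)
    idx_fg <- NULL
    if (axis == 1L) {
      if (dir > 0) w <- a[-d[1], , , drop = FALSE] & !a[-1, , , drop = FALSE]
      else w <- a[-1, , , drop = FALSE] & !a[-d[1], , , drop = FALSE]
    } else if (axis == 2L) {
      if (dir > 0) w <- a[, -d[2], , drop = FALSE] & !a[, -1, , drop = FALSE]
      else w <- a[, -1, , drop = FALSE] & !a[, -d[2], , drop = FALSE]
    } else {
      if (dir > 0) w <- a[, , -d[3], drop = FALSE] & !a[, , -1, drop = FALSE]
      else w <- a[, , -1, drop = FALSE] & !a[, , -d[3], drop = FALSE]
    }
    ind <- which(w, arr.ind = TRUE)
    if (!nrow(ind)) return(NULL)
    # convert to the index of the foreground voxel in the full grid
    if (dir < 0) ind[, axis] <- ind[, axis] + 1L
    ind
  }
  # lattice corner coordinates are integers 0..d; encode to a single key
  enc <- function(i, j, k) (as.double(k) * (d[2] + 1) + j) * (d[1] + 1) + i
  vkeys <- list(); tris <- list()
  for (axis in 1:3) for (dir in c(1L, -1L)) {
    ind <- shift_cmp(axis, dir)
    if (is.null(ind)) next
    i <- ind[, 1]; j <- ind[, 2]; k <- ind[, 3]
    # face corners in lattice coords; voxel (i,j,k) spans lattice
    # [i-1,i]x[j-1,j]x[k-1,k]
    if (axis == 1L) {
      x0 <- if (dir > 0) i else i - 1L
      c1 <- enc(x0, j - 1L, k - 1L); c2 <- enc(x0, j, k - 1L)
      c3 <- enc(x0, j, k);           c4 <- enc(x0, j - 1L, k)
      if (dir > 0) tris[[length(tris) + 1L]] <-
          rbind(cbind(c1, c2, c3), cbind(c1, c3, c4))
      else tris[[length(tris) + 1L]] <-
          rbind(cbind(c1, c3, c2), cbind(c1, c4, c3))
    } else if (axis == 2L) {
      y0 <- if (dir > 0) j else j - 1L
      c1 <- enc(i - 1L, y0, k - 1L); c2 <- enc(i, y0, k - 1L)
      c3 <- enc(i, y0, k);           c4 <- enc(i - 1L, y0, k)
      if (dir > 0) tris[[length(tris) + 1L]] <-
          rbind(cbind(c1, c3, c2), cbind(c1, c4, c3))
      else tris[[length(tris) + 1L]] <-
          rbind(cbind(c1, c2, c3), cbind(c1, c3, c4))
    } else {
      z0 <- if (dir > 0) k else k - 1L
      c1 <- enc(i - 1L, j - 1L, z0); c2 <- enc(i, j - 1L, z0)
      c3 <- enc(i, j, z0);           c4 <- enc(i - 1L, j, z0)
      if (dir > 0) tris[[length(tris) + 1L]] <-
          rbind(cbind(c1, c2, c3), cbind(c1, c3, c4))
      else tris[[length(tris) + 1L]] <-
          rbind(cbind(c1, c3, c2), cbind(c1, c4, c3))
    }
  }
  tri <- do.call(rbind, tris)
  keys <- unique(as.vector(tri))
  fidx <- matrix(match(as.vector(tri), keys), ncol = 3L)
  # decode lattice keys back to corner coordinates
  i <- keys %% (d[1] + 1)
  rest <- (keys - i) / (d[1] + 1)
  j <- rest %% (d[2] + 1)
  k <- (rest - j) / (d[2] + 1)
  verts <- cbind(origin[1] + i * spacing[1],
                 origin[2] + j * spacing[2],
                 origin[3] + k * spacing[3])
  tri_surface(verts, fidx)
}
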