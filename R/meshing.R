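# Kuhn decomposition of the unit cube into 6 tetrahedra sharing the main
# diagonal (0,0,0)-(1,1,1). Cube corner order: bit pattern (x, y, z), x
# fastest: 1=(0,0,0) ... 8=(1,1,1). Each row lists 4 cube corners in
# positive-orientation order; translation invariance makes face diagonals
# match across neighbouring cubes, so the split is conforming.
kuhn_tets <- function() {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  paths <- rbind(  # permutations of axis insertion order x,y,z
    c(1, 2, 4, 8),   # +x +y +z
    c(1, 2, 6, 8),   # +x +z +y
    c(1, 3, 4, 8),   # +y +x +z
    c(1, 3, 7, 8),   # +y +z +x
    c(1, 5, 6, 8),   # +z +x +y
    c(1, 5, 7, 8))   # +z +y +x
  # enforce positive orientation (det of edge matrix > 0)
  for (r in seq_len(nrow(paths))) {
    p <- corners[paths[r, ], ]
    if (det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])) < 0)
      paths[r, c(3, 4)] <- paths[r, c(4, 3)]
  }
  list(corners = corners, tets = paths)
}

# C3D10 edge list: mid-node i+4 sits between corners edge[i, ]
c3d10_edges <- function() {
  rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
}

#' Quadratic ten-node tetrahedral mesh
#'
#' Node coordinates (mm), element connectivity (4 corner + 6 mid-edge node
#' ids in C3D10 order), per-element part ids, and named node / surface
#' sets. Mid-edge nodes sit at exact edge midpoints ("straight edges"), so
#' the geometry map of every element is affine.
#'
#' @param nodes n x 3 coordinate matrix.
#' @param elements m x 10 integer connectivity.
#' @param part_id integer vector of length m.
#' @param part_names named integer vector part name -> id.
#' @param node_sets,surface_sets named lists (see [define_node_sets()] and
#'   [part_boundary_faces()]).
#' @param spacing,origin voxel geometry the mesh was built from (metadata).
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elements, part_id, part_names,
                     node_sets = list(), surface_sets = list(),
                     spacing = NULL, origin = NULL) {
  nodes <- matrix(as.numeric(nodes), ncol = 3L)
  elements <- matrix(as.integer(elements), ncol = 10L)
  if (max(elements) > nrow(nodes) || min(elements) < 1L)
    stop("element connectivity references missing nodes")
  structure(list(nodes = nodes, elements = elements,
                 part_id = as.integer(part_id),
                 part_names = part_names,
                 node_sets = node_sets, surface_sets = surface_sets,
                 spacing = spacing, origin = origin,
                 contact_pairs = NULL),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d C3D10 elements, %d parts\n",
              nrow(x$nodes), nrow(x$elements), length(x$part_names)))
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Integer downsampling of a label volume
#'
#' Each `factor^3` block becomes one voxel: if at least half the block is
#' foreground, the block takes the most frequent non-background label (ties
#' to the smaller id); otherwise background. Labels listed in `preserve`
#' (typically thin metal parts such as screws, only a few voxels across)
#' win a block whenever they occupy at least `preserve_fraction` of it, so
#' coarsening does not erase them. The stand-in for the vendor "coarseness"
#' control of image-based meshers.
#'
#' @param labels a [label_volume()].
#' @param factor integer >= 1.
#' @param preserve integer label ids (or part names) given priority.
#' @param preserve_fraction block fraction at which a preserved label wins.
#' @return A [label_volume()] with `factor`-times larger voxels.
#' @export
downsample_labels <- function(labels, factor, preserve = integer(0),
                              preserve_fraction = 0.25) {
  stopifnot(inherits(labels, "label_volume"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(labels)
  d <- dim(labels$labels)
  nd <- d %/% factor
  if (any(nd < 1L)) stop("factor larger than the grid")
  sub <- labels$labels[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                       seq_len(nd[3] * factor), drop = FALSE]
  # block index per voxel
  bi <- (rep(seq_len(nd[1] * factor), times = nd[2] * nd[3] * factor^2) - 1L) %/% factor
  bj <- (rep(rep(seq_len(nd[2] * factor), each = nd[1] * factor),
             times = nd[3] * factor) - 1L) %/% factor
  bk <- (rep(seq_len(nd[3] * factor), each = nd[1] * nd[2] * factor^2) - 1L) %/% factor
  block <- (bk * nd[2] + bj) * nd[1] + bi + 1L
  lab <- as.vector(sub)
  nb <- nd[1] * nd[2] * nd[3]
  out <- integer(nb)
  fg <- lab > 0L
  fg_count <- tabulate(block[fg], nb)
  need <- fg_count >= (factor^3) / 2
  if (any(need)) {
    # most frequent non-background label per needed block
    tab <- table(block = block[fg], label = lab[fg])
    blk_ids <- as.integer(rownames(tab))
    # which.max over columns returns the first (smallest label) on ties
    win <- as.integer(colnames(tab))[apply(tab, 1L, which.max)]
    sel <- need[blk_ids]
    out[blk_ids[sel]] <- win[sel]
  }
  if (is.character(preserve))
    preserve <- unname(labels$part_names[preserve])
  preserve <- preserve[!is.na(preserve)]
  if (length(preserve)) {
    # a preserved label takes a block only on its own count, so adding one
    # preserved part never changes how the others downsample
    best_cnt <- numeric(nb)
    for (pl in sort(preserve)) {
      sel <- lab == pl
      if (!any(sel)) next
      cnt <- tabulate(block[sel], nb)
      win <- cnt >= preserve_fraction * factor^3 & cnt > best_cnt
      out[win] <- pl
      best_cnt <- pmax(best_cnt, ifelse(win, cnt, best_cnt))
    }
  }
  label_volume(array(out, nd), labels$part_names,
               spacing = labels$spacing * factor, origin = labels$origin)
}

#' Mesh a label volume with quadratic tetrahedra
#'
#' Optionally downsamples the label grid by an integer coarseness factor,
#' splits every labelled voxel into 6 tetrahedra (Kuhn decomposition,
#' conforming across voxels and parts), and promotes to quadratic C3D10 by
#' edge-midpoint insertion. Nodes are deduplicated by exact integer lattice
#' coordinates, so interfaces between parts share nodes.
#'
#' @param labels a [label_volume()].
#' @param coarseness integer downsample factor (default 1).
#' @param preserve labels protected during downsampling (see
#'   [downsample_labels()]).
#' @return A [tet_mesh()].
#' @export
mesh_from_labels <- function(labels, coarseness = 1L, preserve = integer(0)) {
  stopifnot(inherits(labels, "label_volume"))
  labels <- downsample_labels(labels, coarseness, preserve = preserve)
  d <- dim(labels$labels)
  vox <- which(labels$labels > 0L)
  if (!length(vox)) stop("label volume is empty: nothing to mesh")
  part <- labels$labels[vox]
  # voxel index -> lattice corner (0-based) of its low corner
  i0 <- (vox - 1L) %% d[1]
  j0 <- ((vox - 1L) %/% d[1]) %% d[2]
  k0 <- (vox - 1L) %/% (d[1] * d[2])

  kt <- kuhn_tets()
  edges <- c3d10_edges()
  nx2 <- 2L * d[1] + 1L; ny2 <- 2L * d[2] + 1L
  enc <- function(x, y, z) (as.double(z) * ny2 + y) * nx2 + x

  nvox <- length(vox)
  conn_keys <- vector("list", 6L)
  for (t_ in 1:6) {
    cn <- kt$corners[kt$tets[t_, ], , drop = FALSE]  # 4 x 3 offsets
    # double-lattice corner coordinates
    cx <- lapply(1:4, function(a) 2L * (i0 + cn[a, 1]))
    cy <- lapply(1:4, function(a) 2L * (j0 + cn[a, 2]))
    cz <- lapply(1:4, function(a) 2L * (k0 + cn[a, 3]))
    keys <- matrix(0, nvox, 10L)
    for (a in 1:4) keys[, a] <- enc(cx[[a]], cy[[a]], cz[[a]])
    for (e in 1:6) {
      a <- edges[e, 1]; b <- edges[e, 2]
      keys[, 4L + e] <- enc((cx[[a]] + cx[[b]]) %/% 2L,
                            (cy[[a]] + cy[[b]]) %/% 2L,
                            (cz[[a]] + cz[[b]]) %/% 2L)
    }
    conn_keys[[t_]] <- keys
  }
  all_keys <- do.call(rbind, conn_keys)
  uk <- unique(as.vector(all_keys))
  conn <- matrix(match(as.vector(all_keys), uk), ncol = 10L)
  # decode lattice keys -> coordinates
  x <- uk %% nx2
  rest <- (uk - x) / nx2
  y <- rest %% ny2
  z <- (rest - y) / ny2
  nodes <- cbind(labels$origin[1] + x * labels$spacing[1] / 2,
                 labels$origin[2] + y * labels$spacing[2] / 2,
                 labels$origin[3] + z * labels$spacing[3] / 2)
  tet_mesh(nodes, conn, part_id = rep(part, 6L),
           part_names = labels$part_names,
           spacing = labels$spacing, origin = labels$origin)
}

#' Volumes of all elements (corner tetrahedra)
#'
#' @param mesh a [tet_mesh()].
#' @return Numeric vector of signed volumes (mm^3); all positive for a
#'   valid mesh.
#' @export
element_volumes <- function(mesh) {
  X <- mesh$nodes
  e <- mesh$elements
  a <- X[e[, 1], , drop = FALSE]
  u <- X[e[, 2], , drop = FALSE] - a
  v <- X[e[, 3], , drop = FALSE] - a
  w <- X[e[, 4], , drop = FALSE] - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
      u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
      u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

# evaluate a geometric predicate spec on points; spec: list(type =
# "box"|"sphere", lo/hi or centre/radius), or list of such (union)
predicate_hits <- function(pts, spec) {
  if (!is.null(spec$type)) spec <- list(spec)
  hit <- rep(FALSE, nrow(pts))
  for (s in spec) {
    if (s$type == "box") {
      hit <- hit | (pts[, 1] >= s$lo[1] & pts[, 1] <= s$hi[1] &
                      pts[, 2] >= s$lo[2] & pts[, 2] <= s$hi[2] &
                      pts[, 3] >= s$lo[3] & pts[, 3] <= s$hi[3])
    } else if (s$type == "sphere") {
      hit <- hit | (rowSums(sweep(pts, 2L, s$centre)^2) <= s$radius^2)
    } else stop("unknown predicate type: ", s$type)
  }
  hit
}

#' Define named node sets from geometric predicates
#'
#' Each spec selects nodes by a world-coordinate box or sphere, optionally
#' restricted to the nodes of one part. Empty sets are kept (and flagged
#' with a warning); solves reject empty required sets.
#'
#' @param mesh a [tet_mesh()].
#' @param specs named list; each element a list with `type`
#'   (`"box"`/`"sphere"`), its geometry (`lo`/`hi` or `centre`/`radius`),
#'   and optional `part` name. A list of such predicates denotes their
#'   union.
#' @return The mesh with populated `node_sets`.
#' @export
define_node_sets <- function(mesh, specs) {
  stopifnot(inherits(mesh, "tet_mesh"))
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    part <- if (!is.null(spec$part)) spec$part else NULL
    hit <- predicate_hits(mesh$nodes, spec)
    ids <- which(hit)
    if (!is.null(part)) {
      pid <- mesh$part_names[[part]]
      pnodes <- unique(as.vector(mesh$elements[mesh$part_id == pid, ]))
      ids <- intersect(ids, pnodes)
    }
    if (!length(ids))
      warning("node set '", nm, "' is empty")
    mesh$node_sets[[nm]] <- as.integer(ids)
  }
  mesh
}

# all corner faces of all elements with element ids and an order-free key
element_faces <- function(mesh) {
  e <- mesh$elements
  ftpl <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  m <- nrow(e)
  fa <- rbind(e[, ftpl[1, ]], e[, ftpl[2, ]], e[, ftpl[3, ]], e[, ftpl[4, ]])
  elem <- rep(seq_len(m), times = 4L)
  lo <- pmin(fa[, 1], fa[, 2], fa[, 3])
  hi <- pmax(fa[, 1], fa[, 2], fa[, 3])
  md <- fa[, 1] + fa[, 2] + fa[, 3] - lo - hi
  key <- paste(lo, md, hi)
  list(faces = fa, elem = elem, key = key)
}

#' Boundary / interface triangle facets of parts
#'
#' Returns the corner-node triangles of element faces that lie on the
#' boundary of `part` — either against the exterior (`against = NULL`) or
#' against another part.
#'
#' @param mesh a [tet_mesh()].
#' @param part part name whose facets are returned.
#' @param against `NULL` for free boundary, or the neighbouring part name.
#' @return Integer matrix (k x 3) of corner node ids (facets of `part`).
#' @export
part_boundary_faces <- function(mesh, part, against = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  ef <- element_faces(mesh)
  pid <- mesh$part_names[[part]]
  owner <- mesh$part_id[ef$elem]
  uk <- unique(ef$key)
  gid <- match(ef$key, uk)
  cnt <- tabulate(gid, length(uk))
  if (is.null(against)) {
    sel <- cnt[gid] == 1L & owner == pid
    return(ef$faces[sel, , drop = FALSE])
  }
  qid <- mesh$part_names[[against]]
  idx2 <- which(cnt[gid] == 2L)
  o <- idx2[order(gid[idx2])]
  a <- o[seq(1L, length(o), 2L)]
  b <- o[seq(2L, length(o), 2L)]
  selA <- owner[a] == pid & owner[b] == qid
  selB <- owner[b] == pid & owner[a] == qid
  rbind(ef$faces[a[selA], , drop = FALSE],
        ef$faces[b[selB], , drop = FALSE])
}

#' Free-boundary facets with their mid-edge nodes
#'
#' Returns the exterior facets of the mesh (optionally restricted to one
#' part and/or to facets whose corners all satisfy a geometric predicate),
#' including the three mid-edge nodes of each facet — needed for
#' consistent (quadratic) surface loading.
#'
#' @param mesh a [tet_mesh()].
#' @param part optional part name filter.
#' @param within optional predicate spec (as in [define_node_sets()]).
#' @return A list with `corners` (k x 3), `mids` (k x 3), `nodes6`
#'   (k x 6) and `elem` (owning element ids).
#' @export
free_boundary_facets <- function(mesh, part = NULL, within = NULL) {
  ef <- element_faces(mesh)
  uk <- unique(ef$key)
  gid <- match(ef$key, uk)
  cnt <- tabulate(gid, length(uk))
  sel <- cnt[gid] == 1L
  if (!is.null(part))
    sel <- sel & mesh$part_id[ef$elem] == mesh$part_names[[part]]
  tri <- ef$faces[sel, , drop = FALSE]
  own <- ef$elem[sel]
  if (!is.null(within) && nrow(tri)) {
    ok <- matrix(predicate_hits(mesh$nodes[as.vector(tri), , drop = FALSE],
                                within), nrow(tri))
    keep <- rowSums(ok) == 3L
    tri <- tri[keep, , drop = FALSE]
    own <- own[keep]
  }
  ed <- c3d10_edges()
  mids <- matrix(0L, nrow(tri), 3L)
  el <- mesh$elements
  for (k in seq_len(nrow(tri))) {
    e10 <- el[own[k], ]
    loc <- match(tri[k, ], e10[1:4])
    pair <- rbind(c(loc[1], loc[2]), c(loc[2], loc[3]), c(loc[3], loc[1]))
    for (j in 1:3) {
      hit <- which((ed[, 1] == pair[j, 1] & ed[, 2] == pair[j, 2]) |
                     (ed[, 1] == pair[j, 2] & ed[, 2] == pair[j, 1]))
      mids[k, j] <- e10[4L + hit]
    }
  }
  list(corners = tri, mids = mids, nodes6 = cbind(tri, mids), elem = own)
}

#' Detach two part groups along their shared interface for contact
#'
#' Nodes referenced exclusively by elements of the slave part and the
#' master part are duplicated: slave elements are rewired to the new copies
#' while master elements keep the originals, so the two bodies can separate
#' or slide. Nodes also touched by any other part (e.g. screws crossing the
#' interface) stay shared, which keeps those parts bonded. The coincident
#' node pairs, together with area-weighted master-side interface normals
#' (pointing from master into slave), are stored in `mesh$contact_pairs`.
#'
#' @param mesh a conforming [tet_mesh()].
#' @param slave,master part names.
#' @return The modified mesh; `contact_pairs` has columns `slave`,
#'   `master` and a `normal` matrix.
#' @export
split_interface <- function(mesh, slave, master) {
  stopifnot(inherits(mesh, "tet_mesh"))
  sid <- mesh$part_names[[slave]]; mid <- mesh$part_names[[master]]
  if (is.null(sid) || is.null(mid)) stop("unknown part name")
  e <- mesh$elements
  # which parts reference each node
  n <- nrow(mesh$nodes)
  touched_by <- function(pid) {
    v <- logical(n)
    v[unique(as.vector(e[mesh$part_id == pid, , drop = FALSE]))] <- TRUE
    v
  }
  tslave <- touched_by(sid); tmaster <- touched_by(mid)
  tother <- logical(n)
  for (pid in setdiff(mesh$part_names, c(sid, mid)))
    tother[unique(as.vector(e[mesh$part_id == pid, , drop = FALSE]))] <- TRUE
  iface <- which(tslave & tmaster & !tother)
  if (!length(iface)) {
    warning("no exclusive interface nodes between '", slave, "' and '",
            master, "'")
    mesh$contact_pairs <- data.frame(slave = integer(0), master = integer(0))
    return(mesh)
  }
  new_ids <- n + seq_along(iface)
  mesh$nodes <- rbind(mesh$nodes, mesh$nodes[iface, , drop = FALSE])
  remap <- seq_len(n)
  remap[iface] <- new_ids
  sel <- mesh$part_id == sid
  es <- e[sel, , drop = FALSE]
  es[] <- remap[es]
  e[sel, ] <- es
  mesh$elements <- e

  # master-side interface facets (free boundary after the split) with mid
  # nodes; outward normals (master -> slave) and consistent tributary
  # areas: a uniform contact pressure lumps to zero at facet corners and
  # one third of the facet area at each mid-edge node
  fb <- free_boundary_facets(mesh, part = master)
  keep <- rowSums(matrix(fb$corners %in% iface, nrow(fb$corners))) == 3L
  tri <- fb$corners[keep, , drop = FALSE]
  mids <- fb$mids[keep, , drop = FALSE]
  own <- fb$elem[keep]
  nrm_acc <- matrix(0, nrow(mesh$nodes), 3L)
  wt_acc <- numeric(nrow(mesh$nodes))
  if (nrow(tri)) {
    X <- mesh$nodes
    e1 <- X[tri[, 2], , drop = FALSE] - X[tri[, 1], , drop = FALSE]
    e2 <- X[tri[, 3], , drop = FALSE] - X[tri[, 1], , drop = FALSE]
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area <- 0.5 * sqrt(rowSums(fn^2))
    for (k in seq_len(nrow(tri))) {
      cen <- colMeans(X[mesh$elements[own[k], 1:4], , drop = FALSE])
      fc <- colMeans(X[tri[k, ], , drop = FALSE])
      nk <- fn[k, ]
      if (sum(nk * (fc - cen)) < 0) nk <- -nk
      nrm_acc[c(tri[k, ], mids[k, ]), ] <-
        nrm_acc[c(tri[k, ], mids[k, ]), ] + rep(nk, each = 6L)
      wt_acc[mids[k, ]] <- wt_acc[mids[k, ]] + area[k] / 3
    }
  }
  nrm <- nrm_acc[iface, , drop = FALSE]
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  mesh$contact_pairs <- list(slave = new_ids, master = iface, normal = nrm,
                             weight = wt_acc[iface])
  mesh$surface_sets[[paste0("contact_", master)]] <- tri
  mesh
}
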