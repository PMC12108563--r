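# 4-point Gauss rule on the reference tetrahedron (degree-2 exact),
# barycentric points; weights sum to 1 (reference volume handled via det/6)
tet_quadrature <- function() {
  a <- (5 + 3 * sqrt(5)) / 20
  b <- (5 - sqrt(5)) / 20
  list(points = rbind(c(a, b, b, b), c(b, a, b, b),
                      c(b, b, a, b), c(b, b, b, a)),
       weights = rep(0.25, 4L))
}

# C3D10 shape-function gradients wrt reference coords (xi, eta, zeta) =
# (L2, L3, L4) at barycentric point L; 10 x 3
shape_grad_ref <- function(L) {
  dNdL <- matrix(0, 10L, 4L)
  for (c_ in 1:4) dNdL[c_, c_] <- 4 * L[c_] - 1
  ed <- c3d10_edges()
  for (e in 1:6) {
    a <- ed[e, 1]; b <- ed[e, 2]
    dNdL[4L + e, a] <- 4 * L[b]
    dNdL[4L + e, b] <- 4 * L[a]
  }
  cbind(dNdL[, 2] - dNdL[, 1], dNdL[, 3] - dNdL[, 1], dNdL[, 4] - dNdL[, 1])
}

# isotropic elasticity matrix, engineering shear, order xx yy zz xy yz zx
elasticity_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6L, 6L)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

#' Stiffness matrix of one C3D10 element
#'
#' Standard isoparametric formulation with the 4-point Gauss rule. The
#' result is symmetric positive-semidefinite with exactly six zero-energy
#' (rigid-body) modes.
#'
#' @param nodes10 10 x 3 node coordinates in C3D10 order (4 corners, then
#'   mid-edge nodes 1-2, 2-3, 3-1, 1-4, 2-4, 3-4).
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @return 30 x 30 stiffness matrix (N/mm); dof order (x1, y1, z1, x2, ...).
#' @export
element_stiffness <- function(nodes10, E, nu) {
  X <- matrix(as.numeric(nodes10), 10L, 3L)
  q <- tet_quadrature()
  D <- elasticity_matrix(E, nu)
  K <- matrix(0, 30L, 30L)
  for (g in 1:4) {
    Dref <- shape_grad_ref(q$points[g, ])
    J <- t(X) %*% Dref
    dJ <- det(J)
    if (dJ <= 0) stop("inverted element (non-positive Jacobian)")
    G <- Dref %*% solve(J)
    B <- matrix(0, 6L, 30L)
    ix <- 3 * (1:10) - 2
    B[1, ix] <- G[, 1]; B[2, ix + 1] <- G[, 2]; B[3, ix + 2] <- G[, 3]
    B[4, ix] <- G[, 2]; B[4, ix + 1] <- G[, 1]
    B[5, ix + 1] <- G[, 3]; B[5, ix + 2] <- G[, 2]
    B[6, ix] <- G[, 3]; B[6, ix + 2] <- G[, 1]
    K <- K + (q$weights[g] * dJ / 6) * (t(B) %*% D %*% B)
  }
  K
}

# constant corner Jacobian inverse and determinant for all elements;
# returns list(detJ = m-vector, inv = list of 3x3 of m-vectors inv[[k]][[i]])
corner_jacobians <- function(mesh) {
  X <- mesh$nodes; el <- mesh$elements
  x1 <- X[el[, 1], , drop = FALSE]
  a <- X[el[, 2], , drop = FALSE] - x1
  b <- X[el[, 3], , drop = FALSE] - x1
  c_ <- X[el[, 4], , drop = FALSE] - x1
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bc <- cr(b, c_); ca <- cr(c_, a); ab <- cr(a, b)
  detJ <- rowSums(a * bc)
  if (any(detJ <= 0))
    stop("inverted element(s): ", paste(utils::head(which(detJ <= 0)),
                                        collapse = ", "))
  inv <- list(bc / detJ, ca / detJ, ab / detJ)  # rows k of J^{-1}
  list(detJ = detJ, inv = inv)
}

# per-gauss shape gradients in world coords for all elements:
# list over gauss of list over node a of (m x 3) matrices
world_gradients <- function(mesh) {
  jac <- corner_jacobians(mesh)
  q <- tet_quadrature()
  out <- vector("list", 4L)
  for (g in 1:4) {
    Dref <- shape_grad_ref(q$points[g, ])
    Gg <- vector("list", 10L)
    for (a_ in 1:10) {
      Gg[[a_]] <- Dref[a_, 1] * jac$inv[[1]] + Dref[a_, 2] * jac$inv[[2]] +
        Dref[a_, 3] * jac$inv[[3]]
    }
    out[[g]] <- Gg
  }
  list(G = out, detJ = jac$detJ, weights = q$weights)
}

#' Assemble the global stiffness matrix
#'
#' Vectorized over elements, exploiting the constant (affine) Jacobian of
#' straight-edged quadratic tetrahedra.
#'
#' @param mesh a [tet_mesh()].
#' @param materials an `element_material_field` (per-element E, nu).
#' @return Sparse symmetric stiffness matrix (3n x 3n, N/mm).
#' @export
assemble_stiffness <- function(mesh, materials) {
  el <- mesh$elements
  m <- nrow(el)
  stopifnot(nrow(materials) == m)
  wg <- world_gradients(mesh)
  E <- materials$E; nu <- materials$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  cg <- wg$detJ / 24                 # weight * detJ/6 per gauss point
  # P_ab[i,j] = sum_g cg * G_g[a][,i] * G_g[b][,j]
  nblocks <- 55L                     # a <= b
  est <- m * (55L * 9L * 2L - 10L * 9L)  # upper+mirror minus double diag
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  ti_list <- vector("list", 110L); tj_list <- vector("list", 110L)
  tx_list <- vector("list", 110L)
  slot <- 0L
  dof <- function(a_, i) 3L * (el[, a_] - 1L) + i
  for (a_ in 1:10) for (b_ in a_:10) {
    P <- vector("list", 9L)            # [ (i-1)*3 + j ]
    for (i in 1:3) for (j in 1:3) {
      acc <- 0
      for (g in 1:4)
        acc <- acc + cg * wg$G[[g]][[a_]][, i] * wg$G[[g]][[b_]][, j]
      P[[(i - 1L) * 3L + j]] <- acc
    }
    trP <- P[[1]] + P[[5]] + P[[9]]
    # 3x3 block values
    vals <- matrix(0, m, 9L)
    for (i in 1:3) for (j in 1:3) {
      v <- lam * P[[(i - 1L) * 3L + j]] + mu * P[[(j - 1L) * 3L + i]]
      if (i == j) v <- v + mu * trP
      vals[, (i - 1L) * 3L + j] <- v
    }
    ii <- cbind(dof(a_, 1L), dof(a_, 2L), dof(a_, 3L))
    jj <- cbind(dof(b_, 1L), dof(b_, 2L), dof(b_, 3L))
    idx <- rep(1:3, each = 3L); jdx <- rep(1:3, times = 3L)
    slot <- slot + 1L
    ti_list[[slot]] <- as.vector(ii[, idx])
    tj_list[[slot]] <- as.vector(jj[, jdx])
    tx_list[[slot]] <- as.vector(vals)
    if (b_ > a_) {                    # mirror block
      slot <- slot + 1L
      ti_list[[slot]] <- as.vector(jj[, jdx])
      tj_list[[slot]] <- as.vector(ii[, idx])
      tx_list[[slot]] <- as.vector(vals)
    }
  }
  n3 <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(
    i = unlist(ti_list[seq_len(slot)]),
    j = unlist(tj_list[seq_len(slot)]),
    x = unlist(tx_list[seq_len(slot)]),
    dims = c(n3, n3))
  Matrix::forceSymmetric(K, uplo = "U")
}

#' Distribute a total force over a node or surface set
#'
#' Node sets split the total equally over the member nodes. Surface sets
#' lump per facet proportionally to facet area; within a facet the
#' `"equal"` scheme spreads the facet share equally over its three corner
#' nodes, while the `"consistent"` scheme uses the consistent nodal loads
#' of a uniform traction on a straight-edge quadratic facet (zero at
#' corners, one third per mid-edge node) — exact for uniform-stress
#' states. The emitted nodal loads sum to the total exactly.
#'
#' @param mesh a [tet_mesh()].
#' @param set a node-set name (or integer node ids); for surfaces a
#'   surface-set name, a k x 3 corner facet matrix, or a facet list from
#'   [free_boundary_facets()] (required for `"consistent"`).
#' @param total length-3 total force vector (N).
#' @param type `"node"` or `"surface"`.
#' @param scheme per-facet lumping, `"equal"` or `"consistent"`.
#' @return Dense numeric load vector of length `3 * n_nodes`.
#' @export
distribute_load <- function(mesh, set, total, type = c("node", "surface"),
                            scheme = c("equal", "consistent")) {
  type <- match.arg(type)
  scheme <- match.arg(scheme)
  total <- as.numeric(total)
  f <- numeric(3L * nrow(mesh$nodes))
  if (type == "node") {
    ids <- if (is.character(set)) mesh$node_sets[[set]] else as.integer(set)
    if (is.null(ids) || !length(ids))
      stop("empty or missing node set for load application")
    share <- rep(1 / length(ids), length(ids))
    for (i in 1:3)
      f[3L * (ids - 1L) + i] <- f[3L * (ids - 1L) + i] + total[i] * share
    return(f)
  }
  mids <- NULL
  if (is.list(set) && !is.null(set$corners)) {
    tri <- set$corners
    mids <- set$mids
  } else {
    tri <- if (is.character(set)) mesh$surface_sets[[set]] else set
  }
  if (is.null(tri) || !nrow(tri))
    stop("empty or missing surface set for load application")
  if (scheme == "consistent" && is.null(mids))
    stop("consistent lumping needs facets with mid nodes ",
         "(use free_boundary_facets())")
  ar <- triangle_areas(mesh$nodes, tri)
  w <- ar / sum(ar)
  recv <- if (scheme == "equal") tri else mids
  for (k in seq_len(nrow(recv))) {
    for (i in 1:3) {
      d <- 3L * (recv[k, ] - 1L) + i
      f[d] <- f[d] + total[i] * w[k] / 3
    }
  }
  f
}

#' Bonded multi-point constraints between two parts
#'
#' For conforming interfaces (shared nodes) no constraint equations are
#' needed and an empty set is returned. Otherwise every slave-part boundary
#' node within the capture distance of a master facet is tied to its
#' closest point on that facet, interpolated with the quadratic 6-node
#' triangle shape functions — the tied pair then moves as one body under
#' rigid motion.
#'
#' @param mesh a [tet_mesh()].
#' @param slave,master part names.
#' @param capture capture distance (mm); slave boundary nodes further from
#'   the master surface than this are not tied.
#' @param all_within_capture error if a slave interface candidate lies
#'   beyond capture (default: such nodes are simply not tied).
#' @return A list of constraints `list(slave = node, masters = ids,
#'   weights = w)`, possibly empty; class `mpc_set`.
#' @export
apply_bonded_mpc <- function(mesh, slave, master, capture = NULL,
                             all_within_capture = FALSE) {
  stopifnot(inherits(mesh, "tet_mesh"))
  sid <- mesh$part_names[[slave]]; mid <- mesh$part_names[[master]]
  if (is.null(sid) || is.null(mid)) stop("unknown part name")
  el <- mesh$elements
  snodes <- unique(as.vector(el[mesh$part_id == sid, , drop = FALSE]))
  mnodes <- unique(as.vector(el[mesh$part_id == mid, , drop = FALSE]))
  shared <- intersect(snodes, mnodes)
  if (length(shared))
    return(structure(list(), class = "mpc_set"))  # conforming: merged
  if (is.null(capture))
    capture <- 0.51 * max(mesh$spacing %||% 1)
  # master free-boundary facets and their owning elements (for mid nodes)
  ef <- element_faces(mesh)
  uk <- unique(ef$key); gid <- match(ef$key, uk)
  cnt <- tabulate(gid, length(uk))
  sel <- cnt[gid] == 1L & mesh$part_id[ef$elem] == mid
  tri <- ef$faces[sel, , drop = FALSE]
  own <- ef$elem[sel]
  if (!nrow(tri)) stop("master part has no free boundary facets")
  surf <- tri_surface(mesh$nodes, tri)
  # candidate slaves: boundary nodes of the slave part, including the
  # facet mid-edge nodes
  sfb <- free_boundary_facets(mesh, part = slave)
  cand <- sort(unique(as.vector(sfb$nodes6)))
  cl <- closest_points_on_surface(mesh$nodes[cand, , drop = FALSE], surf)
  near <- cl$distance <= capture
  if (all_within_capture && !all(near)) {
    far <- cand[!near][1]
    stop("slave node beyond capture distance at (",
         paste(signif(mesh$nodes[far, ], 5), collapse = ", "), ")")
  }
  cons <- list()
  # map: find facet + barycentric coords for each tied node
  X <- mesh$nodes
  for (q_ in which(near)) {
    p <- cl$point[q_, ]
    # locate the facet containing p (smallest point-triangle distance)
    # reuse: recompute against each facet is costly; find facet by
    # barycentric solve on the nearest facets only
    dmin <- Inf; best <- NULL
    for (kf in seq_len(nrow(tri))) {
      A <- X[tri[kf, 1], ]; B <- X[tri[kf, 2], ]; C <- X[tri[kf, 3], ]
      M <- cbind(B - A, C - A)
      ab <- tryCatch(qr.solve(M, p - A), error = function(e) NULL)
      if (is.null(ab)) next
      res <- sqrt(sum((A + M %*% ab - p)^2))
      if (ab[1] >= -1e-9 && ab[2] >= -1e-9 && sum(ab) <= 1 + 1e-9 &&
          res < dmin) {
        dmin <- res; best <- list(k = kf, b = c(1 - sum(ab), ab))
      }
    }
    if (is.null(best)) next
    kf <- best$k; L <- best$b          # barycentric L1, L2, L3
    e10 <- el[own[kf], ]
    corners <- tri[kf, ]
    # local corner indices within the owning element
    loc <- match(corners, e10[1:4])
    ed <- c3d10_edges()
    midnode <- function(a_, b_) {
      hit <- which((ed[, 1] == a_ & ed[, 2] == b_) |
                     (ed[, 1] == b_ & ed[, 2] == a_))
      e10[4L + hit]
    }
    ids <- c(corners,
             midnode(loc[1], loc[2]), midnode(loc[2], loc[3]),
             midnode(loc[3], loc[1]))
    wts <- c(L[1] * (2 * L[1] - 1), L[2] * (2 * L[2] - 1),
             L[3] * (2 * L[3] - 1),
             4 * L[1] * L[2], 4 * L[2] * L[3], 4 * L[3] * L[1])
    cons[[length(cons) + 1L]] <- list(slave = cand[q_], masters = ids,
                                      weights = wts)
  }
  structure(cons, class = "mpc_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build the elimination transform T (3n x 3n) for an mpc_set: slave dofs
# are expressed as weighted master dofs; returns list(T, keep_dofs)
mpc_transform <- function(n_nodes, ties) {
  n3 <- 3L * n_nodes
  if (!length(ties)) {
    return(list(TT = Matrix::Diagonal(n3), keep = seq_len(n3),
                slaves = integer(0)))
  }
  slave_nodes <- vapply(ties, function(t_) t_$slave, integer(1))
  ti <- list(); tj <- list(); tx <- list()
  for (t_ in ties) {
    for (i in 1:3) {
      ti[[length(ti) + 1L]] <- rep(3L * (t_$slave - 1L) + i,
                                   length(t_$masters))
      tj[[length(tj) + 1L]] <- 3L * (t_$masters - 1L) + i
      tx[[length(tx) + 1L]] <- t_$weights
    }
  }
  slave_dofs <- as.vector(outer(1:3, 3L * (slave_nodes - 1L), "+"))
  keep <- setdiff(seq_len(n3), slave_dofs)
  ident <- Matrix::sparseMatrix(i = keep, j = keep, x = 1,
                                dims = c(n3, n3))
  Tfull <- ident + Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                                        x = unlist(tx), dims = c(n3, n3))
  list(TT = Tfull[, keep, drop = FALSE], keep = keep, slaves = slave_dofs)
}

#' Load case for a solve
#'
#' @param dirichlet list of specs `list(set =, components =, value =)`;
#'   `value` is a scalar, length-3 vector, or `function(coords)` returning
#'   an n x 3 matrix of prescribed displacements (mm).
#' @param loads list of `list(set =, force =)` concentrated loads over node
#'   sets (equal split, N).
#' @param surface_loads list of `list(set =, force =)` area-lumped loads
#'   over surface sets.
#' @param contact `NULL`, or `list(mode = "ignored"|"bonded"|"frictional",
#'   mu =, penalty_scale =)` referring to the mesh's split contact pairs.
#' @param ties an `mpc_set` from [apply_bonded_mpc()].
#' @param split optional load split bookkeeping
#'   `c(ipsilateral =, contralateral =)`, fractions summing to 1.
#' @return A `load_case` object.
#' @export
load_case <- function(dirichlet = list(), loads = list(),
                      surface_loads = list(), contact = NULL,
                      ties = structure(list(), class = "mpc_set"),
                      split = NULL) {
  if (!is.null(split)) {
    if (abs(sum(split) - 1) > 1e-12)
      stop("load split fractions must sum to 1")
  }
  if (!is.null(contact)) {
    if (!is.null(contact$mu) && contact$mu < 0)
      stop("friction coefficient must be >= 0")
  }
  structure(list(dirichlet = dirichlet, loads = loads,
                 surface_loads = surface_loads, contact = contact,
                 ties = ties, split = split),
            class = "load_case")
}

# resolve dirichlet specs to dof indices + values
dirichlet_dofs <- function(mesh, specs) {
  idx <- integer(0); val <- numeric(0)
  for (s in specs) {
    ids <- if (is.character(s$set)) mesh$node_sets[[s$set]] else
      as.integer(s$set)
    if (is.null(ids) || !length(ids))
      stop("empty required Dirichlet node set: ",
           if (is.character(s$set)) s$set else "<ids>")
    comps <- s$components %||% 1:3
    v <- s$value %||% 0
    if (is.function(v)) {
      vm <- v(mesh$nodes[ids, , drop = FALSE])
      for (ci in seq_along(comps)) {
        idx <- c(idx, 3L * (ids - 1L) + comps[ci])
        val <- c(val, vm[, comps[ci]])
      }
    } else {
      v <- rep(as.numeric(v), length.out = 3L)
      for (ci in seq_along(comps)) {
        idx <- c(idx, 3L * (ids - 1L) + comps[ci])
        val <- c(val, rep(v[comps[ci]], length(ids)))
      }
    }
  }
  o <- !duplicated(idx)
  list(idx = idx[o], val = val[o])
}

# assemble the applied load vector of a load case; surface loads default
# to consistent lumping whenever the facet mid nodes are known
applied_loads <- function(mesh, lc) {
  f <- numeric(3L * nrow(mesh$nodes))
  for (s in lc$loads) f <- f + distribute_load(mesh, s$set, s$force, "node")
  for (s in lc$surface_loads) {
    has_mids <- is.list(s$set) && !is.null(s$set$mids)
    scheme <- s$scheme %||% (if (has_mids) "consistent" else "equal")
    f <- f + distribute_load(mesh, s$set, s$force, "surface",
                             scheme = scheme)
  }
  f
}

# core reduced solve: K (full dofs), f (full dofs), ties, dirichlet
# returns u (full), reactions (at dirichlet dofs, reduced-space residual),
# residual norm
solve_system <- function(mesh, K, f, lc, symmetric = TRUE) {
  n3 <- 3L * nrow(mesh$nodes)
  tr <- mpc_transform(nrow(mesh$nodes), lc$ties)
  Kr <- Matrix::t(tr$TT) %*% K %*% tr$TT
  if (symmetric) Kr <- Matrix::forceSymmetric(Kr)
  fr <- as.numeric(Matrix::t(tr$TT) %*% f)
  dd <- dirichlet_dofs(mesh, lc$dirichlet)
  if (length(dd$idx) < 6L)
    stop("insufficient constraints: at least 6 dof must be fixed")
  if (any(dd$idx %in% tr$slaves))
    stop("Dirichlet constraint on an MPC slave dof; fix the master instead")
  fixed_red <- match(dd$idx, tr$keep)
  nred <- length(tr$keep)
  free <- setdiff(seq_len(nred), fixed_red)
  uc <- dd$val
  Kff <- Kr[free, free, drop = FALSE]
  rhs <- fr[free] - as.numeric(Kr[free, fixed_red, drop = FALSE] %*% uc)
  uf <- tryCatch(
    as.numeric(Matrix::solve(Kff, rhs)),
    error = function(e) stop("singular system (insufficient constraints?): ",
                             conditionMessage(e)))
  ur <- numeric(nred)
  ur[free] <- uf
  ur[fixed_red] <- uc
  res_free <- as.numeric(Kr[free, , drop = FALSE] %*% ur) - fr[free]
  fn <- sqrt(sum(fr^2))
  resid <- if (fn > 0) sqrt(sum(res_free^2)) / fn else sqrt(sum(res_free^2))
  reactions <- as.numeric(Kr[fixed_red, , drop = FALSE] %*% ur) -
    fr[fixed_red]
  u <- as.numeric(tr$TT %*% ur)
  list(u = matrix(u, ncol = 3L, byrow = TRUE),
       reactions = data.frame(dof = dd$idx, value = reactions),
       residual = resid)
}

#' Recover stresses at element quadrature points
#'
#' @param mesh a [tet_mesh()].
#' @param materials per-element material field.
#' @param u n x 3 nodal displacement matrix (mm).
#' @return m x 4 x 6 array of stress-tensor components
#'   (xx, yy, zz, xy, yz, zx) in MPa at the 4 Gauss points.
#' @export
compute_stresses <- function(mesh, materials, u) {
  el <- mesh$elements
  m <- nrow(el)
  wg <- world_gradients(mesh)
  E <- materials$E; nu <- materials$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  out <- array(0, c(m, 4L, 6L))
  ux <- matrix(u[el, 1L], m, 10L)
  uy <- matrix(u[el, 2L], m, 10L)
  uz <- matrix(u[el, 3L], m, 10L)
  for (g in 1:4) {
    G <- wg$G[[g]]
    exx <- eyy <- ezz <- exy <- eyz <- ezx <- 0
    for (a_ in 1:10) {
      exx <- exx + G[[a_]][, 1] * ux[, a_]
      eyy <- eyy + G[[a_]][, 2] * uy[, a_]
      ezz <- ezz + G[[a_]][, 3] * uz[, a_]
      exy <- exy + 0.5 * (G[[a_]][, 2] * ux[, a_] + G[[a_]][, 1] * uy[, a_])
      eyz <- eyz + 0.5 * (G[[a_]][, 3] * uy[, a_] + G[[a_]][, 2] * uz[, a_])
      ezx <- ezx + 0.5 * (G[[a_]][, 1] * uz[, a_] + G[[a_]][, 3] * ux[, a_])
    }
    tr_ <- exx + eyy + ezz
    out[, g, 1] <- lam * tr_ + 2 * mu * exx
    out[, g, 2] <- lam * tr_ + 2 * mu * eyy
    out[, g, 3] <- lam * tr_ + 2 * mu * ezz
    out[, g, 4] <- 2 * mu * exy
    out[, g, 5] <- 2 * mu * eyz
    out[, g, 6] <- 2 * mu * ezx
  }
  out
}

#' Linear-elastic solve without contact
#'
#' Assembles the global stiffness, applies bonded MPCs and Dirichlet
#' conditions, solves the sparse system by direct factorization, verifies
#' the equilibrium residual and recovers quadrature-point stresses.
#'
#' @param mesh a [tet_mesh()].
#' @param materials per-element material field.
#' @param lc a [load_case()] (its `contact` entry, if any, is ignored
#'   here).
#' @param residual_tol acceptable relative equilibrium residual.
#' @return A `solution` list: `u` (n x 3 mm), `stress` (m x 4 x 6 MPa),
#'   `reactions` (N, at Dirichlet dofs), `applied` (total applied force),
#'   `residual`, `diagnostics`.
#' @export
solve_linear <- function(mesh, materials, lc, residual_tol = 1e-8) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(lc, "load_case"))
  K <- assemble_stiffness(mesh, materials)
  f <- applied_loads(mesh, lc)
  sol <- solve_system(mesh, K, f, lc)
  if (sol$residual > residual_tol)
    stop(sprintf("equilibrium residual %.3e exceeds tolerance %.1e",
                 sol$residual, residual_tol))
  stress <- compute_stresses(mesh, materials, sol$u)
  structure(list(u = sol$u, stress = stress, reactions = sol$reactions,
                 applied = colSums(matrix(f, ncol = 3L, byrow = TRUE)),
                 residual = sol$residual,
                 diagnostics = list(contact_iterations = 0L,
                                    converged = TRUE)),
            class = "solution")
}

#' @export
print.solution <- function(x, ...) {
  cat(sprintf(
    "<solution> %d nodes, max |u| %.4g mm, residual %.2e, %s\n",
    nrow(x$u), max(sqrt(rowSums(x$u^2))), x$residual,
    if (x$diagnostics$converged) "converged" else "NOT converged"))
  invisible(x)
}
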