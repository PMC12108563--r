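# closest point on each triangle (A,B,C rows) to a single point p,
# Ericson's region classification, vectorized over triangles
closest_point_on_triangles <- function(p, A, B, C) {
  m <- nrow(A)
  P <- matrix(p, m, 3L, byrow = TRUE)
  ab <- B - A; ac <- C - A
  ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  Q <- A + v * ab + w * ac                       # interior (default)
  sel <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge BC
  if (any(sel)) {
    t_ <- (d4[sel] - d3[sel]) / ((d4[sel] - d3[sel]) + (d5[sel] - d6[sel]))
    Q[sel, ] <- B[sel, , drop = FALSE] +
      t_ * (C[sel, , drop = FALSE] - B[sel, , drop = FALSE])
  }
  sel <- vb <= 0 & d2 >= 0 & d6 <= 0             # edge AC
  if (any(sel)) {
    t_ <- d2[sel] / (d2[sel] - d6[sel])
    Q[sel, ] <- A[sel, , drop = FALSE] + t_ * ac[sel, , drop = FALSE]
  }
  sel <- vc <= 0 & d1 >= 0 & d3 <= 0             # edge AB
  if (any(sel)) {
    t_ <- d1[sel] / (d1[sel] - d3[sel])
    Q[sel, ] <- A[sel, , drop = FALSE] + t_ * ab[sel, , drop = FALSE]
  }
  sel <- d1 <= 0 & d2 <= 0                       # vertex A
  if (any(sel)) Q[sel, ] <- A[sel, , drop = FALSE]
  sel <- d3 >= 0 & d4 <= d3                      # vertex B
  if (any(sel)) Q[sel, ] <- B[sel, , drop = FALSE]
  sel <- d6 >= 0 & d5 <= d6                      # vertex C
  if (any(sel)) Q[sel, ] <- C[sel, , drop = FALSE]
  Q
}

# for each query point, the closest point on any triangle of `s` and its
# distance; candidate triangles are prefiltered with a nearest-vertex bound
closest_points_on_surface <- function(pts, s) {
  stopifnot(inherits(s, "tri_surface"))
  if (!nrow(s$faces)) stop("target surface has no triangles")
  V <- s$vertices
  A <- V[s$faces[, 1], , drop = FALSE]
  B <- V[s$faces[, 2], , drop = FALSE]
  C <- V[s$faces[, 3], , drop = FALSE]
  cen <- (A + B + C) / 3
  # circumscribing bound: max distance centroid -> corner, per triangle
  rad <- sqrt(pmax(rowSums((A - cen)^2),
                   pmax(rowSums((B - cen)^2), rowSums((C - cen)^2))))
  n <- nrow(pts)
  out_d <- numeric(n)
  out_q <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    dc <- sqrt((cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2 +
                 (cen[, 3] - p[3])^2)
    best_upper <- min(dc + rad)
    cand <- which(dc - rad <= best_upper)
    Q <- closest_point_on_triangles(p, A[cand, , drop = FALSE],
                                    B[cand, , drop = FALSE],
                                    C[cand, , drop = FALSE])
    dq <- (Q[, 1] - p[1])^2 + (Q[, 2] - p[2])^2 + (Q[, 3] - p[3])^2
    k <- which.min(dq)
    out_d[i] <- sqrt(dq[k])
    out_q[i, ] <- Q[k, ]
  }
  list(distance = out_d, point = out_q)
}

# Kabsch rigid fit: transform mapping P onto Q in the least-squares sense
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2L, cp)) %*% sweep(Q, 2L, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cq - as.vector(R %*% cp))
}

#' Align a CAD surface onto a segmented target surface
#'
#' With `refine = "off"` the supplied initial transform is returned
#' verbatim — the reproducible stand-in for interactive manual alignment.
#' With `refine = "on"`, point-to-surface ICP is run from `init` (sampled
#' CAD vertices matched to their closest points on the target, rigid Kabsch
#' update per iteration); the returned transform never has a larger mean
#' closest-point distance than `init`.
#'
#' @param cad,target non-empty [tri_surface()] objects.
#' @param init initial [rigid_transform()] (validated orthonormal).
#' @param refine `"on"` or `"off"`.
#' @param max_iter,tol ICP iteration cap and mean-distance convergence
#'   tolerance (mm).
#' @param max_sample maximum number of CAD vertices used as ICP samples.
#' @return A [rigid_transform()] mapping `cad` into the target frame.
#' @export
align_surface <- function(cad, target, init = rigid_transform(),
                          refine = c("on", "off"), max_iter = 50L,
                          tol = 1e-10, max_sample = 500L) {
  stopifnot(inherits(cad, "tri_surface"), inherits(target, "tri_surface"))
  if (!nrow(cad$vertices) || !nrow(target$vertices))
    stop("both surfaces must be non-empty")
  if (!inherits(init, "rigid_transform"))
    init <- rigid_transform(init$R, init$t)    # re-validates orthonormality
  refine <- match.arg(refine)
  if (refine == "off") return(init)
  P0 <- cad$vertices
  if (nrow(P0) > max_sample)
    P0 <- P0[round(seq(1, nrow(P0), length.out = max_sample)), , drop = FALSE]
  cur <- init
  mean_d <- function(tr) {
    mean(closest_points_on_surface(apply_transform(tr, P0), target)$distance)
  }
  best <- cur
  best_d <- mean_d(cur)
  prev_d <- Inf
  for (it in seq_len(max_iter)) {
    moved <- apply_transform(cur, P0)
    cl <- closest_points_on_surface(moved, target)
    cur <- kabsch_fit(P0, cl$point)
    d <- mean(closest_points_on_surface(apply_transform(cur, P0),
                                        target)$distance)
    if (d < best_d) { best <- cur; best_d <- d }
    if (abs(prev_d - d) < tol) break
    prev_d <- d
  }
  best
}

#' Surface-deviation map (closest-point method)
#'
#' For every reference vertex (sampling point), the unsigned Euclidean
#' distance to the nearest point on any target triangle (point-to-triangle,
#' not point-to-vertex). Both surfaces must already share a frame.
#'
#' @param reference a [tri_surface()] whose vertices are the sampling
#'   points.
#' @param target non-empty [tri_surface()].
#' @return A `deviation_map`: `distance` per sample point, `points`
#'   (sampling coordinates), and `summary` with `max`, `mean` and
#'   `fraction_below_1mm`.
#' @export
surface_deviation <- function(reference, target) {
  stopifnot(inherits(reference, "tri_surface"))
  if (!inherits(target, "tri_surface") || !nrow(target$faces))
    stop("target surface is empty")
  cl <- closest_points_on_surface(reference$vertices, target)
  structure(list(
    distance = cl$distance,
    points = reference$vertices,
    summary = list(max = max(cl$distance), mean = mean(cl$distance),
                   fraction_below_1mm = mean(cl$distance < 1))),
    class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  cat(sprintf(
    "<deviation_map> %d samples: max %.4f mm, mean %.4f mm, %.1f%% < 1 mm\n",
    length(x$distance), x$summary$max, x$summary$mean,
    100 * x$summary$fraction_below_1mm))
  invisible(x)
}
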