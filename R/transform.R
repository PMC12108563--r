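#' Rigid transform (rotation + translation)
#'
#' @param R 3x3 rotation matrix, orthonormal with det +1 (checked to 1e-9).
#' @param t numeric length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3L, 3L)
  t <- as.numeric(t)
  if (length(t) != 3L) stop("translation must have length 3")
  if (max(abs(R %*% t(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("R must be orthonormal with det +1")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' Rotation about a coordinate axis
#'
#' @param axis 1, 2 or 3 (x, y, z).
#' @param angle rotation angle in radians.
#' @param t optional translation.
#' @return A [rigid_transform()].
#' @export
axis_rotation <- function(axis, angle, t = c(0, 0, 0)) {
  c_ <- cos(angle); s_ <- sin(angle)
  R <- diag(3)
  ax <- setdiff(1:3, axis)
  R[ax[1], ax[1]] <- c_; R[ax[2], ax[2]] <- c_
  R[ax[1], ax[2]] <- -s_; R[ax[2], ax[1]] <- s_
  rigid_transform(R, t)
}

#' Apply a rigid transform to points
#'
#' @param tr a [rigid_transform()].
#' @param pts n x 3 matrix of points.
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(tr, pts) {
  stopifnot(inherits(tr, "rigid_transform"))
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(pts %*% t(tr$R), 2L, tr$t, "+")
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$R), -as.vector(t(tr$R) %*% tr$t))
}

#' @rdname apply_transform
#' @param a,b transforms; the composite applies `b` first, then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

# is a transform numerically the identity
is_identity_transform <- function(tr, tol = 1e-12) {
  max(abs(tr$R - diag(3))) < tol && max(abs(tr$t)) < tol
}
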