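#' Von Mises stress of symmetric stress tensors
#'
#' `sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) +
#' 3 * (sxy^2 + syz^2 + szx^2))`.
#'
#' @param sigma either a symmetric 3 x 3 matrix (MPa) or an n x 6 matrix of
#'   components (xx, yy, zz, xy, yz, zx).
#' @return Scalar or length-n vector of von Mises stresses (MPa).
#' @export
von_mises <- function(sigma) {
  if (is.matrix(sigma) && nrow(sigma) == 3L && ncol(sigma) == 3L) {
    if (max(abs(sigma - t(sigma))) > 1e-9 * max(1, max(abs(sigma))))
      stop("stress tensor must be symmetric")
    sigma <- matrix(c(sigma[1, 1], sigma[2, 2], sigma[3, 3],
                      sigma[1, 2], sigma[2, 3], sigma[1, 3]), 1L, 6L)
  }
  sigma <- matrix(sigma, ncol = 6L)
  s <- sqrt(0.5 * ((sigma[, 1] - sigma[, 2])^2 +
                     (sigma[, 2] - sigma[, 3])^2 +
                     (sigma[, 3] - sigma[, 1])^2) +
              3 * (sigma[, 4]^2 + sigma[, 5]^2 + sigma[, 6]^2))
  if (length(s) == 1L) as.numeric(s) else s
}

#' Peak von Mises stress of a part, normalized by a reference
#'
#' The peak is taken over the part's quadrature-point values (no nodal
#' extrapolation, which inflates maxima mesh-dependently).
#'
#' @param sol a `solution` from [solve_linear()] / [solve_contact()].
#' @param mesh the solved [tet_mesh()].
#' @param part part name.
#' @param reference reference stress (MPa, > 0) for normalization.
#' @param variant label carried into reports.
#' @return A `stress_summary`: part, `peak` (MPa), `normalized`, peak
#'   location (element id, Gauss point, world coordinates), variant label
#'   and reference.
#' @export
peak_stress <- function(sol, mesh, part, reference, variant = "run") {
  stopifnot(inherits(sol, "solution"), inherits(mesh, "tet_mesh"))
  if (reference <= 0) stop("reference stress must be > 0")
  if (!part %in% names(mesh$part_names)) stop("unknown part: ", part)
  pid <- mesh$part_names[[part]]
  sel <- which(mesh$part_id == pid)
  if (!length(sel)) stop("part has no elements: ", part)
  vm <- matrix(0, length(sel), 4L)
  for (g in 1:4) vm[, g] <- von_mises(sol$stress[sel, g, ])
  k <- which(vm == max(vm), arr.ind = TRUE)[1, ]
  elem <- sel[k[1]]
  q <- tet_quadrature()$points[k[2], ]
  loc <- as.numeric(q %*% mesh$nodes[mesh$elements[elem, 1:4], ,
                                     drop = FALSE])
  structure(list(part = part, peak = max(vm), normalized = max(vm) / reference,
                 element = elem, gauss_point = unname(k[2]), location = loc,
                 reference = reference, variant = variant),
            class = "stress_summary")
}

#' @export
print.stress_summary <- function(x, ...) {
  cat(sprintf("<stress_summary> %s / %s: peak %.4g MPa (normalized %.4g)\n",
              x$variant, x$part, x$peak, x$normalized))
  invisible(x)
}

#' Compare normalized peak stresses across model variants
#'
#' @param runs list of `stress_summary` objects sharing one reference.
#' @param location_radius two peaks within this distance (mm) are flagged
#'   as coinciding.
#' @return A `variant_report`: `table` (variant, part, peak, normalized),
#'   `pairwise` (percentage differences `(a - b) / b` of normalized peaks),
#'   `locations_agree` flags.
#' @export
compare_variants <- function(runs, location_radius = 2) {
  if (length(runs) < 2L) stop("need at least 2 runs to compare")
  refs <- vapply(runs, function(r) r$reference, numeric(1))
  if (max(abs(refs - refs[1])) > 1e-9 * refs[1])
    stop("runs use different normalization references")
  tab <- data.frame(
    variant = vapply(runs, function(r) r$variant, character(1)),
    part = vapply(runs, function(r) r$part, character(1)),
    peak = vapply(runs, function(r) r$peak, numeric(1)),
    normalized = vapply(runs, function(r) r$normalized, numeric(1)))
  n <- length(runs)
  pw <- expand.grid(a = seq_len(n), b = seq_len(n))
  pw <- pw[pw$a != pw$b, ]
  pw$variant_a <- tab$variant[pw$a]
  pw$variant_b <- tab$variant[pw$b]
  pw$pct_diff <- 100 * (tab$normalized[pw$a] - tab$normalized[pw$b]) /
    tab$normalized[pw$b]
  loc <- t(vapply(runs, function(r) r$location, numeric(3)))
  pw$locations_agree <- sqrt(rowSums((loc[pw$a, , drop = FALSE] -
                                        loc[pw$b, , drop = FALSE])^2)) <=
    location_radius
  structure(list(table = tab,
                 pairwise = pw[, c("variant_a", "variant_b", "pct_diff",
                                   "locations_agree")]),
            class = "variant_report")
}

#' @export
print.variant_report <- function(x, ...) {
  cat("<variant_report>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a solution as a legacy VTK unstructured grid
#'
#' Quadratic tetrahedra (VTK cell type 24) with nodal displacements and
#' cell fields for part id, Young's modulus and mean von Mises stress.
#'
#' @param mesh a [tet_mesh()].
#' @param path output file.
#' @param sol optional `solution`.
#' @param materials optional material field.
#' @return `path`, invisibly.
#' @export
write_solution_vtk <- function(mesh, path, sol = NULL, materials = NULL) {
  nv <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tmjfem solution", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", ne, 11L * ne), con)
  # VTK quadratic tet mid-node order matches C3D10 edge order 1-2, 2-3,
  # 3-1, 1-4, 2-4, 3-4
  e0 <- mesh$elements - 1L
  writeLines(apply(e0, 1L, function(r) paste(c(10L, r), collapse = " ")),
             con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("24", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS part_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$part_id), con)
  if (!is.null(materials)) {
    writeLines(c("SCALARS youngs_modulus double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", materials$E), con)
  }
  if (!is.null(sol)) {
    vm <- rowMeans(vapply(1:4, function(g) von_mises(sol$stress[, g, ]),
                          numeric(ne)))
    writeLines(c("SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", vm), con)
    writeLines(sprintf("POINT_DATA %d", nv), con)
    writeLines("VECTORS displacement double", con)
    writeLines(sprintf("%.9g %.9g %.9g", sol$u[, 1], sol$u[, 2],
                       sol$u[, 3]), con)
  }
  invisible(path)
}
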