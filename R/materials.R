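#' Material mapping table
#'
#' Loads the versioned JSON asset describing the CT-value to density to
#' Young's-modulus mapping: two bone regimes (trabecular and cortical) with
#' linear HU-to-density intervals and power laws `E = c * rho^p` (E in MPa,
#' rho in kg/m^3), plus constants for dentin, enamel, Ti-6Al-4V and the
#' uniform 10 GPa bone used by the simplified models. The printed E ranges
#' of the source table are carried as metadata only; the power laws are
#' authoritative.
#'
#' @param path JSON file; defaults to the table shipped with the package.
#' @return A `material_table` list.
#' @export
material_table <- function(path = system.file("extdata",
                                              "material_table.json",
                                              package = "tmjfem")) {
  tb <- jsonlite::read_json(path, simplifyVector = TRUE)
  # list columns -> 2-column matrices (rows = regimes)
  for (cl in c("ct_interval", "density_interval", "printed_E_range"))
    tb$bone_regimes[[cl]] <- do.call(rbind, tb$bone_regimes[[cl]])
  for (r in seq_len(nrow(tb$bone_regimes))) {
    law <- tb$bone_regimes$law[r, ]
    if (law$coefficient <= 0) stop("law coefficients must be > 0")
    nu <- tb$bone_regimes$poisson[r]
    if (nu <= 0 || nu >= 0.5) stop("Poisson ratio must be in (0, 0.5)")
  }
  structure(tb, class = "material_table")
}

#' Map calibrated CT values to CT density
#'
#' Piecewise-linear map sending each bone regime's CT interval endpoints to
#' its density interval endpoints: `[-1000, 500] -> [0, 1000]` and
#' `[501, 1500] -> [1001, 2000]` with the defaults. Values between the two
#' regimes (HU in (500, 501)) are interpolated across the density gap;
#' values below / above the outermost endpoints are clamped to the density
#' floor / ceiling, since the table defines no behaviour outside its
#' intervals.
#'
#' @param hu numeric vector of calibrated CT values (HU).
#' @param table a [material_table()].
#' @return Densities in kg/m^3, monotone nondecreasing in `hu`.
#' @export
hu_to_density <- function(hu, table = material_table()) {
  br <- table$bone_regimes
  # knots across both regimes (plus the bridging segment)
  ct <- c(br$ct_interval[1, 1], br$ct_interval[1, 2],
          br$ct_interval[2, 1], br$ct_interval[2, 2])
  rho <- c(br$density_interval[1, 1], br$density_interval[1, 2],
           br$density_interval[2, 1], br$density_interval[2, 2])
  stats::approx(ct, rho, xout = pmin(pmax(hu, ct[1]), ct[4]),
                method = "linear", ties = "ordered")$y
}

#' Evaluate the bone modulus power law
#'
#' Regime selection by density: `rho < 1000` uses the trabecular law,
#' `rho >= 1000` the cortical law (the density gap `[1000, 1001)` of the
#' printed intervals is assigned to the cortical law; the resulting jump
#' between the two laws is a property of the printed table and is not
#' smoothed). A configurable floor keeps E positive at `rho = 0`.
#'
#' @param rho densities in kg/m^3 (>= 0).
#' @param table a [material_table()].
#' @return Young's moduli in MPa.
#' @export
density_to_E <- function(rho, table = material_table()) {
  if (any(rho < 0)) stop("density must be >= 0")
  br <- table$bone_regimes
  trab <- br$law[1, ]; cort <- br$law[2, ]
  E <- ifelse(rho < br$density_interval[2, 1] - 1,   # < 1000
              trab$coefficient * rho^trab$exponent,
              cort$coefficient * rho^cort$exponent)
  pmax(E, table$E_floor)
}

#' Classify a tooth voxel as dentin or enamel
#'
#' HU at or below the split (2000 HU, inclusive) is dentin, above it
#' enamel; both at Poisson ratio 0.3.
#'
#' @param hu numeric vector of calibrated CT values.
#' @param table a [material_table()].
#' @return A data frame with columns `tissue`, `E` (MPa), `nu`.
#' @export
classify_tooth_tissue <- function(hu, table = material_table()) {
  dent <- hu <= table$tooth_hu_split
  data.frame(
    tissue = ifelse(dent, "dentin", "enamel"),
    E = ifelse(dent, table$constants$dentin$E, table$constants$enamel$E),
    nu = ifelse(dent, table$constants$dentin$poisson,
                table$constants$enamel$poisson))
}

#' Assign per-element material properties
#'
#' For parts in `"mapped"` mode, each element's HU is the mean of trilinear
#' samples of the calibrated volume at the element's four quadrature points
#' (where the stiffness is integrated; `"centroid"` aggregation samples the
#' element centroid instead), mapped through [hu_to_density()] and
#' [density_to_E()]. `"tooth"` mode classifies each element as dentin or
#' enamel from the same HU aggregate. `"titanium"` and `"bone_uniform"`
#' assign the homogeneous table constants.
#'
#' @param mesh a [tet_mesh()].
#' @param vol calibrated [image_volume()] in HU (needed for mapped/tooth
#'   parts; may be `NULL` if all parts are homogeneous).
#' @param table a [material_table()].
#' @param modes named character vector: part name -> one of `"mapped"`,
#'   `"tooth"`, `"titanium"`, `"bone_uniform"`.
#' @param aggregation `"quadrature"` (default) or `"centroid"`.
#' @return An `element_material_field` data frame with per-element `E`
#'   (MPa), `nu` and `provenance` (`"mapped"` or `"homogeneous"`).
#' @export
assign_element_materials <- function(mesh, vol = NULL,
                                     table = material_table(), modes,
                                     aggregation = c("quadrature",
                                                     "centroid")) {
  stopifnot(inherits(mesh, "tet_mesh"))
  aggregation <- match.arg(aggregation)
  m <- nrow(mesh$elements)
  part_of <- names(mesh$part_names)[match(mesh$part_id, mesh$part_names)]
  miss <- setdiff(unique(part_of), names(modes))
  if (length(miss))
    stop("no material mode given for part(s): ", paste(miss, collapse = ", "))
  E <- numeric(m); nu <- numeric(m); prov <- character(m)

  need_hu <- any(modes[unique(part_of)] %in% c("mapped", "tooth"))
  hu_elem <- NULL
  if (need_hu) {
    if (is.null(vol)) stop("mapped/tooth parts require a calibrated volume")
    X <- mesh$nodes
    # world bounding check
    box_hi <- vol$origin + dim(vol$data) * vol$spacing
    corners <- mesh$elements[, 1:4, drop = FALSE]
    cx <- X[as.vector(corners), , drop = FALSE]
    if (any(cx < rep(vol$origin, each = nrow(cx)) - 1e-9) ||
        any(cx > rep(box_hi, each = nrow(cx)) + 1e-9)) {
      bad <- which(apply(matrix(
        cx < rep(vol$origin, each = nrow(cx)) |
          cx > rep(box_hi, each = nrow(cx)), nrow(cx)), 1L, any))[1]
      stop("element node outside the volume's world box (element ",
           ceiling(bad / 4), ")")
    }
    if (aggregation == "quadrature") {
      qp <- tet_quadrature()$points    # 4 x 4 barycentric
      hu_elem <- 0
      for (g in 1:4) {
        pts <- qp[g, 1] * X[corners[, 1], , drop = FALSE] +
          qp[g, 2] * X[corners[, 2], , drop = FALSE] +
          qp[g, 3] * X[corners[, 3], , drop = FALSE] +
          qp[g, 4] * X[corners[, 4], , drop = FALSE]
        hu_elem <- hu_elem + sample_trilinear(vol, pts) / 4
      }
    } else {
      pts <- (X[corners[, 1], , drop = FALSE] + X[corners[, 2], , drop = FALSE] +
                X[corners[, 3], , drop = FALSE] +
                X[corners[, 4], , drop = FALSE]) / 4
      hu_elem <- sample_trilinear(vol, pts)
    }
  }

  for (p in unique(part_of)) {
    sel <- part_of == p
    mode <- modes[[p]]
    if (mode == "mapped") {
      E[sel] <- density_to_E(hu_to_density(hu_elem[sel], table), table)
      nu[sel] <- table$bone_regimes$poisson[1]
      prov[sel] <- "mapped"
    } else if (mode == "tooth") {
      cl <- classify_tooth_tissue(hu_elem[sel], table)
      E[sel] <- cl$E; nu[sel] <- cl$nu
      prov[sel] <- "mapped"
    } else if (mode == "titanium") {
      E[sel] <- table$constants$titanium$E
      nu[sel] <- table$constants$titanium$poisson
      prov[sel] <- "homogeneous"
    } else if (mode == "bone_uniform") {
      E[sel] <- table$constants$bone_uniform$E
      nu[sel] <- table$constants$bone_uniform$poisson
      prov[sel] <- "homogeneous"
    } else stop("unknown material mode '", mode, "' for part ", p)
  }
  if (any(E <= 0)) stop("internal error: non-positive element modulus")
  structure(data.frame(E = E, nu = nu, provenance = prov),
            class = c("element_material_field", "data.frame"))
}

#' Constant material field for every element
#'
#' @param mesh a [tet_mesh()].
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @return An `element_material_field`.
#' @export
uniform_material <- function(mesh, E, nu) {
  m <- nrow(mesh$elements)
  structure(data.frame(E = rep(E, m), nu = rep(nu, m),
                       provenance = rep("homogeneous", m)),
            class = c("element_material_field", "data.frame"))
}
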