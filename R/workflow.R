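#' Model-variant specification
#'
#' The four model variants of the comparison ladder from a purely
#' segmented model to the industrial-style simplified model:
#' \itemize{
#'   \item Model 1: segmented prosthesis, no dummy screws, HU-mapped bone,
#'     individual teeth, no contact.
#'   \item Model 2: CAD prosthesis, otherwise as Model 1.
#'   \item Model 3: Model 2 plus the two planned "dummy" screws.
#'   \item Model 4: CAD prosthesis + dummy screws, uniform 10 GPa bone with
#'     teeth merged in, coarse mesh, configurable prosthesis-mandible
#'     contact (`"ignored"`, `"bonded"` or `"frictional"`).
#' }
#'
#' @param model integer 1-4, or `"industrial"` for the industrial-style
#'   run (uniform bone, merged teeth, fine mesh, contact not considered).
#' @param contact contact mode, only configurable for model 4 /
#'   industrial.
#' @param coarseness mesh downsample factor override.
#' @param label variant label carried into reports.
#' @return A `variant_spec`.
#' @export
variant_spec <- function(model, contact = NULL, coarseness = NULL,
                         label = NULL) {
  base <- list(
    `1` = list(source = "segmented", dummy = FALSE, bone = "mapped",
               teeth = "individual", contact = "none", coarseness = 3L),
    `2` = list(source = "cad", dummy = FALSE, bone = "mapped",
               teeth = "individual", contact = "none", coarseness = 3L),
    `3` = list(source = "cad", dummy = TRUE, bone = "mapped",
               teeth = "individual", contact = "none", coarseness = 3L),
    `4` = list(source = "cad", dummy = TRUE, bone = "uniform",
               teeth = "merged", contact = "ignored", coarseness = 6L),
    industrial = list(source = "cad", dummy = TRUE, bone = "uniform",
                      teeth = "merged", contact = "ignored",
                      coarseness = 3L))
  key <- as.character(model)
  if (!key %in% names(base)) stop("model must be 1, 2, 3, 4 or 'industrial'")
  sp <- base[[key]]
  sp$model <- model
  if (!is.null(contact)) {
    if (sp$contact == "none")
      stop("contact is only configurable for model 4 / industrial")
    sp$contact <- match.arg(contact, c("ignored", "bonded", "frictional"))
  }
  if (!is.null(coarseness)) sp$coarseness <- as.integer(coarseness)
  sp$label <- label %||% (if (key == "industrial") "industrial"
                          else paste0("model_", key))
  structure(sp, class = "variant_spec")
}

# segmentation chain on a calibrated phantom volume: per-part threshold
# masks from tissue-HU midpoints + truth bounding regions, morphological
# cleanup, priority resolution (prosthesis > screws > teeth > mandible)
segment_phantom <- function(hu_vol, truth, min_island = 20L,
                            closing_radius = 0) {
  hu <- truth$tissue_hu
  mid <- function(a, b) (hu[[a]] + hu[[b]]) / 2
  bone_lo <- mid("soft_tissue", "trabecular")
  bone_hi <- mid("cortical", "dentin")
  tooth_hi <- mid("enamel", "titanium")
  reg <- truth$part_regions
  mk <- function(part, lo, hi) {
    m <- threshold_mask(hu_vol, "fixed", lo = lo, hi = hi,
                        region = reg[[part]], part = part)
    morph_clean(m, min_island = min_island, closing_radius = closing_radius)
  }
  masks <- list(
    mk("prosthesis", tooth_hi, Inf),
    mk("screws", tooth_hi, Inf),
    mk("tooth_33", bone_hi, tooth_hi),
    mk("tooth_41", bone_hi, tooth_hi),
    mk("tooth_43", bone_hi, tooth_hi),
    mk("tooth_47", bone_hi, tooth_hi),
    mk("mandible", bone_lo, bone_hi))
  lv <- resolve_priority(masks)
  # keep the canonical part ids of the truth
  remap <- array(0L, dim(lv$labels))
  for (nm in names(lv$part_names))
    remap[lv$labels == lv$part_names[[nm]]] <- truth$labels$part_names[[nm]]
  label_volume(remap, truth$labels$part_names, spacing = lv$spacing,
               origin = lv$origin)
}

# rasterize the exact ("CAD") prosthesis geometry onto the grid
phantom_metal_arrays <- function(config, include_dummy = FALSE) {
  g <- phantom_geometry(config)
  d <- config$shape
  cc <- voxel_centres(d, config$spacing, c(0, 0, 0))
  x <- rep(cc$x, times = d[2] * d[3])
  y <- rep(rep(cc$y, each = d[1]), times = d[3])
  z <- rep(cc$z, each = d[1] * d[2])
  inv <- invert_transform(config$pose)
  pp <- apply_transform(inv, cbind(x, y, z))
  px <- pp[, 1]; py <- pp[, 2]; pz <- pp[, 3]
  plate <- .in_box(px, py, pz, g$plate_box) | .in_box(px, py, pz, g$head_box)
  screws <- Reduce(`|`, lapply(g$screws, function(s)
    .in_cylinder(px, py, pz, s$p0, s$p1, g$screw_r)))
  out <- list(prosthesis = array(plate, d), screws = array(screws, d))
  if (include_dummy)
    out$dummy_screws <- array(Reduce(`|`, lapply(g$dummy_screws, function(s)
      .in_cylinder(px, py, pz, s$p0, s$p1, g$dummy_r))), d)
  out
}

# build the variant's label volume from the segmented labels and, for the
# CAD path, the exact prosthesis geometry
variant_labels <- function(spec, seg_labels, truth) {
  lab <- seg_labels$labels
  pn <- seg_labels$part_names
  if (spec$source == "cad" || spec$dummy) {
    met <- phantom_metal_arrays(truth$config, include_dummy = spec$dummy)
    lab[lab == pn[["prosthesis"]]] <- 0L
    lab[lab == pn[["screws"]]] <- 0L
    lab[met$screws] <- pn[["screws"]]
    lab[met$prosthesis] <- pn[["prosthesis"]]
    if (spec$dummy) {
      if (!"dummy_screws" %in% names(pn))
        pn <- c(pn, dummy_screws = max(pn) + 1L)
      lab[met$dummy_screws & lab == 0L] <- pn[["dummy_screws"]]
    }
  }
  if (spec$teeth == "merged") {
    for (t_ in grep("^tooth_", names(pn), value = TRUE))
      lab[lab == pn[[t_]]] <- pn[["mandible"]]
    pn <- pn[!grepl("^tooth_", names(pn))]
  }
  label_volume(lab, pn, spacing = seg_labels$spacing,
               origin = seg_labels$origin)
}

# material modes per part for a variant
variant_material_modes <- function(spec, parts) {
  modes <- character(0)
  for (p in parts) {
    modes[[p]] <-
      if (p %in% c("prosthesis", "screws", "dummy_screws")) "titanium"
      else if (grepl("^tooth_", p)) "tooth"
      else if (spec$bone == "uniform") "bone_uniform"
      else "mapped"
  }
  modes
}

#' Run one model variant end-to-end on the phantom
#'
#' Executes phantom generation (or reuse), calibration, segmentation (or
#' the exact-CAD path), material mapping, meshing, the solve with the
#' variant's contact treatment, and peak-stress extraction for the
#' prosthesis.
#'
#' @param spec a [variant_spec()].
#' @param config a [phantom_config()].
#' @param phantom optional prebuilt result of [build_phantom()] (reused
#'   across variants).
#' @param seg_labels optional precomputed segmentation labels.
#' @param reference normalization reference stress (MPa); defaults to the
#'   run's own peak.
#' @param bite_force bite-force magnitude at the molar ROI (N), applied
#'   along the volume's superior (+z) axis.
#' @return A `variant_run`: `spec`, `summary` (a `stress_summary`),
#'   `n_nodes`, `n_elements`, `solution`, `mesh`, and timing.
#' @export
run_variant <- function(spec, config = phantom_config(), phantom = NULL,
                        seg_labels = NULL, reference = NULL,
                        bite_force = 450) {
  stopifnot(inherits(spec, "variant_spec"))
  t0 <- proc.time()[3]
  if (is.null(phantom)) phantom <- build_phantom(config)
  truth <- phantom$truth
  hu <- calibrate(phantom$volume, truth$mean_water_raw, truth$mean_air_raw)
  if (is.null(seg_labels)) seg_labels <- segment_phantom(hu, truth)
  labels <- variant_labels(spec, seg_labels, truth)
  metal_parts <- intersect(c("prosthesis", "screws", "dummy_screws"),
                           names(labels$part_names))
  mesh <- mesh_from_labels(labels, coarseness = spec$coarseness,
                           preserve = metal_parts)
  modes <- variant_material_modes(spec, names(labels$part_names))
  materials <- assign_element_materials(mesh, vol = hu, modes = modes)

  lr <- truth$load_regions
  sets <- list(
    condyle_prosthesis = c(lr$condyle_prosthesis, part = "prosthesis"),
    condyle_contralateral = c(lr$condyle_contralateral, part = "mandible"),
    bite = lr$bite_tooth_47)
  mus <- truth$muscles
  for (k in seq_len(nrow(mus)))
    sets[[paste0("muscle_", mus$name[k])]] <-
      list(type = "sphere", centre = c(mus$x[k], mus$y[k], mus$z[k]),
           radius = mus$radius[k], part = "mandible")
  mesh <- suppressWarnings(define_node_sets(mesh, sets))
  for (req in c("condyle_prosthesis", "condyle_contralateral", "bite"))
    if (!length(mesh$node_sets[[req]]))
      stop("required node set '", req, "' is empty at coarseness ",
           spec$coarseness, "; refine the mesh or enlarge the region")

  loads <- list(list(set = "bite", force = c(0, 0, bite_force)))
  for (k in seq_len(nrow(mus))) {
    nm <- paste0("muscle_", mus$name[k])
    if (length(mesh$node_sets[[nm]]))
      loads[[length(loads) + 1L]] <-
        list(set = nm, force = c(mus$Fx[k], mus$Fy[k], mus$Fz[k]))
    else
      message("muscle '", mus$name[k],
              "' attaches to resected bone: dropped")
  }
  dir_specs <- list(
    list(set = "condyle_prosthesis", components = 1:3, value = 0),
    list(set = "condyle_contralateral", components = 1:3, value = 0))

  if (spec$contact == "none") {
    lc <- load_case(dirichlet = dir_specs, loads = loads)
    sol <- solve_linear(mesh, materials, lc)
  } else {
    mesh <- split_interface(mesh, slave = "prosthesis", master = "mandible")
    lc <- load_case(dirichlet = dir_specs, loads = loads,
                    contact = list(mode = spec$contact, mu = 0.3,
                                   penalty_scale = 50))
    sol <- solve_contact(mesh, materials, lc)
  }
  if (is.null(reference)) {
    own <- peak_stress(sol, mesh, "prosthesis", reference = 1,
                       variant = spec$label)
    reference <- own$peak
  }
  summ <- peak_stress(sol, mesh, "prosthesis", reference = reference,
                      variant = spec$label)
  structure(list(spec = spec, summary = summ,
                 n_nodes = nrow(mesh$nodes),
                 n_elements = nrow(mesh$elements),
                 solution = sol, mesh = mesh, materials = materials,
                 elapsed_s = unname(proc.time()[3] - t0)),
            class = "variant_run")
}

#' @export
print.variant_run <- function(x, ...) {
  cat(sprintf(
    "<variant_run> %s: %d nodes, %d elements, peak %.4g MPa (norm %.3f), %ds\n",
    x$spec$label, x$n_nodes, x$n_elements, x$summary$peak,
    x$summary$normalized, round(x$elapsed_s)))
  invisible(x)
}

#' Run the full variant ladder on one phantom
#'
#' Executes the industrial-style run (the normalization reference), Models
#' 1-3, and Model 4 with and without frictional contact, then compiles the
#' cross-variant comparison report and a reproduction manifest.
#'
#' @param config a [phantom_config()].
#' @param bite_force bite-force magnitude (N).
#' @param out_dir optional directory for artifacts (VTK solutions, report
#'   CSV/JSON, manifest).
#' @return A `run_all_result`: `runs` (named list of `variant_run`),
#'   `report` (a `variant_report`), `reference` (MPa), `manifest`.
#' @export
run_all <- function(config = phantom_config(), bite_force = 450,
                    out_dir = NULL) {
  phantom <- build_phantom(config)
  truth <- phantom$truth
  hu <- calibrate(phantom$volume, truth$mean_water_raw, truth$mean_air_raw)
  seg_labels <- segment_phantom(hu, truth)
  industrial <- run_variant(variant_spec("industrial"), config,
                            phantom = phantom, seg_labels = seg_labels,
                            bite_force = bite_force)
  reference <- industrial$summary$peak
  industrial$summary <- peak_stress(industrial$solution, industrial$mesh,
                                    "prosthesis", reference = reference,
                                    variant = "industrial")
  runs <- list(industrial = industrial)
  specs <- list(
    model_1 = variant_spec(1),
    model_2 = variant_spec(2),
    model_3 = variant_spec(3),
    model_4 = variant_spec(4),                        # contact ignored
    model_4_contact = variant_spec(4, contact = "frictional",
                                   label = "model_4_contact"))
  for (nm in names(specs)) {
    runs[[nm]] <- run_variant(specs[[nm]], config, phantom = phantom,
                              seg_labels = seg_labels,
                              reference = reference,
                              bite_force = bite_force)
  }
  order_out <- c("model_1", "model_2", "model_3", "model_4",
                 "model_4_contact", "industrial")
  runs <- runs[order_out]
  report <- compare_variants(lapply(runs, function(r) r$summary))
  manifest <- list(
    package_version = as.character(utils::packageVersion("tmjfem")),
    seed = config$seed,
    grid = config$shape, spacing = config$spacing,
    noise_sd = config$noise_sd, bite_force = bite_force,
    coarseness = vapply(runs, function(r) r$spec$coarseness, integer(1)),
    reference_MPa = reference)
  out <- structure(list(runs = runs, report = report,
                        reference = reference, manifest = manifest),
                   class = "run_all_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(runs))
      write_solution_vtk(runs[[nm]]$mesh,
                         file.path(out_dir, paste0(nm, ".vtk")),
                         sol = runs[[nm]]$solution,
                         materials = runs[[nm]]$materials)
    utils::write.csv(report$table, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(table = report$table,
                              pairwise = report$pairwise,
                              manifest = manifest),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_stl(truth$cad_surface, file.path(out_dir, "prosthesis_cad.stl"))
  }
  out
}

#' @export
print.run_all_result <- function(x, ...) {
  cat("<run_all_result> reference", signif(x$reference, 5), "MPa\n")
  print(x$report)
  invisible(x)
}
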