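#' Configuration of the synthetic CT phantom
#'
#' The phantom stands in for the post-operative CT of a unilateral TMJ
#' replacement: a horseshoe-shaped mandible body (cortical shell over a
#' trabecular core) with one intact condylar stub, four teeth (enamel caps
#' over dentin), a titanium condyle-replacing prosthesis plate on the
#' resected side fixed by three cylindrical screws, optional "dummy" screws
#' from the planning stage, and an air / soft-tissue background. Voxel size
#' defaults to 0.3 mm isotropic.
#'
#' Raw scanner values are generated as `raw = g * HU + h` plus seeded
#' Gaussian noise, so the calibration stage has a real transform to invert;
#' `g` and `h` are recorded in the phantom truth.
#'
#' @param shape integer length-3 voxel grid (default `c(120, 120, 90)`).
#' @param spacing voxel spacing in mm (scalar or length 3, default 0.3).
#' @param hu named numeric vector of nominal HU per tissue; must be ordered
#'   air < soft_tissue < trabecular < cortical <= dentin < enamel < titanium.
#' @param noise_sd Gaussian noise standard deviation in HU (default 30).
#' @param metal_artifacts add streak-like extra noise on slices intersecting
#'   titanium (default `FALSE`).
#' @param seed integer random seed.
#' @param pose a [rigid_transform()] applied to the prosthesis and screws.
#' @param dummy_screws rasterize the two planned-but-unplaced screws into the
#'   volume (default `FALSE`; their geometry is always carried in the truth).
#' @param raw_gain,raw_offset the affine raw-value transform `g`, `h`.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(120L, 120L, 90L),
                           spacing = 0.3,
                           hu = c(air = -1000, soft_tissue = 40,
                                  trabecular = 300, cortical = 1200,
                                  dentin = 1700, enamel = 2400,
                                  titanium = 3000),
                           noise_sd = 30,
                           metal_artifacts = FALSE,
                           seed = 1L,
                           pose = rigid_transform(),
                           dummy_screws = FALSE,
                           raw_gain = 0.8, raw_offset = 1024) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("grid shape must be 3 integers, each >= 8")
  need <- c("air", "soft_tissue", "trabecular", "cortical", "dentin",
            "enamel", "titanium")
  if (!all(need %in% names(hu))) stop("`hu` must name all seven tissues")
  hu <- hu[need]
  ok <- hu[["air"]] < hu[["soft_tissue"]] &&
    hu[["soft_tissue"]] < hu[["trabecular"]] &&
    hu[["trabecular"]] < hu[["cortical"]] &&
    hu[["cortical"]] <= hu[["dentin"]] &&
    hu[["dentin"]] < hu[["enamel"]] &&
    hu[["enamel"]] < hu[["titanium"]]
  if (!ok)
    stop("tissue HU must be ordered air < soft tissue < trabecular < ",
         "cortical <= dentin < enamel < titanium")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(inherits(pose, "rigid_transform"))
  structure(list(shape = shape, spacing = spacing, hu = hu,
                 noise_sd = noise_sd, metal_artifacts = metal_artifacts,
                 seed = as.integer(seed), pose = pose,
                 dummy_screws = isTRUE(dummy_screws),
                 raw_gain = raw_gain, raw_offset = raw_offset),
            class = "phantom_config")
}

# Fixed world-space geometry parameters of the phantom (mm). The grid box is
# shape * spacing; the default 120x120x90 at 0.3 mm gives 36 x 36 x 27 mm.
# Geometry is expressed in fractions of the default box so non-default grids
# still contain it.
phantom_geometry <- function(cfg) {
  box <- cfg$shape * cfg$spacing
  s <- box / c(36, 36, 27)        # scale relative to the reference box
  sc <- function(p) p * s         # scale a point
  r1 <- min(s)                    # isotropic-ish scale for radii
  list(
    torus_centre = sc(c(18, 22, 8)),
    torus_R = 10 * min(s[1:2]),
    torus_r = 3.2 * r1,
    shell = 1.0 * r1,
    stub_centre = sc(c(8, 22, 8))[1:2],
    stub_r = 2.6 * r1,
    stub_z = c(8, 20) * s[3],
    teeth = list(
      tooth_33 = list(centre = sc(c(10.93, 14.93, 0))[1:2]),
      tooth_41 = list(centre = sc(c(15.41, 12.34, 0))[1:2]),
      tooth_43 = list(centre = sc(c(20.59, 12.34, 0))[1:2]),
      tooth_47 = list(centre = sc(c(25.07, 14.93, 0))[1:2])),
    tooth_r = 1.1 * r1,
    tooth_z = c(10.8, 14.4) * s[3],
    enamel_z = 13.2 * s[3],
    # flat lateral "ramus" slab the fixation plate sits on (cortical)
    seat_box = rbind(lo = sc(c(28.6, 20.0, 6.0)), hi = sc(c(31.0, 24.0, 14.0))),
    plate_box = rbind(lo = sc(c(31.0, 20.0, 6.0)), hi = sc(c(33.0, 24.0, 20.0))),
    head_box = rbind(lo = sc(c(30.4, 20.5, 18.0)), hi = sc(c(33.6, 23.5, 20.0))),
    screws = list(
      list(p0 = sc(c(26.0, 22.0, 7.5)), p1 = sc(c(31.0, 22.0, 7.5))),
      list(p0 = sc(c(25.4, 21.0, 9.5)), p1 = sc(c(31.0, 21.0, 9.5))),
      list(p0 = sc(c(25.4, 23.0, 9.5)), p1 = sc(c(31.0, 23.0, 9.5)))),
    screw_r = 1.2 * r1,
    dummy_screws = list(
      list(p0 = sc(c(29.8, 20.8, 16.5)), p1 = sc(c(31.0, 20.8, 16.5))),
      list(p0 = sc(c(29.8, 23.2, 16.5)), p1 = sc(c(31.0, 23.2, 16.5)))),
    dummy_r = 0.9 * r1,
    soft_centre = sc(c(18, 19, 10)),
    soft_semi = sc(c(16, 13, 11))
  )
}

# inside tests on flattened coordinate vectors ------------------------------

.in_box <- function(x, y, z, box) {
  x >= box["lo", 1] & x <= box["hi", 1] &
    y >= box["lo", 2] & y <= box["hi", 2] &
    z >= box["lo", 3] & z <= box["hi", 3]
}

# cylinder along the segment p0 -> p1 (axis-aligned use only needs the
# general form once, so keep it general)
.in_cylinder <- function(x, y, z, p0, p1, r) {
  d <- p1 - p0
  L2 <- sum(d^2)
  t <- ((x - p0[1]) * d[1] + (y - p0[2]) * d[2] + (z - p0[3]) * d[3]) / L2
  inside_t <- t >= 0 & t <= 1
  px <- p0[1] + t * d[1]; py <- p0[2] + t * d[2]; pz <- p0[3] + t * d[3]
  inside_t & ((x - px)^2 + (y - py)^2 + (z - pz)^2) <= r^2
}

.in_vert_cylinder <- function(x, y, z, centre_xy, r, z0, z1) {
  (x - centre_xy[1])^2 + (y - centre_xy[2])^2 <= r^2 & z >= z0 & z <= z1
}

#' Build the synthetic CT phantom
#'
#' Rasterizes the phantom geometry onto the voxel grid, assigns nominal HU
#' per tissue, applies the raw affine transform and seeded Gaussian noise,
#' and returns both the raw (uncalibrated) volume and the ground truth.
#'
#' Part priority during rasterization is prosthesis > screws > teeth >
#' mandible; overlapping user part specifications beyond the deliberate
#' plate-bone apposition are rejected.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `volume` (raw [image_volume()]) and `truth`,
#'   a `phantom_truth` list holding the label volume, nominal-HU volume,
#'   exact prosthesis CAD surface, screw geometry, per-tissue HU, the raw
#'   transform (`raw_gain`, `raw_offset`, and the water/air raw reference
#'   means), part bounding regions, muscle-force table and the fixation /
#'   bite region specs.
#' @export
build_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  g <- phantom_geometry(config)
  d <- config$shape
  cc <- voxel_centres(d, config$spacing, c(0, 0, 0))
  x <- rep(cc$x, times = d[2] * d[3])
  y <- rep(rep(cc$y, each = d[1]), times = d[3])
  z <- rep(cc$z, each = d[1] * d[2])

  # pose: prosthesis + screws are rasterized in posed coordinates by pulling
  # voxel centres back through the inverse transform
  inv <- invert_transform(config$pose)
  pp <- apply_transform(inv, cbind(x, y, z))
  px <- pp[, 1]; py <- pp[, 2]; pz <- pp[, 3]

  # mandible: half-torus body (opening posterior, y > centre) + left stub
  ring <- sqrt((sqrt((x - g$torus_centre[1])^2 + (y - g$torus_centre[2])^2) -
                  g$torus_R)^2 + (z - g$torus_centre[3])^2)
  body <- ring <= g$torus_r & y <= g$torus_centre[2]
  cortical_body <- body & ring >= (g$torus_r - g$shell)
  rad_stub <- sqrt((x - g$stub_centre[1])^2 + (y - g$stub_centre[2])^2)
  stub <- rad_stub <= g$stub_r & z >= g$stub_z[1] & z <= g$stub_z[2]
  cortical_stub <- stub & (rad_stub >= (g$stub_r - g$shell) |
                             z >= (g$stub_z[2] - g$shell))
  seat <- .in_box(x, y, z, g$seat_box)
  mandible <- body | stub | seat
  cortical <- cortical_body | cortical_stub | seat

  teeth <- lapply(g$teeth, function(t)
    .in_vert_cylinder(x, y, z, t$centre, g$tooth_r, g$tooth_z[1], g$tooth_z[2]))
  enamel <- z >= g$enamel_z

  plate <- .in_box(px, py, pz, g$plate_box) | .in_box(px, py, pz, g$head_box)
  screws <- Reduce(`|`, lapply(g$screws, function(s)
    .in_cylinder(px, py, pz, s$p0, s$p1, g$screw_r)))
  dummies <- Reduce(`|`, lapply(g$dummy_screws, function(s)
    .in_cylinder(px, py, pz, s$p0, s$p1, g$dummy_r)))

  soft <- ((x - g$soft_centre[1]) / g$soft_semi[1])^2 +
    ((y - g$soft_centre[2]) / g$soft_semi[2])^2 +
    ((z - g$soft_centre[3]) / g$soft_semi[3])^2 <= 1

  # overlap check: metal vs teeth means the part specification is inconsistent
  metal <- plate | screws | (if (config$dummy_screws) dummies else FALSE)
  any_tooth <- Reduce(`|`, teeth)
  if (any(metal & any_tooth))
    stop("overlapping part specification: prosthesis/screws intersect teeth ",
         "(check the prosthesis pose)")

  part_names <- c(mandible = 1L, tooth_33 = 2L, tooth_41 = 3L,
                  tooth_43 = 4L, tooth_47 = 5L, prosthesis = 6L, screws = 7L)
  if (config$dummy_screws)
    part_names <- c(part_names, dummy_screws = 8L)

  lab <- integer(length(x))
  tissue <- rep(config$hu[["air"]], length(x))
  tissue[soft] <- config$hu[["soft_tissue"]]
  lab[mandible] <- 1L
  tissue[mandible] <- config$hu[["trabecular"]]
  tissue[cortical] <- config$hu[["cortical"]]
  for (i in seq_along(teeth)) {
    ti <- teeth[[i]]
    lab[ti] <- 1L + i
    tissue[ti] <- ifelse(enamel[ti], config$hu[["enamel"]],
                         config$hu[["dentin"]])
  }
  if (config$dummy_screws) {
    lab[dummies] <- 8L
    tissue[dummies] <- config$hu[["titanium"]]
  }
  lab[screws] <- 7L
  tissue[screws] <- config$hu[["titanium"]]
  lab[plate] <- 6L
  tissue[plate] <- config$hu[["titanium"]]

  lab <- array(lab, d)
  tissue <- array(tissue, d)

  set.seed(config$seed)
  hu_noisy <- tissue
  if (config$noise_sd > 0)
    hu_noisy <- hu_noisy + stats::rnorm(length(tissue), 0, config$noise_sd)
  if (config$metal_artifacts) {
    ti_slices <- which(apply(array(tissue == config$hu[["titanium"]], d),
                             3L, any))
    if (length(ti_slices)) {
      cx <- mean(g$plate_box[, 1]); cy <- mean(g$plate_box[, 2])
      th <- atan2(array(y, d)[, , 1] - cy, array(x, d)[, , 1] - cx)
      streak <- abs(cos(4 * th))
      for (k in ti_slices)
        hu_noisy[, , k] <- hu_noisy[, , k] +
          streak * stats::rnorm(d[1] * d[2], 0, 150)
    }
  }
  raw <- config$raw_gain * hu_noisy + config$raw_offset
  vol <- image_volume(raw, spacing = config$spacing, units = "raw")

  labels <- label_volume(lab, part_names, spacing = config$spacing)
  regions <- phantom_part_regions(labels, config)
  truth <- structure(list(
    labels = labels,
    nominal_hu = image_volume(tissue, spacing = config$spacing, units = "HU"),
    tissue_hu = config$hu,
    cad_surface = phantom_cad_surface(config),
    geometry = g,
    pose = config$pose,
    raw_gain = config$raw_gain,
    raw_offset = config$raw_offset,
    mean_water_raw = config$raw_offset,
    mean_air_raw = -1000 * config$raw_gain + config$raw_offset,
    part_regions = regions,
    muscles = phantom_muscle_table(config),
    load_regions = phantom_load_regions(config),
    config = config), class = "phantom_truth")
  list(volume = vol, truth = truth)
}

# exact triangulated "CAD" surface of the prosthesis (plate + head boxes,
# emitted as a triangle soup of the two posed boxes)
phantom_cad_surface <- function(config) {
  g <- phantom_geometry(config)
  s1 <- box_surface(g$plate_box["lo", ], g$plate_box["hi", ])
  s2 <- box_surface(g$head_box["lo", ], g$head_box["hi", ])
  merged <- merge_surfaces(s1, s2)
  transform_surface(config$pose, merged)
}

# padded world bounding regions used by the segmentation stage; prosthesis
# boxes are exact (unpadded) so that threshold + region reproduces the
# rasterization at the default pose
phantom_part_regions <- function(labels, config) {
  g <- phantom_geometry(config)
  d <- dim(labels$labels)
  sp <- labels$spacing
  pad_box_of <- function(id, pad) {
    w <- which(labels$labels == id, arr.ind = TRUE)
    lo <- (apply(w, 2L, min) - 1L) * sp - pad
    hi <- apply(w, 2L, max) * sp + pad
    list(list(lo = lo, hi = hi))
  }
  regions <- list(
    mandible = pad_box_of(1L, pad = 2 * config$spacing),
    tooth_33 = pad_box_of(2L, pad = config$spacing),
    tooth_41 = pad_box_of(3L, pad = config$spacing),
    tooth_43 = pad_box_of(4L, pad = config$spacing),
    tooth_47 = pad_box_of(5L, pad = config$spacing),
    prosthesis = list(list(lo = g$plate_box["lo", ], hi = g$plate_box["hi", ]),
                      list(lo = g$head_box["lo", ], hi = g$head_box["hi", ])),
    screws = pad_box_of(7L, pad = config$spacing))
  if (config$dummy_screws)
    regions$dummy_screws <- pad_box_of(8L, pad = config$spacing)
  regions
}

# placeholder muscle-force table: representative masticatory muscle forces
# (N) with spherical attachment regions on the mandible surface; real
# patient values from a musculoskeletal simulation should replace these
phantom_muscle_table <- function(config) {
  s <- config$shape * config$spacing / c(36, 36, 27)
  sc <- function(p) p * s
  m <- rbind(
    data.frame(name = "masseter_right", t(sc(c(27.5, 20.0, 9.5))),
               radius = 2.5 * min(s), Fx = 0, Fy = -50, Fz = 180),
    data.frame(name = "masseter_left", t(sc(c(8.5, 20.0, 10.0))),
               radius = 2.5 * min(s), Fx = 0, Fy = -50, Fz = 180),
    data.frame(name = "temporalis_right", t(sc(c(26.5, 21.5, 10.5))),
               radius = 2.2 * min(s), Fx = 0, Fy = 40, Fz = 140),
    data.frame(name = "temporalis_left", t(sc(c(9.5, 21.5, 10.5))),
               radius = 2.2 * min(s), Fx = 0, Fy = 40, Fz = 140),
    data.frame(name = "pterygoid_right", t(sc(c(24.0, 18.0, 8.0))),
               radius = 2.2 * min(s), Fx = -20, Fy = -20, Fz = 110),
    data.frame(name = "pterygoid_left", t(sc(c(12.0, 18.0, 8.0))),
               radius = 2.2 * min(s), Fx = 20, Fy = -20, Fz = 110))
  names(m)[2:4] <- c("x", "y", "z")
  m
}

# fixation and bite-force region specs (world mm)
phantom_load_regions <- function(config) {
  g <- phantom_geometry(config)
  s <- config$shape * config$spacing / c(36, 36, 27)
  sc <- function(p) p * s
  list(
    condyle_prosthesis = list(type = "box",
                              lo = g$head_box["lo", ] - c(0, 0, -0.5),
                              hi = g$head_box["hi", ] + 0.01),
    condyle_contralateral = list(type = "box",
                                 lo = sc(c(5.0, 19.0, 18.5)),
                                 hi = sc(c(11.0, 25.0, 20.1))),
    bite_tooth_47 = list(type = "box",
                         lo = sc(c(23.8, 13.6, 13.7)),
                         hi = sc(c(26.4, 16.3, 14.5))))
}

#' Simulate a gravimetric wear-test series
#'
#' Generates cumulative specimen mass-loss readings and soak-control mass
#' changes at `n = step, 2*step, ...` cycles, following the linear model
#' `loss(n) = true_rate * n + intercept` with an environmental drift common
#' to specimen and soak control (removed by the soak correction) and
#' optional Gaussian reading noise. Defaults follow the study conditions of
#' a 5-million-cycle test read out in steps of 500,000 cycles.
#'
#' @param true_rate true wear rate in mg per cycle.
#' @param intercept running-in constant `b` in mg.
#' @param soak_drift environmental drift in mg per cycle (adds to the
#'   apparent specimen loss; the soak control gains the opposite).
#' @param n_points number of readings (>= 2, default 10).
#' @param step cycles between readings (default 500000).
#' @param noise_sd reading noise standard deviation in mg.
#' @param seed integer random seed.
#' @return A `wear_series` list with `n`, `specimen_loss` and `soak_gain`
#'   (all readings cumulative; mass in mg).
#' @export
simulate_wear_series <- function(true_rate = 0.58032e-6, intercept = 0.05,
                                 soak_drift = 0, n_points = 10L,
                                 step = 500000, noise_sd = 0.01, seed = 1L) {
  if (n_points < 2L)
    stop("n_points must be >= 2 (regression impossible otherwise)")
  if (step <= 0) stop("step must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  n <- step * seq_len(n_points)
  e1 <- if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else 0
  e2 <- if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else 0
  specimen <- true_rate * n + intercept + soak_drift * n + e1
  soak <- -soak_drift * n + e2
  structure(list(n = n, specimen_loss = specimen, soak_gain = soak),
            class = "wear_series")
}
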