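#' Voxel volume containers
#'
#' An `image_volume` holds a 3D scalar array (raw scanner units or calibrated
#' Hounsfield units) together with its voxel spacing and world origin, in the
#' convention used throughout the package: array index `[i, j, k]` maps to
#' world coordinate `origin + (c(i, j, k) - 0.5) * spacing` (voxel centres),
#' axes ordered x, y, z in mm.
#'
#' @param data numeric 3D array of voxel values.
#' @param spacing numeric length-3 voxel spacing in mm (all > 0).
#' @param origin numeric length-3 world position of the volume corner in mm.
#' @param units label for the value scale, `"raw"` or `"HU"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(0.3, 0.3, 0.3), origin = c(0, 0, 0),
                         units = "raw") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  if (any(!is.finite(data)))
    stop("volume values must all be finite")
  structure(list(data = data, spacing = spacing, origin = origin,
                 units = units),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, units %s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              x$units))
  cat(sprintf("  value range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Per-voxel part labels
#'
#' A `label_volume` assigns one integer part id per voxel (0 = background)
#' and carries the id-to-name map.
#'
#' @param labels integer 3D array of part ids, 0 for background.
#' @param part_names named integer vector mapping part name -> id.
#' @param spacing,origin geometry as in [image_volume()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, part_names, spacing = c(0.3, 0.3, 0.3),
                         origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  part_names <- as.integer(part_names) |> stats::setNames(names(part_names))
  if (anyDuplicated(part_names) || anyDuplicated(names(part_names)))
    stop("part names and ids must be one-to-one")
  used <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!all(used %in% part_names))
    stop("labels present in the volume without a part name: ",
         paste(setdiff(used, part_names), collapse = ", "))
  structure(list(labels = labels, part_names = part_names,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d parts\n",
              d[1], d[2], d[3], length(x$part_names)))
  for (nm in names(x$part_names)) {
    n <- sum(x$labels == x$part_names[[nm]])
    cat(sprintf("  %-16s id %2d  %d voxels\n", nm, x$part_names[[nm]], n))
  }
  invisible(x)
}

#' Extract one part of a label volume as a mask
#'
#' @param lab a [label_volume()].
#' @param part part name or integer id.
#' @return A [mask()].
#' @export
label_mask <- function(lab, part) {
  stopifnot(inherits(lab, "label_volume"))
  id <- if (is.character(part)) lab$part_names[[part]] else as.integer(part)
  if (is.null(id)) stop("unknown part: ", part)
  mask(lab$labels == id, part = if (is.character(part)) part else
    names(lab$part_names)[match(id, lab$part_names)],
    spacing = lab$spacing, origin = lab$origin)
}

#' Boolean voxel mask
#'
#' @param data logical 3D array.
#' @param part part name the mask describes.
#' @param spacing,origin geometry as in [image_volume()].
#' @return An object of class `mask`.
#' @export
mask <- function(data, part = "mask", spacing = c(0.3, 0.3, 0.3),
                 origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  structure(list(data = data, part = part, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "mask")
}

#' @export
print.mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask> '%s' %d x %d x %d voxels, %d foreground\n",
              x$part, d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

# world coordinates of all voxel centres for a voxel geometry
voxel_centres <- function(dim3, spacing, origin) {
  list(x = origin[1] + (seq_len(dim3[1]) - 0.5) * spacing[1],
       y = origin[2] + (seq_len(dim3[2]) - 0.5) * spacing[2],
       z = origin[3] + (seq_len(dim3[3]) - 0.5) * spacing[3])
}

#' Trilinear interpolation of a volume at world points
#'
#' Samples voxel-centre values with trilinear weights; points are clamped to
#' the voxel-centre bounding box, so queries within half a voxel of the
#' border take border values.
#'
#' @param vol an [image_volume()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return Numeric vector of n sampled values.
#' @export
sample_trilinear <- function(vol, pts) {
  stopifnot(inherits(vol, "image_volume"))
  pts <- matrix(as.numeric(pts), ncol = 3L)
  d <- dim(vol$data)
  # continuous index of the voxel-centre lattice (1-based)
  ci <- sweep(sweep(pts, 2L, vol$origin, "-"), 2L, vol$spacing, "/") + 0.5
  out <- numeric(nrow(pts))
  i0 <- j0 <- k0 <- integer(nrow(pts))
  fr <- matrix(0, nrow(pts), 3L)
  for (ax in 1:3) {
    v <- pmin(pmax(ci[, ax], 1), d[ax])
    lo <- pmin(floor(v), d[ax] - 1L)
    lo <- pmax(lo, 1L)
    fr[, ax] <- v - lo
    if (ax == 1L) i0 <- as.integer(lo)
    if (ax == 2L) j0 <- as.integer(lo)
    if (ax == 3L) k0 <- as.integer(lo)
  }
  if (any(d < 2L)) stop("volume too small to interpolate")
  idx <- function(i, j, k) ((k - 1L) * d[2] + (j - 1L)) * d[1] + i
  v <- as.vector(vol$data)
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  out <-
    v[idx(i0,     j0,     k0)]     * (1 - fx) * (1 - fy) * (1 - fz) +
    v[idx(i0 + 1L, j0,     k0)]     * fx       * (1 - fy) * (1 - fz) +
    v[idx(i0,     j0 + 1L, k0)]     * (1 - fx) * fy       * (1 - fz) +
    v[idx(i0 + 1L, j0 + 1L, k0)]     * fx       * fy       * (1 - fz) +
    v[idx(i0,     j0,     k0 + 1L)] * (1 - fx) * (1 - fy) * fz +
    v[idx(i0 + 1L, j0,     k0 + 1L)] * fx       * (1 - fy) * fz +
    v[idx(i0,     j0 + 1L, k0 + 1L)] * (1 - fx) * fy       * fz +
    v[idx(i0 + 1L, j0 + 1L, k0 + 1L)] * fx       * fy       * fz
  out
}

#' Write / read a volume as a slice directory with JSON sidecar
#'
#' The on-disk layout mirrors a DICOM-like stack: one binary 16-bit
#' little-endian file per z-slice (`slice_0001.raw`, ...) plus
#' `volume.json` holding shape, spacing, origin, units, value offset/scale
#' and any extra metadata. Values are stored as
#' `round((v - offset) / scale)` in signed 16-bit range.
#'
#' @param vol an [image_volume()].
#' @param dir output directory (created if missing).
#' @param meta optional named list merged into the sidecar.
#' @return `dir`, invisibly.
#' @export
write_volume <- function(vol, dir, meta = list()) {
  stopifnot(inherits(vol, "image_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$data)
  rng <- range(vol$data)
  scale <- max((rng[2] - rng[1]) / 60000, 1e-12)
  offset <- mean(rng)
  side <- c(list(shape = d, spacing = vol$spacing, origin = vol$origin,
                 units = vol$units, offset = offset, scale = scale,
                 slice_format = "int16-le"), meta)
  jsonlite::write_json(side, file.path(dir, "volume.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_len(d[3])) {
    con <- file(file.path(dir, sprintf("slice_%04d.raw", k)), "wb")
    writeBin(as.integer(round((vol$data[, , k] - offset) / scale)),
             con, size = 2L, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' @rdname write_volume
#' @param dir directory previously written by [write_volume()].
#' @export
read_volume <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "volume.json"),
                              simplifyVector = TRUE)
  d <- as.integer(side$shape)
  arr <- array(0, d)
  for (k in seq_len(d[3])) {
    con <- file(file.path(dir, sprintf("slice_%04d.raw", k)), "rb")
    raw <- readBin(con, "integer", n = d[1] * d[2], size = 2L,
                   signed = TRUE, endian = "little")
    close(con)
    arr[, , k] <- raw * side$scale + side$offset
  }
  image_volume(arr, spacing = side$spacing, origin = side$origin,
               units = side$units)
}
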