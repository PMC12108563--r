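#' Calibrate a raw CT volume to Hounsfield units
#'
#' Two-point linear calibration: the mean raw value of water maps to 0 HU
#' and the mean raw value of air to -1000 HU, applied voxelwise.
#'
#' @param raw an [image_volume()] in raw scanner units.
#' @param mean_water,mean_air mean raw values of the water and air
#'   references (must differ).
#' @return An [image_volume()] in HU.
#' @export
calibrate <- function(raw, mean_water, mean_air) {
  stopifnot(inherits(raw, "image_volume"))
  if (mean_water == mean_air)
    stop("water and air reference means are equal: calibration line degenerate")
  hu <- -1000 * (raw$data - mean_water) / (mean_air - mean_water)
  image_volume(hu, spacing = raw$spacing, origin = raw$origin, units = "HU")
}

# logical array of voxels whose centre lies in the union of world boxes;
# boxes is a list of list(lo=, hi=)
region_array <- function(dim3, spacing, origin, boxes) {
  if (is.null(boxes)) return(array(TRUE, dim3))
  cc <- voxel_centres(dim3, spacing, origin)
  out <- array(FALSE, dim3)
  for (b in boxes) {
    ix <- cc$x >= b$lo[1] & cc$x <= b$hi[1]
    iy <- cc$y >= b$lo[2] & cc$y <= b$hi[2]
    iz <- cc$z >= b$lo[3] & cc$z <= b$hi[3]
    out <- out | outer(outer(ix, iy, "&"), iz, "&")
  }
  out
}

#' Otsu threshold of a sample
#'
#' Maximizes the between-class variance over a binned histogram; returns the
#' value separating the two classes (the upper edge of the optimal bin).
#'
#' @param values numeric sample.
#' @param nbins number of histogram bins (default 256).
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to threshold")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(values, br, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  # between-class variance for split after each bin
  valid <- w0 > 0 & w0 < 1
  bc <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bc[!valid] <- -Inf
  k <- which.max(bc[-nbins])
  br[k + 1L]
}

#' Threshold a calibrated volume into a mask
#'
#' `method = "fixed"` selects voxels with value in `[lo, hi]`.
#' `method = "adaptive"` computes an Otsu-style bimodal split of the
#' histogram restricted to `region` and selects the requested side, capped
#' by `lo`/`hi` when given.
#'
#' @param vol an [image_volume()] (calibrated HU for CT use).
#' @param method `"fixed"` or `"adaptive"`.
#' @param lo,hi value range (fixed) or optional caps (adaptive).
#' @param region optional list of world boxes (`list(lo=, hi=)`) restricting
#'   the mask; also the histogram support for the adaptive split.
#' @param side for adaptive: keep values `"above"` (default) or `"below"`
#'   the split.
#' @param part part name stored on the mask.
#' @return A [mask()]; empty masks are produced with a warning. The adaptive
#'   threshold is stored as attribute `"threshold"`.
#' @export
threshold_mask <- function(vol, method = c("fixed", "adaptive"),
                           lo = -Inf, hi = Inf, region = NULL,
                           side = c("above", "below"), part = "mask") {
  stopifnot(inherits(vol, "image_volume"))
  method <- match.arg(method)
  side <- match.arg(side)
  reg <- region_array(dim(vol$data), vol$spacing, vol$origin, region)
  thr <- NULL
  if (method == "fixed") {
    sel <- vol$data >= lo & vol$data <= hi & reg
  } else {
    vals <- vol$data[reg]
    thr <- otsu_threshold(vals)
    sel <- if (side == "above") vol$data > thr else vol$data < thr
    sel <- sel & vol$data >= lo & vol$data <= hi & reg
  }
  if (!any(sel)) warning("threshold produced an empty mask for part '",
                         part, "'")
  out <- mask(sel, part = part, spacing = vol$spacing, origin = vol$origin)
  if (!is.null(thr)) attr(out, "threshold") <- thr
  out
}

# shift a numeric array by integer offset s, padding with `fill`
shift_array <- function(v, s, fill) {
  d <- dim(v)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (s[ax] >= 0) {
      dst[[ax]] <- seq_len(d[ax] - s[ax]) + s[ax]
      src[[ax]] <- seq_len(d[ax] - s[ax])
    } else {
      dst[[ax]] <- seq_len(d[ax] + s[ax])
      src[[ax]] <- seq_len(d[ax] + s[ax]) - s[ax]
    }
    if (!length(dst[[ax]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  out
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1L, , drop = FALSE]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26")
  off
}

#' Connected-component labelling of a 3D logical array
#'
#' Label propagation with pointer jumping; components are numbered 1..n in
#' order of their smallest linear index. Foreground connectivity defaults to
#' 26-neighbourhood (use 6 for background/cavity analysis, the standard dual
#' pair).
#'
#' @param arr logical 3D array.
#' @param connectivity 26 (default) or 6.
#' @return Integer array of component ids, 0 for background.
#' @export
connected_components <- function(arr, connectivity = 26L) {
  d <- dim(arr)
  if (!any(arr)) return(array(0L, d))
  off <- neighbour_offsets(as.integer(connectivity))
  lab <- array(Inf, d)
  lab[arr] <- which(as.vector(arr))
  repeat {
    new <- lab
    for (r in seq_len(nrow(off)))
      new <- pmin(new, shift_array(lab, off[r, ], Inf))
    new[!arr] <- Inf
    # pointer jumping: follow representatives a few hops per sweep
    fg <- which(arr)
    for (hop in 1:3) {
      ln <- new[fg]
      new[fg] <- pmin(ln, new[ln])
    }
    if (identical(new[fg], lab[fg])) break
    lab <- new
  }
  out <- array(0L, d)
  fg <- which(arr)
  reps <- lab[fg]
  out[fg] <- match(reps, sort(unique(reps)))
  out
}

# spherical structuring-element offsets for radius r (voxels)
ball_offsets <- function(r) {
  r_i <- ceiling(r)
  off <- as.matrix(expand.grid(-r_i:r_i, -r_i:r_i, -r_i:r_i))
  off[rowSums(off^2) <= r^2, , drop = FALSE]
}

dilate_arr <- function(a, off) {
  out <- array(FALSE, dim(a))
  for (r in seq_len(nrow(off)))
    out <- out | shift_array(a, off[r, ], FALSE)
  out
}

erode_arr <- function(a, off) {
  out <- array(TRUE, dim(a))
  for (r in seq_len(nrow(off)))
    out <- out & shift_array(a, off[r, ], FALSE)
  out
}

#' Morphological cleanup of a mask
#'
#' Applies, in order: island removal (drop 26-connected foreground
#' components smaller than `min_island` voxels), cavity fill (fill
#' 6-connected background components not reaching the volume border), and
#' fill gaps (morphological closing with a spherical element of
#' `closing_radius` voxels; 0 skips the step). Because closing can enclose
#' new cavities, the sequence is iterated to a fixed point, which makes
#' the operation idempotent on its own output.
#'
#' @param m a [mask()].
#' @param min_island minimum component size kept, in voxels.
#' @param closing_radius closing radius in voxels.
#' @return The cleaned [mask()].
#' @export
morph_clean <- function(m, min_island = 1L, closing_radius = 0) {
  stopifnot(inherits(m, "mask"))
  out <- m
  for (pass in 1:5) {
    cleaned <- morph_clean_pass(out, min_island, closing_radius)
    if (identical(cleaned$data, out$data)) break
    out <- cleaned
  }
  out
}

morph_clean_pass <- function(m, min_island, closing_radius) {
  a <- m$data
  d <- dim(a)
  if (min_island > 1L && any(a)) {
    # crop to bounding box for the labelling pass
    w <- which(a, arr.ind = TRUE)
    lo <- pmax(apply(w, 2L, min) - 1L, 1L)
    hi <- pmin(apply(w, 2L, max) + 1L, d)
    sub <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    cc <- connected_components(sub, 26L)
    sz <- tabulate(cc[cc > 0L])
    keep <- which(sz >= min_island)
    sub <- array(cc %in% keep, dim(sub))
    a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  }
  if (any(a)) {
    bg <- connected_components(!a, 6L)
    border_ids <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                           bg[, , 1], bg[, , d[3]]))
    border_ids <- setdiff(border_ids, 0L)
    cavity <- bg > 0L & !(bg %in% border_ids)
    a[cavity] <- TRUE
  }
  if (closing_radius > 0 && any(a)) {
    off <- ball_offsets(closing_radius)
    a <- erode_arr(dilate_arr(a, off), off)
  }
  mask(a, part = m$part, spacing = m$spacing, origin = m$origin)
}

#' Combine masks into a label volume by priority
#'
#' Each voxel takes the label of the first mask in the list that contains
#' it (list order = priority, highest first); uncovered voxels are
#' background. Labels are numbered in list order and named after the masks'
#' part names.
#'
#' @param masks ordered list of congruent [mask()] objects, highest
#'   priority first.
#' @return A [label_volume()].
#' @export
resolve_priority <- function(masks) {
  stopifnot(length(masks) >= 1L)
  d <- dim(masks[[1]]$data)
  for (m in masks) {
    stopifnot(inherits(m, "mask"))
    if (!identical(dim(m$data), d)) stop("masks are not congruent")
  }
  lab <- array(0L, d)
  for (i in rev(seq_along(masks)))      # lowest priority first, overwritten
    lab[masks[[i]]$data] <- i
  nm <- vapply(masks, function(m) m$part, character(1))
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  label_volume(lab, stats::setNames(seq_along(masks), nm),
               spacing = masks[[1]]$spacing, origin = masks[[1]]$origin)
}

#' Gaussian surface smoothing of a mask
#'
#' Filters the binary field with a separable Gaussian of standard deviation
#' `sigma` voxels and re-thresholds at 0.5. `sigma = 0` is the identity.
#' Not recommended for thin, screw-bearing masks: structures around one
#' voxel thick erode or vanish.
#'
#' @param m a [mask()].
#' @param sigma Gaussian standard deviation in voxels (>= 0).
#' @return The smoothed [mask()].
#' @export
smooth_surface <- function(m, sigma) {
  stopifnot(inherits(m, "mask"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(m)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  f <- array(as.numeric(m$data), dim(m$data))
  for (ax in 1:3) {
    acc <- array(0, dim(f))
    for (i in seq_along(k)) {
      s <- c(0L, 0L, 0L)
      s[ax] <- i - r - 1L
      acc <- acc + k[i] * shift_array(f, s, 0)
    }
    f <- acc
  }
  mask(f > 0.5, part = m$part, spacing = m$spacing, origin = m$origin)
}

#' Dice overlap coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b congruent [mask()] objects.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "mask"), inherits(b, "mask"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("masks have different shapes")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) return(1.0)
  2 * sum(a$data & b$data) / (na + nb)
}
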