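test_that("two-point calibration maps the references exactly and is affine", {
  raw <- image_volume(array(c(1024, 224, 624, 500), c(4, 1, 1)) * 1.0,
                      spacing = 1)
  hu <- calibrate(raw, mean_water = 1024, mean_air = 224)
  expect_equal(hu$data[1, 1, 1], 0)
  expect_equal(hu$data[2, 1, 1], -1000)
  expect_equal(hu$data[3, 1, 1], -500)     # midpoint -> -500 HU
  expect_error(calibrate(raw, 5, 5), "degenerate")
  # affine invariance: transforming raw values and references together
  # leaves the calibrated volume unchanged
  a <- 2.5; b <- -37
  raw2 <- image_volume(a * raw$data + b, spacing = 1)
  hu2 <- calibrate(raw2, a * 1024 + b, a * 224 + b)
  expect_equal(hu2$data, hu$data, tolerance = 1e-12)
})

test_that("adaptive threshold splits a two-valued volume strictly between", {
  set.seed(1)
  v <- array(sample(c(100, 900), 4000, TRUE), c(20, 20, 10)) * 1.0
  vol <- image_volume(v, spacing = 1, units = "HU")
  m <- threshold_mask(vol, "adaptive", part = "hi")
  thr <- attr(m, "threshold")
  expect_gt(thr, 100)
  expect_lt(thr, 900)
  expect_identical(m$data, v > thr)
  # exhaustive-split oracle: the between-class variance optimum separates
  # the two values no matter where the cut lands between them
  cuts <- seq(101, 899, by = 1)
  oracle_best <- cuts[which.max(vapply(cuts, function(ct) {
    lo <- v[v <= ct]; hi <- v[v > ct]
    length(lo) * length(hi) / length(v)^2 * (mean(hi) - mean(lo))^2
  }, numeric(1)))]
  expect_identical(v > thr, v > oracle_best)
})

test_that("fixed-range threshold warns on empty masks", {
  vol <- image_volume(array(5, c(4, 4, 4)), spacing = 1, units = "HU")
  expect_warning(m <- threshold_mask(vol, "fixed", lo = 100, hi = 200),
                 "empty")
  expect_equal(sum(m$data), 0)
})

test_that("morph_clean removes islands, fills cavities, is idempotent", {
  a <- array(FALSE, c(16, 16, 16))
  idx <- as.matrix(expand.grid(1:16, 1:16, 1:16))
  ball <- (idx[, 1] - 8)^2 + (idx[, 2] - 8)^2 + (idx[, 3] - 8)^2 <= 25
  a[idx[ball, ]] <- TRUE
  a[2, 2, 2] <- TRUE                      # 1-voxel speck
  m <- mask(a, spacing = c(1, 1, 1))
  out <- morph_clean(m, min_island = 5)
  expect_false(out$data[2, 2, 2])
  expect_true(all(out$data[idx[ball, ]]))
  # hollow ball: enclosed cavity is filled
  h <- a
  core <- (idx[, 1] - 8)^2 + (idx[, 2] - 8)^2 + (idx[, 3] - 8)^2 <= 4
  h[idx[core, ]] <- FALSE
  h[2, 2, 2] <- FALSE
  hm <- morph_clean(mask(h, spacing = c(1, 1, 1)), min_island = 1)
  expect_true(all(hm$data[idx[core, ]]))
  # idempotence on its own output (including a closing step)
  set.seed(42)
  r <- array(stats::runif(27 * 64) > 0.6, c(12, 12, 12))
  once <- morph_clean(mask(r, spacing = c(1, 1, 1)), min_island = 4,
                      closing_radius = 1)
  twice <- morph_clean(once, min_island = 4, closing_radius = 1)
  expect_identical(once$data, twice$data)
})

test_that("island removal keeps components at least min_island large", {
  set.seed(7)
  r <- array(stats::runif(1000) > 0.5, c(10, 10, 10))
  big_before <- max(tabulate(connected_components(r, 26)))
  out <- morph_clean(mask(r, spacing = c(1, 1, 1)), min_island = 5)
  cc <- connected_components(out$data, 26)
  if (max(cc) > 0) expect_true(all(tabulate(cc[cc > 0]) >= 5))
  expect_gte(max(c(0, tabulate(cc[cc > 0]))), big_before * (big_before >= 5))
})

test_that("priority resolution matches a per-voxel first-hit oracle", {
  set.seed(5)
  d <- c(8, 8, 8)
  masks <- lapply(1:4, function(i)
    mask(array(stats::runif(prod(d)) > 0.6, d), part = paste0("p", i),
         spacing = c(1, 1, 1)))
  lv <- resolve_priority(masks)
  oracle <- array(0L, d)
  for (i in rev(seq_along(masks))) oracle[masks[[i]]$data] <- i
  expect_identical(lv$labels, oracle)
  # disjoint masks: order irrelevant
  dis <- list(mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)), "a",
                   spacing = c(1, 1, 1)),
              mask(array(c(FALSE, TRUE, rep(FALSE, 6)), c(2, 2, 2)), "b",
                   spacing = c(1, 1, 1)))
  l1 <- resolve_priority(dis)
  l2 <- resolve_priority(rev(dis))
  expect_equal(sum(l1$labels > 0), sum(l2$labels > 0))
  # fully overlapping pair: higher priority wins everywhere
  full <- array(TRUE, c(2, 2, 2))
  lo <- resolve_priority(list(mask(full, "first", spacing = c(1, 1, 1)),
                              mask(full, "second", spacing = c(1, 1, 1))))
  expect_true(all(lo$labels == 1L))
})

test_that("gaussian mask smoothing is identity at sigma 0 and erodes rods", {
  slab <- array(FALSE, c(20, 20, 9))
  slab[3:18, 3:18, 3:7] <- TRUE
  m <- mask(slab, spacing = c(1, 1, 1))
  expect_identical(smooth_surface(m, 0)$data, slab)
  sm <- smooth_surface(m, 1.5)
  # interior of a large flat slab is untouched; only boundary voxels flip
  expect_true(all(sm$data[6:15, 6:15, 5]))
  interior_only <- slab & !sm$data
  w <- which(interior_only, arr.ind = TRUE)
  if (nrow(w))
    expect_true(all(w[, 1] %in% c(3, 18) | w[, 2] %in% c(3, 18) |
                      w[, 3] %in% c(3, 7)))
  # a 1-voxel rod vanishes under sigma = 1.5 (why screws skip smoothing)
  rod <- array(FALSE, c(20, 5, 5))
  rod[2:19, 3, 3] <- TRUE
  rs <- smooth_surface(mask(rod, spacing = c(1, 1, 1)), 1.5)
  expect_equal(sum(rs$data), 0)
})

test_that("dice coefficient matches direct counting", {
  a <- mask(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)),
            spacing = c(1, 1, 1))
  expect_equal(dice(a, a), 1)
  b <- mask(array(c(rep(FALSE, 4), rep(TRUE, 4)), c(2, 2, 2)),
            spacing = c(1, 1, 1))
  expect_equal(dice(a, b), 0)
  half <- mask(array(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
                     c(2, 2, 2)), spacing = c(1, 1, 1))
  # |a| = 4, |half| = 4, overlap = 2 -> dice 0.5
  expect_equal(dice(a, half), 0.5)
  empty <- mask(array(FALSE, c(2, 2, 2)), spacing = c(1, 1, 1))
  expect_equal(dice(empty, empty), 1.0)
  expect_error(dice(a, mask(array(TRUE, c(3, 3, 3)), spacing = c(1, 1, 1))),
               "shape")
})

test_that("segmentation chain reproduces truth labels on the phantom", {
  ph <- build_phantom(small_phantom_config(noise_sd = 0))
  hu <- calibrate(ph$volume, ph$truth$mean_water_raw, ph$truth$mean_air_raw)
  seg <- tmjfem:::segment_phantom(hu, ph$truth)
  for (p in names(ph$truth$labels$part_names))
    expect_equal(dice(label_mask(seg, p), label_mask(ph$truth$labels, p)),
                 1.0)
})
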