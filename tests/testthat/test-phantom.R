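test_that("default phantom has 0.3 mm isotropic voxels and all parts", {
  cfg <- phantom_config()
  expect_equal(cfg$spacing, rep(0.3, 3))
  ph <- build_phantom(small_phantom_config(noise_sd = 0))
  expect_equal(ph$volume$spacing, rep(0.3, 3))
  counts <- table(ph$truth$labels$labels)
  for (p in c("mandible", "prosthesis", "screws", "tooth_33", "tooth_41",
              "tooth_43", "tooth_47"))
    expect_gt(sum(ph$truth$labels$labels ==
                    ph$truth$labels$part_names[[p]]), 0)
})

test_that("noise-free phantom voxels carry exactly their nominal HU", {
  ph <- build_phantom(small_phantom_config(noise_sd = 0))
  hu <- calibrate(ph$volume, ph$truth$mean_water_raw, ph$truth$mean_air_raw)
  expect_equal(hu$data, ph$truth$nominal_hu$data, tolerance = 1e-12)
})

test_that("phantom generation is deterministic in the seed", {
  a <- build_phantom(small_phantom_config(seed = 3L))
  b <- build_phantom(small_phantom_config(seed = 3L))
  c_ <- build_phantom(small_phantom_config(seed = 4L))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$labels$labels, b$truth$labels$labels)
  expect_false(identical(a$volume$data, c_$volume$data))
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(phantom_config(spacing = 0), "positive")
  expect_error(phantom_config(hu = c(air = 0, soft_tissue = -10,
                                     trabecular = 300, cortical = 1200,
                                     dentin = 1700, enamel = 2400,
                                     titanium = 3000)), "ordered")
  # a pose that drops the prosthesis onto the teeth must be rejected
  bad_pose <- rigid_transform(t = c(-8, -8, -2) * 0.5)
  expect_error(build_phantom(small_phantom_config() |>
                               (\(cfg) { cfg$pose <- bad_pose; cfg })()),
               "overlap")
})

test_that("prosthesis CAD surface matches the rasterized prosthesis voxels", {
  cfg <- small_phantom_config(noise_sd = 0)
  ph <- build_phantom(cfg)
  s <- ph$truth$cad_surface
  # every prosthesis voxel centre lies inside (on) the CAD boxes, and the
  # voxelization of the same boxes reproduces the prosthesis label exactly
  met <- tmjfem:::phantom_metal_arrays(cfg)
  pros <- ph$truth$labels$labels == ph$truth$labels$part_names[["prosthesis"]]
  expect_identical(pros, met$prosthesis)
  # CAD volume equals the analytic union of plate and head boxes
  g <- tmjfem:::phantom_geometry(cfg)
  v_plate <- prod(g$plate_box["hi", ] - g$plate_box["lo", ])
  v_head <- prod(g$head_box["hi", ] - g$head_box["lo", ])
  v_overlap <- prod(pmax(pmin(g$plate_box["hi", ], g$head_box["hi", ]) -
                           pmax(g$plate_box["lo", ], g$head_box["lo", ]), 0))
  # the triangle-soup union double-counts the overlap region
  expect_equal(enclosed_volume(s), v_plate + v_head, tolerance = 1e-12)
  expect_true(v_overlap > 0)
})

test_that("wear series generator honours its model and determinism", {
  s <- simulate_wear_series(true_rate = 3e-7, intercept = 0.05,
                            soak_drift = 0, n_points = 10, noise_sd = 0)
  expect_equal(s$specimen_loss, 3e-7 * s$n + 0.05, tolerance = 1e-14)
  expect_equal(s$soak_gain, rep(0, 10))
  z <- simulate_wear_series(true_rate = 0, intercept = 0, soak_drift = 0,
                            noise_sd = 0)
  expect_true(all(z$specimen_loss == 0) && all(z$soak_gain == 0))
  a <- simulate_wear_series(noise_sd = 0.01, seed = 11)
  b <- simulate_wear_series(noise_sd = 0.01, seed = 11)
  expect_identical(a, b)
  expect_error(simulate_wear_series(n_points = 1), "regression")
  # drift cancels in the soak-corrected net loss
  d <- simulate_wear_series(true_rate = 3e-7, intercept = 0.02,
                            soak_drift = 1e-7, noise_sd = 0)
  expect_equal(net_mass_loss(d), 3e-7 * d$n + 0.02, tolerance = 1e-12)
})

test_that("volume slice IO round-trips within quantization error", {
  ph <- build_phantom(phantom_config(shape = c(24L, 20L, 16L),
                                     noise_sd = 10))
  dir <- withr::local_tempdir()
  write_volume(ph$volume, dir)
  back <- read_volume(dir)
  rng <- diff(range(ph$volume$data))
  expect_lt(max(abs(back$data - ph$volume$data)), rng / 60000)
  expect_equal(back$spacing, ph$volume$spacing)
})
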