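tb <- material_table()

test_that("HU to density mapping hits the printed interval endpoints", {
  expect_identical(hu_to_density(c(-1000, 500, 501, 1500), tb),
                   c(0, 1000, 1001, 2000))
  expect_equal(hu_to_density(-250, tb), 500)   # linear interpolation
  # clamping outside the table's intervals
  expect_equal(hu_to_density(c(-2000, 3000), tb), c(0, 2000))
  # monotone nondecreasing across the whole range
  hu <- seq(-1200, 1700, by = 7)
  expect_true(all(diff(hu_to_density(hu, tb)) >= 0))
})

test_that("bone power laws match an arbitrary-precision oracle", {
  # oracle values computed to 50 digits with an independent tool
  oracle <- c(`500` = 106.41177807473735, `999` = 427.74665563044929,
              `1000` = 5357.5965261880321, `1500` = 12103.568573139925,
              `2000` = 21579.446228038543)
  rho <- as.numeric(names(oracle))
  expect_equal(density_to_E(rho, tb), unname(oracle), tolerance = 1e-12)
  # rho = 0 returns the configured floor, keeping stiffness positive
  expect_equal(density_to_E(0, tb), tb$E_floor)
  expect_error(density_to_E(-1, tb), ">= 0")
  # monotone within each regime
  expect_true(all(diff(density_to_E(seq(1, 999, 2), tb)) >= 0))
  expect_true(all(diff(density_to_E(seq(1000, 2000, 2), tb)) >= 0))
})

test_that("dentin/enamel split follows the 2000 HU rule inclusively", {
  cl <- classify_tooth_tissue(c(1500, 2000, 2500), tb)
  expect_identical(cl$tissue, c("dentin", "dentin", "enamel"))
  expect_equal(cl$E, c(24535, 24535, 39605))
  expect_equal(cl$nu, rep(0.3, 3))
})

test_that("element material assignment maps, classifies and is pure", {
  lab <- label_volume(array(1L, c(6, 4, 4)), c(bone = 1L),
                      spacing = c(1, 1, 1))
  mesh <- mesh_from_labels(lab)
  # uniform HU: every mapped element shares a single modulus
  vol_u <- image_volume(array(300, c(6, 4, 4)), spacing = 1, units = "HU")
  mu <- assign_element_materials(mesh, vol_u, tb, modes = c(bone = "mapped"))
  expect_equal(length(unique(mu$E)), 1L)
  expect_equal(mu$E[1],
               density_to_E(hu_to_density(300, tb), tb), tolerance = 1e-12)
  expect_true(all(mu$provenance == "mapped"))
  # purity: identical call, identical output
  expect_identical(mu, assign_element_materials(mesh, vol_u, tb,
                                                modes = c(bone = "mapped")))
  # titanium constants are exact
  mt <- assign_element_materials(mesh, NULL, tb,
                                 modes = c(bone = "titanium"))
  expect_true(all(mt$E == 113800) && all(mt$nu == 0.342))
  # linear HU ramp along x: element modulus is monotone in centroid x
  ramp <- image_volume(array(rep(seq(-500, 500, length.out = 6),
                                 times = 16), c(6, 4, 4)),
                       spacing = 1, units = "HU")
  mr <- assign_element_materials(mesh, ramp, tb, modes = c(bone = "mapped"))
  e <- mesh$elements[, 1:4]
  cx <- (mesh$nodes[e[, 1], 1] + mesh$nodes[e[, 2], 1] +
           mesh$nodes[e[, 3], 1] + mesh$nodes[e[, 4], 1]) / 4
  ord <- order(cx)
  expect_true(all(diff(mr$E[ord]) >= -1e-9))
  # per-element quadrature sampling oracle for a handful of elements
  qp <- tmjfem:::tet_quadrature()$points
  for (k in c(1L, 10L, 20L)) {
    pts <- qp %*% mesh$nodes[mesh$elements[k, 1:4], ]
    hu_k <- mean(sample_trilinear(ramp, pts))
    expect_equal(mr$E[k], density_to_E(hu_to_density(hu_k, tb), tb),
                 tolerance = 1e-12)
  }
  # nodes outside the volume's world box are rejected
  small <- image_volume(array(0, c(3, 3, 3)), spacing = 1, units = "HU")
  expect_error(assign_element_materials(mesh, small, tb,
                                        modes = c(bone = "mapped")),
               "world box")
})

test_that("trilinear sampling reproduces a trilinear field exactly", {
  f <- function(p) 2 + 0.5 * p[, 1] - 1.5 * p[, 2] + 3 * p[, 3] +
    0.25 * p[, 1] * p[, 2]
  cc <- tmjfem:::voxel_centres(c(8, 8, 8), c(1, 1, 1), c(0, 0, 0))
  grid <- as.matrix(expand.grid(cc$x, cc$y, cc$z))
  vol <- image_volume(array(f(grid), c(8, 8, 8)), spacing = 1)
  set.seed(2)
  pts <- cbind(stats::runif(50, 1, 7), stats::runif(50, 1, 7),
               stats::runif(50, 1, 7))
  expect_equal(sample_trilinear(vol, pts), f(pts), tolerance = 1e-12)
})
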