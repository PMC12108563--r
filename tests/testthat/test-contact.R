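contact_fixture <- function() {
  mesh <- stacked_blocks(4)
  mesh <- split_interface(mesh, slave = "top", master = "bottom")
  mesh <- define_node_sets(mesh, list(
    base = list(type = "box", lo = c(-1, -1, -1), hi = c(5, 5, 1e-9))))
  topf <- free_boundary_facets(mesh, part = "top", within = list(
    type = "box", lo = c(-1, -1, 4 - 1e-9), hi = c(5, 5, 5)))
  list(mesh = mesh, topf = topf,
       mat = uniform_material(mesh, 1000, 0))
}

test_that("separated bodies with no closing load carry zero contact force", {
  arr <- array(0L, c(4, 4, 5))
  arr[, , 1:2] <- 1L; arr[, , 4:5] <- 2L     # one-voxel air gap
  lab <- label_volume(arr, c(bottom = 1L, top = 2L), spacing = c(1, 1, 1))
  mesh <- mesh_from_labels(lab)
  expect_warning(split_interface(mesh, "top", "bottom"), "interface")
})

test_that("frictionless flat-on-flat contact transmits uniform pressure", {
  fx <- contact_fixture()
  lc <- load_case(
    dirichlet = list(list(set = "base", components = 1:3, value = 0)),
    surface_loads = list(list(set = fx$topf, force = c(0, 0, -16))),
    contact = list(mode = "frictional", mu = 0))
  sol <- solve_contact(fx$mesh, fx$mat, lc)
  expect_true(sol$diagnostics$converged)
  expect_equal(as.vector(sol$stress[, , 3]),
               rep(-1, 4 * nrow(fx$mesh$elements)), tolerance = 1e-6)
  # penetration bounded by the gap tolerance (1e-3 of the mean edge)
  expect_lt(sol$diagnostics$penetration, 1e-3)
  # equilibrium with contact
  expect_lt(max(abs(reaction_sums(sol) + sol$applied)),
            1e-8 * sqrt(sum(sol$applied^2)))
})

test_that("tangential load below the Coulomb limit does not slide", {
  fx <- contact_fixture()
  lc <- load_case(
    dirichlet = list(list(set = "base", components = 1:3, value = 0)),
    surface_loads = list(list(set = fx$topf, force = c(1, 0, -16))),
    contact = list(mode = "frictional", mu = 0.3))
  sol <- solve_contact(fx$mesh, fx$mat, lc)
  expect_true(sol$diagnostics$converged)
  # every pair sticks: no Coulomb slip anywhere
  expect_equal(sol$diagnostics$slip_pairs, 0)
  cp <- fx$mesh$contact_pairs
  du <- sol$u[cp$slave, ] - sol$u[cp$master, ]
  slip <- sqrt(du[, 1]^2 + du[, 2]^2)
  # tangential jumps stay at the penalty-compliance level, the same order
  # as the (regularization-controlled) normal penetration
  expect_lt(max(slip), 10 * (sol$diagnostics$penetration + 1e-12))
})

test_that("bodies moving apart separate cleanly with zero contact force", {
  fx <- contact_fixture()
  mesh <- define_node_sets(fx$mesh, list(
    lid = list(type = "box", lo = c(-1, -1, 4 - 1e-9), hi = c(5, 5, 5))))
  lc <- load_case(
    dirichlet = list(list(set = "base", components = 1:3, value = 0),
                     list(set = "lid", components = 1:3,
                          value = c(0, 0, 0.1))),   # lift the top block
    contact = list(mode = "frictional", mu = 0.3))
  sol <- solve_contact(mesh, fx$mat, lc)
  expect_true(sol$diagnostics$converged)
  expect_equal(sol$diagnostics$active_pairs, 0)
  # both blocks end up stress-free: the top translates rigidly, the
  # bottom sees no load at all (independent solves)
  expect_lt(max(abs(sol$stress)), 1e-6)
})

test_that("bonded pairs reproduce the merged-mesh solution", {
  fx <- contact_fixture()
  lc <- load_case(
    dirichlet = list(list(set = "base", components = 1:3, value = 0)),
    surface_loads = list(list(set = fx$topf, force = c(0, 0, -16))),
    contact = list(mode = "bonded"))
  sol <- solve_contact(fx$mesh, fx$mat, lc)
  # merged-mesh oracle: the unsplit conforming mesh under the same load
  merged <- stacked_blocks(4)
  merged <- define_node_sets(merged, list(
    base = list(type = "box", lo = c(-1, -1, -1), hi = c(5, 5, 1e-9))))
  topf_m <- free_boundary_facets(merged, part = "top", within = list(
    type = "box", lo = c(-1, -1, 4 - 1e-9), hi = c(5, 5, 5)))
  lc_m <- load_case(
    dirichlet = list(list(set = "base", components = 1:3, value = 0)),
    surface_loads = list(list(set = topf_m, force = c(0, 0, -16))))
  sol_m <- solve_linear(merged, uniform_material(merged, 1000, 0), lc_m)
  expect_equal(as.vector(sol$stress[, , 3]), as.vector(sol_m$stress[, , 3]),
               tolerance = 1e-8)
})
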