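ref_tet10 <- function() {
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ed <- tmjfem:::c3d10_edges()
  rbind(corners, (corners[ed[, 1], ] + corners[ed[, 2], ]) / 2)
}

test_that("element stiffness is symmetric with exactly 6 rigid-body modes", {
  K <- element_stiffness(ref_tet10(), E = 1000, nu = 0.3)
  expect_lt(max(abs(K - t(K))), 1e-9 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6)
  expect_true(all(ev[ev > 1e-9 * max(ev)] > 0))
  # rigid translation produces zero internal force
  u <- rep(c(0.3, -0.1, 0.7), 10)
  expect_lt(max(abs(K %*% u)), 1e-9 * max(abs(K)))
  # inverted element (swapped corners) is rejected
  bad <- ref_tet10()[c(2, 1, 3, 4, 5, 7, 6, 9, 8, 10), ]
  expect_error(element_stiffness(bad, 1000, 0.3), "inverted")
})

test_that("load distribution conserves totals and respects areas", {
  mesh <- bar_mesh(4, 2, 1)
  mesh$node_sets$ten <- 1:10
  f <- distribute_load(mesh, "ten", c(0, 0, -450), type = "node")
  fm <- matrix(f, ncol = 3, byrow = TRUE)
  expect_equal(fm[1:10, 3], rep(-45, 10))
  expect_equal(colSums(fm), c(0, 0, -450), tolerance = 1e-12)
  # facet force shares proportional to facet areas (1/3 and 2/3 for A, 2A)
  tri <- rbind(c(1, 2, 4), c(2, 3, 4))
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0), c(0, 1, 0))
  m2 <- tet_mesh(rbind(nodes, ref_tet10() + 10), cbind(matrix(5:14, 1)),
                 1L, c(p = 1L))
  m2$nodes[1:4, ] <- nodes
  f2 <- distribute_load(m2, tri, c(0, 0, 9), type = "surface")
  fm2 <- matrix(f2, ncol = 3, byrow = TRUE)
  # areas 0.5 and 1.0 -> facet shares 3 N and 6 N, spread per corner:
  # node 1 gets 1, node 3 gets 2, shared nodes 2 and 4 get 1 + 2
  expect_equal(fm2[1:4, 3], c(1, 3, 2, 3), tolerance = 1e-12)
  expect_equal(colSums(fm2), c(0, 0, 9), tolerance = 1e-12)
  expect_error(distribute_load(mesh, integer(0), c(1, 0, 0)), "empty")
})

test_that("uniaxial bars match closed-form displacement and stress", {
  L <- 8; A <- 4; F <- 40; E1 <- 100
  mesh <- bar_mesh(8, 2, 1)
  mesh <- define_node_sets(mesh, list(
    fix = list(type = "box", lo = c(-1, -1, -1), hi = c(1e-9, 3, 3))))
  tip <- bar_tip_facets(mesh, L)
  lc <- load_case(
    dirichlet = list(list(set = "fix", components = 1:3, value = 0)),
    surface_loads = list(list(set = tip, force = c(F, 0, 0))))
  sol <- solve_linear(mesh, uniform_material(mesh, E1, 0), lc)
  tipn <- which(abs(mesh$nodes[, 1] - L) < 1e-9)
  expect_equal(sol$u[tipn, 1], rep(F * L / (E1 * A), length(tipn)),
               tolerance = 1e-6)
  expect_equal(as.vector(sol$stress[, , 1]),
               rep(F / A, 4 * nrow(mesh$elements)), tolerance = 1e-6)
  # two segments in series: compliances add, interface stress uniform
  E2 <- 50
  cx <- (mesh$nodes[mesh$elements[, 1], 1] +
           mesh$nodes[mesh$elements[, 2], 1] +
           mesh$nodes[mesh$elements[, 3], 1] +
           mesh$nodes[mesh$elements[, 4], 1]) / 4
  mats <- structure(data.frame(E = ifelse(cx < 4, E1, E2), nu = 0,
                               provenance = "homogeneous"),
                    class = c("element_material_field", "data.frame"))
  sol2 <- solve_linear(mesh, mats, lc)
  d_exp <- F * (4 / (E1 * A) + 4 / (E2 * A))
  expect_equal(sol2$u[tipn, 1], rep(d_exp, length(tipn)), tolerance = 1e-6)
  expect_equal(as.vector(sol2$stress[, , 1]),
               rep(F / A, 4 * nrow(mesh$elements)), tolerance = 1e-6)
  # zero load gives zero displacement
  lc0 <- load_case(dirichlet = lc$dirichlet)
  sol0 <- solve_linear(mesh, uniform_material(mesh, E1, 0), lc0)
  expect_equal(max(abs(sol0$u)), 0, tolerance = 1e-15)
})

test_that("under-constrained systems are rejected", {
  mesh <- bar_mesh(2, 1, 1)
  mesh$node_sets$one <- 1L
  lc <- load_case(dirichlet = list(list(set = "one", components = 1,
                                        value = 0)),
                  loads = list(list(set = "one", force = c(1, 0, 0))))
  expect_error(solve_linear(mesh, uniform_material(mesh, 100, 0.3), lc),
               "constraints|singular")
})

test_that("bonded MPCs merge conforming parts and tie non-conforming ones", {
  # conforming interface: zero constraint equations
  mesh <- stacked_blocks(2)
  ties <- apply_bonded_mpc(mesh, "top", "bottom")
  expect_length(ties, 0)
  # non-conforming two-block column: coarse bottom, fine top, uniform
  # compression reproduces the merged-column stress exactly
  labB <- label_volume(array(1L, c(2, 2, 2)), c(bot = 1L),
                       spacing = c(1, 1, 1))
  mB <- mesh_from_labels(labB)
  labT <- label_volume(array(1L, c(4, 4, 2)), c(top = 1L),
                       spacing = c(0.5, 0.5, 0.5))
  mT <- mesh_from_labels(labT)
  mT$nodes[, 3] <- mT$nodes[, 3] + 2
  glue <- tet_mesh(rbind(mB$nodes, mT$nodes),
                   rbind(mB$elements, mT$elements + nrow(mB$nodes)),
                   c(mB$part_id, mT$part_id + 1L),
                   c(bot = 1L, top = 2L), spacing = c(1, 1, 1))
  ties <- apply_bonded_mpc(glue, slave = "top", master = "bot",
                           capture = 1e-6)
  expect_gt(length(ties), 0)
  glue <- define_node_sets(glue, list(
    base = list(type = "box", lo = c(-1, -1, -1), hi = c(3, 3, 1e-9))))
  topf <- free_boundary_facets(glue, part = "top", within = list(
    type = "box", lo = c(-1, -1, 3 - 1e-9), hi = c(3, 3, 4)))
  lc <- load_case(
    dirichlet = list(list(set = "base", components = 1:3, value = 0)),
    surface_loads = list(list(set = topf, force = c(0, 0, -4))),
    ties = ties)
  sol <- solve_linear(glue, uniform_material(glue, 1000, 0), lc)
  expect_equal(as.vector(sol$stress[, , 3]),
               rep(-1, 4 * nrow(glue$elements)), tolerance = 1e-8)
  # rigid translation of the tied assembly: zero constraint violation
  trans <- function(X) cbind(X[, 1] * 0 + 0.3, X[, 2] * 0 - 0.2,
                             X[, 3] * 0 + 0.1)
  bnd <- unique(as.vector(free_boundary_facets(glue)$nodes6))
  # tied slave nodes follow their masters; they cannot carry Dirichlet data
  bnd <- setdiff(bnd, vapply(ties, function(t_) t_$slave, integer(1)))
  glue$node_sets$bnd <- bnd
  lcr <- load_case(dirichlet = list(list(set = "bnd", components = 1:3,
                                         value = trans)), ties = ties)
  solr <- solve_linear(glue, uniform_material(glue, 1000, 0), lcr)
  expect_lt(max(abs(sweep(solr$u, 2, c(0.3, -0.2, 0.1)))), 1e-10)
})

test_that("solutions are frame-objective under rigid rotation", {
  mesh <- bar_mesh(4, 2, 1)
  mesh <- define_node_sets(mesh, list(
    fix = list(type = "box", lo = c(-1, -1, -1), hi = c(1e-9, 3, 3))))
  tip <- bar_tip_facets(mesh, 4)
  F <- c(5, 0, -3)
  lc <- load_case(
    dirichlet = list(list(set = "fix", components = 1:3, value = 0)),
    surface_loads = list(list(set = tip, force = F)))
  mat <- uniform_material(mesh, 500, 0.3)
  sol <- solve_linear(mesh, mat, lc)
  R <- axis_rotation(2, 0.61)$R %*% axis_rotation(1, -0.33)$R
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes %*% t(R)
  lc2 <- load_case(
    dirichlet = list(list(set = "fix", components = 1:3, value = 0)),
    surface_loads = list(list(set = tip, force = as.vector(R %*% F))))
  sol2 <- solve_linear(mesh2, mat, lc2)
  expect_lt(max(abs(sol2$u - sol$u %*% t(R))),
            1e-8 * max(abs(sol$u)))
})

test_that("reactions balance applied loads on every solve", {
  mesh <- bar_mesh(4, 2, 1)
  mesh <- define_node_sets(mesh, list(
    fix = list(type = "box", lo = c(-1, -1, -1), hi = c(1e-9, 3, 3)),
    tipn = list(type = "box", lo = c(4 - 1e-9, -1, -1), hi = c(5, 3, 3))))
  lc <- load_case(
    dirichlet = list(list(set = "fix", components = 1:3, value = 0)),
    loads = list(list(set = "tipn", force = c(12, -7, 31))))
  sol <- solve_linear(mesh, uniform_material(mesh, 800, 0.25), lc)
  expect_lt(max(abs(reaction_sums(sol) + sol$applied)),
            1e-8 * sqrt(sum(sol$applied^2)))
})
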