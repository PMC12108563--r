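test_that("a single voxel splits into 6 positive tets with 27 unique nodes", {
  lab <- label_volume(array(1L, c(1, 1, 1)), c(p = 1L), spacing = c(1, 1, 1))
  mesh <- mesh_from_labels(lab)
  expect_equal(nrow(mesh$elements), 6)
  expect_equal(nrow(mesh$nodes), 27)      # 8 corners + 19 unique edge mids
  expect_true(all(element_volumes(mesh) > 0))
  expect_equal(sum(element_volumes(mesh)), 1, tolerance = 1e-14)
  # mid nodes sit exactly at edge midpoints (straight edges)
  ed <- tmjfem:::c3d10_edges()
  for (e in 1:6) {
    mid <- mesh$nodes[mesh$elements[, 4 + e], , drop = FALSE]
    a <- mesh$nodes[mesh$elements[, ed[e, 1]], , drop = FALSE]
    b <- mesh$nodes[mesh$elements[, ed[e, 2]], , drop = FALSE]
    expect_equal(mid, (a + b) / 2, tolerance = 1e-15)
  }
})

test_that("mesh volume equals the voxel volume exactly and interfaces conform", {
  set.seed(9)
  arr <- array(0L, c(5, 4, 3))
  arr[stats::runif(60) > 0.4] <- 1L
  arr[1, 1, 1] <- 2L; arr[2, 1, 1] <- 1L   # adjacent different labels
  lab <- label_volume(arr, c(a = 1L, b = 2L), spacing = c(0.5, 0.5, 0.5))
  mesh <- mesh_from_labels(lab)
  expect_equal(sum(element_volumes(mesh)), sum(arr > 0) * 0.125,
               tolerance = 1e-12)
  # conforming interface: nodes on the shared face appear exactly once
  # (coordinate-duplication oracle)
  key <- paste(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3])
  expect_false(anyDuplicated(key) > 0)
  # no orphan nodes
  expect_setequal(seq_len(nrow(mesh$nodes)), unique(as.vector(mesh$elements)))
  expect_error(mesh_from_labels(label_volume(array(0L, c(2, 2, 2)),
                                             c(a = 1L),
                                             spacing = c(1, 1, 1))), "empty")
})

test_that("node sets follow their geometric predicates", {
  mesh <- bar_mesh(4, 2, 1)
  mesh <- suppressWarnings(define_node_sets(mesh, list(
    ball = list(type = "sphere", centre = c(0, 0, 0), radius = 1.1),
    off = list(type = "box", lo = c(50, 50, 50), hi = c(60, 60, 60)),
    left = list(type = "box", lo = c(-1, -1, -1), hi = c(1.01, 3, 3)),
    right = list(type = "box", lo = c(2.99, -1, -1), hi = c(5, 3, 3)))))
  expect_true(all(sqrt(rowSums(mesh$nodes[mesh$node_sets$ball, ]^2)) <= 1.1))
  expect_length(mesh$node_sets$off, 0)
  expect_warning(define_node_sets(mesh, list(
    off2 = list(type = "box", lo = c(50, 50, 50), hi = c(60, 60, 60)))),
    "empty")
  # union of disjoint predicates: sizes add
  mesh <- define_node_sets(mesh, list(both = list(
    list(type = "box", lo = c(-1, -1, -1), hi = c(1.01, 3, 3)),
    list(type = "box", lo = c(2.99, -1, -1), hi = c(5, 3, 3)))))
  expect_length(mesh$node_sets$both,
                length(mesh$node_sets$left) + length(mesh$node_sets$right))
})

test_that("downsampling preserves protected thin labels", {
  arr <- array(0L, c(12, 12, 12))
  arr[, , 1:6] <- 1L                       # bulk part
  arr[6:7, 6:7, 7:12] <- 2L                # thin pillar, 2x2 voxels
  lab <- label_volume(arr, c(bulk = 1L, pillar = 2L), spacing = c(1, 1, 1))
  plain <- downsample_labels(lab, 4L)
  kept <- downsample_labels(lab, 4L, preserve = "pillar")
  expect_equal(sum(plain$labels == 2L), 0)     # majority vote erases it
  expect_gt(sum(kept$labels == 2L), 0)         # preservation keeps it
  expect_identical(downsample_labels(lab, 1L), lab)
})

test_that("boundary facets and interface splitting are consistent", {
  mesh <- stacked_blocks(4)
  # free boundary of the whole cube: 6 faces x 16 quads x 2 triangles
  fb <- free_boundary_facets(mesh)
  expect_equal(nrow(fb$corners), 6 * 16 * 2)
  # interface facets between the parts: 16 quads x 2 triangles each side
  tri <- part_boundary_faces(mesh, "top", against = "bottom")
  expect_equal(nrow(tri), 32)
  n0 <- nrow(mesh$nodes)
  sp <- split_interface(mesh, slave = "top", master = "bottom")
  cp <- sp$contact_pairs
  expect_gt(length(cp$slave), 0)
  # duplicated pairs are coincident and normals are unit +z (flat interface)
  expect_equal(sp$nodes[cp$slave, ], sp$nodes[cp$master, ],
               tolerance = 1e-15)
  expect_equal(sqrt(rowSums(cp$normal^2)), rep(1, length(cp$slave)),
               tolerance = 1e-12)
  expect_equal(abs(cp$normal[, 3]), rep(1, length(cp$slave)),
               tolerance = 1e-12)
  # consistent tributary areas cover the interface exactly once
  expect_equal(sum(cp$weight), 16, tolerance = 1e-12)
})
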