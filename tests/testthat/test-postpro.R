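test_that("von Mises invariant matches its defining cases", {
  expect_equal(von_mises(c(50, 0, 0, 0, 0, 0)), 50)
  expect_equal(von_mises(c(-50, 0, 0, 0, 0, 0)), 50)   # magnitude
  expect_equal(von_mises(c(7, 7, 7, 0, 0, 0)), 0)      # hydrostatic
  # pure shear tau: principal stresses (tau, -tau, 0) -> sqrt(3) tau
  tau <- 3.7
  sig <- matrix(c(0, tau, 0, tau, 0, 0, 0, 0, 0), 3, 3)
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  oracle <- sqrt(0.5 * ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                          (ev[3] - ev[1])^2))
  expect_equal(von_mises(sig), sqrt(3) * tau, tolerance = 1e-12)
  expect_equal(von_mises(sig), oracle, tolerance = 1e-12)
  expect_error(von_mises(matrix(c(0, 1, 0, 2, 0, 0, 0, 0, 0), 3, 3)),
               "symmetric")
})

test_that("von Mises is rotation and hydrostatic-shift invariant", {
  set.seed(10)
  worst <- 0
  for (k in 1:1000) {
    s6 <- stats::rnorm(6, sd = 40)
    S <- matrix(c(s6[1], s6[4], s6[6],
                  s6[4], s6[2], s6[5],
                  s6[6], s6[5], s6[3]), 3, 3)
    v0 <- von_mises(S)
    th <- stats::runif(3, 0, 2 * pi)
    R <- axis_rotation(1, th[1])$R %*% axis_rotation(2, th[2])$R %*%
      axis_rotation(3, th[3])$R
    Sr <- R %*% S %*% t(R)
    Sr <- (Sr + t(Sr)) / 2
    worst <- max(worst, abs(von_mises(Sr) - v0) / max(v0, 1e-12))
    p <- stats::rnorm(1, sd = 100)
    worst <- max(worst, abs(von_mises(S + p * diag(3)) - v0) /
                   max(v0, 1e-12))
  }
  expect_lt(worst, 1e-10)
})

peak_fixture <- function() {
  mesh <- stacked_blocks(2)
  mesh <- define_node_sets(mesh, list(
    base = list(type = "box", lo = c(-1, -1, -1), hi = c(3, 3, 1e-9))))
  topf <- free_boundary_facets(mesh, within = list(
    type = "box", lo = c(-1, -1, 2 - 1e-9), hi = c(3, 3, 3)))
  lc <- load_case(
    dirichlet = list(list(set = "base", components = 1:3, value = 0)),
    surface_loads = list(list(set = topf, force = c(0, 0, -4))))
  sol <- solve_linear(mesh, uniform_material(mesh, 1000, 0), lc)
  list(mesh = mesh, sol = sol)
}

test_that("peak stress reports per-part maxima and normalizes linearly", {
  fx <- peak_fixture()
  # uniform compression: peak equals the uniform von Mises value (1 MPa)
  s_top <- peak_stress(fx$sol, fx$mesh, "top", reference = 1)
  expect_equal(s_top$peak, 1, tolerance = 1e-9)
  expect_equal(s_top$normalized, s_top$peak)
  # self-normalization
  expect_equal(peak_stress(fx$sol, fx$mesh, "top",
                           reference = s_top$peak)$normalized, 1,
               tolerance = 1e-12)
  # doubling the reference halves the normalized peak
  expect_equal(peak_stress(fx$sol, fx$mesh, "top",
                           reference = 2)$normalized, s_top$peak / 2,
               tolerance = 1e-12)
  # brute-force exhaustive scan oracle per part
  for (p in c("top", "bottom")) {
    sel <- fx$mesh$part_id == fx$mesh$part_names[[p]]
    vm <- vapply(1:4, function(g) max(von_mises(fx$sol$stress[sel, g, ])),
                 numeric(1))
    expect_equal(peak_stress(fx$sol, fx$mesh, p, 1)$peak, max(vm),
                 tolerance = 1e-12)
  }
  expect_error(peak_stress(fx$sol, fx$mesh, "nope", 1), "unknown|part")
  expect_error(peak_stress(fx$sol, fx$mesh, "top", 0), "> 0")
})

test_that("variant comparison reports pairwise differences and locations", {
  fx <- peak_fixture()
  mk <- function(label, ref = 10) {
    s <- peak_stress(fx$sol, fx$mesh, "top", reference = ref,
                     variant = label)
    s
  }
  same <- compare_variants(list(mk("a"), mk("b")))
  expect_true(all(same$pairwise$pct_diff == 0))
  expect_true(all(same$pairwise$locations_agree))
  # the published-style arithmetic: normalized peaks 1.20 vs 1.09 differ
  # by (1.20 - 1.09) / 1.09 = +10.09%
  a <- mk("seg"); a$normalized <- 1.20
  b <- mk("cad"); b$normalized <- 1.09
  rep2 <- compare_variants(list(a, b))
  up <- rep2$pairwise[rep2$pairwise$variant_a == "seg", ]
  expect_equal(up$pct_diff, 100 * (1.20 - 1.09) / 1.09, tolerance = 1e-12)
  # mixed normalization references are rejected
  bad <- mk("c", ref = 99)
  expect_error(compare_variants(list(mk("a"), bad)), "reference")
})
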