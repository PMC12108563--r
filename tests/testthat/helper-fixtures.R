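# shared in-code fixtures for the test suite

# uniform-bar label mesh: nx x b x b voxels of edge `sp` mm
bar_mesh <- function(nx = 8L, b = 2L, sp = 1) {
  lab <- label_volume(array(1L, c(nx, b, b)), c(bar = 1L),
                      spacing = rep(sp, 3L))
  mesh_from_labels(lab)
}

# facets of the +x end face of a bar mesh (with mid nodes)
bar_tip_facets <- function(mesh, L) {
  free_boundary_facets(mesh, within = list(
    type = "box", lo = c(L - 1e-9, -1e9, -1e9), hi = c(L + 1e9, 1e9, 1e9)))
}

# two stacked blocks (bottom part 1, top part 2), nz voxels each, unit edge
stacked_blocks <- function(n = 4L) {
  arr <- array(0L, c(n, n, n))
  arr[, , seq_len(n / 2)] <- 1L
  arr[, , (n / 2 + 1):n] <- 2L
  lab <- label_volume(arr, c(bottom = 1L, top = 2L), spacing = c(1, 1, 1))
  mesh_from_labels(lab)
}

# small phantom configuration used by module-level workflow tests
small_phantom_config <- function(seed = 1L, noise_sd = 30) {
  phantom_config(shape = c(60L, 60L, 45L), seed = seed, noise_sd = noise_sd)
}

# per-component sums of reaction forces of a solution
reaction_sums <- function(sol) {
  vapply(1:3, function(i)
    sum(sol$reactions$value[(sol$reactions$dof - 1L) %% 3L + 1L == i]),
    numeric(1))
}
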