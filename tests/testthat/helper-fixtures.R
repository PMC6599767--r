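# Shared fixtures: small meshes, canonical grids and a load-history builder.

default_times <- function(T = 1, dt = 0.004) dt * (0:(round(T / dt) - 1L))

make_load_history <- function(F_zeta, params, times = default_times(),
                              F_eta = 0) {
  n <- length(times)
  load_from_wss(cbind(rep_len(F_eta, n), rep_len(F_zeta, n)) / params$A_cap,
                params, times)
}

# analytic Timoshenko cantilever tip deflection under a tip point load
timoshenko_tip_deflection <- function(F, p) {
  F * p$L^3 / (3 * p$EI) + F * p$L / (p$kappa * p$G * p$A)
}

small_mesh <- function() build_patch_mesh(6, 8, radius = 1, length = 5)

# rigid rotation helper for frame-covariance tests
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  outer(a, a) * (1 - ca) + diag(3) * ca +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * sa
}

rotate_mesh <- function(mesh, R) {
  surface_mesh(mesh$vertices %*% t(R), mesh$triangles, mesh$normals %*% t(R),
               vertex_areas = mesh$vertex_areas)
}
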