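# Seeded synthesis of tangential WSS vector histories on a surface mesh,
# blending an athero-protective and an athero-prone waveform per vertex.

#' Construct a WSS field object
#'
#' @param mesh a [surface_mesh].
#' @param times uniform sample times over one cycle (s).
#' @param tau numeric array `n_vertices x n_times x 3` of WSS vectors (Pa),
#'   tangential to the surface at every vertex.
#' @param meta list of provenance (period, dt, seed, specs).
#' @return An object of class `wss_field`.
#' @export
wss_field <- function(mesh, times, tau, meta = list()) {
  n <- nrow(mesh$vertices)
  if (!is.array(tau) || length(dim(tau)) != 3L ||
      dim(tau)[1] != n || dim(tau)[2] != length(times) || dim(tau)[3] != 3L) {
    stop_invalid("tau must be an n_vertices x n_times x 3 array")
  }
  check_uniform_times(times)
  # tangency: |tau . n| < 1e-9 |tau|
  dots <- tau[, , 1] * mesh$normals[, 1] + tau[, , 2] * mesh$normals[, 2] +
    tau[, , 3] * mesh$normals[, 3]
  mags <- sqrt(tau[, , 1]^2 + tau[, , 2]^2 + tau[, , 3]^2)
  if (any(abs(dots) > 1e-9 * pmax(mags, 1e-300))) {
    stop_invalid("WSS vectors must be tangential to the surface")
  }
  structure(list(mesh = mesh, times = as.numeric(times), tau = tau,
                 meta = meta),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("wss_field: %d vertices x %d samples, T=%g s\n",
              dim(x$tau)[1], dim(x$tau)[2],
              x$times[length(x$times)] + x$times[2] - 2 * x$times[1]))
  invisible(x)
}

# flow-aligned tangent direction per vertex: axial axis projected onto the
# tangent plane (well defined on a cylinder patch)
base_flow_direction <- function(mesh, axis = c(0, 0, 1)) {
  n <- mesh$normals
  d <- matrix(axis, nrow(n), 3, byrow = TRUE)
  d <- d - n * as.vector(d[, 1] * n[, 1] + d[, 2] * n[, 2] + d[, 3] * n[, 3])
  len <- row_norms(d)
  if (any(len < 1e-12)) stop_invalid("flow axis parallel to a surface normal")
  d / len
}

#' Synthesize a phenotype-controlled pulsatile WSS field
#'
#' Builds tangential WSS vector histories per vertex by evaluating the
#' athero-protective and athero-prone waveforms on the shared cycle grid and
#' blending them linearly with the per-vertex `phenotype_map` (0 =
#' protective, 1 = prone). Direction oscillation rotates the vector in the
#' tangent plane around the vertex normal by a zero-mean periodic angle
#' series plus seeded band-limited noise, so spectra stay well-behaved.
#' Identical seeds give bitwise-identical fields.
#'
#' @param mesh a [surface_mesh].
#' @param phenotype_map per-vertex blend values in `[0, 1]`.
#' @param protective_spec,prone_spec [waveform_spec]s sharing `T` and `dt`.
#' @param seed integer seed for the direction noise.
#' @param noise_amp amplitude of the band-limited direction noise (rad).
#' @return A [wss_field].
#' @export
synthesize_wss_field <- function(mesh, phenotype_map,
                                 protective_spec = gcxmech::protective_spec(),
                                 prone_spec = gcxmech::prone_spec(),
                                 seed = 1L, noise_amp = 0.05) {
  nv <- nrow(mesh$vertices)
  if (length(phenotype_map) != nv) {
    stop_invalid("phenotype_map length must equal the vertex count")
  }
  if (any(phenotype_map < 0 | phenotype_map > 1)) {
    stop_invalid("phenotype_map values must lie in [0, 1]")
  }
  if (abs(protective_spec$T - prone_spec$T) > 1e-12 ||
      abs(protective_spec$dt - prone_spec$dt) > 1e-12) {
    stop_invalid("both specs must share T and dt")
  }
  times <- waveform_times(protective_spec)
  nt <- length(times)

  mag_a <- waveform_magnitude(times, protective_spec)
  mag_b <- waveform_magnitude(times, prone_spec)
  ang_a <- direction_angle_series(times, protective_spec)
  ang_b <- direction_angle_series(times, prone_spec)

  zeta0 <- base_flow_direction(mesh)           # flow-aligned tangent
  eta0 <- cross3(mesh$normals, zeta0)          # transverse tangent

  # seeded band-limited noise: harmonics 5..12, random amplitude and phase
  # per vertex, added to the rotation angle
  set.seed(as.integer(seed))
  harmonics <- 5:12
  nh <- length(harmonics)
  amp_noise <- matrix(runif(nv * nh), nv, nh)
  amp_noise <- noise_amp * amp_noise / pmax(rowSums(amp_noise), 1e-300)
  phase_noise <- matrix(runif(nv * nh, 0, 2 * pi), nv, nh)

  tau <- array(0, dim = c(nv, nt, 3))
  blend <- as.numeric(phenotype_map)
  # per-instant: magnitude and angle blended, then rotated in tangent plane
  for (it in seq_len(nt)) {
    mag <- (1 - blend) * mag_a[it] + blend * mag_b[it]
    ang <- (1 - blend) * ang_a[it] + blend * ang_b[it]
    if (noise_amp > 0) {
      nz <- numeric(nv)
      for (h in seq_len(nh)) {
        nz <- nz + amp_noise[, h] *
          sin(2 * pi * harmonics[h] * times[it] / protective_spec$T +
                phase_noise[, h])
      }
      # noise only perturbs the direction where the field oscillates at all
      ang <- ang + blend * nz
    }
    dir <- zeta0 * cos(ang) + eta0 * sin(ang)
    tau[, it, ] <- dir * mag
  }
  meta <- list(T = protective_spec$T, dt = protective_spec$dt,
               seed = as.integer(seed), noise_amp = noise_amp,
               protective_spec = unclass(protective_spec),
               prone_spec = unclass(prone_spec))
  wss_field(mesh, times, tau, meta)
}

#' Write a WSS field to CSV + JSON sidecar
#'
#' Long-format CSV with columns `vertex_id`, `t`, `tau_x`, `tau_y`, `tau_z`
#' (SI units) and a JSON sidecar (`<path>.json`) carrying the period, time
#' step, seed and waveform parameters.
#'
#' @param field a [wss_field].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_wss_csv <- function(field, path) {
  nv <- dim(field$tau)[1]
  nt <- dim(field$tau)[2]
  dt_tab <- data.table::data.table(
    vertex_id = rep(seq_len(nv), times = nt),
    t = rep(field$times, each = nv),
    tau_x = as.vector(field$tau[, , 1]),
    tau_y = as.vector(field$tau[, , 2]),
    tau_z = as.vector(field$tau[, , 3])
  )
  data.table::setorder(dt_tab, vertex_id, t)
  data.table::fwrite(dt_tab, path)
  jsonlite::write_json(field$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a WSS field from CSV (+ JSON sidecar) against a given mesh
#'
#' @param path CSV path written by [write_wss_csv()].
#' @param mesh the [surface_mesh] the histories live on.
#' @return A [wss_field].
#' @export
read_wss_csv <- function(path, mesh) {
  tab <- data.table::fread(path)
  data.table::setorder(tab, vertex_id, t)
  nv <- length(unique(tab$vertex_id))
  times <- sort(unique(tab$t))
  nt <- length(times)
  if (nv != nrow(mesh$vertices)) {
    stop_invalid("CSV vertex count does not match the mesh")
  }
  tau <- array(0, dim = c(nv, nt, 3))
  ord <- order(tab$t, tab$vertex_id)
  tau[, , 1] <- tab$tau_x[ord]
  tau[, , 2] <- tab$tau_y[ord]
  tau[, , 3] <- tab$tau_z[ord]
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  wss_field(mesh, times, tau, meta)
}
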