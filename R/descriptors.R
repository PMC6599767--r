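# Time-domain descriptors of the haemodynamic stimulus and the transmitted
# anchor force, and percentile-region co-localization on the surface.
# All cycle integrals use the trapezoidal rule with the periodic closing
# sample (equivalent to the rectangle sum on a uniform periodic grid).

#' Local tangent frame from the time-averaged WSS direction
#'
#' `zeta` points along the time-averaged WSS vector, `eta = zeta x n`; the
#' pair is orthonormal and tangent to the surface.
#'
#' @param mean_wss_vector time-averaged WSS 3-vector (Pa), tangential.
#' @param normal unit surface normal.
#' @param eps_dir degeneracy threshold (Pa): below it no flow direction is
#'   defined and an error of class `gcx_degenerate_direction` is thrown.
#' @return list with unit 3-vectors `zeta`, `eta` and `normal`.
#' @export
local_frame <- function(mean_wss_vector, normal, eps_dir = 1e-6) {
  m <- sqrt(sum(mean_wss_vector^2))
  if (m <= eps_dir) {
    stop(structure(class = c("gcx_degenerate_direction", "error", "condition"),
                   list(message = "time-averaged WSS too small to define a direction",
                        call = NULL)))
  }
  zeta <- mean_wss_vector / m
  eta <- cross3(zeta, normal)
  eta <- eta / sqrt(sum(eta^2))
  list(zeta = zeta, eta = eta, normal = normal)
}

#' Time-averaged wall shear stress
#'
#' Cycle average of the WSS magnitude, `(1/T) int |tau_w| dt`.
#'
#' @param tau_history `n_t x k` matrix of WSS vector samples (Pa), one cycle
#'   on a uniform grid (a plain vector is treated as one component).
#' @return TAWSS (Pa).
#' @export
tawss <- function(tau_history) {
  tau <- as.matrix(tau_history)
  if (nrow(tau) == 0L) stop_invalid("empty history")
  cycle_mean(row_norms(tau))
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 * (1 - |int tau dt| / int |tau| dt)`: 0 for unidirectional
#' WSS, 0.5 for a fully reversing zero-mean stimulus. An all-zero history is
#' defined to give 0.
#'
#' @inheritParams tawss
#' @return OSI, in `[0, 0.5]`.
#' @export
osi <- function(tau_history) {
  tau <- as.matrix(tau_history)
  if (nrow(tau) == 0L) stop_invalid("empty history")
  mm <- sum(row_norms(tau))
  if (mm == 0) return(0)
  rm_ <- sqrt(sum(colSums(tau)^2))
  0.5 * (1 - rm_ / mm)
}

#' Time-averaged force magnitude
#'
#' Cycle average of `|F|`; applied to the stimulus it gives `TAF_shear`, to
#' the anchor reaction `TAF_mem`.
#'
#' @param force_history `n_t x k` matrix of force vector samples (pN).
#' @return TAF (pN).
#' @export
taf <- function(force_history) {
  tawss(force_history)
}

#' Cycle-averaged transmitted-to-applied force ratio
#'
#' Average of the pointwise ratio `|F_mem| / |F_shear|` over the cycle.
#' Instants where `|F_shear| < eps_F` are excluded and the average is taken
#' over the retained instants; the excluded fraction is attached as the
#' `"excluded_fraction"` attribute.
#'
#' @param Fmem_history,Fshear_history `n_t x k` force histories (pN) on a
#'   shared grid.
#' @param eps_F denominator exclusion threshold (pN).
#' @return F_ratio (dimensionless) with attribute `excluded_fraction`.
#' @export
f_ratio <- function(Fmem_history, Fshear_history, eps_F = 1e-6) {
  fm <- row_norms(as.matrix(Fmem_history))
  fs <- row_norms(as.matrix(Fshear_history))
  if (length(fm) != length(fs)) stop_invalid("histories must share the grid")
  keep <- fs >= eps_F
  if (!any(keep)) {
    stop("F_ratio undefined: every instant excluded by the eps_F rule",
         call. = FALSE)
  }
  out <- mean(fm[keep] / fs[keep])
  attr(out, "excluded_fraction") <- 1 - mean(keep)
  out
}

#' Oscillatory force index
#'
#' OSI analogue for the transmitted force:
#' `OFI = 0.5 * (1 - |int F_mem dt| / int |F_mem| dt)`. An all-zero history
#' gives 0.
#'
#' @param Fmem_history `n_t x k` anchor-force history (pN).
#' @return OFI, in `[0, 0.5]`.
#' @export
ofi <- function(Fmem_history) {
  osi(Fmem_history)
}

#' Area-weighted percentile region on a surface
#'
#' Thresholds a per-vertex map at the area-weighted `q`-th percentile (the
#' percentile of the field over the surface, not of the vertex list; linear
#' interpolation between order statistics on the cumulative area) and masks
#' the vertices strictly below (`side = "low"`) or strictly above
#' (`side = "high"`) the threshold. Values within 1e-9 (relative to the map
#' scale) of the threshold count as *at* the threshold and are never
#' selected: this keeps region membership stable when tied values sit
#' exactly on the percentile. Vertices with `NA` values are never selected.
#'
#' @param values per-vertex map values.
#' @param vertex_areas per-vertex areas (mm^2).
#' @param q percentile in (0, 100).
#' @param side `"low"` or `"high"`.
#' @return An object of class `region_mask`: logical `mask`, the `threshold`
#'   value, and the selected surface area `SA`.
#' @export
percentile_region <- function(values, vertex_areas, q, side = c("low", "high")) {
  side <- match.arg(side)
  if (q <= 0 || q >= 100) stop_invalid("q must lie in (0, 100)")
  ok <- is.finite(values)
  if (!any(ok)) stop_invalid("no finite values")
  thr <- weighted_percentile(values[ok], vertex_areas[ok], q / 100)
  band <- 1e-9 * max(abs(values[ok]), 1e-300)
  mask <- rep(FALSE, length(values))
  mask[ok] <- if (side == "low") values[ok] < thr - band else
    values[ok] > thr + band
  if (!any(mask)) {
    warning("empty region: the map may be constant at the threshold",
            call. = FALSE)
  }
  structure(list(mask = mask, threshold = thr,
                 SA = sum(vertex_areas[mask])),
            class = "region_mask")
}

# area-weighted percentile with linear interpolation between order
# statistics on the normalized cumulative weight
weighted_percentile <- function(values, weights, p) {
  o <- order(values)
  v <- values[o]; w <- weights[o]
  cw <- cumsum(w) - w / 2   # midpoint convention
  cw <- cw / sum(w)
  if (p <= cw[1]) return(v[1])
  if (p >= cw[length(cw)]) return(v[length(v)])
  stats::approx(cw, v, xout = p, ties = "ordered")$y
}

#' Similarity index between two surface regions
#'
#' Area-weighted overlap coefficient
#' `SI = 2 * SA(i and j) / (SA_i + SA_j)`: 1 for perfectly overlapping
#' regions, 0 for disjoint ones.
#'
#' @param mask_i,mask_j `region_mask` objects (or plain logical vectors) on
#'   the same mesh.
#' @param vertex_areas per-vertex areas (mm^2).
#' @return SI in `[0, 1]`.
#' @export
similarity_index <- function(mask_i, mask_j, vertex_areas) {
  get_mask <- function(m) if (inherits(m, "region_mask")) m$mask else as.logical(m)
  mi <- get_mask(mask_i); mj <- get_mask(mask_j)
  if (length(mi) != length(mj)) stop_invalid("masks must share the mesh")
  sa_i <- sum(vertex_areas[mi]); sa_j <- sum(vertex_areas[mj])
  if (sa_i + sa_j == 0) {
    stop("similarity index undefined: both regions are empty", call. = FALSE)
  }
  2 * sum(vertex_areas[mi & mj]) / (sa_i + sa_j)
}
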