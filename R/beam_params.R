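# Parameters of the glycocalyx-unit beam model. Working units: nm, pN, s.
# With these, pressure-like moduli are pN/nm^2, flexural rigidity pN*nm^2,
# mass is pN*s^2/nm (= 1e-3 kg), so a density in kg/m^3 converts by 1e-24.

RHO_SI_TO_INTERNAL <- 1e-24

#' Define the glycocalyx-unit beam model
#'
#' A solid circular Timoshenko cantilever of length `L` and diameter `d`
#' represents the effective mechanical unit of a heparan-sulfate chain; the
#' clamped end is the syndecan anchor at the endothelial membrane. The
#' elastic modulus is derived from the flexural rigidity `EI` and the
#' section (`E = EI/I`, `I = pi d^4/64`), and `G = E/(2(1+nu))` so `E` and
#' `G` rescale together when `EI` changes.
#'
#' @param L beam length (nm).
#' @param d beam diameter (nm).
#' @param EI flexural rigidity (pN nm^2).
#' @param nu Poisson ratio.
#' @param kappa Timoshenko shear coefficient (0.8864 for a circular section
#'   at `nu = 0.3`).
#' @param rho_b effective material density (kg m^-3). The default places the
#'   first natural frequency of the default unit near 40 Hz, inside the
#'   cardiac 0-125 Hz band; set `rho_b = 0` for quasi-static behaviour.
#' @param alpha_R,beta_R Rayleigh damping coefficients (s^-1, s);
#'   `C = alpha_R M + beta_R K`. Defaults give about 20% modal damping at
#'   the first mode of the default unit.
#' @param n_elem number of 3-node quadratic elements.
#' @param f_load fraction of the beam length, measured from the free tip,
#'   over which the drag load is spread (default 1/6).
#' @param A_cap capture area converting WSS (Pa) into total drag force (pN)
#'   per unit (`1 Pa x 1 um^2 = 1 pN`). A calibration parameter, chosen so
#'   WSS of 0.4-2.5 Pa yields anchor forces of order 1-10 pN.
#' @return An object of class `beam_params` with derived section quantities
#'   `A`, `I`, `E`, `G` attached.
#' @export
beam_params <- function(L = 50, d = 1, EI = 100, nu = 0.3, kappa = 0.8864,
                        rho_b = 4e15, alpha_R = 50, beta_R = 8e-4,
                        n_elem = 100L, f_load = 1 / 6, A_cap = 2.0) {
  if (L <= 0 || d <= 0 || EI <= 0 || kappa <= 0 || A_cap <= 0) {
    stop_invalid("L, d, EI, kappa and A_cap must be positive")
  }
  if (f_load <= 0 || f_load > 1) stop_invalid("f_load must lie in (0, 1]")
  if (n_elem < 1L) stop_invalid("n_elem must be >= 1")
  if (rho_b < 0) stop_invalid("rho_b must be >= 0")
  A <- pi * d^2 / 4
  I <- pi * d^4 / 64
  E <- EI / I
  G <- E / (2 * (1 + nu))
  for (v in c(A, I, E, G)) {
    if (!is.finite(v) || v <= 0) stop_invalid("derived section quantity not positive")
  }
  structure(
    list(L = L, d = d, EI = EI, nu = nu, kappa = kappa, rho_b = rho_b,
         alpha_R = alpha_R, beta_R = beta_R, n_elem = as.integer(n_elem),
         f_load = f_load, A_cap = A_cap,
         A = A, I = I, E = E, G = G,
         rho = rho_b * RHO_SI_TO_INTERNAL),
    class = "beam_params"
  )
}

#' @export
print.beam_params <- function(x, ...) {
  cat(sprintf(
    "beam_params: L=%g nm, d=%g nm, EI=%g pN nm^2, nu=%g, kappa=%g\n",
    x$L, x$d, x$EI, x$nu, x$kappa))
  cat(sprintf("  rho_b=%g kg/m^3, Rayleigh (%g /s, %g s), %d elements, f_load=%g, A_cap=%g um^2\n",
              x$rho_b, x$alpha_R, x$beta_R, x$n_elem, x$f_load, x$A_cap))
  invisible(x)
}

#' Write/read beam parameters as JSON with explicit units in key names
#'
#' @param params a [beam_params].
#' @param path JSON file path.
#' @return `path` invisibly (write); a [beam_params] (read).
#' @export
write_beam_json <- function(params, path) {
  jsonlite::write_json(list(
    L_nm = params$L, d_nm = params$d, EI_pN_nm2 = params$EI,
    nu = params$nu, kappa = params$kappa, rho_b_kg_m3 = params$rho_b,
    alpha_R_per_s = params$alpha_R, beta_R_s = params$beta_R,
    n_elem = params$n_elem, f_load = params$f_load, A_cap_um2 = params$A_cap
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_beam_json
#' @export
read_beam_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  beam_params(L = j$L_nm, d = j$d_nm, EI = j$EI_pN_nm2, nu = j$nu,
              kappa = j$kappa, rho_b = j$rho_b_kg_m3,
              alpha_R = j$alpha_R_per_s, beta_R = j$beta_R_s,
              n_elem = j$n_elem, f_load = j$f_load, A_cap = j$A_cap_um2)
}
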