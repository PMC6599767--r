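# Finite-element assembly for one bending plane of the Timoshenko beam:
# 3-node quadratic elements, two fields per node (transverse displacement w,
# cross-section rotation phi), DOF order (w1, phi1, w2, phi2, ...).
# Bending and mass terms use 3-point Gauss; the shear term uses 2-point
# reduced integration to avoid shear locking.

gauss_rule <- function(n) {
  if (n == 2L) {
    list(x = c(-1, 1) / sqrt(3), w = c(1, 1))
  } else if (n == 3L) {
    list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9)
  } else stop_invalid("unsupported Gauss rule")
}

# quadratic shape functions and derivatives on the parent element [-1, 1]
shape_quad <- function(xi) {
  list(N = c(xi * (xi - 1) / 2, 1 - xi^2, xi * (xi + 1) / 2),
       dN = c(xi - 0.5, -2 * xi, xi + 0.5))
}

#' Assemble stiffness, mass and damping matrices for one bending plane
#'
#' Builds the free-free (pre-boundary-condition) matrices of the clamped
#' Timoshenko cantilever discretization: `K` (stiffness), `M` (consistent
#' mass including rotary inertia) and `C = alpha_R M + beta_R K`. The
#' clamped anchor sits at node 1 (`x = 0`); the free tip at `x = L`.
#'
#' @param params a [beam_params].
#' @return A list with sparse matrices `K`, `M`, `C`, the node coordinates
#'   `x_nodes` (nm), the DOF count `ndof`, index vectors `fixed` (the two
#'   clamped DOFs) and `free`, and `f_unit`, the consistent nodal load
#'   vector for a unit total force spread uniformly over the top
#'   `f_load * L` segment.
#' @export
assemble <- function(params) {
  ne <- params$n_elem
  nn <- 2L * ne + 1L
  ndof <- 2L * nn
  h <- params$L / ne
  x_nodes <- params$L * (seq_len(nn) - 1L) / (nn - 1L)

  EI <- params$EI
  kGA <- params$kappa * params$G * params$A
  rhoA <- params$rho * params$A
  rhoI <- params$rho * params$I

  g3 <- gauss_rule(3L)
  g2 <- gauss_rule(2L)
  jac <- h / 2

  # element matrices (6x6), identical for every element
  idx_w <- c(1L, 3L, 5L)
  idx_p <- c(2L, 4L, 6L)
  Ke <- matrix(0, 6, 6)
  Me <- matrix(0, 6, 6)
  for (q in 1:3) {
    sh <- shape_quad(g3$x[q])
    dNdx <- sh$dN / jac
    wq <- g3$w[q] * jac
    Bb <- numeric(6); Bb[idx_p] <- dNdx          # bending curvature
    Ke <- Ke + wq * EI * tcrossprod(Bb)
    Nw <- numeric(6); Nw[idx_w] <- sh$N
    Np <- numeric(6); Np[idx_p] <- sh$N
    Me <- Me + wq * (rhoA * tcrossprod(Nw) + rhoI * tcrossprod(Np))
  }
  for (q in 1:2) {
    sh <- shape_quad(g2$x[q])
    dNdx <- sh$dN / jac
    wq <- g2$w[q] * jac
    Bs <- numeric(6)                              # shear strain w' - phi
    Bs[idx_w] <- dNdx
    Bs[idx_p] <- -sh$N
    Ke <- Ke + wq * kGA * tcrossprod(Bs)
  }

  # assemble by triplets
  nel6 <- 36L
  ii <- integer(ne * nel6); jj <- integer(ne * nel6)
  kv <- numeric(ne * nel6); mv <- numeric(ne * nel6)
  loc <- as.matrix(expand.grid(a = 1:6, b = 1:6))
  for (e in seq_len(ne)) {
    first_node <- 2L * (e - 1L) + 1L
    edofs <- c(2L * first_node - 1L, 2L * first_node,
               2L * first_node + 1L, 2L * first_node + 2L,
               2L * first_node + 3L, 2L * first_node + 4L)
    sl <- ((e - 1L) * nel6 + 1L):(e * nel6)
    ii[sl] <- edofs[loc[, "a"]]
    jj[sl] <- edofs[loc[, "b"]]
    kv[sl] <- Ke[loc]
    mv[sl] <- Me[loc]
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kv, dims = c(ndof, ndof))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mv, dims = c(ndof, ndof))
  C <- params$alpha_R * M + params$beta_R * K

  f_unit <- load_vector(params, x_nodes, h)

  fixed <- c(1L, 2L)
  list(K = K, M = M, C = C, x_nodes = x_nodes, ndof = ndof,
       fixed = fixed, free = setdiff(seq_len(ndof), fixed),
       f_unit = f_unit)
}

# consistent nodal load vector for unit total transverse force spread
# uniformly over [L*(1 - f_load), L]; handles partial element coverage by
# Gauss integration over the loaded sub-interval
load_vector <- function(params, x_nodes, h) {
  ne <- params$n_elem
  ndof <- 2L * (2L * ne + 1L)
  a <- params$L * (1 - params$f_load)
  q_line <- 1 / (params$f_load * params$L)   # force per unit length
  g3 <- gauss_rule(3L)
  f <- numeric(ndof)
  for (e in seq_len(ne)) {
    x0 <- (e - 1L) * h
    x1 <- e * h
    lo <- max(x0, a)
    hi <- x1
    if (hi <= lo) next
    first_node <- 2L * (e - 1L) + 1L
    wdofs <- c(2L * first_node - 1L, 2L * first_node + 1L,
               2L * first_node + 3L)
    half <- (hi - lo) / 2
    mid <- (hi + lo) / 2
    for (q in 1:3) {
      xq <- mid + half * g3$x[q]
      xi <- 2 * (xq - x0) / h - 1
      sh <- shape_quad(xi)
      f[wdofs] <- f[wdofs] + g3$w[q] * half * q_line * sh$N
    }
  }
  f
}

# consistent nodal load for a point force at the tip
tip_point_load_vector <- function(params) {
  ndof <- 2L * (2L * params$n_elem + 1L)
  f <- numeric(ndof)
  f[ndof - 1L] <- 1
  f
}
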