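# Dynamic response: implicit Newmark time integration (beta = 1/4,
# gamma = 1/2) from rest, periodic load repetition, anchor reactions from
# the constrained-equation residual, and a discrete unit-response fast path
# used by the pipeline (the system is linear and time-invariant with a
# single spatial load pattern).

#' Build a load history from a WSS vector history
#'
#' Converts a tangential WSS history into the total drag force per instant,
#' `F_shear(t) = tau_w(t) * A_cap` (1 Pa x 1 um^2 = 1 pN), spread uniformly
#' over the top `f_load * L` segment of the beam.
#'
#' @param tau_history WSS samples (Pa): an `n_t x 2` matrix of tangent-plane
#'   components, or `n_t x 3` Cartesian vectors together with `frame`.
#' @param params a [beam_params] (supplies `A_cap` and `f_load`).
#' @param times sample times (s), uniform.
#' @param frame optional local frame (list with unit vectors `eta`, `zeta`,
#'   `normal`) used to project 3-component input; tangency is checked
#'   against `frame$normal`.
#' @return An object of class `load_history` with elements `times` and `F`
#'   (`n_t x 2` total force, pN); `F` is also the stimulus `F_shear(t)`.
#' @export
load_from_wss <- function(tau_history, params, times, frame = NULL) {
  tau <- as.matrix(tau_history)
  if (ncol(tau) == 3L) {
    if (is.null(frame)) stop_invalid("3-component input requires a frame")
    ndot <- abs(tau %*% frame$normal)
    if (any(ndot > 1e-9 * pmax(row_norms(tau), 1e-300))) {
      stop_invalid("WSS history is not tangential")
    }
    tau <- cbind(tau %*% frame$eta, tau %*% frame$zeta)
  } else if (ncol(tau) != 2L) {
    stop_invalid("tau_history must have 2 or 3 components")
  }
  check_uniform_times(times)
  structure(list(times = as.numeric(times), F = tau * params$A_cap,
                 f_load = params$f_load),
            class = "load_history")
}

#' First natural frequencies of the clamped beam
#'
#' Undamped eigenfrequencies of the boundary-condition-reduced generalized
#' problem `K u = omega^2 M u` for one bending plane.
#'
#' @param params a [beam_params] with `rho_b > 0`.
#' @param n number of frequencies to return.
#' @return frequencies (Hz), ascending.
#' @export
natural_frequencies <- function(params, n = 3L) {
  if (params$rho_b <= 0) stop_invalid("natural frequencies need rho_b > 0")
  sys <- assemble(params)
  Kf <- as.matrix(sys$K[sys$free, sys$free])
  Mf <- as.matrix(sys$M[sys$free, sys$free])
  ev <- eigen(solve(Mf, Kf), only.values = TRUE)$values
  ev <- Re(ev[abs(Im(ev)) < 1e-6 * abs(ev) | Im(ev) == 0])
  ev <- sort(ev[ev > 0])
  sqrt(head(ev, n)) / (2 * pi)
}

# smooth 0 -> 1 cosine ramp over one cycle, used to bring the periodic load
# in from rest without a step discontinuity
startup_ramp <- function(nt) {
  (1 - cos(pi * (seq_len(nt) - 1L) / nt)) / 2
}

# Newmark constant-average-acceleration constants
newmark_consts <- function(dt, beta = 1 / 4, gamma = 1 / 2) {
  list(a0 = 1 / (beta * dt^2), a1 = gamma / (beta * dt),
       a2 = 1 / (beta * dt), a3 = 1 / (2 * beta) - 1,
       a4 = gamma / beta - 1, a5 = dt / 2 * (gamma / beta - 2),
       a6 = dt * (1 - gamma), a7 = gamma * dt)
}

# Core Newmark sweep for one plane with the fixed spatial load pattern
# sys$f_unit scaled per step by the columns of `scale` (n_steps x n_rhs).
# Starts from rest (u = v = a = 0). Returns per-step anchor force and
# moment reactions (n_steps x n_rhs each) and the free-DOF displacement
# snapshots for requested steps.
newmark_sweep <- function(sys, dt, scale, keep_steps = integer()) {
  n_steps <- nrow(scale)
  n_rhs <- ncol(scale)
  cst <- newmark_consts(dt)
  free <- sys$free; fixed <- sys$fixed
  Kf <- sys$K[free, free]; Mf <- sys$M[free, free]; Cf <- sys$C[free, free]
  Keff <- Kf + cst$a0 * Mf + cst$a1 * Cf
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Keff), LDL = FALSE)
  fu <- sys$f_unit[free]
  # fixed-row slices for the reaction residual
  Kx <- sys$K[fixed, free, drop = FALSE]
  Mx <- sys$M[fixed, free, drop = FALSE]
  Cx <- sys$C[fixed, free, drop = FALSE]
  fx <- sys$f_unit[fixed]

  nf <- length(free)
  u <- matrix(0, nf, n_rhs); v <- u; a <- u
  Rforce <- matrix(0, n_steps, n_rhs)
  Rmom <- matrix(0, n_steps, n_rhs)
  kept <- vector("list", length(keep_steps))
  names(kept) <- as.character(keep_steps)
  for (k in seq_len(n_steps)) {
    if (k > 1L) {
      f_k <- outer(fu, scale[k, ])
      feff <- f_k + Mf %*% (cst$a0 * u + cst$a2 * v + cst$a3 * a) +
        Cf %*% (cst$a1 * u + cst$a4 * v + cst$a5 * a)
      u1 <- as.matrix(Matrix::solve(fac, feff))
      a1 <- cst$a0 * (u1 - u) - cst$a2 * v - cst$a3 * a
      v <- v + cst$a6 * a + cst$a7 * a1
      u <- u1; a <- a1
    }
    # residual at the clamped DOFs; reaction on the anchor is its negative
    res <- as.matrix(Mx %*% a + Cx %*% v + Kx %*% u) -
      outer(fx, scale[k, ])
    Rforce[k, ] <- -res[1, ]
    Rmom[k, ] <- -res[2, ]
    if (k %in% keep_steps) kept[[as.character(k)]] <- u
  }
  list(Rforce = Rforce, Rmom = Rmom, kept = kept)
}

#' Dynamic beam solution under a periodic load history
#'
#' Integrates the clamped Timoshenko beam through `n_cycles` repetitions of
#' the one-cycle load history, starting from rest, with implicit Newmark
#' integration (beta = 1/4, gamma = 1/2), and returns the final cycle. The
#' two tangent-plane bending components are uncoupled and share matrices,
#' so they are integrated together. The anchor reaction is recovered from
#' the constrained-equation residual
#' `[M u'' + C u' + K u - f]` at the clamped DOFs.
#'
#' @param params a [beam_params].
#' @param load a [load_history] covering exactly one cycle.
#' @param n_cycles number of cycles integrated from rest (>= 2); the last
#'   is reported, the decay of the start-up transient is measured by the
#'   relative change between the final two cycles.
#' @return An object of class `beam_solution`: `times` (final-cycle grid),
#'   `F_mem` (`n_t x 2` anchor force, pN), `M_anchor` (`n_t x 2` anchor
#'   moment, pN nm), `w_tip` (`n_t x 2`, nm), `F_shear` (the input force),
#'   and `cycle_change`, the max relative cycle-to-cycle reaction change.
#' @export
dynamic_solve <- function(params, load, n_cycles = 3L) {
  if (n_cycles < 2L) stop_invalid("n_cycles must be >= 2")
  dt <- check_uniform_times(load$times)
  Fmat <- as.matrix(load$F)
  if (ncol(Fmat) == 1L) Fmat <- cbind(Fmat, 0)
  nt <- nrow(Fmat)
  sys <- assemble(params)
  scale <- Fmat[rep(seq_len(nt), n_cycles), , drop = FALSE]
  # cosine start-up ramp over the first cycle: avoids seeding the marginally
  # damped Nyquist mode of the Newmark scheme with a hard step from rest;
  # the reported final cycle (periodic steady state) is unaffected
  scale[seq_len(nt), ] <- scale[seq_len(nt), ] * startup_ramp(nt)
  n_total <- nrow(scale)
  last <- (n_total - nt + 1L):n_total
  prev <- last - nt

  # track the tip DOF as well: augment reaction extraction with tip rows
  sweep <- newmark_sweep_with_tip(sys, dt, scale)
  Rf <- sweep$Rforce; Rm <- sweep$Rmom; tip <- sweep$tip

  denom <- max(abs(Rf[last, ]), 1e-300)
  cycle_change <- max(abs(Rf[last, ] - Rf[prev, ])) / denom
  structure(list(
    times = load$times,
    F_mem = Rf[last, , drop = FALSE],
    M_anchor = Rm[last, , drop = FALSE],
    w_tip = tip[last, , drop = FALSE],
    F_shear = Fmat,
    cycle_change = cycle_change,
    params = params
  ), class = "beam_solution")
}

# newmark_sweep variant that also records the tip translational DOF
newmark_sweep_with_tip <- function(sys, dt, scale) {
  n_steps <- nrow(scale); n_rhs <- ncol(scale)
  cst <- newmark_consts(dt)
  free <- sys$free; fixed <- sys$fixed
  Kf <- sys$K[free, free]; Mf <- sys$M[free, free]; Cf <- sys$C[free, free]
  Keff <- Kf + cst$a0 * Mf + cst$a1 * Cf
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Keff), LDL = FALSE)
  fu <- sys$f_unit[free]
  Kx <- sys$K[fixed, free, drop = FALSE]
  Mx <- sys$M[fixed, free, drop = FALSE]
  Cx <- sys$C[fixed, free, drop = FALSE]
  fx <- sys$f_unit[fixed]
  tip_row <- which(free == sys$ndof - 1L)

  nf <- length(free)
  u <- matrix(0, nf, n_rhs); v <- u; a <- u
  Rforce <- matrix(0, n_steps, n_rhs)
  Rmom <- matrix(0, n_steps, n_rhs)
  tip <- matrix(0, n_steps, n_rhs)
  for (k in seq_len(n_steps)) {
    if (k > 1L) {
      f_k <- outer(fu, scale[k, ])
      feff <- f_k + Mf %*% (cst$a0 * u + cst$a2 * v + cst$a3 * a) +
        Cf %*% (cst$a1 * u + cst$a4 * v + cst$a5 * a)
      u1 <- as.matrix(Matrix::solve(fac, feff))
      a1 <- cst$a0 * (u1 - u) - cst$a2 * v - cst$a3 * a
      v <- v + cst$a6 * a + cst$a7 * a1
      u <- u1; a <- a1
    }
    res <- as.matrix(Mx %*% a + Cx %*% v + Kx %*% u) -
      outer(fx, scale[k, ])
    Rforce[k, ] <- -res[1, ]
    Rmom[k, ] <- -res[2, ]
    tip[k, ] <- u[tip_row, ]
  }
  list(Rforce = Rforce, Rmom = Rmom, tip = tip)
}

#' Anchor reaction history of a beam solution
#'
#' @param solution a `beam_solution` from [dynamic_solve()].
#' @return `n_t x 2` matrix of tangent-plane anchor forces `F_mem(t)` (pN),
#'   sign convention: force exerted on the membrane anchor by the beam.
#' @export
anchor_reaction <- function(solution) {
  solution$F_mem
}

# Discrete unit-response kernel of the Newmark scheme: anchor-force
# response to a unit total load applied at step 2 of n_steps (step 1 is the
# rest state). Because the scheme is linear and time-invariant from step 2
# on, the reaction to any input sequence is the discrete convolution with
# this kernel — the pipeline fast path.
newmark_reaction_kernel <- function(params, dt, n_steps) {
  sys <- assemble(params)
  scale <- matrix(0, n_steps, 1)
  scale[2, 1] <- 1
  sweep <- newmark_sweep(sys, dt, scale)
  as.numeric(sweep$Rforce[, 1])
}

# Convolve input force sequences (columns of Fseq, length n) with the unit
# reaction kernel; returns the reaction sequences. FFT-based, linear
# convolution; reproduces the full Newmark sweep to round-off.
kernel_convolve <- function(kernel, Fseq) {
  n <- nrow(Fseq)
  # r[k] = sum_{j>=2} F[j] * kernel[k - j + 2]  (1-based)
  L <- stats::nextn(2L * n, 2)
  kpad <- c(kernel, numeric(L - length(kernel)))
  Kf <- stats::fft(kpad)
  out <- matrix(0, n, ncol(Fseq))
  for (c_ in seq_len(ncol(Fseq))) {
    fpad <- c(Fseq[, c_], numeric(L - n))
    fpad[1L] <- 0   # the rest-state step never propagates its input
    conv <- Re(stats::fft(stats::fft(fpad) * Kf, inverse = TRUE)) / L
    # conv[m] = sum_j F[j] kernel[m - j + 1]; want index m = k + 1
    out[, c_] <- conv[seq_len(n) + 1L]
  }
  out
}
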