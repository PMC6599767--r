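# Newmark dynamics: equilibrium limits, linearity, modal properties and the
# pipeline's unit-response convolution fast path.

test_that("load_from_wss converts Pa to pN through the capture area", {
  p <- beam_params(A_cap = 2)
  times <- default_times()
  lh <- load_from_wss(cbind(rep(0, 250), rep(1, 250)), p, times)
  expect_equal(lh$F[1, ], c(0, 2))
  lh2 <- load_from_wss(cbind(rep(0.3, 250), rep(-0.4, 250)), p, times)
  expect_equal(sqrt(sum(lh2$F[1, ]^2)), 1.0)
  # zero WSS gives zero load
  lh0 <- load_from_wss(matrix(0, 250, 2), p, times)
  expect_true(all(lh0$F == 0))
})

test_that("non-tangential 3-component WSS input is rejected", {
  p <- beam_params()
  frame <- local_frame(c(1, 0, 0), c(0, 0, 1))
  tau <- matrix(rep(c(1, 0, 0.5), each = 10), 10, 3)
  expect_error(load_from_wss(tau, p, default_times()[1:10], frame = frame),
               "tangential")
  tau_ok <- matrix(rep(c(1, 0.2, 0), each = 10), 10, 3)
  lh <- load_from_wss(tau_ok, p, default_times()[1:10], frame = frame)
  expect_equal(lh$F[1, 2], 1 * p$A_cap)  # zeta component
})

test_that("zero load produces zero response and reaction", {
  p <- beam_params()
  lh <- make_load_history(0, p)
  s <- dynamic_solve(p, lh, 2)
  expect_true(all(s$F_mem == 0))
  expect_true(all(s$w_tip == 0))
})

test_that("damped constant-load response settles on the static reaction", {
  p <- beam_params()
  lh <- make_load_history(2, p)
  s <- dynamic_solve(p, lh, 3)
  st <- static_solve(p, 2)
  expect_equal(max(abs(s$F_mem[, 2] - st$anchor_reaction)) /
                 abs(st$anchor_reaction), 0, tolerance = 1e-6)
  expect_lt(s$cycle_change, 0.01)
})

test_that("quasi-static regime tracks the stimulus instant by instant", {
  # light, stiff beam: first natural frequency far above the 0-125 Hz band,
  # in-band damping negligible
  p <- beam_params(rho_b = 1e8, alpha_R = 0, beta_R = 1e-5)
  expect_gt(natural_frequencies(p, 1), 125 * 20)
  times <- default_times()
  Fz <- 2 + 1.5 * sin(2 * pi * times) + 0.5 * cos(2 * pi * 3 * times)
  lh <- make_load_history(Fz, p, times)
  s <- dynamic_solve(p, lh, 3)
  expect_lt(max(abs(sqrt(rowSums(s$F_mem^2)) - abs(Fz)) / abs(Fz)), 1e-3)
})

test_that("bending planes are uncoupled for an isotropic section", {
  p <- beam_params()
  times <- default_times()
  lh <- make_load_history(1 + sin(2 * pi * times), p, times)  # zeta only
  s <- dynamic_solve(p, lh, 2)
  expect_lt(max(abs(s$F_mem[, 1])), 1e-10)   # eta component stays zero
})

test_that("doubling the load history doubles the reaction pointwise", {
  p <- beam_params()
  times <- default_times()
  Fz <- 1 + 0.8 * sin(2 * pi * times) + 0.3 * sin(2 * pi * 4 * times)
  s1 <- dynamic_solve(p, make_load_history(Fz, p, times), 3)
  s2 <- dynamic_solve(p, make_load_history(2 * Fz, p, times), 3)
  expect_equal(s2$F_mem, 2 * s1$F_mem, tolerance = 1e-12)
})

test_that("first natural frequency matches the slender-cantilever estimate", {
  p <- beam_params()  # L/d = 50
  f1 <- natural_frequencies(p, 1)
  analytic <- (1.875^2 / (2 * pi)) * sqrt(p$EI / (p$rho * p$A * p$L^4))
  expect_equal(f1, analytic, tolerance = 0.02)
})

test_that("driving at resonance with light damping amplifies the anchor force", {
  p <- beam_params(alpha_R = 5, beta_R = 1e-5)
  f1 <- natural_frequencies(p, 1)
  times <- default_times()
  Fz <- sin(2 * pi * round(f1) * times)
  s <- dynamic_solve(p, make_load_history(Fz, p, times), 6)
  expect_gt(max(abs(s$F_mem[, 2])), max(abs(Fz)))
})

test_that("unit-response convolution reproduces the full Newmark sweep", {
  p <- beam_params()
  times <- default_times()
  nt <- length(times)
  Fz <- 1.3 + 0.9 * sin(2 * pi * times) + 0.2 * cos(2 * pi * 5 * times)
  s <- dynamic_solve(p, make_load_history(Fz, p, times), 3)

  kernel <- gcxmech:::newmark_reaction_kernel(p, times[2] - times[1], 3 * nt)
  Fseq <- rep(Fz, 3)
  Fseq[seq_len(nt)] <- Fseq[seq_len(nt)] * gcxmech:::startup_ramp(nt)
  r <- gcxmech:::kernel_convolve(kernel, matrix(Fseq, ncol = 1))
  expect_equal(r[(2 * nt + 1):(3 * nt), 1], s$F_mem[, 2], tolerance = 1e-8)
})

test_that("non-uniform time grids and too few cycles are rejected", {
  p <- beam_params()
  bad_times <- c(0, 0.004, 0.009, 0.012)
  expect_error(load_from_wss(matrix(1, 4, 2), p, bad_times), "uniform")
  lh <- make_load_history(1, p)
  expect_error(dynamic_solve(p, lh, 1), "n_cycles")
})
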