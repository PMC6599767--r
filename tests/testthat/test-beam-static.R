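# Static Timoshenko FEM: assembly structure, closed-form verification,
# equilibrium, locking and scaling properties.

test_that("assembled matrices are symmetric with the expected dimension", {
  p <- beam_params(n_elem = 100L)
  sys <- assemble(p)
  expect_equal(sys$ndof, 402L)
  expect_lt(Matrix::norm(sys$K - Matrix::t(sys$K), "F") /
              Matrix::norm(sys$K, "F"), 1e-12)
  expect_lt(Matrix::norm(sys$M - Matrix::t(sys$M), "F") /
              Matrix::norm(sys$M, "F"), 1e-12)
})

test_that("pre-BC stiffness has exactly two zero-energy (rigid body) modes", {
  p <- beam_params(n_elem = 12L)
  sys <- assemble(p)
  ev <- eigen(as.matrix(sys$K), symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev))
  expect_equal(sum(abs(ev) < 1e-9 * scale), 2L)
})

test_that("tip point-load deflection matches the closed-form Timoshenko formula", {
  # spec'd verification case plus a slenderness sweep (no shear locking)
  p0 <- beam_params(L = 50, d = 1, EI = 100, nu = 0.3, kappa = 0.8864)
  s <- static_solve(p0, 0.01, point_load = TRUE)
  expect_equal(s$tip_deflection, 4.1676, tolerance = 1e-4)
  expect_equal(s$tip_deflection, timoshenko_tip_deflection(0.01, p0),
               tolerance = 1e-3)

  for (slenderness in c(5, 50, 200)) {
    d <- 1
    p <- beam_params(L = slenderness * d, d = d, EI = 100)
    s <- static_solve(p, 0.01, point_load = TRUE)
    expect_equal(s$tip_deflection, timoshenko_tip_deflection(0.01, p),
                 tolerance = 1e-3)
  }
})

test_that("distributed top-1/6 load reproduces the influence-function factor", {
  # bending-dominated limit: deflection = 0.291859 F L^3 / EI
  p <- beam_params(L = 200, d = 1, EI = 100)  # slenderness 200
  s <- static_solve(p, 1)
  expect_equal(s$tip_deflection * p$EI / p$L^3, 0.291859, tolerance = 5e-3)
})

test_that("static equilibrium: anchor reaction and moment match the load exactly", {
  set.seed(101)
  p <- beam_params()
  arm <- (1 - p$f_load / 2) * p$L
  for (F in c(runif(5, -5, 5), 1e-4, 37)) {
    s <- static_solve(p, F)
    expect_equal(s$anchor_reaction, F, tolerance = 1e-10)
    expect_equal(s$anchor_moment, F * arm, tolerance = 1e-10)
  }
  # two tangent components at once
  s2 <- static_solve(p, c(0.3, -0.4))
  expect_equal(s2$anchor_reaction, c(0.3, -0.4), tolerance = 1e-10)
})

test_that("static deflection scales as 1/EI over a decade (E, G rescaled together)", {
  # the scaling law is exact; the assertion tolerance reflects the sparse
  # solver's conditioning, not the model
  base <- static_solve(beam_params(EI = 50), 1)$tip_deflection
  for (ei in c(75, 120, 200, 350, 500)) {
    w <- static_solve(beam_params(EI = ei), 1)$tip_deflection
    expect_equal(w, base * 50 / ei, tolerance = 1e-7)
  }
})

test_that("tip deflection is mesh-converged at 100 elements", {
  for (geom in list(c(200, 10), c(50, 10), c(50, 1))) {
    p100 <- beam_params(L = geom[1], d = geom[2], EI = 100, n_elem = 100L)
    p800 <- beam_params(L = geom[1], d = geom[2], EI = 100, n_elem = 800L)
    w100 <- static_solve(p100, 1)$tip_deflection
    w800 <- static_solve(p800, 1)$tip_deflection
    expect_equal(w100, w800, tolerance = 1e-3)
  }
})

test_that("invalid beam geometry is rejected", {
  expect_error(beam_params(L = 0), "positive")
  expect_error(beam_params(d = -1), "positive")
  expect_error(beam_params(f_load = 0), "f_load")
  expect_error(beam_params(n_elem = 0), "n_elem")
})

test_that("beam parameter JSON round-trips", {
  p <- beam_params(L = 123, d = 4.5, EI = 321, rho_b = 1e14)
  path <- withr::local_tempfile(fileext = ".json")
  write_beam_json(p, path)
  q <- read_beam_json(path)
  expect_equal(q[c("L", "d", "EI", "nu", "kappa", "rho_b", "alpha_R",
                   "beta_R", "n_elem", "f_load", "A_cap")],
               p[c("L", "d", "EI", "nu", "kappa", "rho_b", "alpha_R",
                   "beta_R", "n_elem", "f_load", "A_cap")])
})
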