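# Time-domain descriptors and region co-localization.

test_that("local frames are right-handed orthonormal tangent pairs", {
  fr <- local_frame(c(2, 0, 0), c(0, 0, 1))
  expect_equal(fr$zeta, c(1, 0, 0))
  expect_equal(abs(fr$eta), c(0, 1, 0))
  set.seed(7)
  for (k in 1:10) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    v <- rnorm(3); v <- v - sum(v * n) * n   # tangential mean WSS
    fr <- local_frame(v, n)
    expect_equal(sum(fr$eta * fr$zeta), 0, tolerance = 1e-12)
    expect_equal(sqrt(sum(fr$eta^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(fr$zeta^2)), 1, tolerance = 1e-12)
    expect_equal(sum(fr$eta * n), 0, tolerance = 1e-12)
    expect_equal(sum(fr$zeta * n), 0, tolerance = 1e-12)
  }
  expect_error(local_frame(c(0, 0, 0), c(0, 0, 1)), "direction")
})

test_that("TAWSS averages the magnitude: constant, sinusoid and homogeneity", {
  times <- default_times()
  const <- matrix(0, 250, 3); const[, 1] <- 1.5
  expect_equal(tawss(const), 1.5)
  sine <- matrix(0, 250, 3); sine[, 1] <- sin(2 * pi * times)
  expect_equal(tawss(sine), 2 / pi, tolerance = 1e-4)
  expect_equal(tawss(3 * sine), 3 * tawss(sine), tolerance = 1e-12)
  expect_error(tawss(matrix(0, 0, 3)), "empty")
})

test_that("OSI hits its closed-form values and stays in [0, 0.5]", {
  times <- default_times()
  uni <- cbind(1 + 0.5 * sin(2 * pi * times), 0, 0)
  expect_equal(osi(uni), 0, tolerance = 1e-12)
  osc <- cbind(sin(2 * pi * times), 0, 0)
  expect_equal(osi(osc), 0.5, tolerance = 1e-9)
  # +1 Pa for half the cycle, -0.5 Pa for the other half -> 1/3
  half <- cbind(c(rep(1, 125), rep(-0.5, 125)), 0, 0)
  expect_equal(osi(half), 1 / 3, tolerance = 1e-12)
  expect_equal(osi(matrix(0, 250, 3)), 0)
  # property: bounded for arbitrary histories
  set.seed(12)
  for (k in 1:20) {
    h <- matrix(rnorm(750), 250, 3)
    v <- osi(h)
    expect_gte(v, 0); expect_lte(v, 0.5)
  }
})

test_that("TAF matches closed forms for constant-magnitude histories", {
  times <- default_times()
  expect_equal(taf(cbind(rep(2, 250), 0)), 2)
  circle <- cbind(cos(2 * pi * times), sin(2 * pi * times))
  expect_equal(taf(circle), 1, tolerance = 1e-12)
})

test_that("F_ratio averages the pointwise ratio with the eps_F exclusion rule", {
  times <- default_times()
  f <- cbind(1 + 0.5 * sin(2 * pi * times), 0)
  expect_equal(as.numeric(f_ratio(f, f)), 1)
  expect_equal(as.numeric(f_ratio(2 * f, f)), 2, tolerance = 1e-12)
  # |F_mem| = 1, |F_shear| = 1 + 0.5 sin -> 1/sqrt(1 - 0.25)
  ones <- cbind(rep(1, 250), 0)
  expect_equal(as.numeric(f_ratio(ones, f)), 1 / sqrt(0.75), tolerance = 1e-6)
  # exclusion accounting
  fz <- f; fz[1:25, 1] <- 0
  r <- f_ratio(ones, fz)
  expect_equal(attr(r, "excluded_fraction"), 0.1)
  expect_error(f_ratio(ones, 0 * ones), "excluded")
})

test_that("OFI mirrors OSI on force histories", {
  times <- default_times()
  expect_equal(ofi(cbind(1 + 0.2 * cos(2 * pi * times), 0)), 0, tolerance = 1e-12)
  expect_equal(ofi(cbind(sin(2 * pi * times), 0)), 0.5, tolerance = 1e-9)
  expect_equal(ofi(matrix(0, 250, 2)), 0)
})

test_that("area-weighted percentile regions select the expected vertices", {
  # equal areas, values = vertex index: q = 20 selects the lowest fifth
  areas <- rep(0.5, 100)
  reg <- percentile_region(1:100, areas, 20, "low")
  expect_identical(which(reg$mask), 1:20)
  reg_hi <- percentile_region(1:100, areas, 80, "high")
  expect_identical(which(reg_hi$mask), 81:100)
  expect_equal(reg$SA, sum(areas[1:20]))

  # uniform random values on equal areas: ~20% of the area selected
  set.seed(33)
  vals <- runif(2000)
  r2 <- percentile_region(vals, rep(1, 2000), 20, "low")
  expect_equal(mean(r2$mask), 0.2, tolerance = 0.05)

  # constant map -> empty mask with a warning
  expect_warning(rc <- percentile_region(rep(1, 50), rep(1, 50), 20, "low"),
                 "empty")
  expect_false(any(rc$mask))
  expect_error(percentile_region(1:10, rep(1, 10), 0, "low"), "q must")
})

test_that("similarity index: identical, disjoint, half-overlap, symmetry", {
  areas <- rep(1, 40)
  a <- c(rep(TRUE, 10), rep(FALSE, 30))
  b <- c(rep(FALSE, 30), rep(TRUE, 10))
  half <- c(rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 25))
  expect_equal(similarity_index(a, a, areas), 1)
  expect_equal(similarity_index(a, b, areas), 0)
  expect_equal(similarity_index(a, half, areas), 0.5)
  expect_equal(similarity_index(a, half, areas),
               similarity_index(half, a, areas))
  expect_error(similarity_index(rep(FALSE, 40), rep(FALSE, 40), areas),
               "empty")
  # monotone under growing overlap at fixed region sizes
  si_prev <- -1
  for (shift in c(9, 6, 3, 0)) {
    m2 <- c(rep(FALSE, shift), rep(TRUE, 10), rep(FALSE, 30 - shift))
    si <- similarity_index(a, m2, areas)
    expect_gte(si, si_prev)
    si_prev <- si
  }
})

test_that("descriptors are invariant under rigid rotation of mesh and field", {
  m <- small_mesh()
  f <- synthesize_wss_field(m, phenotype_ramp(m), seed = 21)
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  i <- 17
  tau_i <- cbind(f$tau[i, , 1], f$tau[i, , 2], f$tau[i, , 3])
  tau_rot <- tau_i %*% t(R)
  expect_equal(tawss(tau_rot), tawss(tau_i), tolerance = 1e-12)
  expect_equal(osi(tau_rot), osi(tau_i), tolerance = 1e-12)
  # frame-projected components have rotation-invariant magnitudes
  n_rot <- as.numeric(R %*% m$normals[i, ])
  fr <- local_frame(colMeans(tau_i), m$normals[i, ])
  fr_rot <- local_frame(colMeans(tau_rot), n_rot)
  c1 <- project_to_frame(tau_i, fr)
  c2 <- project_to_frame(tau_rot, fr_rot)
  expect_equal(rowSums(c1^2), rowSums(c2^2), tolerance = 1e-12)
})
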