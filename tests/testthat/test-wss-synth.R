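# Waveform generator and synthetic WSS fields.

test_that("a pure-mean waveform is constant and any series is T-periodic", {
  spec <- waveform_spec(a0 = 1.2)
  t <- seq(0, 2, by = 0.01)
  expect_equal(waveform_magnitude(t, spec), rep(1.2, length(t)))

  spec2 <- protective_spec()
  t <- seq(0, 0.996, by = 0.004)
  expect_equal(waveform_magnitude(t, spec2),
               waveform_magnitude(t + spec2$T, spec2), tolerance = 1e-12)
})

test_that("default phenotype waveforms hit the intended magnitude bands", {
  tg <- default_times()
  prot <- waveform_magnitude(tg, protective_spec())
  expect_gt(max(prot), 2.0)
  expect_lt(max(prot), 3.0)
  prone <- waveform_magnitude(tg, prone_spec())
  expect_lt(max(abs(prone)), 0.4)
})

test_that("waveform_spec validates its invariants", {
  expect_error(waveform_spec(T = -1), "positive")
  expect_error(waveform_spec(dt = 0.003), "divide")
  expect_error(waveform_spec(amplitudes = c(0.2, -0.1)), "amplitudes")
  expect_error(waveform_spec(direction_osc = 1.2), "direction_osc")
  expect_error(waveform_spec(direction_osc = 0.3, reversal_fraction = 0.2),
               "reversal")
})

test_that("identical seeds give bitwise-identical fields", {
  m <- small_mesh()
  phen <- phenotype_ramp(m)
  f1 <- synthesize_wss_field(m, phen, seed = 42)
  f2 <- synthesize_wss_field(m, phen, seed = 42)
  expect_identical(f1$tau, f2$tau)
  f3 <- synthesize_wss_field(m, phen, seed = 43)
  expect_false(identical(f1$tau, f3$tau))
})

test_that("fields are tangential at every vertex and instant", {
  m <- small_mesh()
  f <- synthesize_wss_field(m, phenotype_ramp(m), seed = 5)
  dots <- abs(f$tau[, , 1] * m$normals[, 1] + f$tau[, , 2] * m$normals[, 2] +
                f$tau[, , 3] * m$normals[, 3])
  mags <- sqrt(f$tau[, , 1]^2 + f$tau[, , 2]^2 + f$tau[, , 3]^2)
  expect_true(all(dots < 1e-9 * pmax(mags, 1e-300)))
})

test_that("a pure protective field without oscillation is unidirectional (OSI = 0)", {
  m <- small_mesh()
  f <- synthesize_wss_field(m, rep(0, nrow(m$vertices)), seed = 2)
  osis <- vapply(seq_len(nrow(m$vertices)), function(i) {
    osi(cbind(f$tau[i, , 1], f$tau[i, , 2], f$tau[i, , 3]))
  }, numeric(1))
  expect_true(all(osis < 1e-12))
})

test_that("the default prone field reverses its flow-aligned component every cycle", {
  m <- small_mesh()
  nv <- nrow(m$vertices)
  f <- synthesize_wss_field(m, rep(1, nv), seed = 9)
  zeta0 <- gcxmech:::base_flow_direction(m)
  for (i in seq_len(nv)) {
    zc <- cbind(f$tau[i, , 1], f$tau[i, , 2], f$tau[i, , 3]) %*% zeta0[i, ]
    expect_lt(min(zc), 0)
    expect_gt(max(zc), 0)
  }
})

test_that("protective cycle-average magnitude exceeds prone by at least 4x", {
  m <- small_mesh()
  nv <- nrow(m$vertices)
  fp <- synthesize_wss_field(m, rep(0, nv), seed = 3)
  fb <- synthesize_wss_field(m, rep(1, nv), seed = 3)
  mag <- function(f) mean(sqrt(f$tau[, , 1]^2 + f$tau[, , 2]^2 + f$tau[, , 3]^2))
  expect_gt(mag(fp) / mag(fb), 4)
})

test_that("mismatched phenotype map or periods are rejected", {
  m <- small_mesh()
  expect_error(synthesize_wss_field(m, rep(0.5, 3)), "length")
  expect_error(
    synthesize_wss_field(m, rep(0.5, nrow(m$vertices)),
                         protective_spec = protective_spec(T = 1),
                         prone_spec = prone_spec(T = 0.8)),
    "share")
})

test_that("CSV + JSON round-trip preserves the field to 1e-9 relative", {
  m <- build_patch_mesh(3, 5, 1, 2)
  f <- synthesize_wss_field(m, phenotype_ramp(m), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_wss_csv(f, path)
  back <- read_wss_csv(path, m)
  expect_equal(back$tau, f$tau, tolerance = 1e-9)
  expect_equal(back$times, f$times, tolerance = 1e-12)
  expect_equal(back$meta$seed, 11L)
})
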