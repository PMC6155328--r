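# Normal-mode bases: diagonalization, Eckart projection, transforms, ZPE.

test_that("a one-mode surrogate Hessian yields the prescribed frequency", {
  spec <- model_spec(0.01, ci_alphas = 0.5)
  pes <- make_harmonic_surrogate(spec)
  dir <- withr::local_tempdir()
  emit_fixture_files(pes, dir)
  fx <- read_surrogate_fixtures(dir)
  expect_identical(fx$basis$n_modes, 1L)
  expect_equal(fx$basis$frequencies, 0.01, tolerance = 1e-10)
})

test_that("surrogate frequencies are recovered through the file round trip", {
  spec <- model_spec(c(0.002, 0.01), ci_alphas = c(0.5, 0.8))
  dir <- withr::local_tempdir()
  emit_fixture_files(make_harmonic_surrogate(spec), dir)
  fx <- read_surrogate_fixtures(dir)
  expect_equal(fx$basis$frequencies, c(0.002, 0.01), tolerance = 1e-8)
})

test_that("doubling all masses scales frequencies by 1/sqrt(2)", {
  g <- water_like_geometry()
  h <- synthetic_molecular_hessian(g, seed = 5)
  b <- build_modes(h)
  g2 <- geometry(g$elements, g$coords, masses = 2 * g$masses)
  b2 <- build_modes(hessian_record(h$matrix, g2))
  expect_equal(b2$frequencies, b$frequencies / sqrt(2), tolerance = 1e-10)
})

test_that("frequencies are invariant under rigid rotation of geometry and Hessian", {
  g <- water_like_geometry()
  h <- synthetic_molecular_hessian(g, seed = 7)
  b <- build_modes(h)
  set.seed(2)
  for (k in 1:5) {
    rot <- rotate_system(g, h, rotation_z(runif(1, 0, 2 * pi)))
    b2 <- build_modes(rot$hessian)
    expect_equal(b2$frequencies, b$frequencies, tolerance = 1e-9)
  }
})

test_that("mode vectors are orthonormal and orthogonal to rigid motions", {
  g <- water_like_geometry()
  b <- build_modes(synthetic_molecular_hessian(g, seed = 9))
  expect_lt(max(abs(b$L %*% t(b$L) - diag(b$n_modes))), 1e-8)
  V <- ciaccess:::.eckart_vectors(g)
  expect_lt(max(abs(b$L %*% V)), 1e-8)
  expect_identical(b$n_modes, 3L)  # 3N - 6
})

test_that("negative curvature triggers the not-a-minimum error", {
  g <- water_like_geometry()
  h <- synthetic_molecular_hessian(g, seed = 5)
  expect_error(build_modes(hessian_record(-h$matrix, g)), "not a minimum")
})

test_that("normal-coordinate transforms are exact round trips", {
  g <- water_like_geometry()
  b <- build_modes(synthetic_molecular_hessian(g, seed = 3))

  expect_lt(max(abs(to_normal_coords(b, g))), 1e-12)

  # rigidly moved copy projects to Q = 0 after superposition
  g2 <- geometry(g$elements,
                 g$coords %*% rotation_z(0.4) + matrix(c(1, -1, 2), 3, 3, byrow = TRUE))
  expect_lt(max(abs(to_normal_coords(b, g2))), 1e-10)

  # displacement along mode k maps to a unit vector in Q
  for (k in seq_len(b$n_modes)) {
    delta <- 0.37
    gq <- from_normal_coords(b, replace(rep(0, b$n_modes), k, delta))
    q <- to_normal_coords(b, gq)
    expect_equal(q[k], delta, tolerance = 1e-10)
    expect_lt(max(abs(q[-k])), 1e-10)
  }

  expect_error(to_normal_coords(b, geometry("H", matrix(0, 1, 3))),
               "different atoms")
})

test_that("harmonic energy is the additive quadratic form", {
  b <- list(frequencies = c(0.01), n_modes = 1L)
  class(b) <- "normal_mode_basis"
  expect_equal(harmonic_energy(b, 0), 0)
  expect_equal(harmonic_energy(b, 1), 5e-5)
  b2 <- list(frequencies = c(0.002, 0.01), n_modes = 2L)
  class(b2) <- "normal_mode_basis"
  expect_equal(harmonic_energy(b2, c(0.3, 0.7)),
               harmonic_energy(b, 0.7) + 0.5 * 0.002^2 * 0.09)
})

test_that("harmonic energy matches the surrogate surface for random displacements", {
  spec <- model_spec(c(0.003, 0.007, 0.012), ci_alphas = c(0.4, 0.6, 0.8))
  pes <- make_harmonic_surrogate(spec)
  dir <- withr::local_tempdir()
  emit_fixture_files(pes, dir)
  fx <- read_surrogate_fixtures(dir)
  set.seed(6)
  for (k in 1:10) {
    q <- rnorm(3, sd = 5)
    g <- surrogate_geometry(pes, q)
    qq <- to_normal_coords(fx$basis, g, align = FALSE)
    expect_equal(harmonic_energy(fx$basis, qq), pes$energy(q, 2), tolerance = 1e-10)
  }
})

test_that("zero-point energies are omega/2 per mode and drop under deuteration", {
  b <- list(frequencies = c(0.002, 0.01), n_modes = 2L)
  class(b) <- "normal_mode_basis"
  z <- zpe(b)
  expect_equal(z$per_mode, c(0.001, 0.005))
  expect_equal(z$total, 0.006)

  g <- water_like_geometry()
  h <- synthetic_molecular_hessian(g, seed = 5)
  zh <- zpe(build_modes(h))
  gd <- set_masses(g, c(1, 2), element_masses("D"))
  zd <- zpe(build_modes(hessian_record(h$matrix, gd)))
  expect_true(all(zd$per_mode < zh$per_mode))
})

test_that("the mode table reports consistent unit conversions", {
  g <- water_like_geometry()
  b <- build_modes(synthetic_molecular_hessian(g, seed = 5))
  tab <- mode_table(b)
  expect_identical(nrow(tab), b$n_modes)
  expect_equal(tab$omega_cm1, tab$omega_au * au$cm1_per_hartree)
  expect_equal(tab$zpe_hartree, tab$omega_au / 2)
})
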