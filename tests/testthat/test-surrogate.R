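# Surrogate model construction, ground truth, variant pairs, fixture files.

test_that("model specs validate their invariants", {
  expect_error(model_spec(c(0.01, -0.002), ci_alphas = c(0.5, 0.5)), "positive")
  expect_error(model_spec(numeric(0), ci_alphas = numeric(0)), "non-empty")
  expect_error(model_spec(0.01, ci_alphas = 0.5, state2_offset = 0.1), "negative")
  expect_error(model_spec(0.01, ci_alphas = 0.5, coupling_width = 0), "coupling_width")
  expect_error(model_spec(0.01), "exactly one")
  expect_error(model_spec(0.01, ci_alphas = 0.5, ci_displacement = 1), "exactly one")
  # inconsistent prescribed barrier is an infeasible spec
  expect_error(model_spec(0.01, ci_alphas = 0.5, barrier_target = 0.9),
               "infeasible")
  expect_error(model_spec(0.01, ci_alphas = 0.5, barrier_target = -0.1),
               "infeasible")
  # consistent barrier is accepted
  s <- model_spec(0.01, ci_alphas = 0.5, barrier_target = 0.5 * 0.01 / 2)
  expect_equal(s$barrier_target, 0.0025)
})

test_that("both states pass exactly through the prescribed CI at the target barrier", {
  freqs <- c(0.0008, 0.0016, 0.0032, 0.0064)
  barrier <- ev_to_hartree(0.13)
  spec <- model_spec(freqs,
                     ci_alphas = scale_alphas_to_barrier(freqs, rep(1, 4), barrier))
  pes <- make_harmonic_surrogate(spec)
  expect_equal(pes$energy(spec$ci_displacement, 2), barrier, tolerance = 1e-14)
  expect_equal(pes$energy(spec$ci_displacement, 3), barrier, tolerance = 1e-14)
  expect_equal(abs(pes$energy(spec$ci_displacement, 2) -
                   pes$energy(spec$ci_displacement, 3)), 0)
  # state B's minimum is at the prescribed offset
  expect_equal(pes$energy(pes$state2_min, 3), spec$state2_offset)
})

test_that("analytic gradients match finite differences at random points", {
  spec <- random_model_spec(21)
  pes <- make_harmonic_surrogate(spec)
  set.seed(22)
  pts <- replicate(5, rnorm(spec$n_modes, sd = 10), simplify = FALSE)
  expect_true(check_pes_gradients(pes, pts, rel_tol = 1e-6))
})

test_that("ground-truth alphas are recovered by the in-memory pipeline to 1e-10", {
  for (seed in 1:100) {
    spec <- random_model_spec(seed)
    pes <- make_harmonic_surrogate(spec)
    n <- spec$n_modes
    H <- matrix(0, 3 * n, 3 * n)
    for (i in seq_len(n)) H[3 * i - 2, 3 * i - 2] <- spec$frequencies[i]^2
    basis <- suppressMessages(
      build_modes(hessian_record(H, surrogate_geometry(pes)), project = "none"))
    rep <- accessibility_report(basis,
                                surrogate_geometry(pes, spec$ci_displacement),
                                align = FALSE)
    expect_equal(sort(rep$modes$alpha), sort(pes$alphas), tolerance = 1e-10)
  }
})

test_that("variant pairs satisfy their contract", {
  spec <- napa_like_spec()

  # empty rigid list: identical systems, both fully accessible
  vp0 <- make_variant_pair(spec)
  expect_equal(vp0$flexible$alphas, vp0$rigid$alphas)
  expect_equal(vp0$rigid_total_p, 1)
  expect_true(all(vp0$flexible$alphas <= 1))

  # one mode pushed to alpha = 2
  vp1 <- make_variant_pair(spec, rigid_modes = 1, rigid_alphas = 2)
  expect_equal(vp1$rigid$alphas[1], 2, tolerance = 1e-12)
  expect_equal(vp1$rigid$alphas[-1], spec$frequencies[-1] * spec$ci_displacement[-1]^2,
               tolerance = 1e-12)
  expect_equal(vp1$rigid_total_p, 0.6861, tolerance = 1e-4)

  # four modes tuned by root-finding to a 0.10 total probability
  astar <- rigid_alphas_for_probability(0.10, 4)
  vp4 <- make_variant_pair(spec, rigid_modes = 1:4, rigid_alphas = rep(astar, 4))
  expect_equal(vp4$rigid_total_p, 0.10, tolerance = 1e-10)

  expect_error(make_variant_pair(spec, rigid_modes = 1, rigid_alphas = 0.9),
               "exceed 1")
  expect_error(make_variant_pair(spec, rigid_modes = 99, rigid_alphas = 2),
               "out of range")
})

test_that("fixture files round-trip frequencies, Hessian symmetry and alphas", {
  spec <- model_spec(c(0.002, 0.01), ci_alphas = c(0.5, 0.8))
  pes <- make_harmonic_surrogate(spec)
  dir <- withr::local_tempdir()
  paths <- emit_fixture_files(pes, dir)
  expect_true(all(file.exists(paths)))

  fx <- read_surrogate_fixtures(dir)
  expect_equal(fx$basis$frequencies, spec$frequencies, tolerance = 1e-8)
  expect_equal(fx$basis$n_modes, 2L)

  h <- read_hessian(file.path(dir, "hessian.dat"), fx$reference)
  expect_identical(max(abs(h$matrix - t(h$matrix))), 0)

  rep <- accessibility_report(fx$basis, fx$ci, align = FALSE)
  expect_equal(sort(rep$modes$alpha), sort(pes$alphas), tolerance = 1e-8)

  expect_error(emit_fixture_files(pes, file.path(tempfile(), "no", "such", "deep")),
               NA)  # directory is created on demand
})

test_that("spec serialization round-trips and rejects unknown keys", {
  spec <- random_model_spec(33)
  path <- withr::local_tempfile(fileext = ".yml")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$frequencies, spec$frequencies)
  expect_equal(back$ci_displacement, spec$ci_displacement)
  expect_equal(back$barrier_target, spec$barrier_target)
  writeLines(c(readLines(path), "mystery_knob: 3"), path)
  expect_error(read_model_spec(path), "unknown spec key")
})

test_that("seam points generated analytically are degenerate to machine precision", {
  pes <- make_harmonic_surrogate(napa_like_spec())
  pts <- surrogate_seam_points(pes, k = 3, step = 1.5)
  for (q in pts) {
    expect_lt(abs(pes$energy(q, 2) - pes$energy(q, 3)), 1e-12)
  }
})
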