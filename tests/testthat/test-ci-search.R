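# MECI / MDCI penalty optimization, state minimization, seam expansion and
# projection, on the analytic two-paraboloid model and on surrogates.

test_that("the MECI of the two-paraboloid model is recovered", {
  pes <- two_paraboloid_pes()
  m <- optimize_meci(pes, start = c(3, 2), states = c(1, 2), gap_tol = 1e-8)
  expect_equal(m$point, c(1, 0), tolerance = 1e-6)
  expect_equal(m$energy, 0.5, tolerance = 1e-6)
  expect_lt(m$gap, 1e-5)
  expect_true(m$strict)

  # a point already at the seam's mean-energy minimum is a fixed point
  m2 <- optimize_meci(pes, start = c(1, 0), states = c(1, 2), gap_tol = 1e-8)
  expect_equal(m2$point, c(1, 0), tolerance = 1e-8)
})

test_that("MDCI lands on the foot of the perpendicular", {
  pes <- two_paraboloid_pes()
  d0 <- optimize_mdci(pes, reference = c(0, 0), states = c(1, 2), gap_tol = 1e-8)
  expect_equal(d0$point, c(1, 0), tolerance = 1e-6)
  expect_equal(d0$distance, 1, tolerance = 1e-6)

  d3 <- optimize_mdci(pes, reference = c(0, 3), states = c(1, 2), gap_tol = 1e-8)
  expect_equal(d3$point, c(1, 3), tolerance = 1e-6)

  don <- optimize_mdci(pes, reference = c(1, -2), states = c(1, 2), gap_tol = 1e-8)
  expect_lt(don$distance, 1e-6)
})

test_that("MDCI distance matches a brute-force scan over the seam", {
  pes <- two_paraboloid_pes()
  ref <- c(-0.7, 1.3)
  d <- optimize_mdci(pes, reference = ref, states = c(1, 2), gap_tol = 1e-8)
  ys <- seq(-5, 5, by = 1e-4)
  brute <- min(sqrt((1 - ref[1])^2 + (ys - ref[2])^2))
  expect_equal(d$distance, brute, tolerance = 1e-4)
})

test_that("the surrogate MECI energy equals the prescribed barrier", {
  spec <- napa_like_spec()
  pes <- make_harmonic_surrogate(spec)
  m <- optimize_meci(pes, start = spec$ci_displacement * 0.9, states = c(2, 3),
                     gap_tol = 1e-9)
  expect_lt(m$gap, 1e-5)
  expect_equal(m$energy, spec$barrier_target, tolerance = 1e-6)
})

test_that("single-state minimization descends to the analytic minima", {
  pes <- two_paraboloid_pes()
  r <- minimize_on_state(pes, 1, c(5, 5))
  expect_equal(r$point, c(0, 0), tolerance = 1e-6)
  expect_lt(r$gnorm, 1e-6)

  spec <- napa_like_spec()
  spes <- make_harmonic_surrogate(spec)
  # curvatures down at 1.6e-7 hartree/unit^2: a 1e-6 gradient norm still
  # leaves a visible positional slack, so compare accordingly
  rb <- minimize_on_state(spes, 3, spec$ci_displacement)
  expect_equal(rb$point, spes$state2_min, tolerance = 1e-3)
  expect_equal(rb$energy, spec$state2_offset, tolerance = 1e-6)

  r0 <- minimize_on_state(pes, 1, c(0, 0))
  expect_equal(r0$point, c(0, 0), tolerance = 1e-8)
})

test_that("non-convergent penalty optimization reports a trace", {
  # state pair that never becomes degenerate: parallel surfaces
  pes <- pes_backend(
    energy = function(x, state) 0.5 * sum(x^2) + (state - 1) * 0.5,
    n_states = 2,
    gradient = function(x, state) x
  )
  expect_error(optimize_meci(pes, c(1, 1), states = c(1, 2), sigma_cap = 1e4),
               "did not reach gap tolerance")
})

test_that("seam expansion keeps accessible midpoints and logs discards", {
  pes <- two_paraboloid_pes()
  # seam is x = 1; both seeds accessible under loose frequencies
  seeds <- list(c(1, 0), c(1, 2))
  seam <- expand_seam(pes, seeds, frequencies = c(0.05, 0.05), rounds = 1,
                      states = c(1, 2))
  expect_gt(length(seam$points), 2)
  mids <- vapply(seam$points, function(p) p$point[2], 1.0)
  expect_true(any(abs(mids - 1) < 1e-3))  # the lambda = 0.5 combination
  expect_true(all(vapply(seam$points, function(p) abs(p$point[1] - 1) < 1e-3, TRUE)))
  expect_true(all(c("round", "kept", "reason") %in% names(seam$log)))

  # a tight frequency makes distant points inaccessible: they must be logged out
  seam2 <- expand_seam(pes, seeds, frequencies = c(0.05, 0.3), rounds = 1,
                       states = c(1, 2))
  expect_lt(length(seam2$points), length(seam$points))
  expect_gt(sum(!seam2$log$kept), 0)
  expect_true(any(grepl("accessibility", seam2$log$reason)))
})

test_that("relaxing the accessibility filter never shrinks the retained set", {
  pes <- two_paraboloid_pes()
  seeds <- list(c(1, 0), c(1, 2))
  strict <- expand_seam(pes, seeds, frequencies = c(0.05, 0.3), rounds = 1,
                        states = c(1, 2), filter = "strict")
  relaxed <- expand_seam(pes, seeds, frequencies = c(0.05, 0.3), rounds = 1,
                         states = c(1, 2), filter = "total_p", p_threshold = 0)
  expect_gte(length(relaxed$points), length(strict$points))
})

test_that("the flexible member of a variant pair grows a strictly larger seam set", {
  spec <- napa_like_spec()
  astar <- rigid_alphas_for_probability(0.10, 4)
  vp <- make_variant_pair(spec, rigid_modes = 1:4, rigid_alphas = rep(astar, 4))
  sf <- expand_seam(vp$flexible, surrogate_seam_points(vp$flexible, k = 2, step = 2),
                    rounds = 1)
  sr <- expand_seam(vp$rigid, surrogate_seam_points(vp$rigid, k = 2, step = 2),
                    rounds = 1)
  expect_gt(length(sf$points), length(sr$points))
  man <- seam_manifest(sf)
  expect_true(all(man$gap <= ev_to_hartree(0.02) + 1e-12))
})

test_that("2D projection conserves members and separates gap shades", {
  pes <- two_paraboloid_pes()
  seeds <- list(c(1, 0), c(1, 2))
  seam <- expand_seam(pes, seeds, frequencies = c(0.05, 0.05), rounds = 1,
                      states = c(1, 2))
  grid <- project_seam_2d(seam, axes = list(function(q) q[1], function(q) q[2]),
                          breaks = 8)
  expect_equal(sum(grid$count), length(seam$points))
  expect_true(all(grid$loose))

  single <- structure(list(points = seam$points[1], log = seam$log,
                           frequencies = c(0.05, 0.05)), class = "seam_set")
  g1 <- project_seam_2d(single, axes = list(function(q) q[1], function(q) q[2]))
  expect_identical(nrow(g1), 1L)
  expect_identical(g1$count, 1L)

  # an axis that fails on some member: member skipped and logged
  g2 <- project_seam_2d(seam, axes = list(
    function(q) if (q[2] > 1.9) stop("undefined coordinate") else q[1],
    function(q) q[2]))
  expect_lt(sum(g2$count), length(seam$points))
  expect_gt(nrow(attr(g2, "skipped")), 0)
})

test_that("seam sets serialize to XYZ members plus a manifest", {
  spec <- model_spec(c(0.002, 0.01), ci_alphas = c(0.5, 0.8))
  pes <- make_harmonic_surrogate(spec)
  seam <- expand_seam(pes, surrogate_seam_points(pes, k = 1, step = 1), rounds = 1)
  dir <- withr::local_tempdir()
  man_path <- write_seam_set(seam, dir, to_geometry = function(q) surrogate_geometry(pes, q))
  expect_true(file.exists(man_path))
  expect_identical(length(list.files(dir, pattern = "^ci_.*xyz$")),
                   length(seam$points))
  man <- utils::read.csv(man_path)
  expect_identical(nrow(man), length(seam$points))
})
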