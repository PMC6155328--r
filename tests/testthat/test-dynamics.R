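# Wigner sampling, surface hopping, single-surface propagation, passage
# classification.

test_that("Wigner samples have the ground-state moments and are reproducible", {
  omega <- c(0.002, 0.01)
  ws <- wigner_sample(omega, n = 20000, seed = 5)
  # means within 4 sigma / sqrt(n)
  for (k in 1:2) {
    expect_lt(abs(mean(ws$positions[, k])), 4 * sqrt(1 / (2 * omega[k])) / sqrt(20000))
    expect_lt(abs(mean(ws$momenta[, k])), 4 * sqrt(omega[k] / 2) / sqrt(20000))
  }
  # mean energy per mode = ZPE = omega/2 within Monte-Carlo error
  e <- colMeans(0.5 * ws$momenta^2 +
                  0.5 * matrix(omega^2, 20000, 2, byrow = TRUE) * ws$positions^2)
  expect_equal(e, omega / 2, tolerance = 0.03)

  expect_identical(ws, wigner_sample(omega, 20000, seed = 5))
  expect_error(wigner_sample(c(0.01, -0.1), 10, 1), "positive")

  center <- c(3, -1)
  wc <- wigner_sample(omega, 5000, seed = 2, center = center)
  expect_equal(colMeans(wc$positions), center, tolerance = 0.5)
})

test_that("a zero-coupling model conserves energy, norm and populations", {
  w <- 0.001
  m <- diab_model(e0 = c(0, 1), centers = matrix(0, 2, 1),
                  quad = matrix(w^2, 2, 1), coupling_strength = 0)
  amp <- sqrt(1 / (2 * w))  # classical turning point of the ZPE orbit
  ens <- propagate_fssh(m, matrix(amp, 1, 1), matrix(0, 1, 1),
                        dt_fs = 0.25, t_max_fs = 2500, seed = 1,
                        record_stride = 10)
  expect_identical(nrow(ens$hops), 0L)
  expect_lt(ens$final$max_energy_drift, 1e-8)          # 1e4 steps
  expect_lt(ens$final$max_norm_dev, 1e-6)
  expect_lt(max(abs(ens$trajectories[[1]]$pop_lower - 1)), 1e-10)
  expect_false(ens$final$aborted)
})

test_that("single-surface propagation reproduces the harmonic period", {
  w <- 0.001
  m <- diab_model(e0 = c(0, 1), centers = matrix(0, 2, 1),
                  quad = matrix(w^2, 2, 1), coupling_strength = 0)
  amp <- 5
  tr <- propagate_adiabatic(m, matrix(amp, 1, 1), matrix(0, 1, 1), state = 1,
                            dt_fs = 0.25, t_max_fs = 320, record_stride = 1)
  expect_lt(tr$summary$max_energy_drift, 1e-8)
  x <- tr$trajectories[[1]]
  # locate the first return maximum by quadratic interpolation
  xs <- x$q1
  idx <- which(diff(sign(diff(xs))) < 0) + 1L
  i <- idx[which.min(abs(x$time_fs[idx] - aut_to_fs(2 * pi / w)))]
  tt <- x$time_fs[(i - 1):(i + 1)]
  xx <- xs[(i - 1):(i + 1)]
  tpeak <- tt[2] - 0.5 * diff(tt)[1] * (xx[3] - xx[1]) / (xx[1] - 2 * xx[2] + xx[3])
  expect_equal(tpeak, aut_to_fs(2 * pi / w), tolerance = 1e-3)

  still <- propagate_adiabatic(m, matrix(0, 1, 1), matrix(0, 1, 1), state = 1,
                               dt_fs = 0.25, t_max_fs = 25, record_stride = 1)
  expect_lt(max(abs(still$trajectories[[1]]$q1)), 1e-14)
})

test_that("amplitude norm is conserved through a strongly coupled crossing", {
  lz <- lz_oracle_setup()
  ens <- propagate_fssh(lz$model, matrix(lz$x0, 20, 1), matrix(lz$v0, 20, 1),
                        dt_fs = lz$dt_fs, t_max_fs = lz$t_max_fs, seed = 3,
                        record_stride = 5)
  expect_lt(max(ens$final$max_norm_dev), 1e-6)
  expect_true(all(abs(ens$trajectories[[1]]$norm - 1) < 1e-6))
  # accepted hops conserve total energy by construction: drift stays tiny
  expect_lt(max(ens$final$max_energy_drift), 1e-3)
  # populations sum to one by bookkeeping
  expect_equal(ens$populations$pop_lower + ens$populations$pop_upper,
               rep(1, nrow(ens$populations)))
})

test_that("trajectories are reproduced bit-identically under a fixed seed", {
  lz <- lz_oracle_setup()
  e1 <- propagate_fssh(lz$model, matrix(lz$x0, 5, 1), matrix(lz$v0, 5, 1),
                       dt_fs = lz$dt_fs, t_max_fs = lz$t_max_fs, seed = 42,
                       record_stride = 5)
  e2 <- propagate_fssh(lz$model, matrix(lz$x0, 5, 1), matrix(lz$v0, 5, 1),
                       dt_fs = lz$dt_fs, t_max_fs = lz$t_max_fs, seed = 42,
                       record_stride = 5)
  expect_identical(e1$trajectories, e2$trajectories)
  expect_identical(e1$hops, e2$hops)
  expect_identical(e1$seeds, e2$seeds)
})

test_that("Wigner-initialized hop-free runs from a CI log their minimum gaps", {
  spec <- model_spec(c(0.003, 0.008), ci_alphas = c(0.5, 0.7),
                     coupling_strength = 1e-3, coupling_width = 1)
  pes <- make_harmonic_surrogate(spec)
  model <- surrogate_diab_model(pes)
  ws <- wigner_sample(spec$frequencies, n = 10, seed = 9,
                      center = spec$ci_displacement)
  runs <- propagate_adiabatic(model, ws$positions, ws$momenta, state = 1,
                              dt_fs = 0.25, t_max_fs = 350, record_stride = 10)
  expect_identical(nrow(runs$summary), 10L)
  expect_true(all(is.finite(runs$summary$min_gap)))
  expect_true(all(runs$summary$min_gap >= 0))
})

test_that("passage classification follows the diabatic-preservation rule", {
  # sharp spike: diabatic populations equal before/after -> diabatic event
  mk <- function(gaps, pdiab) {
    tibble::tibble(time_fs = seq_along(gaps) * 0.25, gap = gaps,
                   pop_diab1 = pdiab, coupling = 0)
  }
  t1 <- mk(c(1, 1, 0.01, 1, 1) * 0.1, c(0.9, 0.9, 0.5, 0.9, 0.9))
  ev1 <- classify_passage_events(t1, gap_threshold = 0.05)
  expect_identical(nrow(ev1), 1L)
  expect_identical(ev1$label, "diabatic")

  # wide window with monotone transfer -> adiabatic event
  t2 <- mk(c(1, 0.02, 0.02, 0.02, 1) * 0.1,
           c(0.95, 0.8, 0.5, 0.2, 0.05))
  ev2 <- classify_passage_events(t2, gap_threshold = 0.05)
  expect_identical(ev2$label, "adiabatic")
  expect_gt(ev2$width_fs, 0)

  # three windows -> three events in time order
  g3 <- c(1, 0.01, 1, 0.01, 1, 0.01, 1) * 0.1
  p3 <- c(0.9, 0.9, 0.9, 0.5, 0.2, 0.2, 0.2)
  ev3 <- classify_passage_events(mk(g3, p3), gap_threshold = 0.05)
  expect_identical(nrow(ev3), 3L)
  expect_true(!is.unsorted(ev3$t_start_fs))
  expect_identical(ev3$label, c("diabatic", "adiabatic", "diabatic"))

  # no close approach: empty classification
  ev0 <- classify_passage_events(mk(rep(0.5, 4), rep(0.9, 4)), gap_threshold = 0.05)
  expect_identical(nrow(ev0), 0L)
})

test_that("ensemble tables serialize to CSV and JSON lines", {
  lz <- lz_oracle_setup()
  ens <- propagate_fssh(lz$model, matrix(lz$x0, 3, 1), matrix(lz$v0, 3, 1),
                        dt_fs = lz$dt_fs, t_max_fs = lz$t_max_fs, seed = 1,
                        record_stride = 10)
  dir <- withr::local_tempdir()
  paths <- write_ensemble(ens, dir)
  expect_true(all(file.exists(paths)))
  pops <- utils::read.csv(paths[1])
  expect_equal(nrow(pops), nrow(ens$populations))
})
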