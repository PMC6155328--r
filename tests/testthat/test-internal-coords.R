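# Bonds / angles / dihedrals, linear interpolation paths, affine combination.

# 4-atom chain with a controllable dihedral (degrees).
chain_with_dihedral <- function(phi_deg) {
  phi <- phi_deg * pi / 180
  theta <- 1.9  # bond angle in radians
  geometry(rep("C", 4), matrix(c(
    1.4 * cos(theta), 1.4 * sin(theta), 0,
    0, 0, 0,
    1.5, 0, 0,
    1.5 + 1.4 * cos(pi - theta),
    1.4 * sin(pi - theta) * cos(phi),
    1.4 * sin(pi - theta) * sin(phi)), 4, 3, byrow = TRUE))
}

test_that("dihedrals follow the sign convention and its symmetries", {
  cis <- matrix(c(1, 0, 0, 0, 0, 0, 0, 1, 0, 1, 1, 0), 4, 3, byrow = TRUE)
  expect_equal(dihedral_angle(cis), 0)
  trans <- cis
  trans[4, ] <- c(-1, 1, 0)
  expect_equal(dihedral_angle(trans), 180)

  g <- geometry(rep("C", 4), cis)
  expect_equal(ic_value(g, internal_coordinate("dihedral", 0:3)),
               ic_value(g, internal_coordinate("dihedral", 3:0)))

  coll <- cis
  coll[1, ] <- c(0, -1, 0)  # A-B-C collinear
  expect_error(dihedral_angle(coll), "collinear")
})

test_that("dihedral values are invariant under random rigid motions", {
  g <- chain_with_dihedral(63)
  ic <- internal_coordinate("dihedral", 0:3)
  ref <- ic_value(g, ic)
  set.seed(8)
  for (k in 1:10) {
    axis_angle <- runif(1, 0, 2 * pi)
    R <- rotation_z(axis_angle) %*%
      matrix(c(1, 0, 0, 0, cos(k), -sin(k), 0, sin(k), cos(k)), 3, 3, byrow = TRUE)
    g2 <- geometry(g$elements, g$coords %*% R + matrix(rnorm(3), 4, 3, byrow = TRUE))
    expect_equal(ic_value(g2, ic), ref, tolerance = 1e-9)
  }
})

test_that("bond and angle evaluation matches construction", {
  g <- water_like_geometry()
  expect_equal(ic_value(g, internal_coordinate("bond", c(0, 1))),
               bohr_to_angstrom(1.81), tolerance = 1e-12)
  u <- g$coords[2, ] - g$coords[1, ]
  v <- g$coords[3, ] - g$coords[1, ]
  expect_equal(ic_value(g, internal_coordinate("angle", c(1, 0, 2))),
               acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi,
               tolerance = 1e-10)
  expect_error(internal_coordinate("bond", c(1, 1)), "distinct")
})

test_that("cartesian LIP interpolates aligned endpoints linearly", {
  ga <- chain_with_dihedral(40)
  gb <- chain_with_dihedral(90)
  p <- lip_path(path_spec(ga, gb, n_frames = 3, mode = "cartesian"))
  expect_equal(p$parameters, c(0, 0.5, 1))
  gb_al <- kabsch_align(ga, gb)
  expect_lt(max(abs(p$frames[[1]]$coords - ga$coords)), 1e-10)
  expect_lt(max(abs(p$frames[[3]]$coords - gb_al$coords)), 1e-10)
  expect_lt(max(abs(p$frames[[2]]$coords - (ga$coords + gb_al$coords) / 2)), 1e-10)

  same <- lip_path(path_spec(ga, ga, n_frames = 4, mode = "cartesian"))
  for (f in same$frames) expect_lt(max(abs(f$coords - ga$coords)), 1e-12)
})

test_that("internal LIP takes the shorter dihedral arc and hits its endpoints", {
  ga <- chain_with_dihedral(170)
  gb <- chain_with_dihedral(-170)
  ic <- internal_coordinate("dihedral", 0:3)
  p <- lip_path(path_spec(ga, gb, n_frames = 3, mode = "internal"))
  expect_equal(abs(ic_value(p$frames[[2]], ic)), 180, tolerance = 1e-5)
  expect_equal(ic_value(p$frames[[1]], ic), 170, tolerance = 1e-5)
  expect_equal(ic_value(p$frames[[3]], ic), -170, tolerance = 1e-5)
})

test_that("internal LIP varies bond lengths linearly on a triatomic", {
  ga <- water_like_geometry()
  gb <- geometry(ga$elements, ga$coords * 1.15)
  p <- lip_path(path_spec(ga, gb, n_frames = 5, mode = "internal"))
  ic <- internal_coordinate("bond", c(0, 1))
  vals <- vapply(p$frames, ic_value, 1.0, ic = ic)
  target <- seq(ic_value(ga, ic), ic_value(gb, ic), length.out = 5)
  expect_equal(vals, target, tolerance = 1e-6)
})

test_that("affine combination honours weights and records provenance", {
  ga <- chain_with_dihedral(30)
  gb <- chain_with_dihedral(80)
  expect_lt(max(abs(combine_geometries(list(ga, gb), c(1, 0))$coords - ga$coords)), 1e-12)
  ext <- combine_geometries(list(ga, gb), c(1.5, -0.5))
  expect_equal(attr(ext, "provenance")$weights, c(1.5, -0.5))
  expect_error(combine_geometries(list(ga, gb), c(0.6, 0.5)), "sum to 1")
})

test_that("midpoints of surrogate seam points stay on the affine seam", {
  pes <- make_harmonic_surrogate(napa_like_spec())
  pts <- surrogate_seam_points(pes, k = 2, step = 2)
  mid_q <- 0.5 * pts[[1]] + 0.5 * pts[[2]]
  expect_lt(abs(pes$energy(mid_q, 2) - pes$energy(mid_q, 3)), 1e-12)
  ext_q <- 1.25 * pts[[1]] - 0.25 * pts[[2]]
  expect_lt(abs(pes$energy(ext_q, 2) - pes$energy(ext_q, 3)), 1e-12)
})

test_that("multi-frame XYZ paths serialize frame by frame", {
  ga <- chain_with_dihedral(40)
  gb <- chain_with_dihedral(90)
  p <- lip_path(path_spec(ga, gb, n_frames = 3, mode = "cartesian"))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_multixyz(path, p$frames, p$parameters)
  lines <- readLines(path)
  expect_length(lines, 3 * (2 + 4))
  expect_identical(lines[1], "4")
})
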