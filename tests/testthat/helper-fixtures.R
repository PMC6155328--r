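# Shared builders for test fixtures; everything is generated in code.

# Bent triatomic with realistic bond lengths (bohr).
water_like_geometry <- function() {
  geometry(c("O", "H", "H"),
           matrix(c(0, 0, 0,
                    1.81, 0, 0,
                    -0.45, 1.75, 0), 3, 3, byrow = TRUE))
}

# Random PSD vibrational Hessian for a geometry: a positive matrix projected
# onto the Eckart-complement (pure vibrational) subspace, then un-mass-weighted
# so it is a legitimate Cartesian Hessian.
synthetic_molecular_hessian <- function(g, seed = 1, scale = 0.05) {
  n3 <- 3L * n_atoms(g)
  withr::with_seed(seed, {
    M <- crossprod(matrix(stats::rnorm(n3 * n3, sd = scale), n3, n3))
  })
  V <- ciaccess:::.eckart_vectors(g)
  P <- diag(n3) - V %*% t(V)
  sm <- rep(sqrt(g$masses), each = 3L)
  hessian_record((P %*% M %*% P) * outer(sm, sm), g)
}

# Rotate a geometry + Hessian pair rigidly (row-vector convention r' = r R).
rotate_system <- function(g, h, R) {
  g2 <- geometry(g$elements, g$coords %*% R, g$masses)
  T <- kronecker(diag(n_atoms(g)), t(R))
  list(geometry = g2, hessian = hessian_record(T %*% h$matrix %*% t(T), g2))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Study-condition surrogate: 8 modes spanning the low-frequency range of a
# peptide backbone, uniform alpha profile scaled so the prescribed CI sits
# 0.13 eV above the reference minimum, second state 0.69 eV below.
napa_like_spec <- function() {
  freqs <- c(0.0004, 0.0008, 0.0012, 0.0016, 0.0024, 0.0032, 0.0044, 0.0060)
  model_spec(freqs,
             ci_alphas = scale_alphas_to_barrier(freqs, rep(1, 8),
                                                 ev_to_hartree(0.13)),
             state2_offset = ev_to_hartree(-0.69))
}

# Random feasible flexible spec: distinct ascending frequencies, alphas < 1.
random_model_spec <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(1:8, 1)
    freqs <- sort(stats::runif(n, 1e-4, 0.02)) * (1 + 1e-3 * seq_len(n))
    alphas <- stats::runif(n, 0.05, 0.95)
    off <- -ev_to_hartree(stats::runif(1, 0.62, 0.76))
    model_spec(freqs, ci_alphas = alphas, state2_offset = off)
  })
}

# Landau-Zener oracle configuration: fast passage through a linear crossing
# with constant coupling, the regime where the closed form is valid.
lz_oracle_setup <- function() {
  slope <- 0.08; coupling <- 0.10; v0 <- 1.5; x0 <- -8
  model <- lz_model(slope, coupling)
  e_lower <- function(x) -sqrt((slope * x)^2 + coupling^2)
  v_cross <- sqrt(v0^2 - 2 * (e_lower(0) - e_lower(x0)))
  list(model = model, v0 = v0, x0 = x0, v_cross = v_cross,
       p_lz = lz_probability(model, v_cross),
       dt_fs = 0.005, t_max_fs = 0.4)
}
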