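# Synthetic surrogate potential-energy surfaces with analytically known
# ground truth: a harmonic reference excited state, a displaced lower-lying
# second excited state crossing it at a prescribed CI point, a ground state,
# and a localized Gaussian diabatic coupling for the dynamics module.

#' Surrogate model specification
#'
#' Defines a two-excited-state harmonic model in `n_modes` dimensionless
#' normal coordinates. The reference excited state A is
#' \eqn{E_A(Q) = \frac12\sum_i \omega_i^2 Q_i^2}; the second excited state B
#' shares the frequencies, has its minimum at energy `state2_offset` (< 0,
#' hartree, relative to A's minimum) along the ray through the prescribed CI
#' point, and crosses A exactly at `ci_displacement`, where both states sit
#' `barrier_target` above A's minimum. Because state B shares A's Hessian the
#' A/B energy difference is affine and the CI seam is exactly a hyperplane.
#'
#' The per-mode accessibility ratios are fixed by the displacement,
#' \eqn{\alpha_i = \omega_i Q_{CI,i}^2}, and the barrier is then
#' \eqn{\sum_i \alpha_i \omega_i / 2}; `barrier_target`, if supplied, must be
#' consistent with it (relative tolerance 1e-8) or the spec is rejected as
#' infeasible. Supply either `ci_displacement` directly or `ci_alphas`
#' (displacements are then \eqn{\sqrt{\alpha_i/\omega_i}}); use
#' [scale_alphas_to_barrier()] to realize a prescribed barrier with a given
#' alpha profile.
#'
#' @param frequencies per-mode frequencies, atomic units, all > 0.
#' @param ci_displacement per-mode normal coordinates of the prescribed CI
#'   point (mass-weighted a.u.); exactly one of this and `ci_alphas`.
#' @param ci_alphas per-mode target accessibility ratios (>= 0).
#' @param state2_offset energy of state B's minimum relative to A's (hartree,
#'   negative).
#' @param barrier_target optional energy of the prescribed CI above A's
#'   minimum (hartree, > 0); derived from the displacement when `NULL`.
#' @param coupling_strength peak diabatic A/B coupling (hartree, >= 0).
#' @param coupling_width width of the Gaussian coupling region (mass-weighted
#'   a.u., > 0).
#' @param seed integer random seed recorded with the model.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(frequencies, ci_displacement = NULL, ci_alphas = NULL,
                       state2_offset = ev_to_hartree(-0.69),
                       barrier_target = NULL,
                       coupling_strength = 5e-4, coupling_width = 0.5,
                       seed = 1L) {
  frequencies <- as.numeric(frequencies)
  n <- length(frequencies)
  if (n < 1 || any(frequencies <= 0)) {
    stop("frequencies must be a non-empty vector of positive values", call. = FALSE)
  }
  if (is.null(ci_displacement) == is.null(ci_alphas)) {
    stop("supply exactly one of ci_displacement and ci_alphas", call. = FALSE)
  }
  if (is.null(ci_displacement)) {
    ci_alphas <- as.numeric(ci_alphas)
    if (length(ci_alphas) != n || any(ci_alphas < 0)) {
      stop("ci_alphas must be non-negative, one per mode", call. = FALSE)
    }
    ci_displacement <- sqrt(ci_alphas / frequencies)
  }
  ci_displacement <- as.numeric(ci_displacement)
  if (length(ci_displacement) != n) {
    stop("ci_displacement must have one entry per mode", call. = FALSE)
  }
  barrier_implied <- sum(0.5 * frequencies^2 * ci_displacement^2)
  if (is.null(barrier_target)) {
    barrier_target <- barrier_implied
  } else if (barrier_target <= 0) {
    stop("infeasible spec: barrier_target must be positive", call. = FALSE)
  } else if (abs(barrier_target - barrier_implied) > 1e-8 * max(barrier_target, barrier_implied)) {
    stop("infeasible spec: barrier_target ", format(barrier_target),
         " hartree is inconsistent with the CI displacement (implied barrier ",
         format(barrier_implied), " hartree)", call. = FALSE)
  }
  if (state2_offset >= 0) {
    stop("state2_offset must be negative (state B lies below A)", call. = FALSE)
  }
  if (coupling_width <= 0) stop("coupling_width must be positive", call. = FALSE)
  if (coupling_strength < 0) stop("coupling_strength must be non-negative", call. = FALSE)
  structure(
    list(n_modes = n, frequencies = frequencies,
         ci_displacement = ci_displacement,
         state2_offset = as.numeric(state2_offset),
         barrier_target = as.numeric(barrier_target),
         coupling_strength = as.numeric(coupling_strength),
         coupling_width = as.numeric(coupling_width),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$n_modes, " modes; barrier ",
      format(hartree_to_ev(x$barrier_target), digits = 4), " eV; offset ",
      format(hartree_to_ev(x$state2_offset), digits = 4), " eV\n", sep = "")
  invisible(x)
}

#' Scale an alpha profile to a prescribed CI barrier
#'
#' Uniformly rescales per-mode accessibility ratios so the implied CI energy
#' above the reference minimum, \eqn{\sum_i \alpha_i \omega_i / 2}, equals
#' `barrier` exactly.
#'
#' @param frequencies per-mode frequencies (a.u.).
#' @param alpha_shape non-negative relative profile of per-mode ratios.
#' @param barrier target CI energy above the reference minimum (hartree).
#' @return numeric vector of scaled alphas.
#' @export
scale_alphas_to_barrier <- function(frequencies, alpha_shape, barrier) {
  stopifnot(length(frequencies) == length(alpha_shape), barrier > 0,
            all(alpha_shape >= 0), sum(alpha_shape) > 0)
  alpha_shape * barrier / sum(0.5 * alpha_shape * frequencies)
}

#' Serialize / read a model spec (flat key-value, YAML-style)
#'
#' @param spec a `model_spec`.
#' @param path file path.
#' @return [write_model_spec()]: `path` invisibly; [read_model_spec()]: a
#'   `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeLines(c(
    paste0("n_modes: ", spec$n_modes),
    paste0("frequencies: ", num(spec$frequencies)),
    paste0("ci_displacement: ", num(spec$ci_displacement)),
    paste0("state2_offset: ", num(spec$state2_offset)),
    paste0("barrier_target: ", num(spec$barrier_target)),
    paste0("coupling_strength: ", num(spec$coupling_strength)),
    paste0("coupling_width: ", num(spec$coupling_width)),
    paste0("seed: ", spec$seed)
  ), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  lines <- readLines(path)
  kv <- list()
  for (l in lines) {
    if (!nzchar(trimws(l)) || grepl("^\\s*#", l)) next
    parts <- strsplit(l, ":", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = ":"))
    kv[[key]] <- as.numeric(strsplit(val, "\\s+")[[1]])
  }
  known <- c("n_modes", "frequencies", "ci_displacement", "state2_offset",
             "barrier_target", "coupling_strength", "coupling_width", "seed")
  unknown <- setdiff(names(kv), known)
  if (length(unknown)) stop("unknown spec key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  model_spec(frequencies = kv$frequencies, ci_displacement = kv$ci_displacement,
             state2_offset = kv$state2_offset, barrier_target = kv$barrier_target,
             coupling_strength = kv$coupling_strength,
             coupling_width = kv$coupling_width, seed = kv$seed)
}

#' Build the surrogate PES from a model spec
#'
#' Returns a three-state surface (ground, excited A, excited B) over points in
#' normal-coordinate space, with analytic gradients and the per-mode
#' accessibility ratios attached as ground truth. States A and B are exactly
#' degenerate at the prescribed CI point; their difference is affine, so the
#' full seam is the hyperplane through that point orthogonal to
#' \eqn{\omega^2 \odot D} (D = displacement of B's minimum). The ground state
#' is a parallel reference well 0.2 hartree below A and plays no role in the
#' seam analysis; the Gaussian diabatic coupling is consumed only by the
#' dynamics module.
#'
#' @param spec a `model_spec`.
#' @return object of class `surrogate_pes` (also `ci_pes`): list with
#'   `spec`, `n_states = 3`, `energy(q, state)`, `gradient(q, state)`,
#'   `alphas`, `state2_min` (coordinates of B's minimum), `seam_normal`.
#'   States: 1 = ground, 2 = excited A (reference), 3 = excited B.
#' @export
make_harmonic_surrogate <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  w2 <- spec$frequencies^2
  K <- spec$barrier_target
  off <- spec$state2_offset
  qci <- spec$ci_displacement
  if (K <= 0) stop("infeasible spec: CI coincides with the reference minimum", call. = FALSE)
  t_scale <- 1 + sqrt((K - off) / K)
  d <- t_scale * qci                     # minimum of state B
  ground_gap <- 0.2
  energy <- function(q, state) {
    q <- as.numeric(q)
    switch(state,
      sum(0.5 * w2 * q^2) - ground_gap,
      sum(0.5 * w2 * q^2),
      off + sum(0.5 * w2 * (q - d)^2)
    )
  }
  gradient <- function(q, state) {
    q <- as.numeric(q)
    switch(state, w2 * q, w2 * q, w2 * (q - d))
  }
  structure(
    list(spec = spec, n_states = 3L, energy = energy, gradient = gradient,
         alphas = spec$frequencies * qci^2,
         ci_q = qci, state2_min = d, seam_normal = w2 * d,
         ground_gap = ground_gap),
    class = c("surrogate_pes", "ci_pes")
  )
}

#' @export
print.surrogate_pes <- function(x, ...) {
  cat("<surrogate_pes> ", x$spec$n_modes, " modes, 3 states; alphas: ",
      paste(format(x$alphas, digits = 4), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Points on the surrogate CI seam
#'
#' The A/B seam of a surrogate is the hyperplane through the prescribed CI
#' point orthogonal to `seam_normal`; this returns the CI point plus `k`
#' further seam points displaced along an orthonormal basis of the hyperplane
#' (deterministic), useful as seeds for seam expansion.
#'
#' @param pes a `surrogate_pes`.
#' @param k number of extra seam points (>= 0).
#' @param step displacement along each in-seam direction (mass-weighted a.u.).
#' @return list of numeric coordinate vectors; first element is the CI point.
#' @export
surrogate_seam_points <- function(pes, k = 2, step = 1) {
  stopifnot(inherits(pes, "surrogate_pes"))
  n <- pes$spec$n_modes
  pts <- list(pes$ci_q)
  if (k > 0) {
    if (n < 2) stop("a 1-mode surrogate has a single seam point", call. = FALSE)
    nv <- pes$seam_normal / sqrt(sum(pes$seam_normal^2))
    basis <- diag(n) - outer(nv, nv)
    sv <- svd(basis)
    dirs <- sv$u[, sv$d > 1e-10, drop = FALSE]
    for (i in seq_len(k)) {
      dir <- dirs[, ((i - 1L) %% ncol(dirs)) + 1L]
      pts[[i + 1L]] <- pes$ci_q + step * ceiling(i / ncol(dirs)) * dir
    }
  }
  pts
}

#' Rigid-mode alpha targets for a prescribed total probability
#'
#' Finds the common accessibility ratio alpha > 1 such that `n_modes` modes at
#' that ratio give a total tunneling probability `p_total`, by bracketed
#' bisection on the monotone per-mode probability (tolerance 1e-12).
#'
#' @param p_total target total probability in (0, 1).
#' @param n_modes number of tunneling modes sharing the ratio.
#' @return numeric alpha (> 1).
#' @export
rigid_alphas_for_probability <- function(p_total, n_modes) {
  stopifnot(p_total > 0, p_total < 1, n_modes >= 1)
  .alpha_for_probability(p_total^(1 / n_modes))
}

#' Flexible / rigid surrogate variant pair
#'
#' Builds two surrogates differing only in the CI displacements of the listed
#' modes: the "flexible" member is the base spec (every mode classically
#' accessible, total P = 1) and the "rigid" member has the listed modes'
#' displacements rescaled to hit target ratios alpha > 1, emulating a system
#' whose low-frequency out-of-plane modes must tunnel to reach the seam. The
#' rigid member's total probability is the product of the per-mode closed-form
#' probabilities at the target ratios.
#'
#' @param base a `model_spec` with all alphas <= 1.
#' @param rigid_modes integer mode indices (1-based) to stiffen; may be empty.
#' @param rigid_alphas target ratios, one per entry of `rigid_modes`, all > 1.
#' @return list with `flexible` and `rigid` (both `surrogate_pes`) and
#'   `rigid_total_p` (closed-form product over the stiffened modes).
#' @export
make_variant_pair <- function(base, rigid_modes = integer(), rigid_alphas = numeric()) {
  stopifnot(inherits(base, "model_spec"),
            length(rigid_modes) == length(rigid_alphas))
  base_alphas <- base$frequencies * base$ci_displacement^2
  if (any(base_alphas > 1)) {
    stop("base spec must be fully accessible (all alphas <= 1)", call. = FALSE)
  }
  if (any(rigid_alphas <= 1)) {
    stop("rigid target alphas must exceed 1", call. = FALSE)
  }
  rigid_modes <- as.integer(rigid_modes)
  if (any(rigid_modes < 1L | rigid_modes > base$n_modes)) {
    stop("rigid mode index out of range", call. = FALSE)
  }
  disp <- base$ci_displacement
  disp[rigid_modes] <- sign(ifelse(disp[rigid_modes] == 0, 1, disp[rigid_modes])) *
    sqrt(rigid_alphas / base$frequencies[rigid_modes])
  rigid_spec <- model_spec(
    frequencies = base$frequencies, ci_displacement = disp,
    state2_offset = base$state2_offset, coupling_strength = base$coupling_strength,
    coupling_width = base$coupling_width, seed = base$seed
  )
  list(
    flexible = make_harmonic_surrogate(base),
    rigid = make_harmonic_surrogate(rigid_spec),
    rigid_total_p = prod(tunneling_probability(rigid_alphas))
  )
}

#' Geometry realization of a surrogate point
#'
#' Abstract modes are realized as a chain of fictitious unit-mass atoms
#' ("X"), one per mode, spaced 2 angstrom apart along y; mode i displaces atom
#' i along x. With unit masses, mass-weighted normal coordinates coincide with
#' the atoms' x coordinates in bohr, so XYZ/Hessian round trips are exact.
#'
#' @param pes a `surrogate_pes` (or a `model_spec`).
#' @param q numeric vector of normal coordinates; default 0 (the reference).
#' @return a `ci_geometry`.
#' @export
surrogate_geometry <- function(pes, q = NULL) {
  spec <- if (inherits(pes, "surrogate_pes")) pes$spec else pes
  stopifnot(inherits(spec, "model_spec"))
  n <- spec$n_modes
  if (is.null(q)) q <- rep(0, n)
  stopifnot(length(q) == n)
  spacing <- angstrom_to_bohr(2)
  coords <- cbind(as.numeric(q), (seq_len(n) - 1) * spacing, rep(0, n))
  geometry(rep("X", n), coords)
}

#' Normal coordinates of a surrogate fixture geometry
#'
#' Inverse of [surrogate_geometry()]: the x coordinates (bohr) of the chain.
#'
#' @param g a `ci_geometry` of fictitious chain atoms.
#' @return numeric coordinate vector.
#' @export
surrogate_coords <- function(g) {
  stopifnot(inherits(g, "ci_geometry"))
  as.numeric(g$coords[, 1])
}

#' Emit surrogate fixture files
#'
#' Writes `reference.xyz` (the reference minimum as a fictitious-atom chain),
#' `hessian.dat` (Cartesian Hessian of state A: \eqn{\omega_i^2} on each x
#' diagonal entry, zero elsewhere), `ci.xyz` (the prescribed CI candidate) and
#' `spec.yml` (the flat key-value spec). Round-tripping through [read_xyz()],
#' [read_hessian()] and [build_modes()] with `project = "none"` reproduces the
#' spec frequencies and the analytic accessibility ratios.
#'
#' @param pes a `surrogate_pes`.
#' @param dir output directory (created if missing).
#' @return named character vector of the four paths, invisibly.
#' @export
emit_fixture_files <- function(pes, dir) {
  stopifnot(inherits(pes, "surrogate_pes"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spec <- pes$spec
  n <- spec$n_modes
  ref <- surrogate_geometry(pes)
  paths <- c(reference = file.path(dir, "reference.xyz"),
             hessian = file.path(dir, "hessian.dat"),
             ci = file.path(dir, "ci.xyz"),
             spec = file.path(dir, "spec.yml"))
  ok <- tryCatch({
    write_xyz(ref, paths[["reference"]], comment = "surrogate reference minimum")
    H <- matrix(0, 3 * n, 3 * n)
    for (i in seq_len(n)) H[3 * i - 2, 3 * i - 2] <- spec$frequencies[i]^2
    write_hessian(hessian_record(H, ref), paths[["hessian"]])
    write_xyz(surrogate_geometry(pes, spec$ci_displacement), paths[["ci"]],
              comment = "prescribed CI candidate")
    write_model_spec(spec, paths[["spec"]])
    TRUE
  }, error = function(e) {
    stop("fixture emission failed under '", dir, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(paths)
}

#' Read surrogate fixtures back into a normal-mode basis
#'
#' Convenience wrapper for the round trip documented in
#' [emit_fixture_files()].
#'
#' @param dir directory written by [emit_fixture_files()].
#' @return list with `basis` (a `normal_mode_basis`, `project = "none"`),
#'   `reference`, `ci` (geometries) and `spec`.
#' @export
read_surrogate_fixtures <- function(dir) {
  ref <- read_xyz(file.path(dir, "reference.xyz"))
  h <- read_hessian(file.path(dir, "hessian.dat"), ref)
  basis <- suppressMessages(build_modes(h, project = "none"))
  list(basis = basis,
       reference = ref,
       ci = read_xyz(file.path(dir, "ci.xyz")),
       spec = read_model_spec(file.path(dir, "spec.yml")))
}
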