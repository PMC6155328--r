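# Nonadiabatic dynamics on two-state diabatic models: Wigner initial
# conditions, fewest-switches surface hopping (compiled core), single-surface
# propagation, and diabatic/adiabatic classification of crossing passages.

#' Two-state diabatic model for dynamics
#'
#' Each diabatic state s is
#' \eqn{V_s(x) = e_{0,s} + g_s \cdot (x - x_{0,s}) + \frac12 \sum_i
#' w^2_{s,i} (x - x_{0,s})_i^2} over mass-weighted coordinates (unit mass);
#' the diabatic coupling is a Gaussian of the distance to `coupling_center`
#' (constant when `coupling_width = Inf`). This family covers the surrogate
#' surfaces and the linear-crossing Landau-Zener oracle.
#'
#' @param e0 numeric(2) state energies at their centers (hartree).
#' @param centers 2 x n matrix of state centers.
#' @param linear 2 x n matrix of linear coefficients (hartree per unit).
#' @param quad 2 x n matrix of diagonal quadratic coefficients
#'   (\eqn{\omega^2}).
#' @param coupling_strength peak diabatic coupling (hartree).
#' @param coupling_center numeric(n) center of the coupling region.
#' @param coupling_width Gaussian width; `Inf` gives a constant coupling.
#' @return object of class `diab_model`.
#' @export
diab_model <- function(e0, centers, linear = NULL, quad = NULL,
                       coupling_strength = 0, coupling_center = NULL,
                       coupling_width = Inf) {
  centers <- rbind(centers[1, , drop = TRUE], centers[2, , drop = TRUE])
  n <- ncol(centers)
  if (is.null(linear)) linear <- matrix(0, 2, n)
  if (is.null(quad)) quad <- matrix(0, 2, n)
  if (is.null(coupling_center)) coupling_center <- rep(0, n)
  stopifnot(length(e0) == 2, ncol(linear) == n, ncol(quad) == n,
            length(coupling_center) == n, coupling_width > 0,
            coupling_strength >= 0)
  structure(
    list(e0 = as.numeric(e0), centers = centers, linear = linear, quad = quad,
         coupling_strength = as.numeric(coupling_strength),
         coupling_center = as.numeric(coupling_center),
         coupling_width = as.numeric(coupling_width), n = n),
    class = "diab_model"
  )
}

#' Diabatic and adiabatic energies of a model point
#'
#' @param model a `diab_model`.
#' @param x coordinate vector.
#' @return list with `diabatic` (V11, V22), `coupling` (V12), `adiabatic`
#'   (lower, upper).
#' @export
diab_energies <- function(model, x) {
  stopifnot(inherits(model, "diab_model"), length(x) == model$n)
  V <- vapply(1:2, function(s) {
    dx <- x - model$centers[s, ]
    model$e0[s] + sum(model$linear[s, ] * dx) + sum(0.5 * model$quad[s, ] * dx^2)
  }, 1.0)
  V12 <- if (is.finite(model$coupling_width)) {
    model$coupling_strength *
      exp(-sum((x - model$coupling_center)^2) / (2 * model$coupling_width^2))
  } else model$coupling_strength
  rho <- sqrt(((V[1] - V[2]) / 2)^2 + V12^2)
  list(diabatic = V, coupling = V12,
       adiabatic = c(mean(V) - rho, mean(V) + rho))
}

#' Landau-Zener linear-crossing model
#'
#' 1D model with diabatic slopes +/- `slope` and constant coupling: the
#' closed-form diabatic passage probability at velocity v is
#' \eqn{P_{LZ} = \exp(-2\pi V_{12}^2 / (v \, |\Delta F|))} with
#' \eqn{|\Delta F| = 2\,\mathrm{slope}}, the standard oracle for surface
#' hopping in its validity regime.
#'
#' @param slope magnitude of each diabatic slope (hartree per mass-weighted
#'   unit).
#' @param coupling constant diabatic coupling (hartree).
#' @return a `diab_model`.
#' @export
lz_model <- function(slope = 0.01, coupling = 0.005) {
  diab_model(e0 = c(0, 0), centers = matrix(0, 2, 1),
             linear = matrix(c(slope, -slope), 2, 1),
             coupling_strength = coupling, coupling_width = Inf)
}

#' @rdname lz_model
#' @param velocity nuclear velocity at the crossing (mass-weighted a.u.).
#' @param model a `diab_model` built by [lz_model()].
#' @return [lz_probability()]: the closed-form diabatic passage probability.
#' @export
lz_probability <- function(model, velocity) {
  slope <- abs(model$linear[1, 1] - model$linear[2, 1])
  exp(-2 * pi * model$coupling_strength^2 / (velocity * slope))
}

#' Diabatic dynamics model of a surrogate PES
#'
#' Maps the surrogate's two excited states onto a `diab_model`: state A at the
#' origin, state B displaced with offset, both sharing the frequencies, and
#' the Gaussian coupling centered at the prescribed CI point with the spec's
#' width and strength.
#'
#' @param pes a `surrogate_pes`.
#' @return a `diab_model`.
#' @export
surrogate_diab_model <- function(pes) {
  stopifnot(inherits(pes, "surrogate_pes"))
  spec <- pes$spec
  n <- spec$n_modes
  diab_model(
    e0 = c(0, spec$state2_offset),
    centers = rbind(rep(0, n), pes$state2_min),
    quad = rbind(spec$frequencies^2, spec$frequencies^2),
    coupling_strength = spec$coupling_strength,
    coupling_center = spec$ci_displacement,
    coupling_width = spec$coupling_width
  )
}

#' Wigner sampling of harmonic initial conditions
#'
#' Draws positions and momenta from the Wigner distribution of the harmonic
#' vibrational ground state: per mode, position ~ N(0, 1/(2 omega)) and
#' momentum ~ N(0, omega/2), independent, optionally displaced to an
#' arbitrary center geometry (e.g. a MECI). The mean total energy per mode is
#' the ZPE omega/2.
#'
#' @param basis a `normal_mode_basis`, or directly a numeric vector of
#'   frequencies (a.u., all > 0).
#' @param n number of samples.
#' @param seed integer seed (all randomness in the package flows from
#'   explicit seeds).
#' @param center optional numeric center in normal coordinates (default 0).
#' @return list with `positions` and `momenta` (n x n_modes matrices) and
#'   `frequencies`.
#' @export
wigner_sample <- function(basis, n, seed, center = NULL) {
  omega <- if (inherits(basis, "normal_mode_basis")) basis$frequencies else as.numeric(basis)
  if (any(omega <= 0)) stop("Wigner sampling requires positive frequencies", call. = FALSE)
  k <- length(omega)
  if (is.null(center)) center <- rep(0, k)
  stopifnot(length(center) == k)
  withr::with_seed(as.integer(seed), {
    q <- matrix(stats::rnorm(n * k, sd = rep(sqrt(1 / (2 * omega)), each = n)), n, k)
    p <- matrix(stats::rnorm(n * k, sd = rep(sqrt(omega / 2), each = n)), n, k)
  })
  list(positions = sweep(q, 2, center, `+`), momenta = p, frequencies = omega)
}

# Child seed for trajectory i under a master seed: fixed splitting, kept
# below 2^31.
.child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 10007) %% 2147483647)
}

.traj_tibble <- function(raw, n_modes) {
  out <- tibble::tibble(
    time_fs = aut_to_fs(raw$time),
    active = raw$active + 1L,
    pop_lower = raw$pop_lower,
    pop_diab1 = raw$pop_diab1,
    gap = raw$gap,
    coupling = raw$coupling,
    e_total = raw$e_total,
    norm = raw$norm
  )
  pos <- raw$x
  colnames(pos) <- paste0("q", seq_len(n_modes))
  dplyr::bind_cols(out, tibble::as_tibble(pos))
}

#' Fewest-switches surface hopping ensemble
#'
#' Velocity Verlet nuclear propagation on the active adiabatic surface of a
#' two-state diabatic model, electronic amplitudes integrated in the
#' adiabatic basis with `substeps` RK4 substeps per nuclear step
#' (energies/couplings interpolated linearly across the step), standard
#' fewest-switches hop probabilities, velocity rescaling along the derivative
#' coupling on accepted hops, and configurable frustrated-hop policy
#' (velocity kept by default). One master seed deterministically splits into
#' per-trajectory child seeds, all recorded in the result.
#'
#' @param model a `diab_model`.
#' @param positions n_traj x n_modes matrix (or vector recycled) of initial
#'   positions.
#' @param momenta matching initial momenta (mass-weighted: velocities).
#' @param active_init initial adiabatic state (1 = lower, 2 = upper).
#' @param dt_fs nuclear time step in fs.
#' @param t_max_fs propagation time in fs.
#' @param seed master integer seed.
#' @param substeps electronic substeps per nuclear step.
#' @param record_stride record every this-many nuclear steps.
#' @param frustrated `"keep"` (leave velocity unchanged) or `"reverse"`
#'   (invert the component along the coupling direction).
#' @param drift_tol trajectories whose total-energy drift exceeds this
#'   (hartree) are flagged `aborted` and excluded from population averages.
#' @return object of class `fssh_ensemble`: list with `populations` (tibble:
#'   time_fs, pop_lower, pop_upper, frac_active_lower), `trajectories` (list
#'   of per-trajectory tibbles), `hops` (tibble), `final` (tibble with final
#'   active state and diabatic character per trajectory), `seeds`, `model`.
#' @export
propagate_fssh <- function(model, positions, momenta, active_init = 1,
                           dt_fs = 0.25, t_max_fs = 250, seed = 1,
                           substeps = 100, record_stride = 4,
                           frustrated = c("keep", "reverse"),
                           drift_tol = 1e-3) {
  stopifnot(inherits(model, "diab_model"))
  frustrated <- match.arg(frustrated)
  positions <- matrix(positions, ncol = model$n)
  momenta <- matrix(momenta, ncol = model$n)
  stopifnot(nrow(positions) == nrow(momenta))
  n_traj <- nrow(positions)
  dt <- fs_to_aut(dt_fs)
  n_steps <- max(1L, round(fs_to_aut(t_max_fs) / dt))
  seeds <- vapply(seq_len(n_traj), function(i) .child_seed(seed, i), 1L)
  trajs <- vector("list", n_traj)
  finals <- vector("list", n_traj)
  hops <- list()
  for (i in seq_len(n_traj)) {
    raw <- withr::with_seed(seeds[i], {
      .fssh_trajectory_cpp(unclass(model), positions[i, ], momenta[i, ],
                           as.integer(active_init) - 1L, dt, n_steps,
                           as.integer(substeps), as.integer(record_stride),
                           TRUE, frustrated == "reverse")
    })
    aborted <- raw$max_energy_drift > drift_tol
    trajs[[i]] <- .traj_tibble(raw, model$n)
    finals[[i]] <- tibble::tibble(
      trajectory = i, seed = seeds[i],
      final_active = raw$final_active + 1L,
      final_diab1_weight = raw$final_diab1_weight,
      max_energy_drift = raw$max_energy_drift,
      max_norm_dev = raw$max_norm_dev,
      aborted = aborted
    )
    if (length(raw$hops$time)) {
      hops[[length(hops) + 1L]] <- tibble::tibble(
        trajectory = i, time_fs = aut_to_fs(raw$hops$time),
        from = raw$hops$from + 1L, to = raw$hops$to + 1L,
        prob = raw$hops$prob, xi = raw$hops$xi,
        ke_available = raw$hops$ke_available,
        accepted = raw$hops$accepted == 1L
      )
    }
  }
  final <- dplyr::bind_rows(finals)
  keep <- which(!final$aborted)
  times <- trajs[[1]]$time_fs
  act <- matrix(vapply(trajs[keep], function(tr) tr$active,
                       integer(length(times))), nrow = length(times))
  pop_l <- rowMeans(matrix(vapply(trajs[keep], function(tr) tr$pop_lower,
                                  numeric(length(times))), nrow = length(times)))
  populations <- tibble::tibble(
    time_fs = times,
    pop_lower = pop_l,
    pop_upper = 1 - pop_l,
    frac_active_lower = rowMeans(act == 1L)
  )
  structure(
    list(populations = populations, trajectories = trajs,
         hops = if (length(hops)) dplyr::bind_rows(hops) else tibble::tibble(),
         final = final, seeds = seeds, model = model,
         dt_fs = dt_fs, substeps = substeps),
    class = "fssh_ensemble"
  )
}

#' @export
print.fssh_ensemble <- function(x, ...) {
  cat("<fssh_ensemble> ", length(x$trajectories), " trajectories, ",
      nrow(x$hops), " hop events, ", sum(x$final$aborted), " aborted\n", sep = "")
  invisible(x)
}

#' Hop-free single-surface propagation
#'
#' Velocity Verlet on one adiabatic surface with no electronic propagation:
#' the protocol for short excited-state runs launched from a MECI with
#' Wigner-sampled velocities. Records the minimum adiabatic gap encountered
#' per trajectory.
#'
#' @inheritParams propagate_fssh
#' @param state adiabatic surface to propagate on (1 = lower, 2 = upper).
#' @return list with `trajectories` (list of tibbles), `summary` (tibble:
#'   trajectory, min_gap, max_energy_drift).
#' @export
propagate_adiabatic <- function(model, positions, momenta, state = 1,
                                dt_fs = 0.25, t_max_fs = 350,
                                record_stride = 4) {
  stopifnot(inherits(model, "diab_model"))
  positions <- matrix(positions, ncol = model$n)
  momenta <- matrix(momenta, ncol = model$n)
  n_traj <- nrow(positions)
  dt <- fs_to_aut(dt_fs)
  n_steps <- max(1L, round(fs_to_aut(t_max_fs) / dt))
  trajs <- vector("list", n_traj)
  summaries <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    raw <- .fssh_trajectory_cpp(unclass(model), positions[i, ], momenta[i, ],
                                as.integer(state) - 1L, dt, n_steps, 1L,
                                as.integer(record_stride), FALSE, FALSE)
    trajs[[i]] <- .traj_tibble(raw, model$n)
    summaries[[i]] <- tibble::tibble(
      trajectory = i, min_gap = min(trajs[[i]]$gap),
      max_energy_drift = raw$max_energy_drift
    )
  }
  list(trajectories = trajs, summary = dplyr::bind_rows(summaries))
}

#' Classify close-approach passages as diabatic or adiabatic
#'
#' Scans a trajectory trace for contiguous windows where the adiabatic gap
#' drops below `gap_threshold`. A window is labeled `"diabatic"` when the
#' diabatic state populations are preserved across it (the adiabatic
#' characters swap; change below `preserve_tol`), `"adiabatic"` when the
#' diabatic character mixes across the window. Events are returned in time
#' order with their coupling-peak width.
#'
#' @param traj a per-trajectory tibble from [propagate_fssh()] /
#'   [propagate_adiabatic()] (columns `time_fs`, `gap`, `pop_diab1`,
#'   `coupling`).
#' @param gap_threshold adiabatic gap defining a close approach (hartree).
#' @param preserve_tol maximum diabatic-population change still counted as
#'   preserved.
#' @return tibble with one row per event: `event`, `t_start_fs`, `t_end_fs`,
#'   `width_fs`, `min_gap`, `delta_diab_pop`, `label`; zero rows when no
#'   close approach occurs.
#' @export
classify_passage_events <- function(traj, gap_threshold, preserve_tol = 0.1) {
  stopifnot(all(c("time_fs", "gap", "pop_diab1") %in% names(traj)))
  low <- traj$gap < gap_threshold
  if (!any(low)) {
    return(tibble::tibble(event = integer(), t_start_fs = numeric(),
                          t_end_fs = numeric(), width_fs = numeric(),
                          min_gap = numeric(), delta_diab_pop = numeric(),
                          label = character()))
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  win <- which(r$values)
  out <- purrr::map_dfr(seq_along(win), function(k) {
    i0 <- starts[win[k]]; i1 <- ends[win[k]]
    before <- max(1L, i0 - 1L)
    after <- min(nrow(traj), i1 + 1L)
    dpop <- abs(traj$pop_diab1[after] - traj$pop_diab1[before])
    tibble::tibble(
      event = k,
      t_start_fs = traj$time_fs[i0], t_end_fs = traj$time_fs[i1],
      width_fs = traj$time_fs[i1] - traj$time_fs[i0],
      min_gap = min(traj$gap[i0:i1]),
      delta_diab_pop = dpop,
      label = if (dpop <= preserve_tol) "diabatic" else "adiabatic"
    )
  })
  out[order(out$t_start_fs), ]
}

#' Plot ensemble populations
#'
#' Adiabatic population of the lower state (amplitude average and
#' active-state fraction) against time.
#'
#' @param object an `fssh_ensemble`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fssh_ensemble <- function(object, ...) {
  d <- tidyr::pivot_longer(object$populations,
                           c("pop_lower", "frac_active_lower"),
                           names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_fs, y = .data$value,
                                  colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(pop_lower = "#1b7837", frac_active_lower = "#762a83"),
      labels = c(pop_lower = "amplitude population",
                 frac_active_lower = "active-state fraction"),
      name = NULL) +
    ggplot2::labs(x = "time (fs)", y = "lower adiabatic state population")
}

#' Write ensemble tables
#'
#' Population table as CSV and the hop log as JSON lines.
#'
#' @param ens an `fssh_ensemble`.
#' @param dir output directory.
#' @return invisible vector of paths.
#' @export
write_ensemble <- function(ens, dir) {
  stopifnot(inherits(ens, "fssh_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pop_path <- file.path(dir, "populations.csv")
  utils::write.csv(as.data.frame(ens$populations), pop_path, row.names = FALSE)
  hop_path <- file.path(dir, "hops.jsonl")
  con <- file(hop_path, "w")
  if (nrow(ens$hops)) {
    for (i in seq_len(nrow(ens$hops))) {
      row <- ens$hops[i, ]
      writeLines(sprintf(
        '{"trajectory":%d,"time_fs":%.6f,"from":%d,"to":%d,"prob":%.6g,"accepted":%s}',
        row$trajectory, row$time_fs, row$from, row$to, row$prob,
        if (row$accepted) "true" else "false"), con)
    }
  }
  close(con)
  invisible(c(pop_path, hop_path))
}
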