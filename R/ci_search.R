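# Conical-intersection search on pluggable multi-state surfaces: single-state
# minimization, penalty-based MECI and MDCI optimization, seam expansion by
# pair/triplet interpolation with ZPE filtering, and 2D seam projections.

#' Pluggable PES backend
#'
#' A PES backend is any object with fields `n_states` (integer), `energy =
#' function(point, state)` returning hartree, and optionally `gradient =
#' function(point, state)`; points are plain numeric coordinate vectors
#' (mass-weighted atomic units for surrogates). [pes_backend()] wraps bare
#' functions; [check_pes_gradients()] is the consistency hook comparing
#' analytic gradients with central finite differences at random points.
#'
#' @param energy function(point, state) -> hartree.
#' @param n_states number of electronic states.
#' @param gradient optional function(point, state) -> numeric gradient.
#' @return object of class `ci_pes`.
#' @export
pes_backend <- function(energy, n_states, gradient = NULL) {
  stopifnot(is.function(energy), n_states >= 1)
  structure(list(energy = energy, gradient = gradient,
                 n_states = as.integer(n_states)),
            class = "ci_pes")
}

# Gradient of pes at point/state: analytic if provided, else central
# differences with the documented step.
.pes_grad <- function(pes, x, state, fd_step = 1e-5) {
  if (!is.null(pes$gradient)) return(as.numeric(pes$gradient(x, state)))
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + fd_step
    xm <- x; xm[i] <- xm[i] - fd_step
    (pes$energy(xp, state) - pes$energy(xm, state)) / (2 * fd_step)
  }, 1.0)
}

#' Finite-difference gradient check for a PES backend
#'
#' @param pes a `ci_pes` with analytic gradients.
#' @param points list of coordinate vectors to probe.
#' @param rel_tol maximum tolerated relative error.
#' @param fd_step central-difference step.
#' @return TRUE invisibly; errors with the worst offender otherwise.
#' @export
check_pes_gradients <- function(pes, points, rel_tol = 1e-4, fd_step = 1e-6) {
  stopifnot(!is.null(pes$gradient))
  for (x in points) for (s in seq_len(pes$n_states)) {
    ga <- as.numeric(pes$gradient(x, s))
    gn <- vapply(seq_along(x), function(i) {
      xp <- x; xp[i] <- xp[i] + fd_step
      xm <- x; xm[i] <- xm[i] - fd_step
      (pes$energy(xp, s) - pes$energy(xm, s)) / (2 * fd_step)
    }, 1.0)
    err <- sqrt(sum((ga - gn)^2)) / max(sqrt(sum(gn^2)), 1e-10)
    if (!is.finite(err) || err > rel_tol) {
      stop("gradient check failed for state ", s, ": relative error ",
           format(err), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Two-paraboloid test surface
#'
#' The classic 2D model with \eqn{E_1 = (x^2+y^2)/2} and
#' \eqn{E_2 = ((x-2)^2+y^2)/2}: the crossing seam is the line x = 1, the MECI
#' sits at (1, 0) with energy 0.5, and the MDCI from any reference point is
#' the foot of the perpendicular onto the seam. Used as an analytic oracle for
#' the optimizers.
#'
#' @return a `ci_pes` with two states.
#' @export
two_paraboloid_pes <- function() {
  pes_backend(
    energy = function(x, state) {
      if (state == 1) 0.5 * (x[1]^2 + x[2]^2) else 0.5 * ((x[1] - 2)^2 + x[2]^2)
    },
    n_states = 2,
    gradient = function(x, state) {
      if (state == 1) c(x[1], x[2]) else c(x[1] - 2, x[2])
    }
  )
}

# Smoothed gap penalty of the sequential-penalty CI optimizer and its
# derivative with respect to the gap.
.gap_penalty <- function(gap, sigma, alpha_pen) sigma * gap^2 / (gap + alpha_pen)
.gap_penalty_d <- function(gap, sigma, alpha_pen) {
  sigma * (gap^2 + 2 * alpha_pen * gap) / (gap + alpha_pen)^2
}

# One sequential-penalty optimization: minimizes base(x) + penalty(gap(x)),
# doubling sigma until the gap drops below gap_tol. base_fn/base_gr define the
# seam-restricted objective (mean energy for MECI, squared distance for MDCI).
.penalty_optimize <- function(pes, start, states, base_fn, base_gr,
                              sigma0 = 3.5, growth = 2, alpha_pen = 0.02,
                              gap_tol = 1e-5, sigma_cap = 1e9,
                              inner_control = list(maxit = 500, reltol = 1e-14)) {
  sI <- states[1]; sJ <- states[2]
  x <- as.numeric(start)
  sigma <- sigma0
  trace <- list()
  repeat {
    obj <- function(x) {
      eI <- pes$energy(x, sI); eJ <- pes$energy(x, sJ)
      base_fn(x, eI, eJ) + .gap_penalty(abs(eI - eJ), sigma, alpha_pen)
    }
    grd <- function(x) {
      eI <- pes$energy(x, sI); eJ <- pes$energy(x, sJ)
      gI <- .pes_grad(pes, x, sI); gJ <- .pes_grad(pes, x, sJ)
      base_gr(x, eI, eJ, gI, gJ) +
        .gap_penalty_d(abs(eI - eJ), sigma, alpha_pen) * sign(eI - eJ) * (gI - gJ)
    }
    fit <- stats::optim(x, obj, grd, method = "BFGS", control = inner_control)
    x <- fit$par
    gap <- abs(pes$energy(x, sI) - pes$energy(x, sJ))
    trace[[length(trace) + 1L]] <- c(sigma = sigma, gap = gap, value = fit$value)
    if (gap <= gap_tol) break
    sigma <- sigma * growth
    if (sigma > sigma_cap) {
      stop("CI optimization did not reach gap tolerance ", format(gap_tol),
           " (last gap ", format(gap), " at sigma ", format(sigma / growth),
           "); trace has ", length(trace), " stages", call. = FALSE)
    }
  }
  list(point = x, gap = gap, trace = do.call(rbind, trace))
}

.ci_point <- function(pes, x, states, gap, provenance, reference_energy = 0,
                      strict_tol = 1e-5, trace = NULL) {
  e <- mean(c(pes$energy(x, states[1]), pes$energy(x, states[2])))
  structure(
    list(point = as.numeric(x), states = states, gap = gap,
         energy = e, energy_rel_ev = hartree_to_ev(e - reference_energy),
         strict = gap <= strict_tol, provenance = provenance, trace = trace),
    class = "ci_point"
  )
}

#' @export
print.ci_point <- function(x, ...) {
  cat("<ci_point> states ", paste(x$states, collapse = "/"), "; gap ",
      format(x$gap, digits = 3), " hartree; E_rel ",
      format(x$energy_rel_ev, digits = 4), " eV (", x$provenance$kind, ")\n",
      sep = "")
  invisible(x)
}

#' Minimum-energy conical intersection (MECI)
#'
#' Sequential penalty method: minimizes the mean of the two state energies
#' plus a smoothed gap penalty
#' \eqn{\sigma \Delta E^2 / (\Delta E + \alpha)}, geometrically increasing
#' \eqn{\sigma} until the gap falls below `gap_tol`. No nonadiabatic couplings
#' are required. Penalty defaults: \eqn{\sigma_0 = 3.5}, growth 2,
#' \eqn{\alpha = 0.02} hartree.
#'
#' @param pes a `ci_pes`.
#' @param start numeric starting point within the seam's basin.
#' @param states integer pair of state indices.
#' @param gap_tol degeneracy tolerance (hartree) for convergence.
#' @param strict_tol gap below which the point is flagged `strict`.
#' @param reference_energy energy origin (hartree) for eV reporting.
#' @param sigma0,growth,alpha_pen,sigma_cap penalty-scheme parameters.
#' @return a `ci_point`.
#' @export
optimize_meci <- function(pes, start, states = c(1, 2), gap_tol = 1e-5,
                          strict_tol = 1e-5, reference_energy = 0,
                          sigma0 = 3.5, growth = 2, alpha_pen = 0.02,
                          sigma_cap = 1e9) {
  res <- .penalty_optimize(
    pes, start, states,
    base_fn = function(x, eI, eJ) (eI + eJ) / 2,
    base_gr = function(x, eI, eJ, gI, gJ) (gI + gJ) / 2,
    sigma0 = sigma0, growth = growth, alpha_pen = alpha_pen,
    gap_tol = gap_tol, sigma_cap = sigma_cap
  )
  .ci_point(pes, res$point, states, res$gap,
            provenance = list(kind = "meci", start = as.numeric(start)),
            reference_energy = reference_energy, strict_tol = strict_tol,
            trace = res$trace)
}

#' Minimum-distance conical intersection (MDCI)
#'
#' Same penalty scheme as [optimize_meci()] but the seam-restricted objective
#' is the squared (mass-weighted) distance to a reference point, yielding the
#' seam point closest to the reference -- the dynamically relevant entry point
#' of the seam.
#'
#' @inheritParams optimize_meci
#' @param reference numeric reference point (mass-weighted coordinates).
#' @param start starting point; defaults to the reference.
#' @return a `ci_point`; `$distance` holds the final distance to `reference`.
#' @export
optimize_mdci <- function(pes, reference, states = c(1, 2), start = reference,
                          gap_tol = 1e-5, strict_tol = 1e-5,
                          reference_energy = 0, sigma0 = 3.5, growth = 2,
                          alpha_pen = 0.02, sigma_cap = 1e9) {
  ref <- as.numeric(reference)
  res <- .penalty_optimize(
    pes, start, states,
    base_fn = function(x, eI, eJ) sum((x - ref)^2),
    base_gr = function(x, eI, eJ, gI, gJ) 2 * (x - ref),
    sigma0 = sigma0, growth = growth, alpha_pen = alpha_pen,
    gap_tol = gap_tol, sigma_cap = sigma_cap
  )
  out <- .ci_point(pes, res$point, states, res$gap,
                   provenance = list(kind = "mdci", reference = ref),
                   reference_energy = reference_energy,
                   strict_tol = strict_tol, trace = res$trace)
  out$distance <- sqrt(sum((res$point - ref)^2))
  out
}

#' Minimize a single electronic state
#'
#' Quasi-Newton (BFGS) descent with analytic backend gradients when available,
#' else central finite differences (step 1e-5). Converged when the gradient
#' norm drops below `gnorm_tol`.
#'
#' @param pes a `ci_pes`.
#' @param state electronic state index.
#' @param start starting point.
#' @param gnorm_tol gradient-norm convergence threshold (hartree per
#'   mass-weighted unit).
#' @param maxit iteration cap for the quasi-Newton loop.
#' @return list with `point`, `energy`, `gnorm`.
#' @export
minimize_on_state <- function(pes, state, start, gnorm_tol = 1e-6, maxit = 1000) {
  fit <- stats::optim(as.numeric(start), function(x) pes$energy(x, state),
                      function(x) .pes_grad(pes, x, state), method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-15))
  g <- .pes_grad(pes, fit$par, state)
  if (sqrt(sum(g^2)) > gnorm_tol) {
    stop("state minimization did not converge: |g| = ", format(sqrt(sum(g^2))),
         call. = FALSE)
  }
  list(point = fit$par, energy = fit$value, gnorm = sqrt(sum(g^2)))
}

#' Seam expansion by pair/triplet interpolation with ZPE filtering
#'
#' Each round forms affine combinations of the current seam members -- pairs
#' at \eqn{\lambda \in \{0.25, 0.5, 0.75\}} plus extrapolations
#' \eqn{\lambda \in \{-0.25, 1.25\}}, and triplet barycenters -- refines each
#' candidate back onto the seam with [optimize_mdci()] (minimum displacement
#' from the candidate), evaluates per-mode accessibility there, and retains
#' points that pass the filter: `"strict"` keeps only fully accessible points
#' (all \eqn{\alpha_i \le 1}), `"total_p"` keeps points whose total tunneling
#' probability reaches `p_threshold`. Refinement failures are logged and the
#' candidate discarded; the run continues. A full generation log is kept.
#'
#' @param pes a `ci_pes`.
#' @param seeds list of numeric seam points (>= 2).
#' @param frequencies per-mode frequencies used for the accessibility ratios;
#'   defaults to the surrogate's own when `pes` is a `surrogate_pes`.
#' @param rounds number of expansion rounds.
#' @param states state pair.
#' @param filter `"strict"` or `"total_p"`.
#' @param p_threshold total-probability threshold for `filter = "total_p"`.
#' @param loose_tol seam-membership gap tolerance (hartree); defaults to
#'   0.02 eV.
#' @param strict_tol strict-degeneracy gap (hartree).
#' @param dedup_tol points closer than this (mass-weighted a.u.) to an
#'   existing member are folded into it.
#' @param gap_tol refinement degeneracy target passed to [optimize_mdci()].
#' @return object of class `seam_set`: list with `points` (list of
#'   `ci_point`), `log` (tibble), `frequencies`.
#' @export
expand_seam <- function(pes, seeds, frequencies = NULL, rounds = 2,
                        states = c(2, 3), filter = c("strict", "total_p"),
                        p_threshold = 0.5, loose_tol = ev_to_hartree(0.02),
                        strict_tol = 1e-5, dedup_tol = 1e-3, gap_tol = 1e-6) {
  filter <- match.arg(filter)
  if (length(seeds) < 2) stop("need at least 2 seed points", call. = FALSE)
  if (is.null(frequencies)) {
    if (inherits(pes, "surrogate_pes")) frequencies <- pes$spec$frequencies
    else stop("frequencies must be supplied for non-surrogate backends", call. = FALSE)
  }
  passes <- function(alphas) {
    if (filter == "strict") all(alphas <= 1)
    else prod(tunneling_probability(pmin(alphas, 50))) >= p_threshold
  }
  members <- lapply(seeds, function(s) {
    .ci_point(pes, s, states, abs(pes$energy(s, states[1]) - pes$energy(s, states[2])),
              provenance = list(kind = "seed"), strict_tol = strict_tol)
  })
  log <- list()
  note <- function(round, type, parents, weights, gap, amax, tp, kept, reason) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      round = round, type = type, parents = paste(parents, collapse = "+"),
      weights = paste(format(weights, digits = 4), collapse = ","),
      gap = gap, alpha_max = amax, total_p = tp, kept = kept, reason = reason
    )
  }
  pair_lambdas <- c(0.25, 0.5, 0.75, -0.25, 1.25)
  for (round in seq_len(rounds)) {
    current <- lapply(members, function(m) m$point)
    n <- length(current)
    candidates <- list()
    if (n >= 2) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) for (lam in pair_lambdas) {
        candidates[[length(candidates) + 1L]] <- list(
          x = (1 - lam) * current[[i]] + lam * current[[j]],
          type = "pair", parents = c(i, j), weights = c(1 - lam, lam)
        )
      }
    }
    if (n >= 3) {
      for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        candidates[[length(candidates) + 1L]] <- list(
          x = (current[[i]] + current[[j]] + current[[k]]) / 3,
          type = "triplet", parents = c(i, j, k), weights = rep(1 / 3, 3)
        )
      }
    }
    for (cand in candidates) {
      refined <- tryCatch(
        optimize_mdci(pes, reference = cand$x, states = states,
                      gap_tol = gap_tol, strict_tol = strict_tol),
        error = function(e) e
      )
      if (inherits(refined, "error")) {
        note(round, cand$type, cand$parents, cand$weights, NA_real_, NA_real_,
             NA_real_, FALSE, paste("refinement failed:", conditionMessage(refined)))
        next
      }
      alphas <- frequencies * refined$point^2
      tp <- prod(tunneling_probability(pmin(alphas, 50)))
      if (refined$gap > loose_tol) {
        note(round, cand$type, cand$parents, cand$weights, refined$gap,
             max(alphas), tp, FALSE, "gap above loose tolerance")
        next
      }
      if (!passes(alphas)) {
        note(round, cand$type, cand$parents, cand$weights, refined$gap,
             max(alphas), tp, FALSE, "failed accessibility filter")
        next
      }
      dists <- vapply(members, function(m) sqrt(sum((m$point - refined$point)^2)), 1.0)
      if (any(dists < dedup_tol)) {
        note(round, cand$type, cand$parents, cand$weights, refined$gap,
             max(alphas), tp, FALSE, "duplicate of existing member")
        next
      }
      refined$provenance <- list(kind = "interpolation", type = cand$type,
                                 parents = cand$parents, weights = cand$weights,
                                 round = round)
      refined$alpha_max <- max(alphas)
      refined$total_p <- tp
      members[[length(members) + 1L]] <- refined
      note(round, cand$type, cand$parents, cand$weights, refined$gap,
           max(alphas), tp, TRUE, "retained")
    }
  }
  structure(list(points = members,
                 log = if (length(log)) dplyr::bind_rows(log) else tibble::tibble(),
                 frequencies = frequencies),
            class = "seam_set")
}

#' @export
print.seam_set <- function(x, ...) {
  cat("<seam_set> ", length(x$points), " members (",
      sum(vapply(x$points, function(p) p$provenance$kind == "seed", TRUE)),
      " seeds)\n", sep = "")
  invisible(x)
}

#' Manifest table of a seam set
#'
#' @param seam a `seam_set`.
#' @return tibble: `id`, `kind`, `parents`, `gap`, `energy`, `energy_rel_ev`,
#'   `alpha_max`, `total_p`, `strict`.
#' @export
seam_manifest <- function(seam) {
  stopifnot(inherits(seam, "seam_set"))
  purrr::map_dfr(seq_along(seam$points), function(i) {
    p <- seam$points[[i]]
    alphas <- seam$frequencies * p$point^2
    tibble::tibble(
      id = i, kind = p$provenance$kind,
      parents = if (is.null(p$provenance$parents)) NA_character_
                else paste(p$provenance$parents, collapse = "+"),
      gap = p$gap, energy = p$energy, energy_rel_ev = p$energy_rel_ev,
      alpha_max = max(alphas),
      total_p = prod(tunneling_probability(pmin(alphas, 50))),
      strict = p$strict
    )
  })
}

#' 2D occupancy projection of a seam set
#'
#' Projects every member onto two scalar coordinates and bins the result.
#' Cells carry the member count, the smallest gap among their members, and
#' the two degeneracy shades (strict / loose). Members whose coordinates
#' cannot be computed are skipped and logged.
#'
#' @param seam a `seam_set`.
#' @param axes list of two functions, each mapping a member's coordinate
#'   vector to a scalar.
#' @param breaks integer number of bins per axis, or list of two break
#'   vectors.
#' @param strict_tol,loose_tol gap thresholds for the two shades (hartree).
#' @param axis_names length-2 character axis labels.
#' @return tibble with one row per occupied cell: `u_bin`, `v_bin`, `u_mid`,
#'   `v_mid`, `count`, `min_gap`, `strict`, `loose`; attributes `n_projected`,
#'   `skipped` (tibble of skipped member ids and reasons).
#' @export
project_seam_2d <- function(seam, axes, breaks = 12, strict_tol = 1e-5,
                            loose_tol = ev_to_hartree(0.02),
                            axis_names = c("u", "v")) {
  stopifnot(inherits(seam, "seam_set"), length(axes) == 2)
  uv <- matrix(NA_real_, length(seam$points), 2)
  skipped <- list()
  for (i in seq_along(seam$points)) {
    val <- tryCatch(c(axes[[1]](seam$points[[i]]$point),
                      axes[[2]](seam$points[[i]]$point)),
                    error = function(e) conditionMessage(e))
    if (is.character(val) || any(!is.finite(val))) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        id = i, reason = if (is.character(val)) val else "non-finite coordinate")
      next
    }
    uv[i, ] <- val
  }
  ok <- which(!is.na(uv[, 1]))
  if (is.numeric(breaks) && length(breaks) == 1) {
    pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r + c(-1e-9, 1e-9) * diff(r)
    breaks <- list(seq(pad(range(uv[ok, 1]))[1], pad(range(uv[ok, 1]))[2], length.out = breaks + 1),
                   seq(pad(range(uv[ok, 2]))[1], pad(range(uv[ok, 2]))[2], length.out = breaks + 1))
  }
  gaps <- vapply(seam$points, function(p) p$gap, 1.0)
  d <- tibble::tibble(
    id = ok,
    u = uv[ok, 1], v = uv[ok, 2], gap = gaps[ok],
    u_bin = findInterval(uv[ok, 1], breaks[[1]], rightmost.closed = TRUE),
    v_bin = findInterval(uv[ok, 2], breaks[[2]], rightmost.closed = TRUE)
  )
  cells <- d |>
    dplyr::group_by(.data$u_bin, .data$v_bin) |>
    dplyr::summarise(count = dplyr::n(), min_gap = min(.data$gap), .groups = "drop") |>
    dplyr::mutate(
      u_mid = (breaks[[1]][.data$u_bin] + breaks[[1]][.data$u_bin + 1L]) / 2,
      v_mid = (breaks[[2]][.data$v_bin] + breaks[[2]][.data$v_bin + 1L]) / 2,
      strict = .data$min_gap <= strict_tol,
      loose = .data$min_gap <= loose_tol
    )
  names(cells)[names(cells) == "u_mid"] <- paste0(axis_names[1], "_mid")
  names(cells)[names(cells) == "v_mid"] <- paste0(axis_names[2], "_mid")
  attr(cells, "n_projected") <- length(ok)
  attr(cells, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else tibble::tibble()
  cells
}

#' Write a seam set to disk
#'
#' One XYZ per member (via a point-to-geometry mapping) plus the manifest as
#' CSV.
#'
#' @param seam a `seam_set`.
#' @param dir output directory.
#' @param to_geometry function mapping a coordinate vector to a
#'   `ci_geometry`; defaults to the surrogate chain realization.
#' @return the manifest path, invisibly.
#' @export
write_seam_set <- function(seam, dir, to_geometry = NULL) {
  stopifnot(inherits(seam, "seam_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- seam_manifest(seam)
  if (!is.null(to_geometry)) {
    for (i in seq_along(seam$points)) {
      write_xyz(to_geometry(seam$points[[i]]$point),
                file.path(dir, sprintf("ci_%03d.xyz", i)),
                comment = sprintf("gap %.3e hartree", seam$points[[i]]$gap))
    }
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(as.data.frame(man), path, row.names = FALSE)
  invisible(path)
}
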