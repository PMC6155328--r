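# Internal coordinates (bonds/angles/dihedrals), linearly interpolated paths
# (Cartesian or internal), and affine combination of geometries.

# Covalent radii (angstrom, Pyykko-Atsumi) for automatic connectivity.
.cov_radii <- c(
  H = 0.32, D = 0.32, He = 0.46, B = 0.85, C = 0.75, N = 0.71, O = 0.63,
  F = 0.64, Na = 1.55, Mg = 1.39, Al = 1.26, Si = 1.16, P = 1.11, S = 1.03,
  Cl = 0.99, K = 1.96, Ca = 1.71, Fe = 1.16, Zn = 1.18, Br = 1.14, I = 1.33,
  X = 0.75
)

#' Primitive internal coordinate
#'
#' A bond (2 atoms), angle (3) or dihedral (4) identified by 0-based atom
#' indices, the indexing convention used throughout this package's APIs.
#'
#' @param kind `"bond"`, `"angle"` or `"dihedral"`.
#' @param atoms integer vector of 0-based atom indices (2, 3 or 4 of them).
#' @return object of class `internal_coordinate`.
#' @export
internal_coordinate <- function(kind = c("bond", "angle", "dihedral"), atoms) {
  kind <- match.arg(kind)
  atoms <- as.integer(atoms)
  need <- c(bond = 2L, angle = 3L, dihedral = 4L)[[kind]]
  if (length(atoms) != need) stop(kind, " needs ", need, " atoms", call. = FALSE)
  if (anyDuplicated(atoms)) stop("atom indices must be distinct", call. = FALSE)
  if (any(atoms < 0L)) stop("atom indices are 0-based and non-negative", call. = FALSE)
  structure(list(kind = kind, atoms = atoms), class = "internal_coordinate")
}

#' Evaluate an internal coordinate on a geometry
#'
#' Bond lengths are returned in angstrom, angles and dihedrals in degrees.
#' Dihedrals are signed, in (-180, 180], with the IUPAC convention: looking
#' from the first atom along the central bond, clockwise is negative.
#'
#' @param g a `ci_geometry`.
#' @param ic an `internal_coordinate`.
#' @return numeric scalar.
#' @export
ic_value <- function(g, ic) {
  stopifnot(inherits(g, "ci_geometry"), inherits(ic, "internal_coordinate"))
  if (any(ic$atoms >= n_atoms(g))) stop("atom index out of range", call. = FALSE)
  x <- g$coords[ic$atoms + 1L, , drop = FALSE]
  switch(ic$kind,
    bond = bohr_to_angstrom(sqrt(sum((x[2, ] - x[1, ])^2))),
    angle = {
      u <- x[1, ] - x[2, ]; v <- x[3, ] - x[2, ]
      cosb <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      acos(max(-1, min(1, cosb))) * 180 / pi
    },
    dihedral = dihedral_angle(x)
  )
}

#' Signed dihedral from four points
#'
#' @param x a 4 x 3 matrix of Cartesian points (any consistent length unit).
#' @return dihedral in degrees, signed, in (-180, 180].
#' @export
dihedral_angle <- function(x) {
  b1 <- x[2, ] - x[1, ]
  b2 <- x[3, ] - x[2, ]
  b3 <- x[4, ] - x[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12) {
    stop("undefined dihedral: three consecutive atoms are collinear", call. = FALSE)
  }
  ang <- atan2(sum(n1 * (c(b2[2] * n2[3] - b2[3] * n2[2],
                           b2[3] * n2[1] - b2[1] * n2[3],
                           b2[1] * n2[2] - b2[2] * n2[1])) / nb2) * -1,
               sum(n1 * n2)) * 180 / pi
  # atan2(m x n2 . b2hat, n1 . n2) with the sign flipped to the convention
  # "clockwise negative viewed from the first atom"; fold -180 to +180.
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  if (ang == -180) ang <- 180
  ang
}

#' Automatically generated primitive internal set
#'
#' Bonds from a distance-cutoff connectivity (1.6 times the covalent-radius
#' sum), angles for every bonded triple and dihedrals for every bonded
#' quadruple. Used by [lip_path()] in internal mode when no set is supplied.
#'
#' @param g a `ci_geometry`.
#' @param scale cutoff multiplier on the covalent-radius sum.
#' @return list of `internal_coordinate` objects.
#' @export
auto_internals <- function(g, scale = 1.6) {
  n <- n_atoms(g)
  r <- .cov_radii[g$elements]
  r[is.na(r)] <- 0.75
  ang <- bohr_to_angstrom(g$coords)
  bonds <- list()
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((ang[i, ] - ang[j, ])^2)) <= scale * (r[i] + r[j])) {
      bonds[[length(bonds) + 1L]] <- internal_coordinate("bond", c(i - 1L, j - 1L))
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  ics <- bonds
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2) {
      for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb)) {
        ics[[length(ics) + 1L]] <-
          internal_coordinate("angle", c(nb[a] - 1L, j - 1L, nb[b] - 1L))
      }
    }
  }
  for (b in bonds) {
    j <- b$atoms[1] + 1L; k <- b$atoms[2] + 1L
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], c(j, i))) {
      ics[[length(ics) + 1L]] <-
        internal_coordinate("dihedral", c(i - 1L, j - 1L, k - 1L, l - 1L))
    }
  }
  ics
}

# Internal-coordinate vector in radians/bohr (not the user-facing deg/angstrom
# units) -- the back-transformation works in these.
.ic_raw <- function(g, ics) {
  vapply(ics, function(ic) {
    v <- ic_value(g, ic)
    if (ic$kind == "bond") angstrom_to_bohr(v) else v * pi / 180
  }, 1.0)
}

# Wilson B matrix by central finite differences (rows: internals, cols: 3N).
.b_matrix <- function(g, ics, h = 1e-5) {
  n3 <- 3L * n_atoms(g)
  B <- matrix(0, length(ics), n3)
  x0 <- g$coords
  for (c in seq_len(n3)) {
    at <- (c - 1L) %/% 3L + 1L; ax <- (c - 1L) %% 3L + 1L
    xp <- x0; xp[at, ax] <- xp[at, ax] + h
    xm <- x0; xm[at, ax] <- xm[at, ax] - h
    qp <- .ic_raw(geometry(g$elements, xp, g$masses), ics)
    qm <- .ic_raw(geometry(g$elements, xm, g$masses), ics)
    dq <- qp - qm
    dih <- vapply(ics, function(ic) ic$kind == "dihedral", TRUE)
    dq[dih] <- ((dq[dih] + pi) %% (2 * pi)) - pi  # unwrap across the +-180 cut
    B[, c] <- dq / (2 * h)
  }
  B
}

# Shorter-arc difference from angle a to angle b (degrees), result in
# (-180, 180]; exact 180-degree ties resolve toward the positive direction.
.arc_delta <- function(a, b) {
  d <- (b - a) %% 360
  d[d > 180] <- d[d > 180] - 360
  d[d == -180] <- 180
  d
}

#' Path specification for linear interpolation between two geometries
#'
#' @param from,to endpoint `ci_geometry` objects with identical atoms.
#' @param n_frames number of frames including both endpoints (>= 2).
#' @param mode `"cartesian"` (interpolate Cartesians after Kabsch alignment)
#'   or `"internal"` (interpolate bonds/angles/dihedrals and rebuild frames).
#' @param range interpolation-parameter range; the default `c(0, 1)` spans the
#'   endpoints, wider ranges extrapolate.
#' @param internals optional list of `internal_coordinate`s; defaults to
#'   [auto_internals()] of `from`.
#' @return object of class `path_spec`.
#' @export
path_spec <- function(from, to, n_frames = 11, mode = c("cartesian", "internal"),
                      range = c(0, 1), internals = NULL) {
  .check_same_atoms(from, to)
  mode <- match.arg(mode)
  stopifnot(n_frames >= 2, length(range) == 2)
  structure(list(from = from, to = to, n_frames = as.integer(n_frames),
                 mode = mode, range = as.numeric(range), internals = internals),
            class = "path_spec")
}

#' Linearly interpolated path (LIP) between two geometries
#'
#' In Cartesian mode the second endpoint is Kabsch-aligned onto the first and
#' coordinates are interpolated linearly; this is exact for paths on quadratic
#' model surfaces. In internal mode bond lengths, angles and dihedrals are
#' interpolated (dihedrals along the shorter arc; exact 180-degree ties break
#' toward the positive direction) and Cartesian frames are rebuilt by an
#' iterative first-order back-transformation (damping 0.5, convergence 1e-8
#' bohr max displacement, 200-iteration cap).
#'
#' @param spec a [path_spec()].
#' @return list with `frames` (list of `ci_geometry`) and `parameters`
#'   (numeric interpolation parameter per frame).
#' @export
lip_path <- function(spec) {
  stopifnot(inherits(spec, "path_spec"))
  lam <- seq(spec$range[1], spec$range[2], length.out = spec$n_frames)
  from <- spec$from
  to <- kabsch_align(from, spec$to)
  if (spec$mode == "cartesian") {
    frames <- lapply(lam, function(l) {
      geometry(from$elements, (1 - l) * from$coords + l * to$coords, from$masses)
    })
  } else {
    ics <- spec$internals %||% auto_internals(from)
    if (length(ics) < 3L * n_atoms(from) - 6L) {
      stop("internal set too small to determine the geometry", call. = FALSE)
    }
    q0 <- .ic_raw(from, ics)
    q1 <- .ic_raw(to, ics)
    dih <- vapply(ics, function(ic) ic$kind == "dihedral", TRUE)
    dq <- q1 - q0
    dq[dih] <- .arc_delta(q0[dih] * 180 / pi, q1[dih] * 180 / pi) * pi / 180
    frames <- vector("list", length(lam))
    guess <- from
    for (k in seq_along(lam)) {
      target <- q0 + lam[k] * dq
      frames[[k]] <- .backtransform(guess, ics, target, dih)
      guess <- frames[[k]]
    }
  }
  list(frames = frames, parameters = lam)
}

# Iterative internal -> Cartesian back-transformation.
.backtransform <- function(start, ics, q_target, dih,
                           damping = 0.5, tol = 1e-8, max_iter = 200) {
  g <- start
  for (it in seq_len(max_iter)) {
    q <- .ic_raw(g, ics)
    dq <- q_target - q
    dq[dih] <- ((dq[dih] + pi) %% (2 * pi)) - pi
    B <- .b_matrix(g, ics)
    dx <- .pinv_solve(B, dq)
    step <- damping * matrix(dx, ncol = 3, byrow = TRUE)
    g <- geometry(g$elements, g$coords + step, g$masses)
    if (max(abs(step)) < tol) return(g)
  }
  stop("internal-coordinate back-transformation did not converge; ",
       "last max step ", format(max(abs(step))), " bohr", call. = FALSE)
}

# Minimum-norm least-squares solve via SVD pseudo-inverse.
.pinv_solve <- function(A, b, rtol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d)
  sv$v[, keep, drop = FALSE] %*% ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
}

#' Affine combination of two or three geometries
#'
#' Parents 2..k are Kabsch-aligned onto the first parent, then coordinates are
#' combined with the given weights. Weights must sum to 1 (to 1e-12); negative
#' weights extrapolate. The result carries a `provenance` attribute recording
#' parents and weights, which seam-expansion bookkeeping relies on.
#'
#' @param parents list of 2 or 3 `ci_geometry` objects with identical atoms.
#' @param weights numeric weights, one per parent, summing to 1.
#' @return a `ci_geometry` with a `provenance` attribute.
#' @export
combine_geometries <- function(parents, weights) {
  stopifnot(is.list(parents), length(parents) %in% c(2L, 3L),
            length(weights) == length(parents))
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("weights must sum to 1 (got ", format(sum(weights)), ")", call. = FALSE)
  }
  ref <- parents[[1]]
  aligned <- c(list(ref), lapply(parents[-1], function(p) kabsch_align(ref, p)))
  xyz <- Reduce(`+`, Map(function(g, w) w * g$coords, aligned, weights))
  out <- geometry(ref$elements, xyz, ref$masses)
  attr(out, "provenance") <- list(parents = length(parents), weights = as.numeric(weights))
  out
}

#' Write a multi-frame XYZ file
#'
#' Concatenated standard XYZ blocks, one per frame; the comment line carries
#' the interpolation parameter.
#'
#' @param path output file.
#' @param frames list of `ci_geometry` objects.
#' @param parameters optional numeric per-frame parameters for comment lines.
#' @return `path`, invisibly.
#' @export
write_multixyz <- function(path, frames, parameters = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    g <- frames[[k]]
    ang <- bohr_to_angstrom(g$coords)
    cm <- if (is.null(parameters)) sprintf("frame %d", k)
          else sprintf("frame %d lambda %.6f", k, parameters[k])
    writeLines(c(as.character(n_atoms(g)), cm,
                 sprintf("%-3s %16.10f %16.10f %16.10f",
                         g$elements, ang[, 1], ang[, 2], ang[, 3])), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
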