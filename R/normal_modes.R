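# Normal-mode basis: mass-weighted Hessian diagonalization with Eckart
# projection, Cartesian <-> normal-coordinate transforms, harmonic PES, ZPE.

# Orthonormalized translation/rotation vectors (Eckart frame) in mass-weighted
# Cartesian coordinates, as columns. Rotations degenerate for linear molecules
# (moment-of-inertia threshold) and absent for single atoms.
.eckart_vectors <- function(g, inertia_tol = 1e-10) {
  n <- n_atoms(g)
  sm <- sqrt(g$masses)
  com <- colSums(g$coords * g$masses) / sum(g$masses)
  r <- g$coords - matrix(com, n, 3, byrow = TRUE)
  vecs <- matrix(0, 3 * n, 0)
  for (ax in 1:3) {                       # translations: sqrt(m) * e_ax
    v <- matrix(0, n, 3); v[, ax] <- sm
    vecs <- cbind(vecs, as.numeric(t(v)))
  }
  I3 <- diag(3)
  for (ax in 1:3) {                       # rotations: sqrt(m) * (e_ax x r)
    e <- I3[ax, ]
    v <- t(vapply(seq_len(n), function(i) {
      sm[i] * c(e[2] * r[i, 3] - e[3] * r[i, 2],
                e[3] * r[i, 1] - e[1] * r[i, 3],
                e[1] * r[i, 2] - e[2] * r[i, 1])
    }, numeric(3)))
    vecs <- cbind(vecs, as.numeric(t(v)))
  }
  qr_d <- qr(vecs)
  keep <- abs(diag(qr.R(qr_d)))[seq_len(qr_d$rank)] > inertia_tol
  Q <- qr.Q(qr_d)[, seq_len(qr_d$rank), drop = FALSE][, keep, drop = FALSE]
  Q
}

#' Build a normal-mode basis from a Hessian
#'
#' Mass-weights the Cartesian Hessian, optionally projects out rigid
#' translations and rotations (Eckart frame), diagonalizes, and keeps the
#' vibrational modes sorted by ascending frequency \eqn{\omega_i =
#' \sqrt{\lambda_i}} (atomic units). Near-zero frequencies (|omega| below
#' `drop_tol`) after projection are dropped with a warning; any projected
#' eigenvalue below `-neg_tol` raises a "not a minimum" error listing the
#' offending modes. Mode signs are fixed deterministically (largest-magnitude
#' component positive).
#'
#' `project = "none"` skips the rigid-body projection; it is the right choice
#' for surrogate fixture chains of uncoupled fictitious atoms, whose mode
#' space overlaps the rigid-body space by construction.
#'
#' @param h a `ci_hessian` (see [read_hessian()]).
#' @param project `"eckart"` (default) or `"none"`.
#' @param drop_tol frequency magnitude below which a mode is dropped (a.u.).
#' @param neg_tol tolerated magnitude of spurious negative eigenvalues.
#' @return object of class `normal_mode_basis`: list with `reference`
#'   (geometry), `L` (n_modes x 3N matrix, rows = mass-weighted mode vectors),
#'   `frequencies` (a.u., ascending), `n_modes`.
#' @export
build_modes <- function(h, project = c("eckart", "none"),
                        drop_tol = 1e-6, neg_tol = 1e-8) {
  stopifnot(inherits(h, "ci_hessian"))
  project <- match.arg(project)
  g <- h$geometry
  n3 <- 3L * n_atoms(g)
  sm <- rep(sqrt(g$masses), each = 3L)
  Hmw <- h$matrix / outer(sm, sm)
  if (project == "eckart" && n_atoms(g) > 1) {
    V <- .eckart_vectors(g)
    P <- diag(n3) - V %*% t(V)
    Hmw <- P %*% Hmw %*% P
  }
  Hmw <- (Hmw + t(Hmw)) / 2
  ed <- eigen(Hmw, symmetric = TRUE)
  lam <- rev(ed$values)
  vec <- ed$vectors[, rev(seq_len(n3)), drop = FALSE]
  bad <- which(lam < -neg_tol)
  if (length(bad)) {
    stop("not a minimum: negative projected eigenvalue(s) at mode index ",
         paste(bad, collapse = ", "), " (min ", format(min(lam)), ")",
         call. = FALSE)
  }
  omega <- sqrt(pmax(lam, 0))
  keep <- omega > drop_tol
  if (sum(!keep) > 0 && project == "none") {
    # zero modes are expected under eckart projection; only note them otherwise
    message("build_modes: dropped ", sum(!keep), " near-zero frequency mode(s)")
  }
  L <- t(vec[, keep, drop = FALSE])
  omega <- omega[keep]
  for (i in seq_len(nrow(L))) {           # deterministic sign convention
    j <- which.max(abs(L[i, ]))
    if (L[i, j] < 0) L[i, ] <- -L[i, ]
  }
  structure(list(reference = g, L = L, frequencies = omega,
                 n_modes = length(omega)),
            class = "normal_mode_basis")
}

#' @export
print.normal_mode_basis <- function(x, ...) {
  cat("<normal_mode_basis> ", x$n_modes, " modes over ",
      n_atoms(x$reference), " atoms; omega [a.u.] in [",
      format(min(x$frequencies)), ", ", format(max(x$frequencies)), "]\n",
      sep = "")
  invisible(x)
}

#' Normal coordinates of a geometry
#'
#' Q = L (R - R_ref) in mass-weighted Cartesians. The geometry is first
#' brought into the reference's frame (mass-weighted Kabsch superposition), so
#' a rigidly rotated or translated copy of the reference maps to Q = 0.
#'
#' @param basis a `normal_mode_basis`.
#' @param g a `ci_geometry` with the same atoms as the reference.
#' @param align logical; superimpose `g` on the reference first (default TRUE).
#' @return numeric vector of length `n_modes` (mass-weighted atomic units).
#' @export
to_normal_coords <- function(basis, g, align = TRUE) {
  stopifnot(inherits(basis, "normal_mode_basis"))
  ref <- basis$reference
  .check_same_atoms(ref, g)
  if (align && n_atoms(ref) > 2) g <- kabsch_align(ref, g, mass_weighted = TRUE)
  sm <- rep(sqrt(ref$masses), each = 3L)
  dR <- as.numeric(t(g$coords - ref$coords)) * sm
  as.numeric(basis$L %*% dR)
}

#' Geometry at given normal coordinates
#'
#' Inverse of [to_normal_coords()] within the vibrational subspace:
#' R = R_ref + M^{-1/2} L^T Q.
#'
#' @param basis a `normal_mode_basis`.
#' @param q numeric vector of normal coordinates (length `n_modes`).
#' @return a `ci_geometry`.
#' @export
from_normal_coords <- function(basis, q) {
  stopifnot(inherits(basis, "normal_mode_basis"), length(q) == basis$n_modes)
  ref <- basis$reference
  sm <- rep(sqrt(ref$masses), each = 3L)
  dR <- as.numeric(t(basis$L) %*% q) / sm
  geometry(ref$elements, ref$coords + matrix(dR, ncol = 3, byrow = TRUE), ref$masses)
}

#' Harmonic potential energy at normal coordinates
#'
#' W(Q) = 1/2 sum_i omega_i^2 Q_i^2 (hartree): the harmonic expansion of the
#' excited-state surface about the reference minimum, additive over modes.
#'
#' @param basis a `normal_mode_basis`.
#' @param q numeric vector of normal coordinates.
#' @return energy in hartree (non-negative).
#' @export
harmonic_energy <- function(basis, q) {
  stopifnot(inherits(basis, "normal_mode_basis"), length(q) == basis$n_modes)
  sum(0.5 * basis$frequencies^2 * q^2)
}

#' Zero-point energy of a normal-mode basis
#'
#' Per-mode ZPE_i = omega_i / 2 and their sum, in hartree.
#'
#' @param basis a `normal_mode_basis`.
#' @return list with `per_mode` (numeric vector) and `total` (scalar).
#' @export
zpe <- function(basis) {
  stopifnot(inherits(basis, "normal_mode_basis"))
  per <- basis$frequencies / 2
  list(per_mode = per, total = sum(per))
}

#' Mode summary table
#'
#' @param basis a `normal_mode_basis`.
#' @return tibble with columns `mode` (1-based index), `omega_au`,
#'   `omega_cm1`, `zpe_hartree`.
#' @export
mode_table <- function(basis) {
  stopifnot(inherits(basis, "normal_mode_basis"))
  tibble::tibble(
    mode = seq_len(basis$n_modes),
    omega_au = basis$frequencies,
    omega_cm1 = omega_to_cm1(basis$frequencies),
    zpe_hartree = basis$frequencies / 2
  )
}
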