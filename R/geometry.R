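# Geometry container, XYZ / Hessian I/O, atomic masses, Kabsch alignment.

# Isotope-averaged atomic masses (unified amu, IUPAC 2021 conventional values)
# for the elements a small-peptide study needs, plus deuterium. The fictitious
# element "X" (one unit-mass pseudo-atom per abstract mode in surrogate
# fixtures) has mass exactly 1 electron mass and is special-cased in
# element_masses().
.masses_amu <- c(
  H = 1.008, D = 2.014101778, He = 4.002602,
  B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998403163,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815384, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.0983, Ca = 40.078, Fe = 55.845, Zn = 65.38, Br = 79.904, I = 126.90447
)

#' Default atomic masses
#'
#' Masses in electron-mass units for a vector of element symbols. Symbols are
#' the standard IUPAC ones; `"D"` selects deuterium and `"X"` a fictitious
#' unit-mass (1 electron mass) pseudo-atom used by surrogate fixture files.
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses in electron-mass units.
#' @export
element_masses <- function(elements) {
  m <- numeric(length(elements))
  for (i in seq_along(elements)) {
    el <- elements[i]
    if (el == "X") {
      m[i] <- 1
    } else if (el %in% names(.masses_amu)) {
      m[i] <- .masses_amu[[el]] * au$me_per_amu
    } else {
      stop("unknown element symbol: '", el, "'", call. = FALSE)
    }
  }
  m
}

#' Molecular geometry
#'
#' A geometry is a set of atoms with Cartesian coordinates. Coordinates are
#' stored in bohr; XYZ files are read and written in angstrom. Masses default
#' to the isotope-averaged table and can be overridden per atom (0-based
#' indices), which is how deuteration studies are expressed -- overriding
#' masses never touches coordinates.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates, in bohr.
#' @param masses optional numeric vector of per-atom masses in electron-mass
#'   units; defaults to [element_masses()].
#' @return object of class `ci_geometry`.
#' @export
geometry <- function(elements, coords, masses = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(elements) >= 1, nrow(coords) == length(elements))
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  if (is.null(masses)) masses <- element_masses(elements)
  if (length(masses) != length(elements) || any(masses <= 0)) {
    stop("masses must be positive, one per atom", call. = FALSE)
  }
  structure(
    list(elements = as.character(elements), coords = coords,
         masses = as.numeric(masses)),
    class = "ci_geometry"
  )
}

#' @export
print.ci_geometry <- function(x, ...) {
  cat("<ci_geometry> ", n_atoms(x), " atoms: ",
      paste(x$elements, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param g a `ci_geometry`.
#' @return integer atom count.
#' @export
n_atoms <- function(g) length(g$elements)

#' Override per-atom masses
#'
#' @param g a `ci_geometry`.
#' @param index 0-based atom indices to override.
#' @param mass replacement masses in electron-mass units (recycled).
#' @return a new `ci_geometry` with identical coordinates.
#' @export
set_masses <- function(g, index, mass) {
  stopifnot(inherits(g, "ci_geometry"))
  idx <- as.integer(index) + 1L
  if (any(idx < 1L | idx > n_atoms(g))) stop("atom index out of range", call. = FALSE)
  m <- g$masses
  m[idx] <- rep_len(as.numeric(mass), length(idx))
  geometry(g$elements, g$coords, m)
}

.check_same_atoms <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || !identical(a$elements, b$elements)) {
    stop("geometries have different atoms", call. = FALSE)
  }
}

#' Read / write XYZ files
#'
#' Standard XYZ dialect: atom-count line, comment line, then one
#' `element x y z` line per atom with coordinates in angstrom. Coordinates are
#' converted to bohr on read; [write_xyz()] prints 10 decimal places so a
#' write/read round trip is exact to well below 1e-10 angstrom.
#'
#' @param path file path.
#' @param masses optional masses passed to [geometry()].
#' @return [read_xyz()]: a `ci_geometry`. [write_xyz()]: `path`, invisibly.
#' @export
read_xyz <- function(path, masses = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("XYZ parse error (", path, "): file too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("XYZ parse error (", path, ") line 1: bad atom count", call. = FALSE)
  }
  if (length(lines) < 2 + n) {
    stop("XYZ parse error (", path, "): expected ", n, " atom lines, found ",
         max(0L, length(lines) - 2L), call. = FALSE)
  }
  elements <- character(n)
  coords <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ln <- 2L + i
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4) {
      stop("XYZ parse error (", path, ") line ", ln, ": need 'El x y z'", call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz))) {
      stop("XYZ parse error (", path, ") line ", ln, ": non-numeric coordinate", call. = FALSE)
    }
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  if (!all(elements %in% c(names(.masses_amu), "X"))) {
    bad <- setdiff(unique(elements), c(names(.masses_amu), "X"))
    stop("XYZ parse error (", path, "): unknown element symbol '", bad[1], "'", call. = FALSE)
  }
  geometry(elements, angstrom_to_bohr(coords), masses = masses)
}

#' @rdname read_xyz
#' @param g a `ci_geometry` to write.
#' @param comment comment-line text.
#' @export
write_xyz <- function(g, path, comment = "") {
  stopifnot(inherits(g, "ci_geometry"))
  ang <- bohr_to_angstrom(g$coords)
  lines <- c(
    as.character(n_atoms(g)), comment,
    sprintf("%-3s %16.10f %16.10f %16.10f", g$elements, ang[, 1], ang[, 2], ang[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a Cartesian Hessian
#'
#' Plain-text format: optional leading `#` header lines, then the 3N x 3N
#' matrix row-major, one row per line, in hartree/bohr^2 (un-mass-weighted
#' Cartesian second derivatives). On read the matrix is checked against its
#' transpose -- asymmetry beyond `asym_tol` is rejected -- and the symmetrized
#' matrix is returned.
#'
#' @param path file path.
#' @param g the `ci_geometry` the Hessian belongs to (fixes 3N).
#' @param asym_tol maximum tolerated max-norm asymmetry (hartree/bohr^2).
#' @return a `ci_hessian`: list with `matrix` (symmetrized), `geometry`,
#'   `asymmetry` (the max-norm asymmetry found in the file).
#' @export
read_hessian <- function(path, g, asym_tol = 1e-6) {
  stopifnot(inherits(g, "ci_geometry"))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  n3 <- 3L * n_atoms(g)
  if (length(lines) != n3) {
    stop("Hessian dimension mismatch (", path, "): expected ", n3,
         " rows for 3N = ", n3, ", found ", length(lines), call. = FALSE)
  }
  rows <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(vapply(rows, length, 1L) != n3)) {
    stop("Hessian dimension mismatch (", path, "): every row must have ", n3,
         " entries", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  hessian_record(m, g, asym_tol = asym_tol)
}

#' @rdname read_hessian
#' @param matrix a 3N x 3N numeric matrix (for [hessian_record()]).
#' @export
hessian_record <- function(matrix, g, asym_tol = 1e-6) {
  stopifnot(inherits(g, "ci_geometry"))
  n3 <- 3L * n_atoms(g)
  if (!is.matrix(matrix) || nrow(matrix) != n3 || ncol(matrix) != n3) {
    stop("Hessian must be ", n3, " x ", n3, call. = FALSE)
  }
  asym <- max(abs(matrix - t(matrix)))
  if (asym > asym_tol) {
    stop("Hessian asymmetry ", format(asym), " exceeds tolerance ",
         format(asym_tol), call. = FALSE)
  }
  structure(
    list(matrix = (matrix + t(matrix)) / 2, geometry = g, asymmetry = asym),
    class = "ci_hessian"
  )
}

#' @rdname read_hessian
#' @param h a `ci_hessian` to write.
#' @export
write_hessian <- function(h, path) {
  stopifnot(inherits(h, "ci_hessian"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Cartesian Hessian, hartree/bohr^2, %d x %d, row-major",
                     nrow(h$matrix), ncol(h$matrix)), con)
  apply(h$matrix, 1, function(r) writeLines(paste(sprintf("%22.14e", r), collapse = " "), con))
  invisible(path)
}

# Optimal proper rotation (Kabsch) taking moving onto target after removing
# the weighted centroids. Returns list(R, t): x_aligned = x %*% R + t.
.kabsch_rotation <- function(target, moving, w = NULL) {
  n <- nrow(target)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  ct <- colSums(target * w)
  cm <- colSums(moving * w)
  A <- t((moving - matrix(cm, n, 3, byrow = TRUE)) * w) %*%
    (target - matrix(ct, n, 3, byrow = TRUE))
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, t = ct - as.numeric(cm %*% R))
}

#' Optimal superposition and RMSD (Kabsch)
#'
#' [kabsch_align()] rigidly superimposes `moving` onto `target` (rotation
#' restricted to proper rotations via the determinant correction);
#' [kabsch_rmsd()] returns the minimum root-mean-square deviation over all
#' rigid motions, in angstrom. With `mass_weighted = TRUE` both the centroid
#' and the deviation average use atomic masses as weights.
#'
#' @param target,moving,a,b `ci_geometry` objects with identical atoms.
#' @param mass_weighted logical; weight atoms by mass.
#' @return [kabsch_align()]: the aligned `moving` geometry.
#'   [kabsch_rmsd()]: RMSD in angstrom (non-negative, symmetric in `a`, `b`).
#' @export
kabsch_align <- function(target, moving, mass_weighted = FALSE) {
  .check_same_atoms(target, moving)
  w <- if (mass_weighted) target$masses else NULL
  k <- .kabsch_rotation(target$coords, moving$coords, w)
  geometry(moving$elements, moving$coords %*% k$R +
             matrix(k$t, n_atoms(moving), 3, byrow = TRUE), moving$masses)
}

#' @rdname kabsch_align
#' @export
kabsch_rmsd <- function(a, b, mass_weighted = FALSE) {
  .check_same_atoms(a, b)
  bb <- kabsch_align(a, b, mass_weighted = mass_weighted)
  d2 <- rowSums((a$coords - bb$coords)^2)
  w <- if (mass_weighted) a$masses / sum(a$masses) else rep(1 / n_atoms(a), n_atoms(a))
  bohr_to_angstrom(sqrt(sum(w * d2)))
}
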