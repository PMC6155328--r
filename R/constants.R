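#' Physical constants and unit conversions (CODATA 2018)
#'
#' All internal quantities are atomic units: energies in hartree, lengths in
#' bohr, masses in electron masses, time in atomic time units. Coordinates in
#' XYZ files are angstrom; vibrational frequencies in reports may be given in
#' cm^-1. Every conversion in the package goes through this one table.
#'
#' @format Named list of conversion factors:
#' \describe{
#'   \item{ev_per_hartree}{27.211386245988}
#'   \item{angstrom_per_bohr}{0.529177210903}
#'   \item{cm1_per_hartree}{219474.6313632}
#'   \item{me_per_amu}{1822.888486209 (electron masses per unified amu)}
#'   \item{fs_per_aut}{0.02418884254 (femtoseconds per atomic time unit)}
#' }
#' @export
au <- list(
  ev_per_hartree   = 27.211386245988,
  angstrom_per_bohr = 0.529177210903,
  cm1_per_hartree  = 219474.6313632,
  me_per_amu       = 1822.888486209,
  fs_per_aut       = 0.02418884254
)

#' Convert between hartree and electron-volt
#' @param x numeric energies.
#' @return numeric of the same length.
#' @export
hartree_to_ev <- function(x) x * au$ev_per_hartree

#' @rdname hartree_to_ev
#' @export
ev_to_hartree <- function(x) x / au$ev_per_hartree

#' Convert between bohr and angstrom
#' @param x numeric lengths.
#' @return numeric of the same length.
#' @export
bohr_to_angstrom <- function(x) x * au$angstrom_per_bohr

#' @rdname bohr_to_angstrom
#' @export
angstrom_to_bohr <- function(x) x / au$angstrom_per_bohr

#' Convert a harmonic frequency from atomic units to cm^-1
#' @param omega frequency in hartree (atomic units, \eqn{\hbar\omega}).
#' @return frequency in cm^-1.
#' @export
omega_to_cm1 <- function(omega) omega * au$cm1_per_hartree

#' Convert femtoseconds to atomic time units
#' @param t time in fs.
#' @return time in atomic units.
#' @export
fs_to_aut <- function(t) t / au$fs_per_aut

#' @rdname fs_to_aut
#' @export
aut_to_fs <- function(t) t * au$fs_per_aut
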