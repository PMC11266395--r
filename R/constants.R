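# Physical constants and element tables (atomic units unless noted).

#' Unit conversion constants
#'
#' Conversion factors used throughout the package: `hartree_kcal` converts
#' Hartree to kcal/mol (CODATA-consistent 627.5095), `bohr_angstrom` is the
#' Bohr radius in Angstrom.
#'
#' @format Named numeric values.
#' @name units-constants
#' @keywords internal
NULL

HARTREE_KCAL <- 627.5095
BOHR_ANGSTROM <- 0.529177210903
# Boltzmann constant in Hartree/K and time conversion: 1 fs in atomic time units
KB_HARTREE <- 3.166811563e-6
FS_AU <- 41.341373335
# atomic mass unit in electron masses
AMU_ME <- 1822.888486209

.element_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
                F = 9, Ne = 10, Na = 11, Mg = 12, P = 15, S = 16, Cl = 17)

.element_mass <- c(H = 1.00794, He = 4.002602, C = 12.011, N = 14.007,
                   O = 15.999, F = 18.998, P = 30.974, S = 32.06, Cl = 35.45)

# UFF van der Waals radii (Angstrom), used to build solvation cavities
.uff_radii <- c(H = 1.443, He = 1.181, C = 1.9255, N = 1.83, O = 1.75,
                F = 1.682, P = 2.0735, S = 2.0175, Cl = 1.9735)

element_Z <- function(symbols) {
  z <- .element_Z[symbols]
  if (anyNA(z)) stop("unknown element(s): ", paste(symbols[is.na(z)], collapse = ", "))
  unname(z)
}

element_mass <- function(symbols) {
  m <- .element_mass[symbols]
  if (anyNA(m)) stop("no mass for element(s): ", paste(symbols[is.na(m)], collapse = ", "))
  unname(m)
}

#' Convert energies between Hartree and kcal/mol
#'
#' @param x numeric vector of energies.
#' @return Converted numeric vector.
#' @examples
#' kcal_to_hartree(hartree_to_kcal(1)) # exactly 1
#' @export
hartree_to_kcal <- function(x) x * HARTREE_KCAL

#' @rdname hartree_to_kcal
#' @export
kcal_to_hartree <- function(x) x / HARTREE_KCAL
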