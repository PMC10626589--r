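## Physical constants (CODATA 2018). All internal quantities are atomic
## units (Hartree, Bohr); XYZ files and reports use Angstrom / kJ/mol.

#' Unit conversion constants
#'
#' Atomic-unit conversion factors used throughout the package. Internal
#' energies are Hartree and internal lengths Bohr; geometry files are read and
#' written in Angstrom and reports can be requested in kJ/mol.
#'
#' @format A named list with elements
#' \describe{
#'   \item{bohr_per_angstrom}{Bohr in one Angstrom, 1/0.529177210903.}
#'   \item{angstrom_per_bohr}{0.529177210903.}
#'   \item{kjmol_per_hartree}{2625.4996394799.}
#' }
#' @export
dbmbe_units <- list(
  angstrom_per_bohr = 0.529177210903,
  bohr_per_angstrom = 1 / 0.529177210903,
  kjmol_per_hartree = 2625.4996394799
)

#' Convert Hartree to kJ/mol
#' @param x energy in Hartree
#' @return energy in kJ/mol
#' @export
hartree_to_kjmol <- function(x) x * dbmbe_units$kjmol_per_hartree
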