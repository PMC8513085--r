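# Physical constants and unit conversions. Internal unit system is atomic
# units throughout; angstrom appears only at I/O boundaries.

#' Unit conversion constants
#'
#' Conversion factors used throughout the package. All internal quantities are
#' in atomic units (bohr, hartree); structures read from or written to XYZ/PDB
#' files are in angstrom.
#'
#' @format Named list with elements `bohr_per_angstrom`, `angstrom_per_bohr`,
#'   `ev_per_hartree`, `kcalmol_per_hartree`.
#' @export
units_au <- list(
  bohr_per_angstrom  = 1 / 0.529177210903,
  angstrom_per_bohr  = 0.529177210903,
  ev_per_hartree     = 27.211386245988,
  kcalmol_per_hartree = 627.509474
)

ang2bohr <- function(x) x * units_au$bohr_per_angstrom
bohr2ang <- function(x) x * units_au$angstrom_per_bohr
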