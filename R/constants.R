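#' Physical constants (CODATA 2018)
#'
#' A single pinned table of the physical constants used throughout the
#' package. All thermochemistry is expressed in kJ/mol and J/(mol K);
#' Hessians default to Hartree/Bohr^2 and geometries to Angstrom.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{h}{Planck constant, J s}
#'   \item{c}{speed of light, m/s}
#'   \item{NA_}{Avogadro constant, 1/mol}
#'   \item{R}{molar gas constant, J/(mol K)}
#'   \item{amu}{atomic mass constant, kg}
#'   \item{bohr}{Bohr radius, Angstrom}
#'   \item{hartree}{Hartree energy, J}
#'   \item{hartree_kjmol}{Hartree energy, kJ/mol}
#'   \item{hartree_cm1}{Hartree energy, cm^-1}
#'   \item{me_amu}{electron mass, amu}
#' }
#' @export
solv_constants <- list(
  kB = 1.380649e-23,
  h = 6.62607015e-34,
  c = 299792458,
  NA_ = 6.02214076e23,
  R = 8.314462618,
  amu = 1.66053906660e-27,
  bohr = 0.529177210903,
  hartree = 4.3597447222071e-18,
  hartree_kjmol = 2625.4996394799,
  hartree_cm1 = 219474.6313632,
  me_amu = 5.48579909065e-4
)
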