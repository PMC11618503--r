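# Internal unit system: nm / amu / ps / kJ/mol (amu nm^2 ps^-2 == kJ/mol).
# Mass-weighted Hessian eigenvalues then come out in ps^-2 and angular
# frequencies in rad/ps.

#' Physical constants in the package's internal unit system
#'
#' The package works internally in nm / amu / ps / kJ/mol. In this system the
#' unit of energy is consistent (1 amu nm^2/ps^2 = 1 kJ/mol), mass-weighted
#' Hessian eigenvalues are in ps^-2, and angular frequencies in rad/ps.
#'
#' @format A named list with elements
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.0083144626 kJ/mol/K.}
#'   \item{hbar}{Reduced Planck constant, kJ ps/mol (1.054571817e-34 J s
#'     times Avogadro's number).}
#'   \item{c_cm_ps}{Speed of light, 0.0299792458 cm/ps; divides rad/ps by
#'     \eqn{2\pi c} to get wavenumbers in cm\eqn{^{-1}}.}
#'   \item{coulomb}{Coulomb prefactor, 138.935458 kJ mol^-1 nm e^-2.}
#'   \item{avogadro}{Avogadro's number, mol^-1.}
#'   \item{molar_mass_water}{18.01528 g/mol.}
#'   \item{mpa_to_internal}{Pressure conversion, kJ/mol/nm^3 per MPa.}
#' }
#' @export
pel_constants <- list(
  kB   = 0.0083144626,
  hbar = 1.054571817e-34 * 6.02214076e23 * 1e12 / 1e3,  # kJ ps / mol
  c_cm_ps = 0.0299792458,
  coulomb = 138.935458,
  avogadro = 6.02214076e23,
  molar_mass_water = 18.01528,
  mpa_to_internal = 1e-21 * 6.02214076e23 / 1e3
)

.kB <- pel_constants$kB
.hbar <- pel_constants$hbar

# rad/ps -> cm^-1
omega_to_cm1 <- function(omega) omega / (2 * pi * pel_constants$c_cm_ps)
cm1_to_omega <- function(nu) nu * 2 * pi * pel_constants$c_cm_ps
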