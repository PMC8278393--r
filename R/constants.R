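#' Physical constants (CODATA 2018) and derived conversion factors
#'
#' Single source of truth for every unit conversion in the package. All
#' internal computation is in Hartree atomic units; conversions happen only at
#' I/O boundaries and in the spectroscopic unit chain. Derived factors are
#' computed here from the base constants, never hard-coded downstream.
#'
#' @format A named list with elements (SI unless noted):
#' \describe{
#'   \item{c}{speed of light in vacuum, m s^-1}
#'   \item{h}{Planck constant, J s}
#'   \item{e}{elementary charge, C}
#'   \item{N_A}{Avogadro constant, mol^-1}
#'   \item{k_B}{Boltzmann constant, J K^-1}
#'   \item{eps0}{vacuum permittivity, F m^-1}
#'   \item{a0}{Bohr radius, m}
#'   \item{E_h}{Hartree energy, J}
#'   \item{amu}{atomic mass constant, kg}
#'   \item{debye}{1 debye in C m}
#'   \item{bohr_per_angstrom}{1 angstrom in bohr}
#'   \item{hartree_per_kjmol}{1 kJ mol^-1 in hartree}
#' }
#' @export
pe_constants <- local({
  c_si    <- 299792458
  h_si    <- 6.62607015e-34
  e_si    <- 1.602176634e-19
  N_A     <- 6.02214076e23
  k_B     <- 1.380649e-23
  eps0    <- 8.8541878128e-12
  a0      <- 5.29177210903e-11
  E_h     <- 4.3597447222071e-18
  amu     <- 1.66053906660e-27
  debye   <- 1e-21 / c_si           # 1 D = 10^-18 statC cm = 10^-21/c C m
  list(
    c = c_si, h = h_si, e = e_si, N_A = N_A, k_B = k_B, eps0 = eps0,
    a0 = a0, E_h = E_h, amu = amu, debye = debye,
    bohr_per_angstrom = 1e-10 / a0,
    hartree_per_kjmol = 1e3 / (N_A * E_h)
  )
})

#' Derived spectroscopic unit-conversion factors
#'
#' Factors connecting the unit systems in which double-harmonic IR and Raman
#' intensities are commonly reported. Each factor is computed at call time
#' from [pe_constants].
#'
#' @return Named list:
#' \describe{
#'   \item{mu_q_au_to_si}{(e^2 amu^-1) -> C^2 kg^-1 for squared dipole
#'     gradients with respect to mass-weighted normal coordinates}
#'   \item{mu_q_si_to_d2a2amu}{C^2 kg^-1 -> D^2 angstrom^-2 amu^-1}
#'   \item{alpha_q_au_to_si}{a.u. -> C^4 m^2 J^-2 kg^-1 for squared
#'     polarizability gradients}
#'   \item{alpha_q_si_to_a4amu}{C^4 m^2 J^-2 kg^-1 -> angstrom^4 amu^-1}
#'   \item{napierian_per_mu_q}{C^2 kg^-1 -> m mol^-1 (Napierian integrated
#'     molecular attenuation coefficient A = N_A mu^Q / (12 eps0 c^2))}
#' }
#' @export
pe_unit_factors <- function() {
  k <- pe_constants
  # squared dipole gradient: (C kg^-1/2)^2; the debye view restores the metre
  # hidden in D = C m, hence the angstrom^-2
  mu_q_si_to_d2a2amu <- (1 / k$debye)^2 * 1e-20 * k$amu
  # (1/4 pi eps0)^2 turns C^4 m^2 J^-2 kg^-1 into m^4 kg^-1 (polarizability
  # volume derivative squared), then m^4 kg^-1 -> angstrom^4 amu^-1
  alpha_q_si_to_a4amu <- (1 / (4 * pi * k$eps0))^2 * 1e40 * k$amu
  list(
    mu_q_au_to_si       = (k$e / sqrt(k$amu))^2,
    mu_q_si_to_d2a2amu  = mu_q_si_to_d2a2amu,
    alpha_q_au_to_si    = (k$e^2 * k$a0 / k$E_h / sqrt(k$amu))^2,
    alpha_q_si_to_a4amu = alpha_q_si_to_a4amu,
    napierian_per_mu_q  = k$N_A / (12 * k$eps0 * k$c^2)
  )
}

# eigenvalue of a mass-weighted Hessian in hartree bohr^-2 amu^-1 -> cm^-1,
# keeping the sign convention that imaginary frequencies are negative
hessian_eigenvalue_to_wavenumber <- function(lambda) {
  k <- pe_constants
  omega2_si <- lambda * k$E_h / (k$a0^2 * k$amu)   # (rad/s)^2
  sign(lambda) * sqrt(abs(omega2_si)) / (2 * pi * k$c * 100)
}
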