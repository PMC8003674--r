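#' Physical constants and unit conventions
#'
#' The package works in eV for energies, femtoseconds for time and atomic
#' units for transition dipoles, in dimensionless (frequency-weighted) normal
#' coordinates with ground-state nuclear Hamiltonian
#' \eqn{\frac{1}{2}\sum_\alpha \Omega_\alpha (p_\alpha^2 + q_\alpha^2)}, so
#' that \eqn{\langle 0 | q_\alpha^2 | 0\rangle = 1/2} and the zero-point
#' energy is \eqn{\frac{1}{2}\sum_\alpha \Omega_\alpha}.
#'
#' `hbar_ev_fs` is the reduced Planck constant in eV fs. `molar_epsilon_const`
#' converts `E[eV] * |mu[a.u.]|^2 * rho(E)[1/eV]` (with `rho` the unit-area
#' lineshape) into a decadic molar absorption coefficient in M^-1 cm^-1; it is
#' fixed by the oscillator-strength sum rule
#' `f = k_f * integral(epsilon dnu~)` with `k_f ~ 4.319e-9 M cm^2` and
#' `f = (2/3) (E/E_h) |mu|^2` in atomic units.
#'
#' @name vibronic-constants
#' @keywords internal
NULL

hbar_ev_fs <- 0.6582119569

hartree_ev <- 27.211386245988
ev_wavenumber <- 8065.543937  # cm^-1 per eV

# f = .osc_integral_const * integral(epsilon(nu~) dnu~), epsilon in M^-1 cm^-1:
# (1000 ln10 * 4 eps0 m_e c_m c_cm) / (N_A e^2 * 1e4), CODATA 2018 constants.
.osc_integral_const <- local({
  eps0 <- 8.8541878128e-12
  me <- 9.1093837015e-31
  c_m <- 2.99792458e8
  e <- 1.602176634e-19
  na <- 6.02214076e23
  (1000 * log(10) * 4 * eps0 * me * c_m * (c_m * 100)) / (na * e^2 * 1e4)
})

# epsilon(E) = molar_epsilon_const * E[eV] * |mu|^2[au] * rho(E)[1/eV]
molar_epsilon_const <- (2 / 3) / (hartree_ev * .osc_integral_const *
                                    ev_wavenumber)
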