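#' Gaussian broadening: HWHM to quadratic damping and back
#'
#' The time-domain damping \eqn{e^{-\Gamma (t/\hbar)^2}} (with \eqn{\Gamma}
#' in eV^2, t in fs, \eqn{\hbar} in eV fs) Fourier-transforms to a Gaussian
#' lineshape \eqn{e^{-E^2/(4\Gamma)}} in the energy domain, so
#' \eqn{\mathrm{HWHM} = 2\sqrt{\Gamma \ln 2}} and
#' \eqn{\Gamma = \mathrm{HWHM}^2 / (4\ln 2)}.
#'
#' @param hwhm Gaussian half width at half maximum, eV (> 0).
#' @return `hwhm_to_gamma`: damping parameter \eqn{\Gamma} in eV^2.
#' @export
hwhm_to_gamma <- function(hwhm) {
  if (any(hwhm <= 0)) stop("'hwhm' must be positive", call. = FALSE)
  hwhm^2 / (4 * log(2))
}

#' @rdname hwhm_to_gamma
#' @param gamma quadratic damping parameter, eV^2 (> 0).
#' @return `gamma_to_hwhm`: half width at half maximum in eV.
#' @export
gamma_to_hwhm <- function(gamma) {
  if (any(gamma <= 0)) stop("'gamma' must be positive", call. = FALSE)
  2 * sqrt(gamma * log(2))
}

.new_spectrum <- function(energy_ev, epsilon, meta) {
  neg <- epsilon < 0
  if (any(neg)) {
    worst <- max(-epsilon[neg])
    ref <- max(epsilon, 0)
    if (ref > 0 && worst > 1e-6 * ref) {
      warning(sprintf(
        "negative spectral intensity down to %.3g of max clipped", worst / ref),
        call. = FALSE)
    } else if (worst > 0) {
      message(sprintf("numerical ripple: clipped negatives down to %.3g",
                      worst))
    }
    epsilon[neg] <- 0
  }
  structure(list(energy_ev = energy_ev, epsilon = epsilon, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  imax <- which.max(x$epsilon)
  cat(sprintf(
    "<spectrum> %d points on [%.3f, %.3f] eV; max %.4g at %.3f eV\n",
    length(x$energy_ev), min(x$energy_ev), max(x$energy_ev),
    x$epsilon[imax], x$energy_ev[imax]))
  if (!is.null(x$meta$hwhm_ev)) {
    cat(sprintf("  broadening HWHM %.4g eV, shift %+.3g eV, normalization %s\n",
                x$meta$hwhm_ev, x$meta$shift_ev %||% 0,
                x$meta$normalization %||% "none"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.default_grid <- function(E0, n = 2048L) {
  seq(min(E0) - 1, max(E0) + 2, length.out = n)
}

# unit-area lineshape rho(E) [1/eV] from C(t) on a uniform grid from t = 0,
# using the Hermitian extension C(-t) = C(t)*:
# rho(E) = (1 / pi hbar) Re sum_k w_k dt e^{i E t_k / hbar} e^{-G t_k^2/hbar^2} C_k
.lineshape_from_autocorr <- function(times, autocorr, gamma, grid) {
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("time grid must be uniform", call. = FALSE)
  }
  if (times[1] != 0) stop("time grid must start at t = 0", call. = FALSE)
  w <- rep(dt[1], length(times))
  w[c(1L, length(times))] <- dt[1] / 2  # trapezoid endpoints
  damped <- autocorr * exp(-gamma * (times / hbar_ev_fs)^2) * w
  phases <- exp(1i * outer(grid, times) / hbar_ev_fs)
  Re(phases %*% damped)[, 1L] / (pi * hbar_ev_fs)
}

#' Absorption spectrum from propagated autocorrelation functions
#'
#' Implements the zero-Kelvin time-dependent expression: for each doorway
#' state the damped autocorrelation is Fourier-transformed (Hermitian
#' extension, \eqn{e^{+i\omega t}} sign) into a unit-area lineshape, weighted
#' by \eqn{|\mu_{gi}|^2} and by the energy prefactor, and summed. Under the
#' Condon approximation the dipoles come from the model. Cross-correlation
#' contributions \eqn{(\mu_{gj}\cdot\mu_{gi})\,\langle d_j;0|\psi_i(t)\rangle}
#' are available behind `include_cross` but are off by default (their effect
#' is usually negligible).
#'
#' @param results a [propagate()] result or a list of them (one per doorway
#'   state); dipoles and state indices are read from their metadata.
#' @param gamma quadratic damping \eqn{\Gamma} in eV^2; see
#'   [hwhm_to_gamma()].
#' @param grid energy grid (eV, uniform ascending); default 2048 points on
#'   `[min(E0) - 1, max(E0) + 2]`.
#' @param include_cross include cross-correlation terms?
#' @param units `"molar"` for decadic molar absorption (M^-1 cm^-1, dipoles
#'   in a.u.), `"relative"` to skip the constant bundle.
#' @param omega_prefactor apply the linear energy prefactor (the
#'   \eqn{\omega} in the absorption formula)? Disable to obtain the bare
#'   lineshape \eqn{\sum_i |\mu_i|^2 \rho_i(E)}.
#' @return a `spectrum` object.
#' @export
autocorrelation_to_spectrum <- function(results, gamma, grid = NULL,
                                        include_cross = FALSE,
                                        units = c("molar", "relative"),
                                        omega_prefactor = TRUE) {
  units <- match.arg(units)
  if (inherits(results, "propagation_result")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "propagation_result")))
  if (is.null(grid)) grid <- .default_grid(results[[1L]]$meta$E0)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("'grid' must be strictly increasing", call. = FALSE)
  }
  eps <- numeric(length(grid))
  states <- integer(0)
  for (res in results) {
    i <- res$meta$state
    mu_i <- res$meta$dipoles[i, ]
    if (all(mu_i == 0) && units == "molar" && !include_cross) {
      warning(sprintf("doorway state %d is dark (|mu| = 0); contributes nothing",
                      i), call. = FALSE)
    }
    states <- c(states, i)
    eps <- eps + sum(mu_i^2) *
      .lineshape_from_autocorr(res$times, res$autocorr, gamma, grid)
    if (include_cross) {
      for (j in seq_len(ncol(res$doorway_overlaps))) {
        if (j == i) next
        wgt <- sum(res$meta$dipoles[j, ] * mu_i)
        if (wgt == 0) next
        eps <- eps + wgt * .lineshape_from_autocorr(
          res$times, res$doorway_overlaps[, j], gamma, grid)
      }
    }
  }
  if (omega_prefactor) eps <- eps * grid
  if (units == "molar") eps <- eps * molar_epsilon_const
  .new_spectrum(grid, eps, meta = list(
    gamma_ev2 = gamma, hwhm_ev = gamma_to_hwhm(gamma), shift_ev = 0,
    normalization = "none", units = units, states = states,
    cross_terms = include_cross, omega_prefactor = omega_prefactor))
}

#' Broadened stick (pure-electronic) spectrum
#'
#' Sum of Gaussians centered at the vertical energies with areas
#' proportional to the oscillator strengths: the "classical Franck-Condon"
#' spectrum obtained from excitation energies and intensities alone, as used
#' for comparison with the vibronic result (typical phenomenological HWHM
#' 0.25 eV against 0.04 eV for the vibronic spectrum).
#'
#' @param energies stick positions, eV.
#' @param strengths oscillator strengths \eqn{f_k} (dimensionless).
#' @param hwhm Gaussian half width at half maximum, eV.
#' @param grid energy grid; default 2048 points on
#'   `[min(E) - 1, max(E) + 2]`.
#' @param units as in [autocorrelation_to_spectrum()]; `"molar"` converts
#'   each unit-area band through the oscillator-strength sum rule.
#' @param weighting `"oscillator"` (default; band areas proportional to f,
#'   the physical molar-absorption convention) or `"dipole"` (areas
#'   proportional to the dipole strength f/E).
#' @return a `spectrum` object.
#' @export
stick_spectrum <- function(energies, strengths, hwhm, grid = NULL,
                           units = c("molar", "relative"),
                           weighting = c("oscillator", "dipole")) {
  units <- match.arg(units)
  weighting <- match.arg(weighting)
  if (length(energies) != length(strengths)) {
    stop("'energies' and 'strengths' must have equal length", call. = FALSE)
  }
  if (any(strengths < 0)) stop("'strengths' must be >= 0", call. = FALSE)
  if (hwhm <= 0) stop("'hwhm' must be positive", call. = FALSE)
  if (is.null(grid)) grid <- .default_grid(energies)
  sigma <- hwhm / sqrt(2 * log(2))
  areas <- switch(weighting,
                  oscillator = strengths,
                  dipole = strengths / energies)
  if (units == "molar") {
    # f = .osc_integral_const * integral(eps dnu~)  =>  area in eV units
    areas <- areas / (.osc_integral_const * ev_wavenumber)
  }
  eps <- numeric(length(grid))
  for (k in seq_along(energies)) {
    if (areas[k] == 0) next
    eps <- eps + areas[k] * stats::dnorm(grid, energies[k], sigma)
  }
  .new_spectrum(grid, eps, meta = list(
    hwhm_ev = hwhm, shift_ev = 0, normalization = "none", units = units,
    weighting = weighting, sticks = data.frame(energy_ev = energies,
                                               f = strengths)))
}

#' Shift, combine and normalize spectra
#'
#' Utility for comparison plots: each spectrum is displaced along the energy
#' axis, resampled onto a common grid, combined with non-negative weights
#' (e.g. 50:50 for two tautomers of equal population) and finally normalized.
#'
#' @param spectra a `spectrum` or list of `spectrum` objects.
#' @param shifts energy displacement per spectrum (eV; recycled).
#' @param weights non-negative combination weight per spectrum (recycled).
#' @param normalization `"max"` (peak to 1, as in "normalised to 1" figure
#'   captions), `"area"` (unit integral) or `"none"`.
#' @param grid output grid; default: the first spectrum's grid.
#' @return a `spectrum` object; metadata records every applied shift and
#'   weight.
#' @export
shift_normalize_combine <- function(spectra, shifts = 0, weights = 1,
                                    normalization = c("max", "area", "none"),
                                    grid = NULL) {
  normalization <- match.arg(normalization)
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum")))
  shifts <- rep_len(shifts, length(spectra))
  weights <- rep_len(weights, length(spectra))
  if (any(weights < 0)) stop("'weights' must be >= 0", call. = FALSE)
  if (is.null(grid)) grid <- spectra[[1L]]$energy_ev
  eps <- numeric(length(grid))
  for (k in seq_along(spectra)) {
    sp <- spectra[[k]]
    eps <- eps + weights[k] * stats::approx(
      sp$energy_ev + shifts[k], sp$epsilon, xout = grid,
      yleft = 0, yright = 0)$y
  }
  scale <- switch(normalization,
                  max = if (max(eps) > 0) max(eps) else 1,
                  area = {
                    a <- sum(eps) * mean(diff(grid))
                    if (a > 0) a else 1
                  },
                  none = 1)
  .new_spectrum(grid, eps / scale, meta = list(
    hwhm_ev = spectra[[1L]]$meta$hwhm_ev,
    shift_ev = shifts, weights = weights, normalization = normalization,
    units = if (normalization == "none") spectra[[1L]]$meta$units else
      "normalized"))
}

#' Numerical moments of a spectrum
#'
#' Trapezoid-integrated zeroth moment, first moment and central variance of
#' the spectral density, optionally dividing the intensity by the energy
#' first (undoing the \eqn{\omega} prefactor so the moments can be compared
#' with the analytic [spectral_moments()] of the doorway state; remember the
#' Gaussian damping adds \eqn{2\Gamma} to the variance).
#'
#' @param sp a `spectrum` object.
#' @param divide_by_energy divide `epsilon` by the energy axis first?
#' @return list with `m0` (area), `m1` (eV) and `var` (eV^2).
#' @export
spectrum_moments <- function(sp, divide_by_energy = TRUE) {
  stopifnot(inherits(sp, "spectrum"))
  y <- if (divide_by_energy) sp$epsilon / sp$energy_ev else sp$epsilon
  x <- sp$energy_ev
  dx <- diff(x)
  tw <- function(v) sum(dx * (v[-1] + v[-length(v)]) / 2)
  m0 <- tw(y)
  m1 <- tw(x * y) / m0
  list(m0 = m0, m1 = m1, var = tw((x - m1)^2 * y) / m0)
}
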