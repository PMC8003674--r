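#' Normal-mode basis of a linear vibronic coupling model
#'
#' Collects the ground-state vibrational frequencies that define the
#' dimensionless normal coordinates of an LVC Hamiltonian. Imaginary input
#' frequencies (encoded as negative numbers, the usual quantum-chemistry
#' convention) are replaced by their absolute values with a warning; this is
#' the standard workaround for the small out-of-plane imaginary modes that
#' planar-constrained nucleobase optimizations produce.
#'
#' @param frequencies_ev numeric vector of mode frequencies \eqn{\Omega_\alpha}
#'   in eV; negative entries are interpreted as imaginary frequencies.
#' @param labels optional character vector of per-mode identifiers.
#' @param symmetry optional character vector of per-mode symmetry tags
#'   (e.g. `"A'"` / `"A''"` for in-plane / out-of-plane).
#' @return an object of class `normal_mode_basis`.
#' @export
normal_mode_basis <- function(frequencies_ev, labels = NULL, symmetry = NULL) {
  if (!is.numeric(frequencies_ev) || length(frequencies_ev) < 1L) {
    stop("'frequencies_ev' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(frequencies_ev))) {
    stop("'frequencies_ev' must be finite", call. = FALSE)
  }
  if (any(frequencies_ev < 0)) {
    warning(sprintf(
      "%d imaginary frequency(ies) replaced by absolute value",
      sum(frequencies_ev < 0)), call. = FALSE)
    frequencies_ev <- abs(frequencies_ev)
  }
  if (any(frequencies_ev == 0)) {
    stop("frequencies must be non-zero", call. = FALSE)
  }
  nmodes <- length(frequencies_ev)
  if (is.null(labels)) labels <- sprintf("mode%d", seq_len(nmodes))
  if (length(labels) != nmodes) {
    stop("'labels' must have one entry per mode", call. = FALSE)
  }
  if (!is.null(symmetry) && length(symmetry) != nmodes) {
    stop("'symmetry' must have one entry per mode", call. = FALSE)
  }
  structure(list(
    nmodes = nmodes,
    frequencies = as.numeric(frequencies_ev),
    labels = as.character(labels),
    symmetry = symmetry
  ), class = "normal_mode_basis")
}

#' @export
print.normal_mode_basis <- function(x, ...) {
  cat(sprintf("<normal_mode_basis> %d modes, Omega in [%.4g, %.4g] eV\n",
              x$nmodes, min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Linear vibronic coupling (LVC) model
#'
#' Defines the Hamiltonian
#' \deqn{H = \sum_i [K + V^{dia}_{ii}(q)] |d_i\rangle\langle d_i| +
#'   \sum_{i<j} V^{dia}_{ij}(q) (|d_i\rangle\langle d_j| + h.c.)}
#' with \eqn{K = \frac12 p^T \Omega p},
#' \eqn{V^{dia}_{ii}(q) = E^0_i + \lambda_{ii}^T q + \frac12 q^T \Omega q} and
#' \eqn{V^{dia}_{ij}(q) = \lambda_{ij}^T q}, in dimensionless ground-state
#' normal coordinates.
#'
#' @param basis a [normal_mode_basis()], or a numeric vector of frequencies
#'   (eV) which is promoted to one.
#' @param E0_ev numeric vector of vertical excitation energies \eqn{E^0_i}
#'   (eV), one per diabatic state.
#' @param lambda_diag matrix (`nstates x nmodes`) of intrastate gradients
#'   \eqn{\lambda_{ii,\alpha}} (eV).
#' @param lambda_offdiag inter-state coupling gradients
#'   \eqn{\lambda_{ij,\alpha}} (eV): an array `nstates x nstates x nmodes`,
#'   symmetric in its first two indices with zero diagonal slices. `NULL`
#'   means all couplings zero (a vertical-gradient model).
#' @param dipoles matrix (`nstates x 3`) of Cartesian transition dipoles
#'   \eqn{\mu_{gi}} in atomic units; zero rows mark dark states. `NULL` means
#'   all dark.
#' @param state_labels optional character tags (e.g. `"ppistar1"`, `"nOpi1"`).
#' @return an object of class `lvc_model`.
#' @seealso [diabatic_potential_at()], [propagate()], [make_toy_model()]
#' @export
lvc_model <- function(basis, E0_ev, lambda_diag = NULL, lambda_offdiag = NULL,
                      dipoles = NULL, state_labels = NULL) {
  if (!inherits(basis, "normal_mode_basis")) basis <- normal_mode_basis(basis)
  nmodes <- basis$nmodes
  nstates <- length(E0_ev)
  if (nstates < 1L || any(!is.finite(E0_ev))) {
    stop("'E0_ev' must be a finite non-empty numeric vector", call. = FALSE)
  }
  if (is.null(lambda_diag)) lambda_diag <- matrix(0, nstates, nmodes)
  lambda_diag <- as.matrix(lambda_diag)
  if (!all(dim(lambda_diag) == c(nstates, nmodes))) {
    stop("'lambda_diag' must be nstates x nmodes", call. = FALSE)
  }
  if (is.null(lambda_offdiag)) {
    lambda_offdiag <- array(0, dim = c(nstates, nstates, nmodes))
  }
  if (!identical(dim(lambda_offdiag), as.integer(c(nstates, nstates, nmodes)))) {
    stop("'lambda_offdiag' must be nstates x nstates x nmodes", call. = FALSE)
  }
  for (a in seq_len(nmodes)) {
    sl <- lambda_offdiag[, , a, drop = FALSE]
    dim(sl) <- c(nstates, nstates)
    if (max(abs(sl - t(sl))) > 1e-12) {
      stop("'lambda_offdiag' must be symmetric in (i, j)", call. = FALSE)
    }
    if (max(abs(diag(sl))) > 0) {
      stop("diagonal slices of 'lambda_offdiag' must be zero; ",
           "diagonal gradients belong in 'lambda_diag'", call. = FALSE)
    }
  }
  if (is.null(dipoles)) dipoles <- matrix(0, nstates, 3)
  dipoles <- as.matrix(dipoles)
  if (!all(dim(dipoles) == c(nstates, 3)) || any(!is.finite(dipoles))) {
    stop("'dipoles' must be a finite nstates x 3 matrix", call. = FALSE)
  }
  if (is.null(state_labels)) state_labels <- sprintf("S%d", seq_len(nstates))
  if (length(state_labels) != nstates) {
    stop("'state_labels' must have one entry per state", call. = FALSE)
  }
  structure(list(
    nstates = nstates,
    basis = basis,
    E0 = as.numeric(E0_ev),
    lambda_diag = lambda_diag,
    lambda_offdiag = lambda_offdiag,
    dipoles = dipoles,
    state_labels = as.character(state_labels)
  ), class = "lvc_model")
}

#' @export
print.lvc_model <- function(x, ...) {
  bright <- rowSums(x$dipoles^2) > 0
  cat(sprintf("<lvc_model> %d states (%d bright) x %d modes\n",
              x$nstates, sum(bright), x$basis$nmodes))
  cat("  E0 [eV]: ", paste(sprintf("%.3f", x$E0), collapse = ", "), "\n")
  cat("  max |lambda_ii| =", sprintf("%.4g", max(abs(x$lambda_diag))),
      "eV; max |lambda_ij| =", sprintf("%.4g", max(abs(x$lambda_offdiag))),
      "eV\n")
  invisible(x)
}

.check_q <- function(model, q) {
  if (length(q) != model$basis$nmodes || !is.numeric(q)) {
    stop(sprintf("coordinate vector has length %d, model has %d modes",
                 length(q), model$basis$nmodes), call. = FALSE)
  }
}

#' Diabatic potential matrix at a nuclear geometry
#'
#' Evaluates \eqn{V^{dia}(q)}: diagonal elements
#' \eqn{E^0_i + \lambda_{ii}^T q + \frac12 q^T \Omega q}, off-diagonal
#' elements \eqn{\lambda_{ij}^T q}.
#'
#' @param model an [lvc_model()].
#' @param q numeric coordinate vector (dimensionless), one entry per mode.
#' @return symmetric `nstates x nstates` matrix in eV.
#' @export
diabatic_potential_at <- function(model, q) {
  stopifnot(inherits(model, "lvc_model"))
  .check_q(model, q)
  n <- model$nstates
  quad <- 0.5 * sum(model$basis$frequencies * q^2)
  v <- matrix(0, n, n)
  for (a in seq_along(q)) {
    if (q[a] != 0) v <- v + model$lambda_offdiag[, , a] * q[a]
  }
  diag(v) <- model$E0 + as.numeric(model$lambda_diag %*% q) + quad
  v
}

#' Adiabatic energies (and states) at a nuclear geometry
#'
#' Eigenvalues of the diabatic potential matrix, in ascending order. With
#' `vectors = TRUE` the eigenvector matrix (columns in the same order,
#' expressed in the diabatic basis) is returned as well, which is what a
#' mock adiabatic scan needs.
#'
#' @inheritParams diabatic_potential_at
#' @param vectors return eigenvectors too?
#' @return numeric vector of ascending energies (eV), or a list with
#'   `energies` and `vectors`.
#' @export
adiabatic_energies_at <- function(model, q, vectors = FALSE) {
  v <- diabatic_potential_at(model, q)
  e <- eigen(v, symmetric = TRUE)
  ord <- rev(seq_along(e$values))  # eigen() sorts descending
  if (!vectors) return(e$values[ord])
  list(energies = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
}

#' Analytic spectral moments of a doorway state's lineshape
#'
#' For a vertical excitation of the ground vibrational state onto diabatic
#' state `state` the absorption lineshape (energies referenced to the ground
#' vibrational level, no phenomenological broadening) has exactly
#' \deqn{m_1 = E^0_i, \qquad
#'   \mathrm{var} = \tfrac12 \sum_\alpha \big[\lambda_{ii,\alpha}^2 +
#'   \sum_{j \ne i}\lambda_{ij,\alpha}^2\big],}
#' following from \eqn{\langle 0|q_\alpha^2|0\rangle = 1/2}. These closed
#' forms serve as an independent oracle for the numerically computed spectra.
#'
#' @inheritParams diabatic_potential_at
#' @param state diabatic state index.
#' @return list with `m0` (\eqn{|\mu|^2}), `m1` (eV) and `var` (eV^2).
#' @export
spectral_moments <- function(model, state) {
  stopifnot(inherits(model, "lvc_model"))
  if (state < 1 || state > model$nstates) {
    stop("'state' out of bounds", call. = FALSE)
  }
  lam2 <- model$lambda_diag[state, ]^2
  coup2 <- colSums(matrix(model$lambda_offdiag[state, , ]^2,
                          model$nstates, model$basis$nmodes))
  list(m0 = sum(model$dipoles[state, ]^2),
       m1 = model$E0[state],
       var = 0.5 * sum(lam2 + coup2))
}

#' Zero-point energy of the ground-state nuclear Hamiltonian
#' @param model an [lvc_model()] or [normal_mode_basis()].
#' @return scalar, eV.
#' @export
zero_point_energy <- function(model) {
  b <- if (inherits(model, "lvc_model")) model$basis else model
  0.5 * sum(b$frequencies)
}
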