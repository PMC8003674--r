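#' Default harmonic-oscillator truncation for a model
#'
#' Per-mode maximum quantum number `nmax_alpha = max(8, ceil(4 S_alpha) + 6)`
#' with the Huang-Rhys factor
#' \eqn{S_\alpha = \max_i \lambda_{ii,\alpha}^2 / (2\Omega_\alpha^2)} taken
#' over all states. Large displacements get more basis functions; the floor
#' of 8 keeps weakly displaced modes safely converged.
#'
#' @param model an [lvc_model()].
#' @return integer vector of per-mode `nmax` (basis size is `nmax + 1`).
#' @export
default_truncation <- function(model) {
  stopifnot(inherits(model, "lvc_model"))
  om <- model$basis$frequencies
  s <- apply(sweep(model$lambda_diag^2, 2L, 2 * om^2, `/`), 2L, max)
  pmax(8L, as.integer(ceiling(4 * s)) + 6L)
}

# per-mode ladder operators in the HO basis, <0|q^2|0> = 1/2 convention
.q_matrix <- function(d) {
  n <- seq_len(d - 1L)
  m <- matrix(0, d, d)
  m[cbind(n, n + 1L)] <- sqrt(n / 2)
  m[cbind(n + 1L, n)] <- sqrt(n / 2)
  m
}

.kron_chain <- function(ops) {
  Reduce(function(a, b) methods::as(kronecker(a, b), "CsparseMatrix"), ops)
}

#' Sparse LVC Hamiltonian in the truncated HO product basis
#'
#' Assembles \eqn{H} of the LVC model with \eqn{q_\alpha = (a_\alpha +
#' a_\alpha^\dagger)/\sqrt2} in a direct-product basis of per-mode harmonic
#' oscillator functions, ordered state-major (all vibrational configurations
#' of state 1, then state 2, ...). Mode 1 is the slowest-varying vibrational
#' index. The zero-point energy \eqn{\frac12\sum_\alpha\Omega_\alpha} is
#' included.
#'
#' @param model an [lvc_model()].
#' @param nmax per-mode maximum quantum number (scalar or vector); default
#'   from [default_truncation()].
#' @param max_basis guard on the total basis size (electronic x vibrational).
#' @return a real symmetric `Matrix::dgCMatrix`.
#' @export
lvc_hamiltonian <- function(model, nmax = NULL, max_basis = 5e5) {
  stopifnot(inherits(model, "lvc_model"))
  if (is.null(nmax)) nmax <- default_truncation(model)
  nmodes <- model$basis$nmodes
  nmax <- rep_len(as.integer(nmax), nmodes)
  if (any(nmax < 1L)) stop("'nmax' must be >= 1", call. = FALSE)
  d <- nmax + 1L
  nvib <- prod(d)
  ntot <- model$nstates * nvib
  if (ntot > max_basis) {
    stop(sprintf(
      "basis size %d exceeds cap %d; reduce modes (see reduce_modes()) or lower nmax",
      ntot, as.integer(max_basis)), call. = FALSE)
  }
  om <- model$basis$frequencies
  ident <- lapply(d, function(k) Matrix::Diagonal(k))
  # vibrational H0 = sum_a Omega_a (n_a + 1/2), diagonal
  h0_diag <- rep(0, nvib)
  for (a in seq_len(nmodes)) {
    ops <- ident
    ops[[a]] <- Matrix::Diagonal(x = om[a] * (seq_len(d[a]) - 1L + 0.5))
    h0_diag <- h0_diag + Matrix::diag(.kron_chain(ops))
  }
  q_ops <- lapply(seq_len(nmodes), function(a) {
    ops <- ident
    ops[[a]] <- methods::as(Matrix::Matrix(.q_matrix(d[a]), sparse = TRUE),
                            "CsparseMatrix")
    .kron_chain(ops)
  })
  blocks <- vector("list", model$nstates^2)
  zero <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(nvib, nvib))
  for (i in seq_len(model$nstates)) {
    for (j in seq_len(model$nstates)) {
      idx <- (i - 1L) * model$nstates + j
      if (i == j) {
        b <- Matrix::Diagonal(x = h0_diag + model$E0[i])
        for (a in seq_len(nmodes)) {
          if (model$lambda_diag[i, a] != 0) {
            b <- b + model$lambda_diag[i, a] * q_ops[[a]]
          }
        }
      } else {
        b <- zero
        for (a in seq_len(nmodes)) {
          if (model$lambda_offdiag[i, j, a] != 0) {
            b <- b + model$lambda_offdiag[i, j, a] * q_ops[[a]]
          }
        }
      }
      blocks[[idx]] <- b
    }
  }
  rows <- lapply(seq_len(model$nstates), function(i) {
    do.call(cbind, blocks[((i - 1L) * model$nstates + 1L):(i * model$nstates)])
  })
  h <- methods::as(do.call(rbind, rows), "CsparseMatrix")
  attr(h, "truncation") <- nmax
  h
}

#' Doorway wavepacket
#'
#' The vertical-excitation initial condition \eqn{|d_i; 0\rangle}: the ground
#' vibrational state placed on diabatic surface `state` with unit
#' coefficient.
#'
#' @param model an [lvc_model()].
#' @param state diabatic state index.
#' @param nmax per-mode truncation; default [default_truncation()].
#' @return object of class `wavepacket` with complex `coefficients`,
#'   `nstates`, `truncation` and `norm`.
#' @export
make_doorway <- function(model, state, nmax = NULL) {
  stopifnot(inherits(model, "lvc_model"))
  if (state < 1 || state > model$nstates) {
    stop("'state' out of bounds", call. = FALSE)
  }
  if (is.null(nmax)) nmax <- default_truncation(model)
  nmax <- rep_len(as.integer(nmax), model$basis$nmodes)
  nvib <- prod(nmax + 1L)
  coef <- complex(model$nstates * nvib)
  coef[(state - 1L) * nvib + 1L] <- 1 + 0i
  structure(list(coefficients = coef, nstates = model$nstates,
                 truncation = nmax, state = as.integer(state),
                 norm = 1), class = "wavepacket")
}

#' @export
print.wavepacket <- function(x, ...) {
  cat(sprintf("<wavepacket> %d states x %d vibrational configs, norm %.8f\n",
              x$nstates, length(x$coefficients) / x$nstates, x$norm))
  invisible(x)
}

.wp_populations <- function(coef, nstates) {
  nvib <- length(coef) / nstates
  vapply(seq_len(nstates), function(i) {
    idx <- ((i - 1L) * nvib + 1L):(i * nvib)
    sum(Re(coef[idx])^2 + Im(coef[idx])^2)
  }, numeric(1))
}

# complex matvec through a real sparse matrix
.cmatvec <- function(h, v) {
  as.vector(h %*% Re(v)) + 1i * as.vector(h %*% Im(v))
}

# one short-iterative-Lanczos step: exp(-1i * H * dt / hbar) %*% psi
# (dt may be negative for backward propagation); full reorthogonalization.
.sil_step <- function(h, psi, dt, tol = 1e-10, mmax = 48L) {
  nrm0 <- sqrt(sum(Re(psi)^2 + Im(psi)^2))
  v <- matrix(0i, length(psi), mmax)
  v[, 1L] <- psi / nrm0
  alpha <- numeric(mmax)
  beta <- numeric(mmax)
  u <- NULL
  m_used <- mmax
  for (m in seq_len(mmax)) {
    w <- .cmatvec(h, v[, m])
    alpha[m] <- Re(sum(Conj(v[, m]) * w))
    w <- w - alpha[m] * v[, m]
    if (m > 1L) w <- w - beta[m - 1L] * v[, m - 1L]
    # one classical Gram-Schmidt sweep against all previous vectors
    proj <- crossprod(Conj(v[, seq_len(m), drop = FALSE]), w)
    w <- w - v[, seq_len(m), drop = FALSE] %*% proj
    beta[m] <- sqrt(sum(Re(w)^2 + Im(w)^2))
    tmat <- diag(alpha[seq_len(m)], m, m)
    if (m > 1L) {
      ij <- cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)
      tmat[ij] <- beta[seq_len(m - 1L)]
      tmat[ij[, 2:1, drop = FALSE]] <- beta[seq_len(m - 1L)]
    }
    te <- eigen(tmat, symmetric = TRUE)
    u <- te$vectors %*% (exp(-1i * te$values * dt / hbar_ev_fs) *
                           te$vectors[1L, ])
    err <- beta[m] * abs(u[m]) * abs(dt) / hbar_ev_fs
    if (err < tol || beta[m] < 1e-13) {
      m_used <- m
      break
    }
    if (m < mmax) v[, m + 1L] <- w / beta[m]
  }
  list(psi = nrm0 * as.vector(v[, seq_len(m_used), drop = FALSE] %*%
                                u[seq_len(m_used)]),
       energy = alpha[1L], order = m_used)
}

#' Propagate a wavepacket under the LVC Hamiltonian
#'
#' Numerically exact unitary evolution in the truncated HO product basis
#' using a short-iterative Lanczos (Krylov) expansion of the propagator on
#' the sparse Hamiltonian, with per-step error control. The autocorrelation
#' \eqn{C(t) = \langle\psi(0)|\psi(t)\rangle} and the stored per-state
#' doorway overlaps are phase-referenced to the ground vibrational level
#' (the zero-point energy is factored out), which is the convention of the
#' closed-form displaced-oscillator correlation and of the spectra.
#'
#' @param model an [lvc_model()].
#' @param psi0 initial [make_doorway()] wavepacket (or any `wavepacket`).
#' @param t_final propagation length (fs). Default 250 fs.
#' @param dt time step between stored samples (fs), > 0. Default 0.1 fs.
#' @param krylov_tol per-step truncation tolerance of the Lanczos expansion.
#' @param mmax maximum Krylov order per step.
#' @param max_basis passed to [lvc_hamiltonian()].
#' @param backward propagate with `exp(+i H t / hbar)` instead (time
#'   reversal).
#' @param hamiltonian optionally a prebuilt [lvc_hamiltonian()] matching
#'   `psi0`'s truncation, to amortize construction across runs.
#' @return object of class `propagation_result`: `times` (fs), complex
#'   `autocorr`, `populations` (`ntimes x nstates`), `doorway_overlaps`
#'   (`ntimes x nstates`, \eqn{\langle d_j;0|\psi(t)\rangle}), `norm_trace`,
#'   `energy_trace` (eV, includes zero-point energy), final `psi`, and `meta`.
#' @export
propagate <- function(model, psi0, t_final = 250, dt = 0.1,
                      krylov_tol = 1e-10, mmax = 48L, max_basis = 5e5,
                      backward = FALSE, hamiltonian = NULL) {
  stopifnot(inherits(model, "lvc_model"), inherits(psi0, "wavepacket"))
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (t_final <= 0) stop("'t_final' must be positive", call. = FALSE)
  h <- if (is.null(hamiltonian)) {
    lvc_hamiltonian(model, psi0$truncation, max_basis)
  } else hamiltonian
  n <- nrow(h)
  if (n != length(psi0$coefficients)) {
    stop("Hamiltonian and wavepacket dimensions disagree", call. = FALSE)
  }
  # center the spectrum to halve the Krylov polynomial degree
  dvals <- Matrix::diag(h)
  rad <- abs(h)
  row_r <- as.vector(rad %*% rep(1, n)) - abs(dvals)
  center <- (max(dvals + row_r) + min(dvals - row_r)) / 2
  hs <- h - Matrix::Diagonal(n, center)
  zpe <- zero_point_energy(model)
  sgn <- if (backward) -1 else 1
  nsteps <- as.integer(round(t_final / dt))
  times <- (0:nsteps) * dt
  nvib <- n / model$nstates
  doorway_idx <- (seq_len(model$nstates) - 1L) * nvib + 1L

  psi <- psi0$coefficients
  psi_ref <- Conj(psi0$coefficients)
  autocorr <- complex(nsteps + 1L)
  overlaps <- matrix(0i, nsteps + 1L, model$nstates)
  pops <- matrix(0, nsteps + 1L, model$nstates)
  norm_trace <- numeric(nsteps + 1L)
  energy_trace <- numeric(nsteps + 1L)

  record <- function(k, psi) {
    # reference phases to the ground vibrational level
    ph <- exp(1i * sgn * zpe * times[k] / hbar_ev_fs)
    autocorr[k] <<- sum(psi_ref * psi) * ph
    overlaps[k, ] <<- psi[doorway_idx] * ph
    pops[k, ] <<- .wp_populations(psi, model$nstates)
    norm_trace[k] <<- sqrt(sum(pops[k, ]))
  }
  record(1L, psi)
  energy_trace[1L] <- Re(sum(Conj(psi) * .cmatvec(h, psi))) /
    norm_trace[1L]^2
  for (k in seq_len(nsteps)) {
    st <- .sil_step(hs, psi, sgn * dt, tol = krylov_tol, mmax = mmax)
    psi <- st$psi * exp(-1i * sgn * center * dt / hbar_ev_fs)
    record(k + 1L, psi)
    energy_trace[k] <- st$energy + center  # Rayleigh quotient at step start
    if (abs(norm_trace[k + 1L] - norm_trace[1L]) > 1e-6 * norm_trace[1L]) {
      stop(sprintf("norm deviates by %.3g at step %d (t = %.2f fs)",
                   abs(norm_trace[k + 1L] - norm_trace[1L]), k,
                   times[k + 1L]), call. = FALSE)
    }
  }
  # energy at the last stored time uses the step-start Rayleigh quotient;
  # recompute it directly for the final state
  energy_trace[nsteps + 1L] <- Re(sum(Conj(psi) * .cmatvec(h, psi))) /
    norm_trace[nsteps + 1L]^2
  structure(list(
    times = times,
    autocorr = autocorr,
    populations = pops,
    doorway_overlaps = overlaps,
    norm_trace = norm_trace,
    energy_trace = energy_trace,
    psi = structure(list(coefficients = psi, nstates = model$nstates,
                         truncation = psi0$truncation, state = psi0$state,
                         norm = norm_trace[nsteps + 1L]),
                    class = "wavepacket"),
    meta = list(state = psi0$state, dt = dt, t_final = t_final,
                truncation = psi0$truncation, krylov_tol = krylov_tol,
                backward = backward, zero_point_ev = zpe,
                state_labels = model$state_labels,
                dipoles = model$dipoles, E0 = model$E0)
  ), class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(
    "<propagation_result> doorway state %d, %d steps of %.3g fs\n",
    x$meta$state, length(x$times) - 1L, x$meta$dt))
  cat(sprintf("  final populations: %s\n",
              paste(sprintf("%.3f", x$populations[nrow(x$populations), ]),
                    collapse = ", ")))
  cat(sprintf("  max |norm - 1| = %.3g, energy drift = %.3g eV\n",
              max(abs(x$norm_trace - 1)),
              diff(range(x$energy_trace))))
  invisible(x)
}

#' Closed-form vertical-gradient autocorrelation
#'
#' For the uncoupled (all \eqn{\lambda_{ij} = 0}) problem each mode is an
#' independent displaced harmonic oscillator, and the doorway
#' autocorrelation has the closed form
#' \deqn{C(t) = e^{-i E^{00}_i t/\hbar} \prod_\alpha
#'   \exp\!\big[S_\alpha (e^{-i\Omega_\alpha t/\hbar} - 1)\big], \qquad
#'   E^{00}_i = E^0_i - \sum_\alpha S_\alpha \Omega_\alpha,}
#' with Huang-Rhys factors
#' \eqn{S_\alpha = \lambda_{ii,\alpha}^2 / (2\Omega_\alpha^2)}, energies
#' referenced to the ground vibrational level. \eqn{E^{00}_i} is the 0-0
#' (adiabatic) energy; using it rather than the vertical energy in the
#' prefactor is what makes the lineshape's first moment come out at
#' \eqn{E^0_i} (the Poisson progression has mean \eqn{S_\alpha}). Used both
#' as the VG spectrum backend and as an oracle for [propagate()].
#'
#' @param model an [lvc_model()] (inter-state couplings are ignored).
#' @param state diabatic state index.
#' @param times numeric time grid (fs).
#' @return complex vector `C(t)`.
#' @export
analytic_vg_autocorrelation <- function(model, state, times) {
  stopifnot(inherits(model, "lvc_model"))
  if (state < 1 || state > model$nstates) {
    stop("'state' out of bounds", call. = FALSE)
  }
  om <- model$basis$frequencies
  s <- model$lambda_diag[state, ]^2 / (2 * om^2)
  e00 <- model$E0[state] - sum(s * om)
  ph <- exp(-1i * e00 * times / hbar_ev_fs)
  for (a in seq_along(om)) {
    ph <- ph * exp(s[a] * (exp(-1i * om[a] * times / hbar_ev_fs) - 1))
  }
  ph
}

#' Reduce an LVC model to its most strongly coupled modes
#'
#' Ranks modes by the importance score
#' \eqn{s_\alpha = \sum_i \lambda_{ii,\alpha}^2 +
#' \sum_{i<j} \lambda_{ij,\alpha}^2} and keeps the `k` largest (ties broken
#' by lower mode index), enabling desk-scale propagation of models whose
#' full dimensionality is out of reach of an explicit product basis.
#'
#' @param model an [lvc_model()].
#' @param k number of modes to keep.
#' @param dressing_state if not `NULL`, additionally return per-discarded-
#'   mode vertical-gradient dressing factors for this initial state: the
#'   approximation multiplies an autocorrelation by the closed-form
#'   displaced-oscillator factor of each discarded mode. Exact only while
#'   the dynamics stays on `dressing_state`; off by default.
#' @return list with `model` (the reduced [lvc_model()]), `report` (a data
#'   frame of per-mode scores and kept flags), `discarded_weight` (fraction
#'   of total score dropped) and, if requested, `dressing` (list of
#'   `omega`/`huang_rhys` for discarded modes) and `apply_dressing`, a
#'   function `(autocorr, times) -> autocorr`.
#' @export
reduce_modes <- function(model, k, dressing_state = NULL) {
  stopifnot(inherits(model, "lvc_model"))
  nmodes <- model$basis$nmodes
  if (k < 1 || k > nmodes) stop("'k' out of range", call. = FALSE)
  score <- vapply(seq_len(nmodes), function(a) {
    off <- model$lambda_offdiag[, , a]
    sum(model$lambda_diag[, a]^2) + sum(off[upper.tri(off)]^2)
  }, numeric(1))
  keep <- sort(order(-score, seq_len(nmodes))[seq_len(k)])
  basis <- normal_mode_basis(model$basis$frequencies[keep],
                             model$basis$labels[keep],
                             model$basis$symmetry[keep])
  red <- lvc_model(basis, model$E0,
                   model$lambda_diag[, keep, drop = FALSE],
                   model$lambda_offdiag[, , keep, drop = FALSE],
                   model$dipoles, model$state_labels)
  report <- data.frame(mode = seq_len(nmodes),
                       label = model$basis$labels,
                       score = score,
                       kept = seq_len(nmodes) %in% keep)
  out <- list(model = red, report = report,
              discarded_weight = if (sum(score) > 0) {
                sum(score[!report$kept]) / sum(score)
              } else 0)
  if (!is.null(dressing_state)) {
    drop_idx <- setdiff(seq_len(nmodes), keep)
    om <- model$basis$frequencies[drop_idx]
    s <- model$lambda_diag[dressing_state, drop_idx]^2 / (2 * om^2)
    out$dressing <- list(omega = om, huang_rhys = s)
    out$apply_dressing <- function(autocorr, times) {
      for (a in seq_along(om)) {
        autocorr <- autocorr *
          exp(s[a] * (exp(-1i * om[a] * times / hbar_ev_fs) - 1))
      }
      autocorr
    }
  }
  out
}
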