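# Independent oracles used across the suite.

hbar <- 0.6582119569

# Brute-force propagation by full dense eigendecomposition of the truncated
# Hamiltonian: psi(t) = V exp(-i E t / hbar) V^T psi(0). Independent of the
# package's Lanczos stepper; shares only the Hamiltonian assembly.
dense_propagate <- function(model, state, times, nmax) {
  h <- as.matrix(lvc_hamiltonian(model, nmax))
  ee <- eigen(h, symmetric = TRUE)
  nvib <- nrow(h) / model$nstates
  psi0 <- numeric(nrow(h))
  psi0[(state - 1L) * nvib + 1L] <- 1
  amp <- as.vector(crossprod(ee$vectors, psi0))
  zpe <- zero_point_energy(model)
  pops <- matrix(0, length(times), model$nstates)
  autocorr <- complex(length(times))
  for (k in seq_along(times)) {
    psi <- ee$vectors %*% (exp(-1i * ee$values * times[k] / hbar) * amp)
    autocorr[k] <- sum(psi0 * psi) * exp(1i * zpe * times[k] / hbar)
    for (i in seq_len(model$nstates)) {
      idx <- ((i - 1L) * nvib + 1L):(i * nvib)
      pops[k, i] <- sum(Mod(psi[idx])^2)
    }
  }
  list(autocorr = autocorr, populations = pops)
}

# a small coupled 2-state/2-mode model with moderate Huang-Rhys factors,
# cheaper than the conical-intersection preset
small_coupled_model <- function() {
  lam_o <- array(0, dim = c(2, 2, 2))
  lam_o[1, 2, 2] <- lam_o[2, 1, 2] <- 0.08
  lvc_model(normal_mode_basis(c(0.12, 0.18)),
            E0_ev = c(4.6, 5.0),
            lambda_diag = rbind(c(0.06, 0), c(-0.09, 0.05)),
            lambda_offdiag = lam_o,
            dipoles = rbind(c(0, 0, 0), c(0.8, 0.3, 0)))
}

# random fully specified toy model drawn through the fixtures module
random_model <- function(seed, nstates = NULL, nmodes = NULL) {
  set.seed(seed)
  if (is.null(nstates)) nstates <- sample(2:6, 1)
  if (is.null(nmodes)) nmodes <- sample(2:8, 1)
  make_toy_model(fixture_spec(nstates, nmodes, seed = seed + 1000L))
}
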