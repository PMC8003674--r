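test_that("model construction enforces the LVC invariants", {
  expect_warning(b <- normal_mode_basis(c(0.1, -0.05)), "imaginary")
  expect_equal(b$frequencies, c(0.1, 0.05))

  lam_o <- array(0, dim = c(2, 2, 1))
  lam_o[1, 2, 1] <- 0.1  # not symmetrized
  expect_error(lvc_model(c(0.1), c(1, 2), lambda_offdiag = lam_o),
               "symmetric")
  lam_o[2, 1, 1] <- 0.1
  diag_bad <- lam_o
  diag_bad[1, 1, 1] <- 0.2
  expect_error(lvc_model(c(0.1), c(1, 2), lambda_offdiag = diag_bad),
               "diagonal")
  m <- lvc_model(c(0.1), c(1, 2), lambda_offdiag = lam_o)
  expect_s3_class(m, "lvc_model")
  expect_error(diabatic_potential_at(m, c(0, 0)), "1 modes")
})

test_that("diabatic potential matches the closed form", {
  # uracil-like vertical energies: at the FC point the matrix is diagonal
  e0 <- c(5.10, 5.50, 6.18, 6.62, 6.88)
  m <- make_toy_model(fixture_spec(5, 4, seed = 3))
  m$E0 <- e0
  v0 <- diabatic_potential_at(m, rep(0, 4))
  expect_equal(diag(v0), e0)
  expect_equal(v0 - diag(diag(v0)), matrix(0, 5, 5))

  # 1 state, 1 mode direct substitution
  m1 <- lvc_model(c(0.05), 2.0, lambda_diag = matrix(0.1, 1, 1))
  expect_equal(diabatic_potential_at(m1, 1)[1, 1], 2.125)

  # symmetry and exact quadratic behaviour along single coordinates
  for (seed in 1:3) {
    m <- random_model(seed)
    q <- rnorm(m$basis$nmodes)
    v <- diabatic_potential_at(m, q)
    expect_equal(v, t(v))
    a <- sample(m$basis$nmodes, 1)
    h <- 0.37
    qp <- qm <- q
    qp[a] <- q[a] + h
    qm[a] <- q[a] - h
    second <- (diabatic_potential_at(m, qp) + diabatic_potential_at(m, qm) -
                 2 * v) / h^2
    expect_equal(diag(second), rep(m$basis$frequencies[a], m$nstates))
    expect_equal(second - diag(diag(second)),
                 matrix(0, m$nstates, m$nstates), tolerance = 1e-10)
  }
})

test_that("adiabatic energies are eigenvalues, sorted, trace-preserving", {
  # 2-state closed form: E0 = (0,0), coupling c at q = 1
  lam_o <- array(0, dim = c(2, 2, 1))
  lam_o[1, 2, 1] <- lam_o[2, 1, 1] <- 0.3
  m2 <- lvc_model(c(0.1), c(0, 0), lambda_offdiag = lam_o)
  e <- adiabatic_energies_at(m2, 1)
  expect_equal(e, 0.05 + c(-0.3, 0.3))

  for (seed in 4:6) {
    m <- random_model(seed, nstates = 4, nmodes = 3)
    q <- rnorm(3)
    e <- adiabatic_energies_at(m, q)
    expect_false(is.unsorted(e))
    # independent dense eigensolve of the matrix assembled from the formula
    v <- matrix(0, 4, 4)
    for (a in 1:3) v <- v + m$lambda_offdiag[, , a] * q[a]
    diag(v) <- m$E0 + m$lambda_diag %*% q +
      0.5 * sum(m$basis$frequencies * q^2)
    expect_equal(e, sort(eigen(v, symmetric = TRUE)$values))
    # trace invariance
    expect_equal(sum(e), sum(diag(diabatic_potential_at(m, q))))
    # eigenvectors diagonalize
    ad <- adiabatic_energies_at(m, q, vectors = TRUE)
    expect_equal(ad$vectors %*% diag(ad$energies) %*% t(ad$vectors),
                 diabatic_potential_at(m, q))
  }
})

test_that("analytic spectral moments match their closed forms", {
  m0 <- lvc_model(c(0.1, 0.2), c(3, 4))
  expect_equal(spectral_moments(m0, 1), list(m0 = 0, m1 = 3, var = 0))

  m1 <- lvc_model(c(0.05), 2.0, lambda_diag = matrix(0.1, 1, 1))
  expect_equal(spectral_moments(m1, 1)$var, 0.005)

  # couplings contribute half their squared sum
  m <- small_coupled_model()
  expect_equal(spectral_moments(m, 2)$var,
               0.5 * (0.09^2 + 0.05^2 + 0.08^2))
  expect_error(spectral_moments(m, 3), "bounds")
})

test_that("lineshape first moment reproduces the analytic m1", {
  # numerically integrated first moment of the computed spectrum equals E0
  m <- random_model(11, nstates = 2, nmodes = 2)
  m$dipoles[1, ] <- c(1, 0, 0)
  res <- propagate(m, make_doorway(m, 1, nmax = 10), t_final = 120, dt = 0.2)
  an <- spectral_moments(m, 1)
  grid <- seq(an$m1 - 8 * sqrt(an$var + 0.02), an$m1 + 8 * sqrt(an$var + 0.02),
              length.out = 1500)
  sp <- autocorrelation_to_spectrum(res, gamma = hwhm_to_gamma(0.05),
                                    grid = grid, units = "relative")
  mom <- spectrum_moments(sp)
  expect_equal(mom$m1, an$m1, tolerance = 1e-3)
})
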