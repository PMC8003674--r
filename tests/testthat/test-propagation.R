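test_that("doorway states have the advertised structure", {
  m <- small_coupled_model()
  psi <- make_doorway(m, 2, nmax = 6)
  expect_equal(psi$norm, 1)
  pops <- vibronic:::.wp_populations(psi$coefficients, 2)
  expect_equal(pops, c(0, 1))
  expect_error(make_doorway(m, 3), "bounds")

  # <psi0|H|psi0> = E0 + zero-point energy, independent of truncation
  for (nm in c(4, 8)) {
    psi <- make_doorway(m, 2, nmax = nm)
    h <- lvc_hamiltonian(m, nm)
    e <- Re(sum(Conj(psi$coefficients) *
                  vibronic:::.cmatvec(h, psi$coefficients)))
    expect_equal(e, m$E0[2] + zero_point_energy(m))
  }
})

test_that("propagator agrees with dense eigendecomposition", {
  m <- small_coupled_model()
  times <- seq(0, 60, by = 0.2)
  res <- propagate(m, make_doorway(m, 2, nmax = 7), t_final = 60, dt = 0.2)
  oracle <- dense_propagate(m, 2, times, nmax = 7)
  expect_lt(max(abs(res$autocorr - oracle$autocorr)), 1e-8)
  expect_lt(max(abs(res$populations - oracle$populations)), 1e-8)
})

test_that("uncoupled propagation matches the closed-form VG correlation", {
  m <- lvc_model(c(0.18, 0.09), c(4.2, 5.1),
                 lambda_diag = rbind(c(0.09, 0.04), c(0, 0)))
  res <- propagate(m, make_doorway(m, 1, nmax = 12), t_final = 80, dt = 0.2)
  cvg <- analytic_vg_autocorrelation(m, 1, res$times)
  expect_lt(max(abs(res$autocorr - cvg)), 1e-6)
  # populations frozen without couplings
  expect_equal(res$populations[, 1], rep(1, length(res$times)),
               tolerance = 1e-12)
})

test_that("analytic VG correlation has its closed-form properties", {
  m <- lvc_model(c(0.05), 2.0, lambda_diag = matrix(0.1, 1, 1))
  ts <- seq(0, 200, by = 0.5)
  c1 <- analytic_vg_autocorrelation(m, 1, ts)
  expect_equal(c1[1], 1 + 0i)
  period <- 2 * pi * 0.6582119569 / 0.05
  expect_equal(abs(analytic_vg_autocorrelation(m, 1, period)), 1,
               tolerance = 1e-12)
  # no displacement: pure phase at E0
  m0 <- lvc_model(c(0.05), 2.0)
  c0 <- analytic_vg_autocorrelation(m0, 1, ts)
  expect_equal(abs(c0), rep(1, length(ts)))
  expect_equal(c0, exp(-1i * 2.0 * ts / 0.6582119569))
})

test_that("conservation, reversal and truncation convergence hold", {
  m <- two_state_conical_preset()
  res <- propagate(m, make_doorway(m, 2), t_final = 50, dt = 0.1)
  expect_lt(max(abs(res$norm_trace - 1)), 1e-8)
  expect_lt(max(abs(rowSums(res$populations) - res$norm_trace^2)), 1e-12)
  expect_lt(diff(range(res$energy_trace)), 1e-8)
  expect_equal(res$autocorr[1], 1 + 0i)

  # time reversal: forward then backward returns the doorway state
  back <- propagate(m, res$psi, t_final = 50, dt = 0.1, backward = TRUE)
  psi0 <- make_doorway(m, 2)$coefficients
  fidelity <- Mod(sum(Conj(psi0) * back$psi$coefficients))^2
  expect_gt(fidelity, 1 - 1e-8)

  # truncation convergence on a converged basis: +4 on every nmax moves the
  # populations by < 1e-4 (the default heuristic only counts diagonal
  # gradients, so the strongly coupled mode needs a manual bump here)
  base <- c(18L, 20L)
  resa <- propagate(m, make_doorway(m, 2, nmax = base),
                    t_final = 50, dt = 0.25)
  resb <- propagate(m, make_doorway(m, 2, nmax = base + 4L),
                    t_final = 50, dt = 0.25)
  expect_lt(max(abs(resa$populations - resb$populations)), 1e-4)
})

test_that("propagation guards its preconditions", {
  m <- small_coupled_model()
  expect_error(propagate(m, make_doorway(m, 1, nmax = 5), dt = 0), "positive")
  psi_big <- make_doorway(m, 1, nmax = 600)
  expect_error(propagate(m, psi_big, t_final = 1), "basis size")
})

test_that("mode reduction keeps the strongly coupled modes", {
  m <- random_model(31, nstates = 3, nmodes = 6)
  full <- reduce_modes(m, 6)
  expect_equal(full$model$lambda_diag, m$lambda_diag)
  expect_equal(full$discarded_weight, 0)

  red <- reduce_modes(m, 3)
  # brute-force ranking oracle
  score <- sapply(seq_len(6), function(a) {
    off <- m$lambda_offdiag[, , a]
    sum(m$lambda_diag[, a]^2) + sum(off[upper.tri(off)]^2)
  })
  expect_equal(which(red$report$kept), sort(order(-score)[1:3]))
  expect_error(reduce_modes(m, 0), "range")

  # all coupling on one mode: always retained
  mm <- make_toy_model(fixture_spec(2, 3, seed = 5, diag_scale = 0,
                                    coupling_scale = 0))
  mm$lambda_diag[1, 2] <- 0.2
  expect_true(reduce_modes(mm, 1)$report$kept[2])

  # VG dressing multiplies in the discarded modes' displaced-oscillator factor
  dr <- reduce_modes(m, 3, dressing_state = 1)
  ts <- seq(0, 20, 0.5)
  dressed <- dr$apply_dressing(rep(1 + 0i, length(ts)), ts)
  manual <- rep(1 + 0i, length(ts))
  for (k in seq_along(dr$dressing$omega)) {
    s <- dr$dressing$huang_rhys[k]
    w <- dr$dressing$omega[k]
    manual <- manual * exp(s * (exp(-1i * w * ts / 0.6582119569) - 1))
  }
  expect_equal(dressed, manual)
})
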