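test_that("Procrustes transformation handles exact and perturbed overlaps", {
  expect_equal(max_overlap_transformation(diag(3)), diag(3))

  th <- 0.4
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(max_overlap_transformation(rot), rot)

  # near-orthogonal 2x2: compare with a brute-force scan over rotation angle
  set.seed(42)
  s <- rot + matrix(rnorm(4, sd = 5e-3), 2)
  d <- max_overlap_transformation(s)
  angles <- seq(-pi, pi, length.out = 200001)
  overlap <- function(a) {
    r <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    sum(r * s)  # Frobenius inner product tr(R^T S)
  }
  best <- angles[which.max(vapply(angles, overlap, numeric(1)))]
  d_scan <- rbind(c(cos(best), -sin(best)), c(sin(best), cos(best)))
  expect_equal(d, d_scan, tolerance = 1e-4)
  expect_equal(crossprod(d), diag(2))

  expect_error(max_overlap_transformation(matrix(c(1, 1, 1, 1), 2)),
               "rank-deficient")
})

test_that("diabatize_point rotates energies correctly", {
  e <- c(1.1, 2.2, 3.3)
  expect_equal(diabatize_point(e, diag(3)), diag(e))
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  v <- diabatize_point(c(2, 5), rot)
  expect_equal(sum(diag(v)), 7)
  expect_equal(v, t(v))
  expect_error(diabatize_point(c(1, 2), matrix(c(1, 0.3, 0, 1), 2)),
               "not orthogonal")
})

test_that("central differences recover linear gradients", {
  z <- matrix(0, 2, 2)
  expect_equal(central_difference_lambda(z, z, 0.1), z)
  vp <- matrix(c(0, 0.01, 0.01, 0), 2)
  expect_equal(central_difference_lambda(vp, -vp, 0.1)[1, 2], 0.1)
  expect_error(central_difference_lambda(vp, vp, 0), "positive")
})

test_that("round trip through a mock scan recovers the generator exactly", {
  for (seed in c(21, 22)) {
    m <- random_model(seed, nstates = 3, nmodes = 2)
    scan <- mock_adiabatic_scan(m, delta = 0.05)
    # the diabatized point reproduces the model's own potential
    p <- scan$points[[1]]
    d <- max_overlap_transformation(p$overlap)
    q <- rep(0, 2)
    q[p$mode] <- p$sign * 0.05
    expect_equal(diabatize_point(p$energies, d),
                 diabatic_potential_at(m, q), tolerance = 1e-12)

    res <- build_lvc_from_scan(scan, m$E0, m$dipoles, m$state_labels)
    expect_lt(max(abs(res$model$lambda_diag - m$lambda_diag)), 1e-10)
    expect_lt(max(abs(res$model$lambda_offdiag - m$lambda_offdiag)), 1e-10)
    expect_equal(max(res$residuals$trace_error), 0, tolerance = 1e-10)

    # phase robustness: arbitrary eigenvector sign flips change nothing
    scan_f <- mock_adiabatic_scan(m, delta = 0.05, flip_signs = TRUE,
                                  seed = seed)
    res_f <- build_lvc_from_scan(scan_f, m$E0)
    expect_lt(max(abs(res_f$model$lambda_offdiag - m$lambda_offdiag)), 1e-10)
  }
})

test_that("uncoupled models diabatize to vanishing couplings", {
  m <- make_toy_model(fixture_spec(4, 3, seed = 9, coupling_scale = 0))
  scan <- mock_adiabatic_scan(m, delta = 0.05)
  res <- build_lvc_from_scan(scan, m$E0)
  expect_lt(max(abs(res$model$lambda_offdiag)), 1e-10)
})

test_that("scan defects are reported with context", {
  m <- random_model(23, nstates = 3, nmodes = 2)
  scan <- mock_adiabatic_scan(m, delta = 0.05)
  broken <- scan
  broken$points <- broken$points[-2]
  expect_error(build_lvc_from_scan(broken, m$E0), "mode 1 sign -1")

  bad <- scan
  bad$points[[3]]$overlap <- matrix(1, 3, 3) / sqrt(3)
  expect_error(build_lvc_from_scan(bad, m$E0), "mode 2 sign \\+1")
})
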