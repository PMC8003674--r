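test_that("HWHM/Gamma conversion follows the Gaussian mapping", {
  expect_equal(hwhm_to_gamma(0.04), 0.0016 / (4 * log(2)))
  expect_equal(hwhm_to_gamma(0.04), 5.7708e-4, tolerance = 1e-4)
  x <- c(0.01, 0.04, 0.25)
  expect_equal(gamma_to_hwhm(hwhm_to_gamma(x)), x)
  expect_equal(hwhm_to_gamma(2 * x), 4 * hwhm_to_gamma(x))
  expect_error(hwhm_to_gamma(0), "positive")
})

test_that("a rigid transition gives a Gaussian at E0 with the chosen HWHM", {
  m <- lvc_model(c(0.1), 5.0, dipoles = matrix(c(1, 0, 0), 1, 3))
  res <- propagate(m, make_doorway(m, 1, nmax = 2), t_final = 150, dt = 0.25)
  gam <- hwhm_to_gamma(0.04)
  grid <- seq(4.5, 5.5, length.out = 4001)
  sp <- autocorrelation_to_spectrum(res, gamma = gam, grid = grid,
                                    units = "relative",
                                    omega_prefactor = FALSE)
  imax <- which.max(sp$epsilon)
  expect_equal(sp$energy_ev[imax], 5.0, tolerance = 1e-3)
  # measure the HWHM by interpolating the half-maximum crossings
  half <- sp$epsilon[imax] / 2
  right <- which(sp$epsilon < half & sp$energy_ev > sp$energy_ev[imax])[1]
  f <- approxfun(sp$epsilon[c(right - 1, right)],
                 sp$energy_ev[c(right - 1, right)])
  expect_equal(f(half) - 5.0, 0.04, tolerance = 0.001)
})

test_that("dipole weighting is quadratic and cross terms are optional", {
  m <- small_coupled_model()
  res <- propagate(m, make_doorway(m, 2, nmax = 6), t_final = 40, dt = 0.2)
  gam <- hwhm_to_gamma(0.1)
  sp1 <- autocorrelation_to_spectrum(res, gam, units = "relative")
  res2 <- res
  res2$meta$dipoles[2, ] <- 2 * res2$meta$dipoles[2, ]
  sp2 <- autocorrelation_to_spectrum(res2, gam, units = "relative")
  expect_equal(sp2$epsilon, 4 * sp1$epsilon)

  spx <- autocorrelation_to_spectrum(res, gam, units = "relative",
                                     include_cross = TRUE)
  expect_equal(length(spx$epsilon), length(sp1$epsilon))
  # state 1 is dark here, so cross terms vanish identically
  expect_equal(spx$epsilon, sp1$epsilon)
})

test_that("stick spectra behave like Gaussian sums", {
  grid <- seq(3, 8, length.out = 5001)
  single <- stick_spectrum(5.0, 1.0, hwhm = 0.25, grid = grid,
                           units = "relative")
  imax <- which.max(single$epsilon)
  expect_equal(single$energy_ev[imax], 5.0, tolerance = 1e-3)
  half <- single$epsilon[imax] / 2
  above <- range(which(single$epsilon >= half))
  fwhm <- diff(single$energy_ev[above])
  expect_equal(fwhm, 0.5, tolerance = 0.01)

  expect_equal(stick_spectrum(c(5, 6), c(0, 0), 0.25, grid,
                              units = "relative")$epsilon,
               rep(0, length(grid)))
  # areas proportional to f (oscillator weighting)
  two <- stick_spectrum(c(5, 6), c(0.1, 0.3), 0.25, grid,
                        units = "relative")
  area <- sum(two$epsilon) * mean(diff(grid))
  expect_equal(area, 0.4, tolerance = 1e-6)
  # molar units recover f through the sum-rule constant
  mol <- stick_spectrum(5.0, 0.2, 0.25, grid)
  a_wavenumber <- sum(mol$epsilon) * mean(diff(grid)) * 8065.543937
  expect_equal(4.319e-9 * a_wavenumber, 0.2, tolerance = 1e-3)
})

test_that("shift, combine and normalize do what the captions say", {
  grid <- seq(3, 8, length.out = 2001)
  sp <- stick_spectrum(c(5, 6.2), c(0.2, 0.1), 0.2, grid, units = "relative")
  norm1 <- shift_normalize_combine(sp, 0, 1, "max")
  expect_equal(max(norm1$epsilon), 1)

  both <- shift_normalize_combine(list(sp, sp), weights = c(0.5, 0.5),
                                  normalization = "max")
  expect_equal(both$epsilon, norm1$epsilon)

  shifted <- shift_normalize_combine(sp, shifts = -0.3,
                                     normalization = "none")
  i0 <- which.max(sp$epsilon)
  i1 <- which.max(shifted$epsilon)
  expect_equal(sp$energy_ev[i0] - shifted$energy_ev[i1], 0.3,
               tolerance = 1e-6)

  area <- shift_normalize_combine(sp, normalization = "area")
  expect_equal(sum(area$epsilon) * mean(diff(grid)), 1, tolerance = 1e-6)
})

test_that("moment theorem: uncoupled lineshape has m1 = E0, var = sum/2 + 2G", {
  m <- lvc_model(c(0.16, 0.07), 5.2,
                 lambda_diag = matrix(c(0.12, 0.05), 1, 2),
                 dipoles = matrix(c(1, 0, 0), 1, 3))
  res <- propagate(m, make_doorway(m, 1, nmax = 12), t_final = 150, dt = 0.25)
  gam <- hwhm_to_gamma(0.06)
  grid <- seq(3.5, 7.0, length.out = 3000)
  sp <- autocorrelation_to_spectrum(res, gam, grid = grid, units = "relative")
  mom <- spectrum_moments(sp)
  an <- spectral_moments(m, 1)
  expect_equal(mom$m1, an$m1, tolerance = 0.01 * an$m1)
  expect_equal(mom$var, an$var + 2 * gam, tolerance = 0.01)
})

test_that("couplings redistribute intensity without creating any", {
  m <- two_state_conical_preset()
  m_off <- m
  m_off$lambda_offdiag[] <- 0
  gam <- hwhm_to_gamma(0.04)
  grid <- seq(3.0, 6.8, length.out = 2500)
  sps <- lapply(list(m, m_off), function(mod) {
    res <- propagate(mod, make_doorway(mod, 2), t_final = 100, dt = 0.2)
    autocorrelation_to_spectrum(res, gam, grid = grid, units = "relative")
  })
  areas <- vapply(sps, function(s) spectrum_moments(s)$m0, numeric(1))
  expect_equal(areas[1], areas[2], tolerance = 1e-3)
  # and the coupled lineshape is strictly broader
  vars <- vapply(sps, function(s) spectrum_moments(s)$var, numeric(1))
  expect_gt(vars[1], vars[2])
})

test_that("VG Franck-Condon progression has peak spacing Omega", {
  om <- 0.15
  m <- lvc_model(om, 5.0, lambda_diag = matrix(0.15, 1, 1),
                 dipoles = matrix(c(1, 0, 0), 1, 3))
  ts <- seq(0, 300, by = 0.2)
  cvg <- analytic_vg_autocorrelation(m, 1, ts)
  fake <- structure(list(times = ts, autocorr = cvg,
                         meta = list(state = 1, E0 = 5.0,
                                     dipoles = matrix(c(1, 0, 0), 1, 3))),
                    class = "propagation_result")
  grid <- seq(4.4, 6.2, length.out = 6000)
  sp <- autocorrelation_to_spectrum(fake, hwhm_to_gamma(0.02), grid = grid,
                                    units = "relative")
  y <- sp$epsilon
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- peaks[y[peaks] > 0.02 * max(y)]
  spacing <- diff(sp$energy_ev[peaks])
  expect_equal(spacing, rep(om, length(spacing)), tolerance = 0.002)
})
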