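#' Specification of a seeded random LVC fixture
#'
#' Describes the statistical ensemble a toy model is drawn from: frequencies
#' uniform on `freq_range` (spanning typical in-plane/out-of-plane
#' vibrational quanta), vertical energies uniform on `e0_range` (a crowded
#' Franck-Condon region of near-UV states), diagonal gradients and
#' inter-state couplings Gaussian with the given scales (exercising
#' Huang-Rhys factors of order 0.01-2), and an optional dark-state mask
#' emulating the bright pi-pi* / dark n-pi* layout of the nucleobases.
#'
#' @param nstates,nmodes model dimensions.
#' @param seed integer seed; fixes all randomness.
#' @param freq_range frequency range, eV.
#' @param e0_range vertical-energy range, eV.
#' @param diag_scale standard deviation of the diagonal gradients, eV.
#' @param coupling_scale standard deviation of the inter-state coupling
#'   gradients, eV.
#' @param dark_mask logical vector (one per state): `TRUE` entries get a
#'   zero transition-dipole row. Default: all states bright.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(nstates, nmodes, seed = 1L,
                         freq_range = c(0.05, 0.4),
                         e0_range = c(4.5, 7.0),
                         diag_scale = 0.08,
                         coupling_scale = 0.04,
                         dark_mask = NULL) {
  stopifnot(nstates >= 1L, nmodes >= 1L,
            diag_scale >= 0, coupling_scale >= 0)
  if (is.null(dark_mask)) dark_mask <- rep(FALSE, nstates)
  stopifnot(length(dark_mask) == nstates)
  structure(list(nstates = as.integer(nstates), nmodes = as.integer(nmodes),
                 seed = as.integer(seed), freq_range = freq_range,
                 e0_range = e0_range, diag_scale = diag_scale,
                 coupling_scale = coupling_scale,
                 dark_mask = as.logical(dark_mask)),
            class = "fixture_spec")
}

#' A nucleobase-like fixture preset
#'
#' Six states x six modes with two bright states, energy layout and coupling
#' scales chosen to resemble a pyrimidine-base Franck-Condon region (a dark
#' low-lying state just below the first bright state, a cluster of higher
#' states), small enough to propagate 250 fs at desk scale.
#'
#' @param seed integer seed.
#' @return a `fixture_spec`.
#' @export
fixture_nucleobase_like <- function(seed = 1L) {
  fixture_spec(nstates = 6L, nmodes = 6L, seed = seed,
               freq_range = c(0.05, 0.4), e0_range = c(4.8, 6.9),
               diag_scale = 0.08, coupling_scale = 0.05,
               dark_mask = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
}

# run expr with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw a deterministic toy LVC model
#'
#' Samples a model from a [fixture_spec()] ensemble. The same spec (hence
#' the same seed) always yields a bit-identical model; dark states receive
#' zero dipole rows, bright states random unit-magnitude dipole vectors.
#'
#' @param spec a [fixture_spec()].
#' @return an [lvc_model()].
#' @export
make_toy_model <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    n <- spec$nstates
    f <- spec$nmodes
    freqs <- sort(stats::runif(f, spec$freq_range[1], spec$freq_range[2]))
    e0 <- sort(stats::runif(n, spec$e0_range[1], spec$e0_range[2]))
    lam_d <- matrix(stats::rnorm(n * f, sd = spec$diag_scale), n, f)
    lam_o <- array(0, dim = c(n, n, f))
    for (a in seq_len(f)) {
      m <- matrix(0, n, n)
      up <- upper.tri(m)
      m[up] <- stats::rnorm(sum(up), sd = spec$coupling_scale)
      lam_o[, , a] <- m + t(m)
    }
    dip <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      if (!spec$dark_mask[i]) {
        v <- stats::rnorm(3)
        dip[i, ] <- v / sqrt(sum(v^2))
      }
    }
    labels <- ifelse(spec$dark_mask, sprintf("dark%d", seq_len(n)),
                     sprintf("bright%d", seq_len(n)))
    lvc_model(normal_mode_basis(freqs), e0, lam_d, lam_o, dip, labels)
  })
}

#' Mock adiabatic scan of a known LVC model
#'
#' Emulates the quantum-chemistry input of the diabatization: at every
#' displaced geometry \eqn{\pm\Delta_\alpha} the diabatic potential matrix
#' is diagonalized, its ascending eigenvalues become the "adiabatic
#' energies" and its eigenvector matrix (reference diabatic basis = the
#' adiabatic basis at q = 0) becomes the overlap matrix. Optional random
#' sign flips of the adiabatic columns exercise the phase fixing of the
#' consumer. A warning (naming the mode) is emitted when a displaced-point
#' adiabatic state has lost its dominant diabatic character, the signature
#' of a crossing-induced reordering at this \eqn{\Delta}.
#'
#' @param model an [lvc_model()].
#' @param delta displacement magnitude (dimensionless), default 0.05.
#' @param flip_signs inject random eigenvector sign flips?
#' @param seed seed for the sign flips.
#' @return an [adiabatic_scan()].
#' @export
mock_adiabatic_scan <- function(model, delta = 0.05, flip_signs = FALSE,
                                seed = 1L) {
  stopifnot(inherits(model, "lvc_model"))
  if (delta <= 0) stop("'delta' must be positive", call. = FALSE)
  nmodes <- model$basis$nmodes
  points <- list()
  flips <- if (flip_signs) {
    .with_seed(seed, matrix(sample(c(-1, 1), 2 * nmodes * model$nstates,
                                   replace = TRUE),
                            nrow = 2 * nmodes))
  } else NULL
  k <- 0L
  for (a in seq_len(nmodes)) {
    for (s in c(1L, -1L)) {
      k <- k + 1L
      q <- rep(0, nmodes)
      q[a] <- s * delta
      ad <- adiabatic_energies_at(model, q, vectors = TRUE)
      overlap <- ad$vectors
      if (any(abs(diag(overlap)) < 1 / sqrt(2))) {
        warning(sprintf(
          "possible adiabatic-state reordering at mode %d sign %+d (delta = %g)",
          a, s, delta), call. = FALSE)
      }
      if (flip_signs) overlap <- sweep(overlap, 2L, flips[k, ], `*`)
      points[[k]] <- list(mode = a, sign = s, energies = ad$energies,
                          overlap = overlap)
    }
  }
  adiabatic_scan(model$basis, delta, points)
}

#' Two-state conical-intersection benchmark model
#'
#' A fixed-parameter two-state, two-mode vibronic-coupling model in the
#' spirit of the classic pyrazine S2/S1 benchmark: one totally symmetric
#' tuning mode (0.0739 eV) with opposite-sign gradients on the two states
#' and one coupling mode (0.1139 eV) carrying a linear inter-state coupling
#' of 0.1825 eV. The upper state is bright, the lower dark, and the conical
#' intersection sits inside the Franck-Condon region, giving visible
#' population transfer well within 100 fs.
#'
#' @return an [lvc_model()].
#' @export
two_state_conical_preset <- function() {
  lam_d <- rbind(c(-0.0964, 0), c(0.1194, 0))
  lam_o <- array(0, dim = c(2, 2, 2))
  lam_o[1, 2, 2] <- lam_o[2, 1, 2] <- 0.1825
  lvc_model(normal_mode_basis(c(0.0739, 0.1139),
                              labels = c("tuning", "coupling")),
            E0_ev = c(3.94, 4.84),
            lambda_diag = lam_d,
            lambda_offdiag = lam_o,
            dipoles = rbind(c(0, 0, 0), c(1, 0, 0)),
            state_labels = c("S1dark", "S2bright"))
}
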