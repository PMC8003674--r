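#' Adiabatic scan container
#'
#' Holds, for each normal mode \eqn{\alpha} and each displacement sign, the
#' adiabatic energies and the overlap matrix
#' \eqn{S_{kl} = \langle \mathrm{ref}\ d_k \,|\, a_l(\pm\Delta_\alpha)\rangle}
#' between the reference diabatic states (the adiabatic states at the
#' expansion point) and the adiabatic states at the displaced geometry.
#' This is the input that external quantum chemistry would provide; the
#' package's [mock_adiabatic_scan()] produces it from a known model instead.
#'
#' @param basis a [normal_mode_basis()] (or frequency vector).
#' @param delta displacement magnitude(s) \eqn{\Delta_\alpha}, dimensionless;
#'   scalar or one per mode.
#' @param points list of scan points, each a list with elements `mode`
#'   (index), `sign` (+1/-1), `energies` (ascending, eV) and `overlap`
#'   (square matrix).
#' @param orth_tol tolerance on `max|S^T S - I|` before a point is flagged
#'   (default 1e-2, matching typical truncated-CI overlap quality).
#' @return object of class `adiabatic_scan`.
#' @export
adiabatic_scan <- function(basis, delta, points, orth_tol = 1e-2) {
  if (!inherits(basis, "normal_mode_basis")) basis <- normal_mode_basis(basis)
  delta <- rep_len(as.numeric(delta), basis$nmodes)
  if (any(delta <= 0)) stop("'delta' must be positive", call. = FALSE)
  for (p in points) {
    stopifnot(is.list(p), !is.null(p$mode), !is.null(p$sign),
              !is.null(p$energies), !is.null(p$overlap))
    if (is.unsorted(p$energies)) {
      stop(sprintf("energies not ascending at mode %d sign %+d",
                   p$mode, p$sign), call. = FALSE)
    }
    s <- as.matrix(p$overlap)
    if (nrow(s) != ncol(s) || nrow(s) != length(p$energies)) {
      stop("overlap matrix dimensions do not match energies", call. = FALSE)
    }
    dev <- max(abs(crossprod(s) - diag(nrow(s))))
    if (dev > orth_tol) {
      message(sprintf(
        "overlap at mode %d sign %+d deviates from orthogonality by %.3g",
        p$mode, p$sign, dev))
    }
  }
  structure(list(basis = basis, delta = delta, points = points,
                 orth_tol = orth_tol),
            class = "adiabatic_scan")
}

#' @export
print.adiabatic_scan <- function(x, ...) {
  cat(sprintf("<adiabatic_scan> %d modes, %d points, delta in [%.3g, %.3g]\n",
              x$basis$nmodes, length(x$points), min(x$delta), max(x$delta)))
  invisible(x)
}

.scan_point <- function(scan, mode, sign) {
  for (p in scan$points) {
    if (p$mode == mode && p$sign == sign) return(p)
  }
  NULL
}

#' Maximum-overlap (orthogonal Procrustes) transformation
#'
#' Finds the orthogonal matrix closest to the overlap matrix `S` in the
#' Frobenius sense: with the SVD \eqn{S = U \Sigma V^T}, \eqn{D = U V^T}.
#' For near-orthogonal `S` this coincides with Lowdin symmetric
#' orthogonalization, and the rows of `D` define the diabatic states at the
#' displaced geometry as the combinations of adiabatic states that resemble
#' the reference states as much as possible. Before the SVD, adiabatic-state
#' signs (columns) are flipped so that `diag(S)` is non-negative, removing
#' the arbitrary phases of electronic-structure eigenvectors.
#'
#' @param S square overlap matrix, `S[k, l] = <ref k | adiabatic l>`.
#' @param force_rotation if `TRUE` and `det(D) = -1`, the reflection is
#'   converted to a proper rotation by flipping the direction associated with
#'   the smallest singular value. Default `FALSE`: a diabatic basis may
#'   legitimately acquire an overall sign.
#' @param svd_tol singular values below this threshold signal a
#'   rank-deficient overlap (state crossing / intruder state) and raise an
#'   error.
#' @return orthogonal matrix `D` of the same dimension.
#' @export
max_overlap_transformation <- function(S, force_rotation = FALSE,
                                       svd_tol = 1e-6) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("'S' must be square", call. = FALSE)
  flip <- ifelse(diag(S) < 0, -1, 1)
  S <- sweep(S, 2L, flip, `*`)
  sv <- svd(S)
  if (min(sv$d) < svd_tol) {
    stop(sprintf(
      "overlap matrix is rank-deficient (min singular value %.3g < %.3g); likely state crossing or intruder state",
      min(sv$d), svd_tol), call. = FALSE)
  }
  d <- sv$u %*% t(sv$v)
  if (force_rotation && det(d) < 0) {
    k <- which.min(sv$d)
    u <- sv$u
    u[, k] <- -u[, k]
    d <- u %*% t(sv$v)
  }
  d
}

#' Rotate adiabatic energies into the diabatic representation
#'
#' \eqn{V^{dia} = D\, \mathrm{diag}(E^{ad})\, D^T}, with `D` from
#' [max_overlap_transformation()] (note the index convention: `D[k, l]` links
#' reference diabatic state `k` to adiabatic state `l`).
#'
#' @param energies ascending adiabatic energies at the scan point (eV).
#' @param D orthogonal transformation for that point.
#' @param orth_tol maximum tolerated `max|D^T D - I|`.
#' @return symmetric diabatic potential matrix (eV) whose trace equals
#'   `sum(energies)`.
#' @export
diabatize_point <- function(energies, D, orth_tol = 1e-8) {
  D <- as.matrix(D)
  n <- length(energies)
  if (!all(dim(D) == n)) stop("dimension mismatch", call. = FALSE)
  dev <- max(abs(crossprod(D) - diag(n)))
  if (dev > orth_tol) {
    stop(sprintf("'D' is not orthogonal (deviation %.3g)", dev),
         call. = FALSE)
  }
  v <- D %*% (energies * t(D))
  0.5 * (v + t(v))
}

#' Central-difference extraction of LVC gradients
#'
#' \eqn{\lambda_{ij,\alpha} = [V^{dia}_{ij}(+\Delta_\alpha) -
#' V^{dia}_{ij}(-\Delta_\alpha)] / (2\Delta_\alpha)}. Exact (not merely
#' second-order) for potentials with no odd terms beyond linear, which is why
#' mock scans of a true LVC model are recovered to machine precision.
#'
#' @param Vdia_plus,Vdia_minus symmetric diabatic potential matrices at
#'   \eqn{\pm\Delta_\alpha}.
#' @param delta displacement magnitude, > 0.
#' @return matrix of \eqn{\lambda_{\cdot\cdot,\alpha}}: diagonal entries are
#'   the intrastate gradients, off-diagonal the coupling gradients (eV).
#' @export
central_difference_lambda <- function(Vdia_plus, Vdia_minus, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("'delta' must be a positive scalar", call. = FALSE)
  }
  Vdia_plus <- as.matrix(Vdia_plus)
  Vdia_minus <- as.matrix(Vdia_minus)
  if (!all(dim(Vdia_plus) == dim(Vdia_minus))) {
    stop("matrices must have the same shape", call. = FALSE)
  }
  (Vdia_plus - Vdia_minus) / (2 * delta)
}

#' Assemble an LVC model from an adiabatic scan
#'
#' Runs the full maximum-overlap diabatization: per scan point a Procrustes
#' transformation and rotation of the adiabatic energies, then per mode a
#' central difference, yielding every \eqn{\lambda_{ii,\alpha}} and
#' \eqn{\lambda_{ij,\alpha}}. `E0` are the adiabatic excitation energies at
#' the reference geometry and are supplied, not derived from the scan.
#'
#' @param scan an [adiabatic_scan()] covering every mode with both signs.
#' @param E0 vertical energies at the reference point (eV).
#' @param dipoles optional `nstates x 3` transition-dipole matrix (a.u.).
#' @param state_labels optional state tags.
#' @param force_rotation,svd_tol passed to [max_overlap_transformation()].
#' @return list of class `diabatization_result` with elements `model` (the
#'   recovered [lvc_model()]), `D_matrices` (per point) and `residuals`
#'   (per-point orthogonality and symmetry diagnostics).
#' @export
build_lvc_from_scan <- function(scan, E0, dipoles = NULL, state_labels = NULL,
                                force_rotation = FALSE, svd_tol = 1e-6) {
  stopifnot(inherits(scan, "adiabatic_scan"))
  nstates <- length(E0)
  nmodes <- scan$basis$nmodes
  lam_diag <- matrix(0, nstates, nmodes)
  lam_off <- array(0, dim = c(nstates, nstates, nmodes))
  d_mats <- list()
  residuals <- data.frame(mode = integer(), sign = integer(),
                          orthogonality = numeric(), trace_error = numeric())
  for (a in seq_len(nmodes)) {
    vd <- list()
    for (s in c(1L, -1L)) {
      p <- .scan_point(scan, a, s)
      if (is.null(p)) {
        stop(sprintf("scan point missing: mode %d sign %+d", a, s),
             call. = FALSE)
      }
      d <- tryCatch(
        max_overlap_transformation(p$overlap, force_rotation, svd_tol),
        error = function(e) {
          stop(sprintf("diabatization failed at mode %d sign %+d: %s",
                       a, s, conditionMessage(e)), call. = FALSE)
        })
      v <- diabatize_point(p$energies, d,
                           orth_tol = max(1e-8, 10 * scan$orth_tol))
      key <- sprintf("mode%d%s", a, if (s > 0) "+" else "-")
      d_mats[[key]] <- d
      residuals <- rbind(residuals, data.frame(
        mode = a, sign = s,
        orthogonality = max(abs(crossprod(d) - diag(nstates))),
        trace_error = abs(sum(diag(v)) - sum(p$energies))))
      vd[[as.character(s)]] <- v
    }
    lam <- central_difference_lambda(vd[["1"]], vd[["-1"]], scan$delta[a])
    lam_diag[, a] <- diag(lam)
    off <- lam
    diag(off) <- 0
    lam_off[, , a] <- 0.5 * (off + t(off))
  }
  model <- lvc_model(scan$basis, E0, lam_diag, lam_off, dipoles, state_labels)
  structure(list(model = model, D_matrices = d_mats, residuals = residuals),
            class = "diabatization_result")
}

#' @export
print.diabatization_result <- function(x, ...) {
  cat("<diabatization_result>\n")
  cat(sprintf("  max orthogonality residual: %.3g\n",
              max(x$residuals$orthogonality)))
  cat(sprintf("  max trace residual:         %.3g eV\n",
              max(x$residuals$trace_error)))
  print(x$model)
  invisible(x)
}
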