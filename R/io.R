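#' Read and write LVC models as JSON
#'
#' Versioned schema with fields `nstates`, `nmodes`, `frequencies_ev`,
#' `E0_ev`, `lambda_diag_ev` (nstates x nmodes), `lambda_offdiag_ev` (list
#' of upper-triangle records `{i, j, lambda}`), `dipoles_au`, `state_labels`
#' and `mode_labels`. Numbers are written at full double precision so the
#' round trip is bit-exact; all model invariants are re-validated on read.
#'
#' @param model an [lvc_model()].
#' @param path file path.
#' @return `write_lvc_json` returns `path` invisibly; `read_lvc_json` an
#'   [lvc_model()].
#' @export
write_lvc_json <- function(model, path) {
  stopifnot(inherits(model, "lvc_model"))
  n <- model$nstates
  off <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      lam <- model$lambda_offdiag[i, j, ]
      if (any(lam != 0)) {
        off[[length(off) + 1L]] <- list(i = i, j = j, lambda = lam)
      }
    }
  }
  obj <- list(
    schema = "lvc-model/1",
    nstates = n,
    nmodes = model$basis$nmodes,
    frequencies_ev = model$basis$frequencies,
    E0_ev = model$E0,
    lambda_diag_ev = model$lambda_diag,
    lambda_offdiag_ev = off,
    dipoles_au = model$dipoles,
    state_labels = model$state_labels,
    mode_labels = model$basis$labels
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_lvc_json
#' @export
read_lvc_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !startsWith(obj$schema, "lvc-model/")) {
    stop("not an LVC model file (missing schema tag)", call. = FALSE)
  }
  n <- obj$nstates
  f <- obj$nmodes
  lam_o <- array(0, dim = c(n, n, f))
  off <- obj$lambda_offdiag_ev
  if (length(off) > 0) {
    if (is.data.frame(off)) {
      for (r in seq_len(nrow(off))) {
        lam <- unlist(off$lambda[r])
        lam_o[off$i[r], off$j[r], ] <- lam
        lam_o[off$j[r], off$i[r], ] <- lam
      }
    } else {
      for (rec in off) {
        lam_o[rec$i, rec$j, ] <- rec$lambda
        lam_o[rec$j, rec$i, ] <- rec$lambda
      }
    }
  }
  lvc_model(normal_mode_basis(obj$frequencies_ev, obj$mode_labels),
            obj$E0_ev,
            matrix(obj$lambda_diag_ev, n, f),
            lam_o,
            matrix(obj$dipoles_au, n, 3),
            obj$state_labels)
}

#' Read and write adiabatic scans
#'
#' JSON container with `delta`, the mode frequencies and one record per
#' scan point (`mode`, `sign`, `energies_ev`, `overlap` row-major). A
#' plain-text variant (`write_scan_text`/`read_scan_text`) with one block
#' per point is provided for hand-made fixtures:
#' ```
#' point <mode> <sign> <delta>
#' energies: e1 e2 ...
#' <row 1 of overlap>
#' <row 2 of overlap>
#' ...
#' ```
#'
#' @param scan an [adiabatic_scan()].
#' @param path file path.
#' @export
write_scan_json <- function(scan, path) {
  stopifnot(inherits(scan, "adiabatic_scan"))
  obj <- list(
    schema = "adiabatic-scan/1",
    delta = scan$delta,
    frequencies_ev = scan$basis$frequencies,
    mode_labels = scan$basis$labels,
    points = lapply(scan$points, function(p) {
      list(mode = p$mode, sign = p$sign, energies_ev = p$energies,
           overlap = as.matrix(p$overlap))
    })
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_scan_json
#' @export
read_scan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !startsWith(obj$schema, "adiabatic-scan/")) {
    stop("not an adiabatic scan file", call. = FALSE)
  }
  pts <- obj$points
  points <- if (is.data.frame(pts)) {
    lapply(seq_len(nrow(pts)), function(r) {
      list(mode = pts$mode[r], sign = pts$sign[r],
           energies = unlist(pts$energies_ev[r]),
           overlap = pts$overlap[[r]])
    })
  } else {
    lapply(pts, function(p) {
      list(mode = p$mode, sign = p$sign, energies = p$energies_ev,
           overlap = do.call(rbind, p$overlap))
    })
  }
  adiabatic_scan(normal_mode_basis(obj$frequencies_ev, obj$mode_labels),
                 obj$delta, points)
}

#' @rdname write_scan_json
#' @export
write_scan_text <- function(scan, path) {
  stopifnot(inherits(scan, "adiabatic_scan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# adiabatic scan, %d modes", scan$basis$nmodes), con)
  writeLines(paste("frequencies:",
                   paste(format(scan$basis$frequencies, digits = 17),
                         collapse = " ")), con)
  for (p in scan$points) {
    writeLines(sprintf("point %d %+d %s", p$mode, p$sign,
                       format(scan$delta[p$mode], digits = 17)), con)
    writeLines(paste("energies:",
                     paste(format(p$energies, digits = 17), collapse = " ")),
               con)
    s <- as.matrix(p$overlap)
    for (r in seq_len(nrow(s))) {
      writeLines(paste(format(s[r, ], digits = 17), collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname write_scan_json
#' @export
read_scan_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  freqs <- NULL
  points <- list()
  delta <- NULL
  i <- 1L
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "frequencies:")) {
      freqs <- num(sub("frequencies:", "", ln))
      i <- i + 1L
    } else if (startsWith(ln, "point")) {
      hdr <- num(sub("point", "", ln))
      mode <- as.integer(hdr[1]); sgn <- as.integer(hdr[2]); dl <- hdr[3]
      en <- num(sub("energies:", "", lines[i + 1L]))
      nst <- length(en)
      s <- t(vapply(seq_len(nst),
                    function(r) num(lines[i + 1L + r]), numeric(nst)))
      points[[length(points) + 1L]] <- list(mode = mode, sign = sgn,
                                            energies = en, overlap = s)
      if (is.null(delta)) delta <- rep(NA_real_, max(mode, length(freqs)))
      delta[mode] <- dl
      i <- i + 2L + nst
    } else {
      stop(sprintf("cannot parse scan line: '%s'", ln), call. = FALSE)
    }
  }
  if (is.null(freqs)) stop("scan file has no 'frequencies:' line",
                           call. = FALSE)
  adiabatic_scan(normal_mode_basis(freqs), delta[seq_along(freqs)], points)
}

#' Serialize a propagation result
#'
#' `write_propagation_json` stores the full result (times, the complex
#' autocorrelation as two real arrays, populations, diagnostics and the
#' configuration echo). `write_populations_tsv` writes the plain
#' `time_fs, P_<state>...` table.
#'
#' @param result a [propagate()] result.
#' @param path file path.
#' @export
write_propagation_json <- function(result, path) {
  stopifnot(inherits(result, "propagation_result"))
  meta <- result$meta
  meta$dipoles <- as.matrix(meta$dipoles)
  obj <- list(
    schema = "propagation-result/1",
    times_fs = result$times,
    autocorr_re = Re(result$autocorr),
    autocorr_im = Im(result$autocorr),
    populations = result$populations,
    norm_trace = result$norm_trace,
    energy_trace_ev = result$energy_trace,
    meta = meta
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_propagation_json
#' @export
read_propagation_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !startsWith(obj$schema, "propagation-result/")) {
    stop("not a propagation result file", call. = FALSE)
  }
  structure(list(
    times = obj$times_fs,
    autocorr = complex(real = obj$autocorr_re, imaginary = obj$autocorr_im),
    populations = as.matrix(obj$populations),
    doorway_overlaps = NULL,
    norm_trace = obj$norm_trace,
    energy_trace = obj$energy_trace_ev,
    psi = NULL,
    meta = utils::modifyList(obj$meta, list(
      dipoles = if (!is.null(obj$meta$dipoles)) {
        matrix(unlist(obj$meta$dipoles), ncol = 3, byrow = FALSE)
      } else NULL))
  ), class = "propagation_result")
}

#' @rdname write_propagation_json
#' @export
write_populations_tsv <- function(result, path) {
  stopifnot(inherits(result, "propagation_result"))
  df <- data.frame(time_fs = result$times, result$populations)
  names(df) <- c("time_fs",
                 paste0("P_", result$meta$state_labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a spectrum as TSV (with JSON metadata sidecar)
#'
#' Two columns `energy_ev`, `epsilon`; header comment lines echo the
#' broadening, shift and normalization. A `<path>.json` sidecar stores the
#' full metadata.
#'
#' @param sp a `spectrum` object.
#' @param path file path for the TSV; the sidecar gets `.json` appended.
#' @export
write_spectrum_tsv <- function(sp, path) {
  stopifnot(inherits(sp, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(sp$meta$hwhm_ev)) {
    writeLines(sprintf("# hwhm_ev = %g", sp$meta$hwhm_ev), con)
  }
  if (!is.null(sp$meta$gamma_ev2)) {
    writeLines(sprintf("# gamma_ev2 = %g", sp$meta$gamma_ev2), con)
  }
  writeLines(sprintf("# shift_ev = %s",
                     paste(sp$meta$shift_ev %||% 0, collapse = ",")), con)
  writeLines(sprintf("# normalization = %s",
                     sp$meta$normalization %||% "none"), con)
  writeLines("energy_ev\tepsilon", con)
  utils::write.table(
    data.frame(sp$energy_ev, sp$epsilon), con, sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(sp$meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  tab <- utils::read.delim(path, comment.char = "#")
  structure(list(energy_ev = tab[[1]], epsilon = tab[[2]], meta = meta),
            class = "spectrum")
}

#' Export an LVC model as an MCTDH/Quantics-style operator section
#'
#' Best-effort plain-text export of the Hamiltonian in the operator-file
#' dialect used by MCTDH-family codes (parameter section with frequencies
#' and couplings in eV, `hamiltonian-section` with one line per term).
#' Intended for eyeballing and as a starting point for external
#' propagations; it is not validated bit-for-bit against any particular
#' code.
#'
#' @param model an [lvc_model()].
#' @param path file path.
#' @export
write_quantics_operator <- function(model, path) {
  stopifnot(inherits(model, "lvc_model"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- model$nstates
  f <- model$basis$nmodes
  w <- function(...) writeLines(sprintf(...), con)
  w("op_define-section")
  w("    title")
  w("        LVC model (%d states, %d modes)", n, f)
  w("    end-title")
  w("end-op_define-section")
  w("")
  w("parameter-section")
  for (a in seq_len(f)) w("    w_%d = %.12f, ev", a,
                          model$basis$frequencies[a])
  for (i in seq_len(n)) w("    E0_%d = %.12f, ev", i, model$E0[i])
  for (i in seq_len(n)) {
    for (a in seq_len(f)) {
      if (model$lambda_diag[i, a] != 0) {
        w("    kap_%d_%d = %.12f, ev", i, a, model$lambda_diag[i, a])
      }
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      for (a in seq_len(f)) {
        if (model$lambda_offdiag[i, j, a] != 0) {
          w("    lam_%d_%d_%d = %.12f, ev", i, j, a,
            model$lambda_offdiag[i, j, a])
        }
      }
    }
  }
  w("end-parameter-section")
  w("")
  w("hamiltonian-section")
  w("modes | el | %s", paste(sprintf("v%d", seq_len(f)), collapse = " | "))
  for (a in seq_len(f)) w("1.0         |1 1 |%d KE", a + 1L)
  for (a in seq_len(f)) w("0.5*w_%d     |1 1 |%d q^2", a, a + 1L)
  for (i in seq_len(n)) w("E0_%d        |1 S%d&%d", i, i, i)
  for (i in seq_len(n)) {
    for (a in seq_len(f)) {
      if (model$lambda_diag[i, a] != 0) {
        w("kap_%d_%d     |1 S%d&%d |%d q", i, a, i, i, a + 1L)
      }
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      for (a in seq_len(f)) {
        if (model$lambda_offdiag[i, j, a] != 0) {
          w("lam_%d_%d_%d   |1 S%d&%d |%d q", i, j, a, i, j, a + 1L)
        }
      }
    }
  }
  w("end-hamiltonian-section")
  w("")
  w("end-operator")
  invisible(path)
}

#' Vertical excitation energies and oscillator strengths of the nucleobases
#'
#' The bundled table of TD-DFT vertical energies (eV), oscillator strengths
#' and state characters for the five DNA/RNA nucleobases (uracil, thymine,
#' cytosine, adenine, 9H- and 7H-guanine) at the ground-state minimum, for
#' the CAM-B3LYP and PBE0 functionals with the 6-311+G(d,p) basis. These are
#' the stick-spectrum inputs used in pure-electronic spectra.
#'
#' @param base optional filter, e.g. `"uracil"`.
#' @param functional optional filter, `"CAM-B3LYP"` or `"PBE0"`.
#' @return data frame with columns `base`, `functional`, `state`, `E0_ev`,
#'   `f`, `character`.
#' @export
nucleobase_states <- function(base = NULL, functional = NULL) {
  path <- system.file("extdata", "nucleobase_states.tsv",
                      package = "vibronic", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(base)) df <- df[tolower(df$base) == tolower(base), ]
  if (!is.null(functional)) {
    df <- df[tolower(df$functional) == tolower(functional), ]
  }
  rownames(df) <- NULL
  df
}
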