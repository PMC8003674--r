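#' Mono-exponential fit of a diabatic population trace
#'
#' Least-squares fit of \eqn{P(t) = b + a\, e^{-t/\tau}} with free baseline
#' (populations need not decay to zero when the transfer is only partial).
#' Nonlinear least squares with multi-start initialization over
#' \eqn{\tau_0 \in \{10, 50, 200\}} fs to avoid local minima. Traces that do
#' not decay on the fit window (fitted \eqn{\tau} beyond 100x the window, or
#' a non-negative slope) are returned flagged, not as a silent failure.
#'
#' @param times time grid, fs.
#' @param P population trace in `[0, 1]`, at least 10 samples.
#' @param tau_starts initial time constants for the multi-start search (fs).
#' @return object of class `decay_fit`: `tau` (fs), `amplitude`, `baseline`,
#'   `completion` (percent of the initial population lost by the end of the
#'   window), `rmse` and `flagged`.
#' @export
fit_exponential_decay <- function(times, P, tau_starts = c(10, 50, 200)) {
  if (length(times) != length(P) || length(P) < 10L) {
    stop("'times' and 'P' must match and contain at least 10 samples",
         call. = FALSE)
  }
  if (any(P < -1e-9) || any(P > 1 + 1e-9)) {
    stop("'P' must lie in [0, 1]", call. = FALSE)
  }
  window <- diff(range(times))
  sse <- function(par) {
    sum((P - (par[1] + par[2] * exp(-times / par[3])))^2)
  }
  lower <- c(baseline = -0.5, amplitude = -1.5, tau = 1e-3 * window)
  upper <- c(baseline = 1.5, amplitude = 1.5, tau = 1e4 * window)
  best <- NULL
  for (tau0 in tau_starts) {
    par0 <- c(baseline = min(P), amplitude = max(P[1] - min(P), 1e-3),
              tau = tau0)
    fit <- tryCatch({
      nl <- stats::nls(P ~ baseline + amplitude * exp(-times / tau),
                       start = as.list(par0), algorithm = "port",
                       lower = lower, upper = upper,
                       control = stats::nls.control(maxiter = 500,
                                                    tol = 1e-10,
                                                    minFactor = 1e-12))
      p <- stats::coef(nl)
      list(par = p, value = sse(p))
    }, error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        stats::optim(par0, sse, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(factr = 10)),
        error = function(e) NULL)
    }
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("exponential fit failed to converge", call. = FALSE)
  par <- best$par
  flagged <- par[["tau"]] > 100 * window || par[["amplitude"]] <= 0
  completion <- if (P[1] > 0) 100 * (P[1] - P[length(P)]) / P[1] else NA_real_
  structure(list(
    tau = par[["tau"]], amplitude = par[["amplitude"]],
    baseline = par[["baseline"]],
    completion = completion,
    rmse = sqrt(best$value / length(P)),
    flagged = flagged
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$flagged) {
    cat("<decay_fit> non-decaying trace (flagged)\n")
  } else {
    cat(sprintf(
      "<decay_fit> tau = %.1f fs, amplitude %.3f, baseline %.3f, %.0f%% complete (rmse %.2g)\n",
      x$tau, x$amplitude, x$baseline, x$completion, x$rmse))
  }
  invisible(x)
}

#' Half-population transfer time
#'
#' First time at which the trace drops to half its initial value, linearly
#' interpolated between samples; `NA` if the level is never reached.
#'
#' @inheritParams fit_exponential_decay
#' @return time in fs, or `NA_real_`.
#' @export
half_transfer_time <- function(times, P) {
  if (length(times) != length(P) || length(P) < 2L) {
    stop("'times' and 'P' must match with at least 2 samples", call. = FALSE)
  }
  target <- P[1] / 2
  below <- which(P <= target)
  if (length(below) == 0L) return(NA_real_)
  k <- below[1L]
  if (k == 1L) return(times[1L])
  # linear interpolation on the bracketing segment
  t0 <- times[k - 1L]; t1 <- times[k]
  p0 <- P[k - 1L]; p1 <- P[k]
  t0 + (p0 - target) / (p0 - p1) * (t1 - t0)
}

#' Tabular population summary of a propagation
#'
#' Per diabatic state: mono-exponential time constant (where the trace
#' decays), half-transfer time, populations at 25/50/100/250 fs
#' (grid-interpolated; `NA` beyond the stored window) and the worst
#' population-closure residual \eqn{\max_t |\sum_i P_i(t) - \|\psi(t)\|^2|}.
#'
#' @param result a [propagate()] result.
#' @param checkpoints times (fs) at which populations are tabulated.
#' @return a data frame, one row per state.
#' @export
population_report <- function(result, checkpoints = c(25, 50, 100, 250)) {
  stopifnot(inherits(result, "propagation_result"))
  times <- result$times
  pops <- result$populations
  closure <- max(abs(rowSums(pops) - result$norm_trace^2))
  rows <- lapply(seq_len(ncol(pops)), function(i) {
    p <- pops[, i]
    fit <- fit_exponential_decay(times, pmin(pmax(p, 0), 1))
    at <- vapply(checkpoints, function(tc) {
      if (tc > max(times)) NA_real_ else stats::approx(times, p, tc)$y
    }, numeric(1))
    names(at) <- sprintf("P_%gfs", checkpoints)
    c(list(state = result$meta$state_labels[i],
           P0 = p[1L],
           tau_fs = if (fit$flagged) NA_real_ else fit$tau,
           t_half_fs = half_transfer_time(times, p)),
      as.list(at),
      list(closure = closure))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
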