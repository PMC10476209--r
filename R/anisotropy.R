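## Anisotropy from parallel- and perpendicular-scheme 2D spectra:
## r = (I_par - I_perp) / (I_par + 2 I_perp).

#' Pointwise anisotropy map
#'
#' `r(omega1, omega3) = (I_par - I_perp) / (I_par + 2 I_perp)`, masked
#' (set to `NA`) where the isotropic denominator is below
#' `mask_threshold` times its absolute maximum, since spectral overlap of
#' signals with opposite signs makes the ratio meaningless there.
#'
#' @param s_par,s_perp [spectrum_2d()] maps from the parallel and
#'   perpendicular schemes, on identical axes and waiting time, computed
#'   on a common (unnormalized) scale.
#' @param mask_threshold mask fraction of the maximal `|I_par + 2 I_perp|`.
#' @return an object of class `anisotropy_map`: `omega1`, `omega3`, `r`
#'   (matrix with `NA` where masked), `t2`.
#' @export
anisotropy_map <- function(s_par, s_perp, mask_threshold = 0.05) {
  stopifnot(inherits(s_par, "spectrum2d"), inherits(s_perp, "spectrum2d"))
  if (!isTRUE(all.equal(s_par$omega1, s_perp$omega1)) ||
      !isTRUE(all.equal(s_par$omega3, s_perp$omega3)))
    stop("parallel and perpendicular spectra are on different axes")
  if (s_par$t2 != s_perp$t2)
    stop("parallel and perpendicular spectra have different waiting times")
  den <- s_par$map + 2 * s_perp$map
  r <- (s_par$map - s_perp$map) / den
  r[abs(den) < mask_threshold * max(abs(den))] <- NA_real_
  structure(list(omega1 = s_par$omega1, omega3 = s_par$omega3,
                 r = r, t2 = s_par$t2),
            class = "anisotropy_map")
}

#' @export
print.anisotropy_map <- function(x, ...) {
  cat("<anisotropy_map> t2 = ", x$t2, " fs; ",
      sum(!is.na(x$r)), "/", length(x$r), " points unmasked\n", sep = "")
  invisible(x)
}

#' Anisotropy spectrum along the diagonal
#'
#' Samples `r` on the diagonal grid (`omega1 = omega3`, by nearest
#' `omega3` point for each `omega1`), dropping masked points.
#'
#' @param map an [anisotropy_map()] (typically at `t2 = 0`).
#' @return data.frame with `omega` (cm^-1) and `r`.
#' @export
anisotropy_spectrum_diagonal <- function(map) {
  stopifnot(inherits(map, "anisotropy_map"))
  j <- vapply(map$omega1, function(w) which.min(abs(map$omega3 - w)),
              integer(1))
  r <- map$r[cbind(seq_along(map$omega1), j)]
  keep <- !is.na(r)
  if (!any(keep)) stop("diagonal is fully masked")
  data.frame(omega = map$omega1[keep], r = r[keep])
}

#' Anisotropy decay trace at a fixed spectral point
#'
#' `r(t2)` at the grid point nearest to the requested `(omega1, omega3)`
#' coordinate, across a series of anisotropy maps.
#'
#' @param maps list of [anisotropy_map()]s at increasing waiting times.
#' @param point numeric `c(omega1, omega3)` in cm^-1.
#' @return an object of class `anisotropy_trace`: `t2_values`,
#'   `r_values`, `point` (the grid point actually used), `fit` (`NULL`
#'   until [fit_exponential()] is applied).
#' @export
anisotropy_trace <- function(maps, point) {
  stopifnot(length(maps) >= 3, length(point) == 2)
  i <- which.min(abs(maps[[1]]$omega1 - point[1]))
  j <- which.min(abs(maps[[1]]$omega3 - point[2]))
  t2v <- vapply(maps, function(m) m$t2, numeric(1))
  rv <- vapply(maps, function(m) m$r[i, j], numeric(1))
  if (anyNA(rv))
    stop("point (", signif(maps[[1]]$omega1[i], 6), ", ",
         signif(maps[[1]]$omega3[j], 6), ") is masked at t2 = ",
         paste(t2v[is.na(rv)], collapse = ", "), " fs")
  structure(list(t2_values = t2v, r_values = rv,
                 point = c(omega1 = maps[[1]]$omega1[i],
                           omega3 = maps[[1]]$omega3[j]),
                 fit = NULL),
            class = "anisotropy_trace")
}

#' @export
print.anisotropy_trace <- function(x, ...) {
  cat(sprintf("<anisotropy_trace> r(0) = %.3f at (%.0f, %.0f) cm^-1, %d waiting times\n",
              x$r_values[1], x$point[1], x$point[2], length(x$t2_values)))
  if (!is.null(x$fit)) {
    f <- x$fit
    if (f$fit_ok)
      cat(sprintf("  fit: r0 = %.3f, r_inf = %.3f, tau = %.0f fs\n",
                  f$r0, f$r_inf, f$tau))
    else cat("  fit: ", f$reason, "\n", sep = "")
  }
  invisible(x)
}

#' Exponential fit of an anisotropy trace
#'
#' Least-squares fit of `r(t2) = r_inf + (r0 - r_inf) exp(-t2 / tau)`.
#' By default waiting times below `t2_min` are excluded from the fit:
#' around `t2 = 0` the pump and probe pulses overlap and interexciton
#' coherences contribute a sharp transient that is not part of the
#' population (energy-transfer) decay the exponential models; including
#' it drives `tau` toward zero.  Set `t2_min = 0` to fit the full trace.
#' The fit is flagged as "no decay" when the fitted amplitude
#' `|r0 - r_inf|` is below `min_amplitude`; non-convergence is reported
#' in the flag, never as an error.
#'
#' @param trace an [anisotropy_trace()] (at least 4 points in the window).
#' @param fixed_r_inf fit a pure decay to this fixed offset (e.g. 0)
#'   instead of floating `r_inf`.
#' @param min_amplitude smallest decay amplitude treated as a real decay.
#' @param t2_min smallest waiting time (fs) included in the fit.
#' @return the trace with a `fit` field: `r0`, `r_inf`, `tau` (fs),
#'   `fit_ok`, `reason`.  `r0` is the fitted amplitude extrapolated to
#'   `t2 = 0`, not necessarily the measured `r` there.
#' @export
fit_exponential <- function(trace, fixed_r_inf = NULL, min_amplitude = 0.02,
                            t2_min = 24) {
  stopifnot(inherits(trace, "anisotropy_trace"))
  keep <- trace$t2_values >= t2_min
  t <- trace$t2_values[keep]
  r <- trace$r_values[keep]
  if (length(t) < 4) stop("need at least 4 waiting times in the fit window")
  span <- diff(range(t))
  fit <- list(r0 = r[1], r_inf = r[length(r)], tau = NA_real_,
              fit_ok = FALSE, reason = "")
  if (abs(r[1] - r[length(r)]) < min_amplitude &&
      abs(max(r) - min(r)) < 2 * min_amplitude) {
    fit$r_inf <- mean(r)
    fit$reason <- "no decay (flat trace)"
    trace$fit <- fit
    return(trace)
  }
  df <- data.frame(t = t, r = r)
  rinf0 <- mean(r[t >= max(t) - span / 4])
  res <- try(suppressWarnings({
    if (is.null(fixed_r_inf)) {
      minpack.lm::nlsLM(r ~ rinf + (r0 - rinf) * exp(-t / tau), data = df,
                        start = list(r0 = r[1], rinf = rinf0, tau = span / 3),
                        lower = c(-0.5, -0.5, 1), upper = c(1, 1, 1e6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(r ~ fixed_r_inf + (r0 - fixed_r_inf) * exp(-t / tau),
                        data = df,
                        start = list(r0 = r[1], tau = span / 3),
                        lower = c(-0.5, 1), upper = c(1, 1e6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }), silent = TRUE)
  if (!inherits(res, "try-error")) {
    cf <- coef(res)
    fit$r0 <- unname(cf["r0"])
    fit$r_inf <- if (is.null(fixed_r_inf)) unname(cf["rinf"]) else fixed_r_inf
    fit$tau <- unname(cf["tau"])
  } else {
    ## direct bounded least squares as a fallback (nlsLM can fail while
    ## building its nls object when the decay collapses onto one point)
    sse <- function(p) {
      rinf <- if (is.null(fixed_r_inf)) p[2] else fixed_r_inf
      pred <- rinf + (p[1] - rinf) * exp(-t / exp(p[3]))
      sum((pred - r)^2)
    }
    p0 <- c(r[1], rinf0, log(span / 3))
    o <- stats::optim(if (is.null(fixed_r_inf)) p0 else p0[c(1, 3)],
                      function(p) sse(if (is.null(fixed_r_inf)) p
                                      else c(p[1], NA, p[2])),
                      method = "Nelder-Mead")
    p <- o$par
    if (is.null(fixed_r_inf)) {
      fit$r0 <- p[1]; fit$r_inf <- p[2]; fit$tau <- exp(p[3])
    } else {
      fit$r0 <- p[1]; fit$r_inf <- fixed_r_inf; fit$tau <- exp(p[2])
    }
  }
  if (!is.finite(fit$tau)) {
    fit$fit_ok <- FALSE
    fit$reason <- "fit did not converge"
  } else if (abs(fit$r0 - fit$r_inf) < min_amplitude) {
    fit$fit_ok <- FALSE
    fit$reason <- "no decay (fitted amplitude below threshold)"
  } else {
    fit$fit_ok <- TRUE
  }
  trace$fit <- fit
  trace
}
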