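## Synthetic bath: stationary colored-noise site-energy trajectories.

#' Specify the site-energy bath
#'
#' Each molecule's transition-energy shift evolves as an independent
#' Ornstein--Uhlenbeck (OU) process around `mean_shift` plus a frozen
#' per-molecule Gaussian offset.  The OU process has stationary standard
#' deviation `sigma_dynamic` and exponential autocorrelation time
#' `tau_corr` and is discretized exactly (no Euler bias).  These
#' trajectories stand in for molecular-dynamics-derived energy
#' fluctuations; the defaults are calibration choices, not measured
#' values.
#'
#' @param mean_shift stationary mean of the shift, cm^-1.
#' @param sigma_dynamic fluctuation amplitude, cm^-1 (>= 0).
#' @param tau_corr correlation time, fs (> 0).
#' @param sigma_static per-molecule frozen offset spread, cm^-1 (>= 0).
#' @param dt time step, fs (> 0).
#' @param n_steps number of frames (>= 2).
#' @param seed integer seed.
#' @return an object of class `bath_spec`.
#' @export
bath_spec <- function(mean_shift = -300, sigma_dynamic = 200,
                      tau_corr = 50, sigma_static = 150,
                      dt = 4, n_steps = 500, seed = 1L) {
  stopifnot(sigma_dynamic >= 0, sigma_static >= 0, tau_corr > 0, dt > 0)
  structure(list(mean_shift = mean_shift, sigma_dynamic = sigma_dynamic,
                 tau_corr = tau_corr, sigma_static = sigma_static,
                 dt = dt, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)),
            class = "bath_spec")
}

#' Generate site-energy trajectories
#'
#' Exact OU discretization: with `rho = exp(-dt/tau_corr)`,
#' `x[t+1] = rho * x[t] + sqrt(1 - rho^2) * sigma_dynamic * xi`, starting
#' from a draw out of the stationary distribution, so the process is
#' stationary from the first frame.
#'
#' @param agg an aggregate (sets the number of sites and row order).
#' @param bath a [bath_spec()].
#' @return an object of class `site_energy_trajectory` with fields
#'   `values` (N x T matrix, cm^-1) and `dt` (fs).
#' @export
generate_site_energies <- function(agg, bath) {
  stopifnot(inherits(agg, "aggregate"), inherits(bath, "bath_spec"))
  if (bath$n_steps < 2) stop("n_steps must be >= 2")
  n <- nrow(agg$positions)
  T <- bath$n_steps
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(bath$seed)
  static <- rnorm(n, 0, bath$sigma_static)
  rho <- exp(-bath$dt / bath$tau_corr)
  x <- matrix(0, n, T)
  x[, 1] <- rnorm(n, 0, bath$sigma_dynamic)
  if (bath$sigma_dynamic > 0) {
    amp <- sqrt(1 - rho^2) * bath$sigma_dynamic
    for (t in 2:T) x[, t] <- rho * x[, t - 1] + amp * rnorm(n)
  } else {
    x[] <- 0
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  vals <- x + bath$mean_shift + static
  structure(list(values = vals, dt = bath$dt, spec = bath),
            class = "site_energy_trajectory")
}

#' Site-averaged autocovariance of a trajectory
#'
#' Plug-in estimate of `cov(x(t), x(t + lag))`, averaged over sites.
#' With per-site demeaning a pure static-offset trajectory has zero
#' deviations, hence an identically zero covariance at every lag; with
#' global demeaning the frozen offsets appear as a flat plateau equal to
#' their variance.
#'
#' @param traj a [generate_site_energies()] trajectory.
#' @param max_lag largest lag (in frames) to evaluate.
#' @param demean `"site"` removes each site's own mean (isolates the
#'   dynamic fluctuations); `"global"` removes the grand mean so that
#'   frozen offsets appear as a flat plateau equal to their variance.
#' @return an object of class `bath_autocovariance`: fields `lag_fs`,
#'   `acov` (cm^-2).
#' @export
autocorrelation <- function(traj, max_lag = NULL, demean = c("site", "global")) {
  stopifnot(inherits(traj, "site_energy_trajectory"))
  demean <- match.arg(demean)
  x <- traj$values
  T <- ncol(x)
  if (T < 10) stop("trajectory too short (need T >= 10)")
  max_lag <- max_lag %||% min(T - 2L, 250L)
  dev <- if (demean == "site") x - rowMeans(x) else x - mean(x)
  acov <- vapply(0:max_lag, function(lag) {
    a <- dev[, seq_len(T - lag), drop = FALSE]
    b <- dev[, seq_len(T - lag) + lag, drop = FALSE]
    sum(a * b) / (nrow(x) * (T - lag))
  }, numeric(1))
  structure(list(lag_fs = (0:max_lag) * traj$dt, acov = acov),
            class = "bath_autocovariance")
}

#' Write site-energy trajectories as delimited text
#'
#' One row per molecule, one column per frame; `#` header lines carry the
#' generating parameters.
#' @param traj a trajectory.
#' @param path output file.
#' @export
write_site_energies <- function(traj, path) {
  stopifnot(inherits(traj, "site_energy_trajectory"))
  hdr <- c(sprintf("# excitube site energies: %d sites x %d frames",
                   nrow(traj$values), ncol(traj$values)),
           sprintf("# dt_fs %.8g", traj$dt))
  if (!is.null(traj$spec))
    hdr <- c(hdr, sprintf("# bath %s",
                          paste(sprintf("%s=%g", names(traj$spec)[1:7],
                                        unlist(traj$spec[1:7])),
                                collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(traj$values, digits = 10, trim = TRUE), con,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read site-energy trajectories written by [write_site_energies()]
#' @param path input file.
#' @return a `site_energy_trajectory`.
#' @export
read_site_energies <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  dtln <- grep("^# dt_fs ", hdr, value = TRUE)
  if (!length(dtln)) stop("malformed site-energy file: missing dt header")
  vals <- as.matrix(read.table(text = lines[!grepl("^#", lines)], sep = "\t"))
  dimnames(vals) <- NULL
  structure(list(values = vals, dt = as.numeric(sub("^# dt_fs ", "", dtln[1])),
                 spec = NULL),
            class = "site_energy_trajectory")
}
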