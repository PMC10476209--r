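## Linear and third-order optical response from propagated wavefunctions.

#' Apodization parameters
#'
#' Response functions are damped in the coherence times by an exponential
#' `exp(-t/tau_homo)` (homogeneous broadening; Lorentzian full width
#' `1/(pi c tau_homo)`, 35.4 cm^-1 at 300 fs) and a Gaussian
#' `exp(-t^2 / (2 tau_inhomo^2))` (mesoscale inhomogeneous broadening;
#' Gaussian full width `2 sqrt(2 log 2) / (2 pi c tau_inhomo)`,
#' 75.3 cm^-1 at 166 fs).  In 2D, `mode = "independent"` applies the
#' Gaussian to `t1` and `t3` separately; `mode = "correlated"` applies
#' it to `(t1 - t3)` for rephasing and `(t1 + t3)` for nonrephasing
#' pathways (photon-echo-like static disorder).
#'
#' @param tau_homo exponential apodization time, fs.
#' @param tau_inhomo Gaussian apodization time, fs.
#' @param mode `"independent"` or `"correlated"` (2D only).
#' @return an object of class `apodization_spec`.
#' @export
apodization_spec <- function(tau_homo = 300, tau_inhomo = 166,
                             mode = c("independent", "correlated")) {
  stopifnot(tau_homo > 0, tau_inhomo > 0)
  structure(list(tau_homo = tau_homo, tau_inhomo = tau_inhomo,
                 mode = match.arg(mode)),
            class = "apodization_spec")
}

#' Coherence/waiting-time grids
#'
#' @param t1_max,t3_max coherence-time maxima, fs (multiples of `dt`).
#' @param dt coherence-time step, fs.
#' @param t2_values waiting times, fs (multiples of `dt`).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(t1_max = 196, t3_max = 196, dt = 4,
                      t2_values = seq(0, 350 - 350 %% 24, by = 24)) {
  stopifnot(dt > 0, t1_max %% dt == 0, t3_max %% dt == 0,
            all(t2_values >= 0), all(t2_values %% dt == 0))
  structure(list(t1_max = t1_max, t3_max = t3_max, dt = dt,
                 t2_values = t2_values),
            class = "grid_spec")
}

## Step propagators of a Hamiltonian trajectory as one complex array
## (N x N x (T-1)), in the rotating frame at omega_ref.
prop_array <- function(ht, omega_ref = ht$omega0) {
  T <- n_frames(ht)
  n <- nrow(ht$J)
  U <- array(complex(real = 0), dim = c(n, n, T - 1))
  for (t in seq_len(T - 1)) U[, , t] <- step_propagator(ht_frame(ht, t), ht$dt, omega_ref)
  U
}

prop_array_2ex <- function(ht, omega_ref = ht$omega0, cap = 150) {
  T <- n_frames(ht)
  np <- nrow(pair_basis(nrow(ht$J)))
  U2 <- array(complex(real = 0), dim = c(np, np, T - 1))
  for (t in seq_len(T - 1))
    U2[, , t] <- step_propagator(two_exciton_hamiltonian(ht_frame(ht, t), cap = cap),
                                 ht$dt, 2 * omega_ref)
  U2
}

## evenly staggered start frames for response sampling
sample_starts <- function(T, n_keep, n_samples, stride = NULL) {
  avail <- T - n_keep          # largest usable start frame
  if (avail < 1)
    stop("trajectory too short: need at least ", n_keep + 1,
         " frames, have ", T)
  if (n_samples == 1) return(1L)
  stride <- stride %||% max(1L, floor((avail - 1L) / (n_samples - 1L)))
  starts <- 1L + (seq_len(n_samples) - 1L) * stride
  if (max(starts) > avail)
    stop("trajectory too short for ", n_samples, " samples with stride ",
         stride, ": need ", (n_samples - 1L) * stride + n_keep + 1L,
         " frames, have ", T)
  starts
}

## apodization window in one coherence time
apod_window_1d <- function(t_fs, apod) {
  exp(-t_fs / apod$tau_homo - t_fs^2 / (2 * apod$tau_inhomo^2))
}

## half-weighted endpoint, zero-pad x4, signed FFT along each axis;
## returns list(freq, values) with freq ascending about 0
spectrum_axis <- function(n_pad, dt) {
  k <- seq_len(n_pad) - 1
  k[k >= n_pad / 2] <- k[k >= n_pad / 2] - n_pad
  sort(k) / (n_pad * dt * C_CM_FS)
}

fft_half_1d <- function(f, dt, pad_factor = 4) {
  n <- length(f)
  f[1] <- f[1] / 2
  np <- pad_factor * n
  fp <- c(f, rep(0 + 0i, np - n))
  z <- fft(fp, inverse = TRUE)
  k <- seq_len(np) - 1
  k[k >= np / 2] <- k[k >= np / 2] - np
  ord <- order(k)
  list(freq = k[ord] / (np * dt * C_CM_FS), values = z[ord])
}

#' Linear absorption from the two-point dipole response
#'
#' Averages the two-point transition-dipole correlation function over
#' staggered trajectory start points, apodizes it, and Fourier-transforms
#' to the frequency domain.  Channels: `iso` (orientationally averaged
#' absorption), `parallel` (z-polarized, cylinder frame) and
#' `perpendicular` (mean of x and y).
#'
#' @param ht a `hamiltonian_trajectory`.
#' @param t1_max coherence-time maximum, fs.
#' @param apod an [apodization_spec()].
#' @param n_samples number of staggered trajectory start points.
#' @param stride spacing between start frames (default: spread evenly;
#'   choose at least the bath correlation time).
#' @param pad_factor zero-padding factor for the transform.
#' @param window half-width of the reported frequency axis about the
#'   monomer energy, cm^-1.
#' @param U optional precomputed propagator array from this trajectory.
#' @return an object of class `spectrum1d`: fields `frequency` (cm^-1,
#'   increasing) and `channels` (matrix with columns `iso`, `parallel`,
#'   `perpendicular`).
#' @export
linear_response <- function(ht, t1_max = 128, apod = apodization_spec(),
                            n_samples = 8, stride = NULL, pad_factor = 4,
                            window = 2500, U = NULL) {
  stopifnot(inherits(ht, "hamiltonian_trajectory"), t1_max %% ht$dt == 0)
  nt <- as.integer(t1_max / ht$dt)
  starts <- sample_starts(n_frames(ht), nt, n_samples, stride)
  U <- U %||% prop_array(ht)
  acc <- array(0 + 0i, dim = c(3, 3, nt + 1))
  for (s in starts) acc <- acc + prop_record_cpp(U, ht$dipole_matrix, s, nt)
  acc <- acc / length(starts)
  chan <- cbind(iso = (acc[1, 1, ] + acc[2, 2, ] + acc[3, 3, ]) / 3,
                parallel = acc[3, 3, ],
                perpendicular = (acc[1, 1, ] + acc[2, 2, ]) / 2)
  t_fs <- (0:nt) * ht$dt
  w <- apod_window_1d(t_fs, apod)
  out <- NULL
  for (j in seq_len(ncol(chan))) {
    ft <- fft_half_1d(chan[, j] * w, ht$dt, pad_factor)
    if (is.null(out)) out <- list(freq = ft$freq + ht$omega0,
                                  mat = matrix(0, length(ft$freq), ncol(chan),
                                               dimnames = list(NULL, colnames(chan))))
    out$mat[, j] <- Re(ft$values)
  }
  keep <- abs(out$freq - ht$omega0) <= window
  structure(list(frequency = out$freq[keep],
                 channels = out$mat[keep, , drop = FALSE]),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat("<spectrum1d> ", length(x$frequency), " frequencies [",
      signif(min(x$frequency), 6), ", ", signif(max(x$frequency), 6),
      "] cm^-1; channels: ", paste(colnames(x$channels), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Linear dichroism decomposition from eigenstates
#'
#' Stick spectra broadened with a Gaussian:
#' `I_par(w) = sum_i M_{i,z}^2 g(w - w_i)`,
#' `I_perp(w) = 1/2 sum_i (M_{i,x}^2 + M_{i,y}^2) g(w - w_i)`,
#' `LD = I_par - I_perp`.
#'
#' @param eig an [eigendecompose_frame()] result.
#' @param sigma Gaussian broadening (standard deviation), cm^-1.
#' @param frequency evaluation grid, cm^-1 (default: spans the
#'   eigenvalues plus 3 sigma).
#' @return a `spectrum1d` with channels `parallel`, `perpendicular`, `LD`.
#' @export
ld_components <- function(eig, sigma = 60, frequency = NULL) {
  stopifnot(inherits(eig, "eigenstate_set"))
  en <- eig$energies
  M <- eig$transition_dipoles
  frequency <- frequency %||%
    seq(min(en) - 3 * sigma, max(en) + 3 * sigma, length.out = 600)
  g <- function(w0) exp(-(frequency - w0)^2 / (2 * sigma^2)) /
    (sigma * sqrt(2 * pi))
  wz <- M[, 3]^2
  wxy <- (M[, 1]^2 + M[, 2]^2) / 2
  ipar <- iperp <- numeric(length(frequency))
  for (i in seq_along(en)) {
    gi <- g(en[i])
    ipar <- ipar + wz[i] * gi
    iperp <- iperp + wxy[i] * gi
  }
  structure(list(frequency = frequency,
                 channels = cbind(parallel = ipar, perpendicular = iperp,
                                  LD = ipar - iperp)),
            class = "spectrum1d")
}

#' Polarization-resolved third-order response
#'
#' Computes the rephasing and nonrephasing GSB, SE and (optionally) ESA
#' response on the `(t1, t2, t3)` grid, averaged over staggered
#' trajectory start points, for both the all-parallel and the
#' pump-perpendicular-probe lab polarization schemes simultaneously
#' (orientational averaging is analytic).  ESA promotes the ket into the
#' hard-core two-exciton manifold during `t3` and enters the absorptive
#' spectrum with opposite sign.
#'
#' @param ht a `hamiltonian_trajectory`.
#' @param grid a [grid_spec()].
#' @param pathways subset of `c("GSB", "SE", "ESA")`.
#' @param n_samples number of staggered start points.
#' @param stride spacing between start frames.
#' @param two_exciton_cap refuse ESA above this many sites.
#' @param U,U2 optional precomputed propagator arrays.
#' @return an object of class `response_tensor`: `data[[k]]` holds, for
#'   waiting time `t2_values[k]`, complex `(nt1+1) x (nt3+1)` matrices
#'   named `<pathway>_<r|nr>_<par|perp>`.
#' @export
twod_response <- function(ht, grid = grid_spec(),
                          pathways = c("GSB", "SE", "ESA"),
                          n_samples = 8, stride = NULL,
                          two_exciton_cap = 150, U = NULL, U2 = NULL) {
  stopifnot(inherits(ht, "hamiltonian_trajectory"), inherits(grid, "grid_spec"))
  pathways <- match.arg(pathways, c("GSB", "SE", "ESA"), several.ok = TRUE)
  n <- nrow(ht$J)
  do_esa <- "ESA" %in% pathways && n >= 2
  if ("ESA" %in% pathways && n > two_exciton_cap)
    stop("ESA requested for N = ", n, " sites, above the two-exciton cap (",
         two_exciton_cap, "); drop \"ESA\" from `pathways` or raise the cap")
  nt1 <- as.integer(grid$t1_max / grid$dt)
  nt3 <- as.integer(grid$t3_max / grid$dt)
  ns2max <- as.integer(max(grid$t2_values) / grid$dt)
  n_keep <- nt1 + ns2max + nt3
  starts <- sample_starts(n_frames(ht), n_keep, n_samples, stride)
  U <- U %||% prop_array(ht)
  if (do_esa && is.null(U2)) U2 <- prop_array_2ex(ht, cap = two_exciton_cap)
  if (!do_esa) U2 <- array(0 + 0i, dim = c(1, 1, 0))
  pairs <- if (n >= 2) pair_basis(n) else matrix(0L, 0, 2)
  storage.mode(pairs) <- "integer"

  keys <- as.vector(outer(
    c("GSB_r", "GSB_nr", "SE_r", "SE_nr", "ESA_r", "ESA_nr"),
    c("par", "perp"), paste, sep = "_"))
  data <- vector("list", length(grid$t2_values))
  for (k in seq_along(grid$t2_values)) {
    ns2 <- as.integer(grid$t2_values[k] / grid$dt)
    acc <- NULL
    for (s in starts) {
      kr <- resp_kernel_cpp(U, ht$dipole_matrix, s, nt1, ns2, nt3,
                            do_esa, U2, pairs)
      acc <- if (is.null(acc)) kr else Map(`+`, acc, kr)
    }
    acc <- lapply(acc, function(m) m / length(starts))
    drop_keys <- setdiff(c("GSB", "SE", "ESA"), pathways)
    for (dk in drop_keys)
      for (nm in grep(paste0("^", dk, "_"), names(acc), value = TRUE))
        acc[[nm]] <- matrix(0 + 0i, nt1 + 1, nt3 + 1)
    data[[k]] <- acc[keys]
  }
  structure(list(t1 = (0:nt1) * grid$dt, t3 = (0:nt3) * grid$dt,
                 t2_values = grid$t2_values, dt = grid$dt,
                 pathways = pathways, omega_ref = ht$omega0,
                 apodized = FALSE, data = data),
            class = "response_tensor")
}

#' @export
print.response_tensor <- function(x, ...) {
  cat("<response_tensor> t1 x t3: ", length(x$t1), " x ", length(x$t3),
      " points; t2 = {", paste(x$t2_values, collapse = ", "),
      "} fs; pathways: ", paste(x$pathways, collapse = "+"),
      if (x$apodized) "; apodized", "\n", sep = "")
  invisible(x)
}

#' Apodize a response tensor
#'
#' Multiplies each pathway by
#' `exp(-(t1 + t3)/tau_homo) * G(t1, t3)` where the Gaussian factor `G`
#' depends on the mode (see [apodization_spec()]).  The `t1 = t3 = 0`
#' value is unchanged.
#'
#' @param resp a [twod_response()] tensor.
#' @param apod an [apodization_spec()].
#' @return the apodized `response_tensor`.
#' @export
apodize <- function(resp, apod = apodization_spec()) {
  stopifnot(inherits(resp, "response_tensor"), inherits(apod, "apodization_spec"))
  if (resp$apodized) warning("response tensor is already apodized")
  T1 <- matrix(resp$t1, length(resp$t1), length(resp$t3))
  T3 <- matrix(resp$t3, length(resp$t1), length(resp$t3), byrow = TRUE)
  expw <- exp(-(T1 + T3) / apod$tau_homo)
  g_ind <- exp(-(T1^2 + T3^2) / (2 * apod$tau_inhomo^2))
  g_cor_r <- exp(-(T1 - T3)^2 / (2 * apod$tau_inhomo^2))
  g_cor_nr <- exp(-(T1 + T3)^2 / (2 * apod$tau_inhomo^2))
  resp$data <- lapply(resp$data, function(d) {
    for (nm in names(d)) {
      g <- if (apod$mode == "independent") g_ind
        else if (grepl("_r_", nm)) g_cor_r else g_cor_nr
      d[[nm]] <- d[[nm]] * expw * g
    }
    d
  })
  resp$apodized <- TRUE
  resp
}

#' Absorptive 2D spectrum from an apodized response tensor
#'
#' The absorptive map is the real part of the sum of the rephasing
#' signal (with the `omega1` sign flipped) and the nonrephasing signal,
#' Fourier-transformed over both coherence times with four-fold zero
#' padding.  ESA is subtracted (opposite sign to GSB/SE).
#'
#' @param resp an apodized [twod_response()] tensor.
#' @param t2 waiting time, fs (must be in `resp$t2_values`).
#' @param scheme `"parallel"` or `"perpendicular"` lab polarization.
#' @param pad_factor zero-padding factor.
#' @param window half-width of the frequency axes about the monomer
#'   energy, cm^-1.
#' @return an object of class `spectrum2d`: `omega1`, `omega3` (cm^-1,
#'   increasing), `map` (real matrix, `omega1` in rows), `t2`, `scheme`.
#' @export
spectrum_2d <- function(resp, t2 = 0, scheme = c("parallel", "perpendicular"),
                        pad_factor = 4, window = 2500) {
  stopifnot(inherits(resp, "response_tensor"))
  scheme <- match.arg(scheme)
  if (!resp$apodized)
    warning("response tensor has not been apodized; spectra will ring")
  k <- match(t2, resp$t2_values)
  if (is.na(k)) stop("t2 = ", t2, " fs is not among the computed waiting times")
  sch <- if (scheme == "parallel") "par" else "perp"
  d <- resp$data[[k]]
  tot_r <- d[[paste0("GSB_r_", sch)]] + d[[paste0("SE_r_", sch)]] -
    d[[paste0("ESA_r_", sch)]]
  tot_nr <- d[[paste0("GSB_nr_", sch)]] + d[[paste0("SE_nr_", sch)]] -
    d[[paste0("ESA_nr_", sch)]]
  n1 <- nrow(tot_r); n3 <- ncol(tot_r)
  half <- function(m) { m[1, ] <- m[1, ] / 2; m[, 1] <- m[, 1] / 2; m }
  p1 <- pad_factor * n1; p3 <- pad_factor * n3
  pad <- function(m) { out <- matrix(0 + 0i, p1, p3); out[1:n1, 1:n3] <- m; out }
  ft2 <- function(m, inverse_t1) {
    s1 <- mvfft(m, inverse = inverse_t1)        # over t1 (rows)
    t(mvfft(t(s1), inverse = TRUE))             # over t3 (columns)
  }
  ## rephasing: e^{+i w t1} phase, forward FFT over t1 flips the sign
  z <- ft2(pad(half(tot_r)), inverse_t1 = FALSE) +
    ft2(pad(half(tot_nr)), inverse_t1 = TRUE)
  shift <- function(nn) { k <- seq_len(nn) - 1; k[k >= nn / 2] <- k[k >= nn / 2] - nn; k }
  k1 <- shift(p1); k3 <- shift(p3)
  o1 <- k1 / (p1 * resp$dt * C_CM_FS) + resp$omega_ref
  o3 <- k3 / (p3 * resp$dt * C_CM_FS) + resp$omega_ref
  ord1 <- order(o1); ord3 <- order(o3)
  map <- Re(z)[ord1, ord3]
  o1 <- o1[ord1]; o3 <- o3[ord3]
  keep1 <- abs(o1 - resp$omega_ref) <= window
  keep3 <- abs(o3 - resp$omega_ref) <= window
  structure(list(omega1 = o1[keep1], omega3 = o3[keep3],
                 map = map[keep1, keep3, drop = FALSE],
                 t2 = t2, scheme = scheme),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat("<spectrum2d> ", length(x$omega1), " x ", length(x$omega3),
      " map, t2 = ", x$t2, " fs, ", x$scheme, " scheme\n", sep = "")
  invisible(x)
}

#' Polarization labels (and transverse momentum) of exciton states
#'
#' Labels each state `parallel` when `M_z^2/|M|^2 > 0.8`, `perpendicular`
#' when `< 0.2`, otherwise `mixed`.  For a disorder-free cylinder built
#' from rings, `k2 = TRUE` additionally assigns the transverse (Bloch)
#' momentum from the dominant discrete azimuthal Fourier component of
#' the eigenvector: `k2 = 0` states are polarized along the cylinder
#' axis, the degenerate `k2 = +/-1` pair perpendicular to it.
#'
#' @param eig an [eigendecompose_frame()] result.
#' @param agg the aggregate the frame was built from (needed for `k2`).
#' @param k2 also compute transverse momenta (homogeneous cylinders only).
#' @return data.frame with `energy`, `strength` (`|M|^2`), `label`, and
#'   (optionally) `k2`.
#' @export
band_polarization <- function(eig, agg = NULL, k2 = FALSE) {
  stopifnot(inherits(eig, "eigenstate_set"))
  M <- eig$transition_dipoles
  s2 <- rowSums(M^2)
  frac <- ifelse(s2 > 0, M[, 3]^2 / s2, NA_real_)
  label <- ifelse(is.na(frac), "dark",
                  ifelse(frac > 0.8, "parallel",
                         ifelse(frac < 0.2, "perpendicular", "mixed")))
  out <- data.frame(energy = eig$energies, strength = s2, label = label)
  if (k2) {
    if (is.null(agg)) stop("k2 assignment needs the aggregate")
    if (!is.null(agg$spec) && (agg$spec$jitter_sd %||% 0) > 0)
      stop("k2 is only defined for homogeneous (jitter-free) cylinders; ",
           "use label-only mode")
    theta <- atan2(agg$positions[, 2], agg$positions[, 1])
    zr <- round(agg$positions[, 3], 6)
    rings <- split(seq_len(nrow(agg$positions)), zr)
    n_ring <- max(lengths(rings))
    kmax <- floor(n_ring / 2)
    out$k2 <- vapply(seq_along(eig$energies), function(i) {
      v <- eig$eigenvectors[, i]
      pw <- vapply(0:kmax, function(k)
        sum(vapply(rings, function(idx)
          Mod(sum(v[idx] * exp(-1i * k * theta[idx])))^2, numeric(1))),
        numeric(1))
      which.max(pw) - 1L
    }, integer(1))
  }
  out
}
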