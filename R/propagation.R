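## Piecewise-constant unitary propagation (NISE scheme): within each
## short interval the Hamiltonian is frozen and the propagator is the
## exact exponential built from the eigendecomposition.  Quantum
## amplitudes evolve under classical bath trajectories with no detailed
## balance (high-temperature limit).

#' Single-interval propagator
#'
#' `U = exp(-i * 2*pi*c * (H - omega_ref) * dt)` via eigendecomposition
#' of the Hermitian frame.  `omega_ref` shifts all energies into a
#' rotating frame (pure numerical conditioning; spectra are shifted back
#' on output).
#'
#' @param frame Hermitian matrix, cm^-1.
#' @param dt interval, fs.
#' @param omega_ref rotating-frame reference energy, cm^-1.
#' @param tol Hermiticity tolerance (cm^-1).
#' @return complex unitary matrix.
#' @export
step_propagator <- function(frame, dt, omega_ref = 0, tol = 1e-9) {
  asym <- max(abs(frame - t(frame)))
  if (asym > tol)
    stop("frame is not Hermitian (max asymmetry ", signif(asym, 3), " cm^-1)")
  e <- eigen((frame + t(frame)) / 2, symmetric = TRUE)
  ph <- exp(-1i * TWO_PI_C * (e$values - omega_ref) * dt)
  e$vectors %*% (ph * t(e$vectors))
}

#' Step propagators for a whole Hamiltonian trajectory
#'
#' `U[[t]]` propagates amplitudes from frame `t` to frame `t + 1` using
#' the frame-`t` Hamiltonian.
#'
#' @param ht a `hamiltonian_trajectory`.
#' @param omega_ref rotating-frame reference (default: the monomer
#'   energy stored in `ht`).
#' @param frames which frame indices to build (default all).
#' @return list of complex N x N matrices.
#' @export
build_propagators <- function(ht, omega_ref = ht$omega0,
                              frames = seq_len(n_frames(ht))) {
  lapply(frames, function(t) step_propagator(ht_frame(ht, t), ht$dt, omega_ref))
}

#' Two-exciton step propagators
#'
#' Same construction on the hard-core pair-space Hamiltonian; the
#' rotating-frame reference is `2 * omega_ref` so that single- and
#' double-exciton coherences rotate consistently.
#'
#' @inheritParams build_propagators
#' @param cap two-exciton site cap (see [two_exciton_hamiltonian()]).
#' @return list of complex `N(N-1)/2` square matrices.
#' @export
build_propagators_2ex <- function(ht, omega_ref = ht$omega0,
                                  frames = seq_len(n_frames(ht)), cap = 150) {
  lapply(frames, function(t)
    step_propagator(two_exciton_hamiltonian(ht_frame(ht, t), cap = cap),
                    ht$dt, 2 * omega_ref))
}

#' Propagate a state vector or operator through a trajectory window
#'
#' Left-multiplies `x` by the ordered product
#' `U[[to - 1]] ... U[[from]]`, i.e. evolves from the time of frame
#' `from` to the time of frame `to`.  `from == to` returns `x`
#' unchanged.
#'
#' @param x complex vector (length N) or matrix with N rows.
#' @param U list of step propagators (as from [build_propagators()]).
#' @param from,to frame indices, `1 <= from <= to <= length(U) + 1`.
#' @return evolved object of the same shape.
#' @export
propagate <- function(x, U, from, to) {
  if (from < 1 || to > length(U) + 1 || from > to)
    stop("invalid propagation window [", from, ", ", to, "] for ",
         length(U), " step propagators")
  was_vec <- !is.matrix(x)
  if (was_vec) x <- matrix(x, ncol = 1)
  if (from < to && nrow(U[[from]]) != nrow(x))
    stop("object dimension ", nrow(x), " does not match propagator size ",
         nrow(U[[from]]))
  for (t in seq_len(to - from) + from - 1L) x <- U[[t]] %*% x
  if (was_vec) drop(x) else x
}
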