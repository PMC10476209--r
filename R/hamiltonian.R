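## Frenkel exciton Hamiltonian: site energies + point-dipole couplings,
## with an on-demand hard-core two-exciton block.

#' Point-dipole excitonic coupling
#'
#' `J = C * [mu_m.mu_n - 3 (mu_m.R)(mu_n.R)] * |mu_m||mu_n| / R^3` with
#' `C = 5034.12 cm^-1 Angstrom^3 Debye^-2` (the SI evaluation of
#' `1 D^2 / (4 pi eps0 * 1 A^3)` in wavenumbers), distances in Angstrom
#' and dipole magnitudes in debye.
#'
#' @param pos_m,pos_n site positions (length-3, Angstrom).
#' @param mu_m,mu_n dipole direction vectors (length-3; normalized
#'   internally).
#' @param mag_m,mag_n dipole magnitudes in debye.
#' @return coupling in cm^-1.
#' @export
point_dipole_coupling <- function(pos_m, mu_m, pos_n, mu_n,
                                  mag_m = 1, mag_n = 1) {
  r <- pos_n - pos_m
  d <- sqrt(sum(r^2))
  if (d <= 1) stop("sites closer than 1 Angstrom (distance ", signif(d, 3),
                   "); coincident or overlapping positions")
  rhat <- r / d
  m1 <- mu_m / sqrt(sum(mu_m^2))
  m2 <- mu_n / sqrt(sum(mu_n^2))
  kappa <- sum(m1 * m2) - 3 * sum(m1 * rhat) * sum(m2 * rhat)
  DIPOLE_PREFACTOR_CM * kappa * mag_m * mag_n / d^3
}

#' Full point-dipole coupling matrix of an aggregate
#'
#' Dense, no distance cutoff by default so that small-system results are
#' exact; `cutoff` (Angstrom) zeroes couplings beyond that distance.
#'
#' @param agg an aggregate.
#' @param cutoff optional distance cutoff in Angstrom.
#' @return symmetric N x N matrix, cm^-1, zero diagonal.
#' @export
coupling_matrix <- function(agg, cutoff = Inf) {
  pos <- agg$positions
  mu <- agg$dipoles / sqrt(rowSums(agg$dipoles^2))
  n <- nrow(pos)
  mag2 <- agg$dipole_magnitude^2
  J <- matrix(0, n, n)
  for (m in seq_len(n - 1)) {
    idx <- (m + 1):n
    r <- pos[idx, , drop = FALSE] - matrix(pos[m, ], length(idx), 3, byrow = TRUE)
    d <- sqrt(rowSums(r^2))
    if (any(d <= 1)) stop("sites closer than 1 Angstrom in aggregate")
    rhat <- r / d
    kap <- drop(mu[idx, , drop = FALSE] %*% mu[m, ]) -
      3 * drop(rhat %*% mu[m, ]) * rowSums(rhat * mu[idx, , drop = FALSE])
    j <- DIPOLE_PREFACTOR_CM * kap * mag2 / d^3
    j[d > cutoff] <- 0
    J[m, idx] <- j
    J[idx, m] <- j
  }
  J
}

#' Assemble the time-dependent exciton Hamiltonian
#'
#' Frame `t` has diagonal `omega0 + dE[n, t]` and static off-diagonal
#' point-dipole couplings (the aggregate geometry is frozen during the
#' dynamics, so J is time independent).  Frames are materialized on
#' demand with [ht_frame()].
#'
#' @param agg an aggregate.
#' @param site_traj a [generate_site_energies()] trajectory whose rows
#'   match the aggregate sites.
#' @param omega0 monomer transition energy, cm^-1.
#' @param cutoff optional coupling distance cutoff (Angstrom).
#' @return an object of class `hamiltonian_trajectory` with fields `J`
#'   (N x N, cm^-1), `dE` (N x T, cm^-1), `omega0`, `dt` (fs) and
#'   `dipole_matrix` (N x 3, debye).
#' @export
build_hamiltonian_trajectory <- function(agg, site_traj,
                                         omega0 = OMEGA0_CM, cutoff = Inf) {
  stopifnot(inherits(agg, "aggregate"),
            inherits(site_traj, "site_energy_trajectory"))
  if (nrow(site_traj$values) != nrow(agg$positions))
    stop("site-energy trajectory has ", nrow(site_traj$values),
         " rows but the aggregate has ", nrow(agg$positions), " sites")
  mu <- agg$dipoles / sqrt(rowSums(agg$dipoles^2))
  structure(list(J = coupling_matrix(agg, cutoff = cutoff),
                 dE = site_traj$values,
                 omega0 = omega0, dt = site_traj$dt,
                 dipole_matrix = mu * agg$dipole_magnitude),
            class = "hamiltonian_trajectory")
}

#' Number of frames in a Hamiltonian trajectory
#' @param ht a `hamiltonian_trajectory`.
#' @export
n_frames <- function(ht) ncol(ht$dE)

#' Materialize one Hermitian Hamiltonian frame
#' @param ht a `hamiltonian_trajectory`.
#' @param t frame index (1-based).
#' @return symmetric N x N matrix in cm^-1.
#' @export
ht_frame <- function(ht, t) {
  stopifnot(t >= 1, t <= n_frames(ht))
  H <- ht$J
  diag(H) <- ht$omega0 + ht$dE[, t]
  H
}

#' Index table of the hard-core two-exciton basis
#'
#' Unordered site pairs `(m < n)` in column-major pair order.
#' @param n number of sites.
#' @return integer matrix `N(N-1)/2 x 2`.
#' @export
pair_basis <- function(n) {
  stopifnot(n >= 2)
  m <- sequence(seq_len(n - 1))
  nn <- rep(2:n, 1:(n - 1))
  cbind(m = m, n = nn)
}

#' Two-exciton Hamiltonian of one frame
#'
#' Hard-core boson (Paulion) convention: each molecule can be excited at
#' most once, and there is no biexciton binding shift.  In the pair basis
#' `(m < n)` the diagonal is `H[m,m] + H[n,n]`; the off-diagonal element
#' between pairs sharing one site is the single-exciton coupling of the
#' differing sites; pairs sharing no site are uncoupled.
#'
#' @param frame a Hermitian N x N single-exciton frame.
#' @param cap refuse above this many sites (the pair space grows as
#'   `N(N-1)/2`; the default cap of 150 sites keeps it at most 11175).
#' @return symmetric `N(N-1)/2` matrix, cm^-1.
#' @export
two_exciton_hamiltonian <- function(frame, cap = 150) {
  n <- nrow(frame)
  stopifnot(n >= 2, ncol(frame) == n)
  if (n > cap)
    stop("two-exciton manifold for N = ", n, " sites exceeds the cap (",
         cap, "); raise `cap` deliberately or restrict the excited-state ",
         "absorption calculation to a smaller aggregate")
  pb <- pair_basis(n)
  np <- nrow(pb)
  H2 <- matrix(0, np, np)
  diag(H2) <- frame[cbind(pb[, 1], pb[, 1])] + frame[cbind(pb[, 2], pb[, 2])]
  for (a in seq_len(np - 1)) {
    pa <- pb[a, ]
    for (b in (a + 1):np) {
      pbv <- pb[b, ]
      shared <- intersect(pa, pbv)
      if (length(shared) == 1) {
        rest <- c(setdiff(pa, shared), setdiff(pbv, shared))
        H2[a, b] <- H2[b, a] <- frame[rest[1], rest[2]]
      }
    }
  }
  H2
}

#' Eigenstates and transition dipoles of one frame
#'
#' Ascending eigenvalues; state transition dipoles
#' `M_i = sum_n c_{i,n} mu_n` satisfy the oscillator-strength sum rule
#' `sum_i |M_i|^2 = sum_n |mu_n|^2`.
#'
#' @param frame Hermitian N x N matrix, cm^-1.
#' @param dipole_matrix N x 3 dipole vectors (debye).
#' @param tol Hermiticity tolerance (cm^-1).
#' @return an object of class `eigenstate_set` with fields `energies`,
#'   `eigenvectors` (columns are states) and `transition_dipoles`
#'   (N_states x 3).
#' @export
eigendecompose_frame <- function(frame, dipole_matrix, tol = 1e-9) {
  asym <- max(abs(frame - t(frame)))
  if (asym > tol)
    stop("frame is not Hermitian (max asymmetry ", signif(asym, 3), " cm^-1)")
  stopifnot(nrow(dipole_matrix) == nrow(frame), ncol(dipole_matrix) == 3)
  e <- eigen((frame + t(frame)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vec <- e$vectors[, ord, drop = FALSE]
  structure(list(energies = e$values[ord],
                 eigenvectors = vec,
                 transition_dipoles = t(vec) %*% dipole_matrix),
            class = "eigenstate_set")
}
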