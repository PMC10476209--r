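## Shared fixtures and independent oracles for the test suite.

TWO_PI_C_T <- 2 * pi * 2.99792458e-5 # rad fs^-1 per cm^-1

## hand-assembled aggregates (bypassing the lattice construction)
make_aggregate <- function(positions, dipoles, magnitude = 5.48) {
  dipoles <- dipoles / sqrt(rowSums(dipoles^2))
  structure(list(positions = positions, dipoles = dipoles,
                 dipole_magnitude = magnitude,
                 molecule_ids = seq_len(nrow(positions)),
                 radius = NA_real_, delta_actual = NA_real_, spec = NULL),
            class = "aggregate")
}

make_monomer <- function(dipole = c(0, 0, 1), magnitude = 5.48) {
  make_aggregate(matrix(0, 1, 3), matrix(dipole, 1, 3), magnitude)
}

## frozen (static-Hamiltonian) trajectory of n_steps identical frames
frozen_ht <- function(agg, n_steps = 60, mean_shift = 0, sigma_static = 0,
                      seed = 1, omega0 = 15390) {
  bs <- bath_spec(mean_shift = mean_shift, sigma_dynamic = 0,
                  sigma_static = sigma_static, n_steps = n_steps, seed = seed)
  build_hamiltonian_trajectory(agg, generate_site_energies(agg, bs),
                               omega0 = omega0)
}

## full width at half maximum by linear interpolation
fwhm_of <- function(s, channel = "iso") {
  y <- s$channels[, channel]
  f <- s$frequency
  hm <- max(y) / 2
  idx <- which(y >= hm)
  lo <- min(idx); hi <- max(idx)
  f1 <- if (lo == 1) f[1] else
    stats::approx(y[c(lo - 1, lo)], f[c(lo - 1, lo)], xout = hm)$y
  f2 <- if (hi == length(f)) f[hi] else
    stats::approx(y[c(hi, hi + 1)], f[c(hi, hi + 1)], xout = hm)$y
  f2 - f1
}

peak_of <- function(s, channel = "iso") s$frequency[which.max(s$channels[, channel])]

## Independent sum-over-states oracle for the third-order response of a
## STATIC Hamiltonian: eigenbasis matrix exponentials, explicit pathway
## amplitudes, explicit isotropic orientational contraction.  Shares no
## code with the stepwise propagation kernel.
sos_response <- function(H, Mdip, w0, t1v, t2, t3v, esa = TRUE) {
  n <- nrow(H)
  evo <- function(t) {
    e <- eigen(H - diag(w0, n), symmetric = TRUE)
    e$vectors %*% (exp(-1i * TWO_PI_C_T * e$values * t) * t(e$vectors))
  }
  if (esa && n >= 2) {
    pb <- pair_basis(n)
    H2 <- two_exciton_hamiltonian(H)
    evo2 <- function(t) {
      e <- eigen(H2 - diag(2 * w0, nrow(H2)), symmetric = TRUE)
      e$vectors %*% (exp(-1i * TWO_PI_C_T * e$values * t) * t(e$vectors))
    }
    V2 <- lapply(1:3, function(g) {
      V <- matrix(0, nrow(pb), n)
      for (p in seq_len(nrow(pb))) {
        m <- pb[p, 1]; nn <- pb[p, 2]
        V[p, nn] <- V[p, nn] + Mdip[m, g]
        V[p, m] <- V[p, m] + Mdip[nn, g]
      }
      V
    })
  }
  A <- function(t) t(Mdip) %*% evo(t) %*% Mdip
  contract <- function(Rt) {
    s1 <- s2 <- s3 <- 0 + 0i
    for (a in 1:3) for (b in 1:3) {
      s1 <- s1 + Rt(a, a, b, b)
      s2 <- s2 + Rt(a, b, a, b)
      s3 <- s3 + Rt(a, b, b, a)
    }
    c(par = (s1 + s2 + s3) / 15, perp = (4 * s1 - s2 - s3) / 30)
  }
  keys <- as.vector(outer(c("GSB_r", "GSB_nr", "SE_r", "SE_nr", "ESA_r", "ESA_nr"),
                          c("par", "perp"), paste, sep = "_"))
  out <- setNames(replicate(length(keys),
                            matrix(0 + 0i, length(t1v), length(t3v)),
                            simplify = FALSE), keys)
  for (i1 in seq_along(t1v)) for (i3 in seq_along(t3v)) {
    t1 <- t1v[i1]; t3 <- t3v[i3]
    A1 <- A(t1); A13 <- A(t1 + t2); A2t <- A(t2)
    A23 <- A(t2 + t3); A123 <- A(t1 + t2 + t3); A3 <- A(t3)
    cz <- contract(function(a, b, g, d) Conj(A1[b, a]) * A3[d, g])
    out$GSB_r_par[i1, i3] <- cz["par"]; out$GSB_r_perp[i1, i3] <- cz["perp"]
    cz <- contract(function(a, b, g, d) A1[b, a] * A3[d, g])
    out$GSB_nr_par[i1, i3] <- cz["par"]; out$GSB_nr_perp[i1, i3] <- cz["perp"]
    cz <- contract(function(a, b, g, d) Conj(A13[g, a]) * A23[d, b])
    out$SE_r_par[i1, i3] <- cz["par"]; out$SE_r_perp[i1, i3] <- cz["perp"]
    cz <- contract(function(a, b, g, d) Conj(A2t[g, b]) * A123[d, a])
    out$SE_nr_par[i1, i3] <- cz["par"]; out$SE_nr_perp[i1, i3] <- cz["perp"]
    if (esa && n >= 2) {
      U1 <- evo(t1); U2i <- evo(t2); U3 <- evo(t3); W3 <- evo2(t3)
      braR <- U3 %*% U2i %*% U1 %*% Mdip
      ketR <- U2i %*% Mdip
      braN <- U3 %*% U2i %*% Mdip
      ketN <- U2i %*% U1 %*% Mdip
      Rr <- function(a, b, g, d)
        sum(Conj(braR[, a]) * (t(V2[[d]]) %*% W3 %*% (V2[[g]] %*% ketR[, b])))
      Rn <- function(a, b, g, d)
        sum(Conj(braN[, b]) * (t(V2[[d]]) %*% W3 %*% (V2[[g]] %*% ketN[, a])))
      cz <- contract(Rr)
      out$ESA_r_par[i1, i3] <- cz["par"]; out$ESA_r_perp[i1, i3] <- cz["perp"]
      cz <- contract(Rn)
      out$ESA_nr_par[i1, i3] <- cz["par"]; out$ESA_nr_perp[i1, i3] <- cz["perp"]
    }
  }
  out
}

## synthetic anisotropy trace object
make_trace <- function(t2, r) {
  structure(list(t2_values = t2, r_values = r, point = c(omega1 = 0, omega3 = 0),
                 fit = NULL),
            class = "anisotropy_trace")
}

## synthetic spectrum2d object
make_spectrum2d <- function(omega1, omega3, map, t2 = 0, scheme = "parallel") {
  structure(list(omega1 = omega1, omega3 = omega3, map = map, t2 = t2,
                 scheme = scheme),
            class = "spectrum2d")
}

## averaged 2DES response over bath realizations for preset runs
averaged_response <- function(agg, grid, seed, pathways = c("GSB", "SE"),
                              n_samples = 4, n_realizations = 3, stride = 16) {
  n_keep <- (grid$t1_max + max(grid$t2_values) + grid$t3_max) / grid$dt
  need <- (n_samples - 1) * stride + n_keep + 1
  acc <- NULL
  for (k in seq_len(n_realizations)) {
    b <- bath_spec(n_steps = need, seed = seed * 100 + k)
    ht <- build_hamiltonian_trajectory(agg, generate_site_energies(agg, b))
    resp <- twod_response(ht, grid, pathways = pathways,
                          n_samples = n_samples, stride = stride)
    acc <- if (is.null(acc)) resp else {
      resp$data <- Map(function(a, b) Map(`+`, a, b), acc$data, resp$data)
      resp
    }
  }
  acc$data <- lapply(acc$data, function(d) lapply(d, function(m) m / n_realizations))
  apodize(acc, apodization_spec())
}

## anisotropy maps for every waiting time of an apodized response
maps_of <- function(resp) {
  lapply(resp$t2_values, function(t2)
    anisotropy_map(spectrum_2d(resp, t2, "parallel"),
                   spectrum_2d(resp, t2, "perpendicular")))
}

## grid point of maximal parallel-scheme intensity at t2 = 0
max_point <- function(resp) {
  sp0 <- spectrum_2d(resp, resp$t2_values[1], "parallel")
  ij <- which(sp0$map == max(sp0$map), arr.ind = TRUE)[1, ]
  c(sp0$omega1[ij[1]], sp0$omega3[ij[2]])
}
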