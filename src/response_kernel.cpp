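// Third-order response kernel for the piecewise-constant (NISE)
// propagation scheme.
//
// For one trajectory start frame i0 and one waiting time (ns2 steps) it
// accumulates the rephasing and nonrephasing ground-state-bleach (GSB),
// stimulated-emission (SE) and, optionally, excited-state-absorption
// (ESA) response on the (t1, t3) coherence grid, already contracted
// with the analytic isotropic four-point orientational weights for the
// all-parallel <ZZZZ> and pump-perpendicular-probe <ZZXX> lab schemes.
//
// Conventions (interaction Cartesian indices a = pulse1, b = pulse2,
// g = pulse3, d = signal; U(x -> y) is the ordered product of step
// propagators):
//   A(s)  = M^T U(i0 -> i0+s) M                (3x3)
//   C(s)  = M^T U(tau2 -> tau2+s) M, tau2 = i0 + it1
//   D(s)  = M^T U(tau3 -> tau3+s) M, tau3 = tau2 + ns2
//   GSB rephasing    R_{abgd} = conj(A(it1))_{ba} * D(it3)_{dg}
//   GSB nonrephasing R_{abgd} =      A(it1)_{ba}  * D(it3)_{dg}
//   SE  rephasing    R_{abgd} = conj(A(it1+ns2))_{ga} * C(ns2+it3)_{db}
//   SE  nonrephasing R_{abgd} = conj(C(ns2))_{gb} * A(it1+ns2+it3)_{da}
// ESA pathways promote the ket into the hard-core pair space during t3
// and are returned with positive sign (the assembly subtracts them).
//
// Isotropic four-point averages for unit lab polarization vectors:
//   <ZZZZ>: (s_aabb + s_abab + s_abba) / 15
//   <ZZXX>: (4 s_aabb - s_abab - s_abba) / 30
// where s_aabb = sum_{a,b} R_{aabb} etc.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline cx_double tr3(const cx_mat& X) {
  return X(0, 0) + X(1, 1) + X(2, 2);
}

struct Triple { cx_double s_aabb, s_abab, s_abba; };

// R_{abgd} = X(b,a) * Y(d,g)
static Triple contract_GSB(const cx_mat& X, const cx_mat& Y) {
  Triple t;
  t.s_aabb = tr3(X) * tr3(Y);
  t.s_abab = accu(X % Y);
  t.s_abba = accu(X % Y.st());
  return t;
}
// R_{abgd} = X(g,a) * Y(d,b)
static Triple contract_SEr(const cx_mat& X, const cx_mat& Y) {
  Triple t;
  t.s_aabb = accu(X % Y);
  t.s_abab = tr3(X) * tr3(Y);
  t.s_abba = accu(X % Y.st());
  return t;
}
// R_{abgd} = X(g,b) * Y(d,a)
static Triple contract_SEnr(const cx_mat& X, const cx_mat& Y) {
  Triple t;
  t.s_aabb = accu(X % Y);
  t.s_abab = accu(X % Y.st());
  t.s_abba = tr3(X) * tr3(Y);
  return t;
}

static inline cx_double w_par(const Triple& t) {
  return (t.s_aabb + t.s_abab + t.s_abba) / 15.0;
}
static inline cx_double w_perp(const Triple& t) {
  return (4.0 * t.s_aabb - t.s_abab - t.s_abba) / 30.0;
}

static void contract_full(const cx_double R[3][3][3][3],
                          cx_double& par, cx_double& perp) {
  cx_double s1(0, 0), s2(0, 0), s3(0, 0);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      s1 += R[a][a][b][b];
      s2 += R[a][b][a][b];
      s3 += R[a][b][b][a];
    }
  par = (s1 + s2 + s3) / 15.0;
  perp = (4.0 * s1 - s2 - s3) / 30.0;
}

// U: cx_cube N x N x (T-1); slice s (0-based) propagates frame s+1 to
// s+2 in R's 1-based frame indexing.  U2: pair-space analogue (may be
// empty when do_esa is false).  pairs: Np x 2, 1-based site indices.
// [[Rcpp::export]]
List resp_kernel_cpp(const arma::cx_cube& U, const arma::mat& Mr, int i0,
                     int nt1, int ns2, int nt3,
                     bool do_esa, const arma::cx_cube& U2,
                     const arma::imat& pairs) {
  const int N = Mr.n_rows;
  const int S = nt1 + ns2 + nt3;
  if ((uword)(i0 - 1 + S) > U.n_slices)
    Rcpp::stop("trajectory too short: need %d step propagators from start %d, have %d",
               S, i0, (int)U.n_slices);
  if (do_esa && (uword)(i0 - 1 + S) > U2.n_slices + 0u && pairs.n_rows > 0)
    Rcpp::stop("two-exciton propagator set too short");
  const cx_mat Mc = conv_to<cx_mat>::from(Mr);

  // forward chain from i0, with full storage for ESA bra/ket reuse
  cx_cube PsiStore(N, 3, S + 1);
  cx_cube A(3, 3, S + 1);
  {
    cx_mat Psi = Mc;
    PsiStore.slice(0) = Psi;
    A.slice(0) = Mc.st() * Psi;
    for (int s = 1; s <= S; ++s) {
      Psi = U.slice(i0 - 1 + s - 1) * Psi;
      PsiStore.slice(s) = Psi;
      A.slice(s) = Mc.st() * Psi;
    }
  }

  const int n1 = nt1 + 1, n3 = nt3 + 1;
  cx_mat GSBr_par(n1, n3), GSBr_perp(n1, n3), GSBnr_par(n1, n3),
      GSBnr_perp(n1, n3), SEr_par(n1, n3), SEr_perp(n1, n3),
      SEnr_par(n1, n3), SEnr_perp(n1, n3), ESAr_par(n1, n3, fill::zeros),
      ESAr_perp(n1, n3, fill::zeros), ESAnr_par(n1, n3, fill::zeros),
      ESAnr_perp(n1, n3, fill::zeros);

  // pair-space raising operators V2[g] (Np x N)
  const int Np = pairs.n_rows;
  std::vector<mat> V2(3);
  if (do_esa && Np > 0) {
    for (int g = 0; g < 3; ++g) {
      V2[g].zeros(Np, N);
      for (int p = 0; p < Np; ++p) {
        const int m = pairs(p, 0) - 1, nn = pairs(p, 1) - 1;
        V2[g](p, nn) += Mr(m, g);
        V2[g](p, m) += Mr(nn, g);
      }
    }
  }

  for (int it1 = 0; it1 <= nt1; ++it1) {
    // chain from tau2 = i0 + it1 over ns2 + nt3 steps
    cx_cube C(3, 3, ns2 + nt3 + 1);
    cx_cube PhiStore(N, 3, nt3 + 1); // slices are s = ns2 .. ns2+nt3
    cx_mat Phi = Mc;
    C.slice(0) = Mc.st() * Phi;
    if (ns2 == 0) PhiStore.slice(0) = Phi;
    for (int s = 1; s <= ns2 + nt3; ++s) {
      Phi = U.slice(i0 - 1 + it1 + s - 1) * Phi;
      C.slice(s) = Mc.st() * Phi;
      if (s >= ns2) PhiStore.slice(s - ns2) = Phi;
    }
    // chain from tau3 = i0 + it1 + ns2 over nt3 steps
    cx_cube D(3, 3, nt3 + 1);
    cx_mat Xi = Mc;
    D.slice(0) = Mc.st() * Xi;
    for (int s = 1; s <= nt3; ++s) {
      Xi = U.slice(i0 - 1 + it1 + ns2 + s - 1) * Xi;
      D.slice(s) = Mc.st() * Xi;
    }

    const cx_mat A2 = A.slice(it1);
    const cx_mat A3 = A.slice(it1 + ns2);
    const cx_mat C3 = C.slice(ns2);
    const cx_mat A2c = conj(A2), A3c = conj(A3), C3c = conj(C3);

    // ESA pair-space chains (both phasings share the same U2 steps)
    cx_mat K2r, K2n;
    if (do_esa && Np > 0) {
      K2r.set_size(Np, 9);
      K2n.set_size(Np, 9);
      const cx_mat kets_r = PhiStore.slice(0);           // U(tau2->tau3) M
      const cx_mat kets_n = PsiStore.slice(it1 + ns2);   // U(i0->tau3) M
      for (int g = 0; g < 3; ++g) {
        K2r.cols(3 * g, 3 * g + 2) = V2[g] * kets_r;
        K2n.cols(3 * g, 3 * g + 2) = V2[g] * kets_n;
      }
    }

    for (int it3 = 0; it3 <= nt3; ++it3) {
      const cx_mat A4 = A.slice(it1 + ns2 + it3);
      const cx_mat C4 = C.slice(ns2 + it3);
      const cx_mat D3 = D.slice(it3);

      Triple t;
      t = contract_GSB(A2c, D3);
      GSBr_par(it1, it3) = w_par(t);
      GSBr_perp(it1, it3) = w_perp(t);
      t = contract_GSB(A2, D3);
      GSBnr_par(it1, it3) = w_par(t);
      GSBnr_perp(it1, it3) = w_perp(t);
      t = contract_SEr(A3c, C4);
      SEr_par(it1, it3) = w_par(t);
      SEr_perp(it1, it3) = w_perp(t);
      t = contract_SEnr(C3c, A4);
      SEnr_par(it1, it3) = w_par(t);
      SEnr_perp(it1, it3) = w_perp(t);

      if (do_esa && Np > 0) {
        const cx_mat bra_r = PsiStore.slice(it1 + ns2 + it3); // cols: a
        const cx_mat bra_n = PhiStore.slice(it3);             // cols: b
        cx_double Rr[3][3][3][3], Rn[3][3][3][3];
        for (int d = 0; d < 3; ++d) {
          const cx_mat Wr = V2[d].t() * K2r; // N x 9, col 3g+c
          const cx_mat Wn = V2[d].t() * K2n;
          for (int g = 0; g < 3; ++g)
            for (int c = 0; c < 3; ++c) {
              for (int o = 0; o < 3; ++o) {
                // rephasing: c indexes the ket pulse (b), o the bra (a)
                Rr[o][c][g][d] = cdot(bra_r.col(o), Wr.col(3 * g + c));
                // nonrephasing: c indexes the ket pulse (a), o the bra (b)
                Rn[c][o][g][d] = cdot(bra_n.col(o), Wn.col(3 * g + c));
              }
            }
        }
        cx_double par, perp;
        contract_full(Rr, par, perp);
        ESAr_par(it1, it3) = par;
        ESAr_perp(it1, it3) = perp;
        contract_full(Rn, par, perp);
        ESAnr_par(it1, it3) = par;
        ESAnr_perp(it1, it3) = perp;
        if (it3 < nt3) {
          K2r = U2.slice(i0 - 1 + it1 + ns2 + it3) * K2r;
          K2n = U2.slice(i0 - 1 + it1 + ns2 + it3) * K2n;
        }
      }
    }
  }

  return List::create(
      Named("GSB_r_par") = GSBr_par, Named("GSB_r_perp") = GSBr_perp,
      Named("GSB_nr_par") = GSBnr_par, Named("GSB_nr_perp") = GSBnr_perp,
      Named("SE_r_par") = SEr_par, Named("SE_r_perp") = SEr_perp,
      Named("SE_nr_par") = SEnr_par, Named("SE_nr_perp") = SEnr_perp,
      Named("ESA_r_par") = ESAr_par, Named("ESA_r_perp") = ESAr_perp,
      Named("ESA_nr_par") = ESAnr_par, Named("ESA_nr_perp") = ESAnr_perp);
}

// Two-point dipole correlation recorder for the linear response:
// A(s) = M^T U(i0 -> i0+s) M for s = 0..nsteps.
// [[Rcpp::export]]
arma::cx_cube prop_record_cpp(const arma::cx_cube& U, const arma::mat& Mr,
                              int i0, int nsteps) {
  if ((uword)(i0 - 1 + nsteps) > U.n_slices)
    Rcpp::stop("trajectory too short for %d steps from start %d", nsteps, i0);
  const cx_mat Mc = conv_to<cx_mat>::from(Mr);
  cx_mat Psi = Mc;
  cx_cube A(3, 3, nsteps + 1);
  A.slice(0) = Mc.st() * Psi;
  for (int s = 1; s <= nsteps; ++s) {
    Psi = U.slice(i0 - 1 + s - 1) * Psi;
    A.slice(s) = Mc.st() * Psi;
  }
  return A;
}
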