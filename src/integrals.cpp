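// Gaussian-basis molecular integrals (McMurchie-Davidson scheme).
// All quantities in atomic units (Bohr, Hartree). Cartesian shells, s and p
// in the shipped basis sets; the primitive routines are general in angular
// momentum, which is what the center-derivative L-shift relations rely on.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Boys function F_m(T), m = 0..mmax
static void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  double e = std::exp(-T);
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2.0 * m + 1.0) * F[m] - e) / (2.0 * T);
  } else {
    // series for F_mmax, then stable downward recursion
    double term = 1.0 / (2.0 * mmax + 1.0), sum = term;
    for (int i = 1; i < 300; ++i) {
      term *= 2.0 * T / (2.0 * mmax + 2.0 * i + 1.0);
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    F[mmax] = e * sum;
    for (int m = mmax - 1; m >= 0; --m) F[m] = (2.0 * T * F[m + 1] + e) / (2.0 * m + 1.0);
  }
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} along one dimension
static double Ecoef(int i, int j, int t, double Qx, double a, double b) {
  double p = a + b, mu = a * b / p;
  if (t < 0 || t > i + j || i < 0 || j < 0) return 0.0;
  if (i == 0 && j == 0 && t == 0) return std::exp(-mu * Qx * Qx);
  if (i > 0) {
    return (1.0 / (2.0 * p)) * Ecoef(i - 1, j, t - 1, Qx, a, b)
         - (mu * Qx / a)     * Ecoef(i - 1, j, t,     Qx, a, b)
         + (t + 1.0)         * Ecoef(i - 1, j, t + 1, Qx, a, b);
  }
  return (1.0 / (2.0 * p)) * Ecoef(i, j - 1, t - 1, Qx, a, b)
       + (mu * Qx / b)     * Ecoef(i, j - 1, t,     Qx, a, b)
       + (t + 1.0)         * Ecoef(i, j - 1, t + 1, Qx, a, b);
}

// Hermite Coulomb integrals R^n_{tuv}
static double Rtuv(int t, int u, int v, int n, double p, const double* PC, const double* F) {
  if (t < 0 || u < 0 || v < 0) return 0.0;
  if (t == 0 && u == 0 && v == 0) {
    double val = F[n];
    for (int k = 0; k < n; ++k) val *= -2.0 * p;
    return val;
  }
  if (t > 0)
    return (t - 1) * Rtuv(t - 2, u, v, n + 1, p, PC, F) + PC[0] * Rtuv(t - 1, u, v, n + 1, p, PC, F);
  if (u > 0)
    return (u - 1) * Rtuv(t, u - 2, v, n + 1, p, PC, F) + PC[1] * Rtuv(t, u - 1, v, n + 1, p, PC, F);
  return (v - 1) * Rtuv(t, u, v - 2, n + 1, p, PC, F) + PC[2] * Rtuv(t, u, v - 1, n + 1, p, PC, F);
}

// ---------------------------------------------------------------------------
// primitive integrals; la/lb/... are int[3] Cartesian angular momenta
static double overlap_prim(const int* la, const int* lb, double a, double b,
                           const double* A, const double* B) {
  double p = a + b, val = 1.0;
  for (int d = 0; d < 3; ++d) val *= Ecoef(la[d], lb[d], 0, A[d] - B[d], a, b);
  return val * std::pow(M_PI / p, 1.5);
}

// 1D overlap without the sqrt(pi/p) factor
static inline double s1d(int i, int j, double Q, double a, double b) {
  return Ecoef(i, j, 0, Q, a, b);
}

static double kinetic_prim(const int* la, const int* lb, double a, double b,
                           const double* A, const double* B) {
  double p = a + b;
  double S[3], K[3];
  for (int d = 0; d < 3; ++d) {
    double Q = A[d] - B[d];
    int i = la[d], j = lb[d];
    S[d] = s1d(i, j, Q, a, b);
    double t = b * (2.0 * j + 1.0) * S[d] - 2.0 * b * b * s1d(i, j + 2, Q, a, b);
    if (j >= 2) t -= 0.5 * j * (j - 1.0) * s1d(i, j - 2, Q, a, b);
    K[d] = t;
  }
  double val = K[0] * S[1] * S[2] + S[0] * K[1] * S[2] + S[0] * S[1] * K[2];
  return val * std::pow(M_PI / p, 1.5);
}

// <a| 1/|r-C| |b>  (positive-definite kernel; caller applies charge sign)
static double attraction_prim(const int* la, const int* lb, double a, double b,
                              const double* A, const double* B, const double* C) {
  double p = a + b;
  double P[3], PC[3];
  for (int d = 0; d < 3; ++d) { P[d] = (a * A[d] + b * B[d]) / p; PC[d] = P[d] - C[d]; }
  double T = p * (PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2]);
  int L = la[0] + la[1] + la[2] + lb[0] + lb[1] + lb[2];
  std::vector<double> F(L + 1);
  boys(L, T, F.data());
  double val = 0.0;
  for (int t = 0; t <= la[0] + lb[0]; ++t) {
    double Ex = Ecoef(la[0], lb[0], t, A[0] - B[0], a, b);
    if (Ex == 0.0) continue;
    for (int u = 0; u <= la[1] + lb[1]; ++u) {
      double Ey = Ecoef(la[1], lb[1], u, A[1] - B[1], a, b);
      if (Ey == 0.0) continue;
      for (int v = 0; v <= la[2] + lb[2]; ++v) {
        double Ez = Ecoef(la[2], lb[2], v, A[2] - B[2], a, b);
        if (Ez == 0.0) continue;
        val += Ex * Ey * Ez * Rtuv(t, u, v, 0, p, PC, F.data());
      }
    }
  }
  return val * 2.0 * M_PI / p;
}

// (ab|cd) in Mulliken/chemists' notation
static double eri_prim(const int* la, const int* lb, const int* lc, const int* ld,
                       double a, double b, double c, double d,
                       const double* A, const double* B, const double* C, const double* D) {
  double p = a + b, q = c + d, alpha = p * q / (p + q);
  double P[3], Q[3], PQ[3];
  for (int k = 0; k < 3; ++k) {
    P[k] = (a * A[k] + b * B[k]) / p;
    Q[k] = (c * C[k] + d * D[k]) / q;
    PQ[k] = P[k] - Q[k];
  }
  double T = alpha * (PQ[0] * PQ[0] + PQ[1] * PQ[1] + PQ[2] * PQ[2]);
  int L = la[0] + la[1] + la[2] + lb[0] + lb[1] + lb[2]
        + lc[0] + lc[1] + lc[2] + ld[0] + ld[1] + ld[2];
  std::vector<double> F(L + 1);
  boys(L, T, F.data());
  double val = 0.0;
  for (int t = 0; t <= la[0] + lb[0]; ++t) {
    double E1x = Ecoef(la[0], lb[0], t, A[0] - B[0], a, b);
    if (E1x == 0.0) continue;
    for (int u = 0; u <= la[1] + lb[1]; ++u) {
      double E1y = Ecoef(la[1], lb[1], u, A[1] - B[1], a, b);
      if (E1y == 0.0) continue;
      for (int v = 0; v <= la[2] + lb[2]; ++v) {
        double E1z = Ecoef(la[2], lb[2], v, A[2] - B[2], a, b);
        if (E1z == 0.0) continue;
        for (int tau = 0; tau <= lc[0] + ld[0]; ++tau) {
          double E2x = Ecoef(lc[0], ld[0], tau, C[0] - D[0], c, d);
          if (E2x == 0.0) continue;
          for (int nu = 0; nu <= lc[1] + ld[1]; ++nu) {
            double E2y = Ecoef(lc[1], ld[1], nu, C[1] - D[1], c, d);
            if (E2y == 0.0) continue;
            for (int phi = 0; phi <= lc[2] + ld[2]; ++phi) {
              double E2z = Ecoef(lc[2], ld[2], phi, C[2] - D[2], c, d);
              if (E2z == 0.0) continue;
              double sign = ((tau + nu + phi) % 2 == 0) ? 1.0 : -1.0;
              val += E1x * E1y * E1z * E2x * E2y * E2z * sign
                   * Rtuv(t + tau, u + nu, v + phi, 0, alpha, PQ, F.data());
            }
          }
        }
      }
    }
  }
  return val * 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
}

// ---------------------------------------------------------------------------
// shells: flattened description passed from R
struct Shell {
  int l;              // 0 = s, 1 = p
  int atom;           // 0-based
  std::vector<double> exps, coefs; // contraction, coefs include all norms
  double center[3];
  int first;          // index of first basis function
  int nfun() const { return l == 0 ? 1 : 3; }
};

static std::vector<Shell> make_shells(IntegerVector sl, IntegerVector satom,
                                      List sexp, List scoef, NumericMatrix coords) {
  int ns = sl.size();
  std::vector<Shell> shells(ns);
  int ifun = 0;
  for (int i = 0; i < ns; ++i) {
    shells[i].l = sl[i];
    shells[i].atom = satom[i];
    shells[i].exps = as<std::vector<double> >(sexp[i]);
    shells[i].coefs = as<std::vector<double> >(scoef[i]);
    for (int d = 0; d < 3; ++d) shells[i].center[d] = coords(satom[i], d);
    shells[i].first = ifun;
    ifun += shells[i].nfun();
  }
  return shells;
}

static int nbf_total(const std::vector<Shell>& sh) {
  int n = 0;
  for (size_t i = 0; i < sh.size(); ++i) n += sh[i].nfun();
  return n;
}

// Cartesian components of a shell: s -> (000); p -> x,y,z
static void comp_l(int l, int k, int* out) {
  out[0] = out[1] = out[2] = 0;
  if (l == 1) out[k] = 1;
}

typedef double (*prim1e_fn)(const int*, const int*, double, double, const double*, const double*);

// generic contracted one-electron matrix for a primitive kernel
static NumericMatrix contract1e(const std::vector<Shell>& sh, prim1e_fn fn) {
  int n = nbf_total(sh);
  NumericMatrix M(n, n);
  int la[3], lb[3];
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j <= i; ++j) {
      const Shell &A = sh[i], &B = sh[j];
      for (int ka = 0; ka < A.nfun(); ++ka) {
        comp_l(A.l, ka, la);
        for (int kb = 0; kb < B.nfun(); ++kb) {
          comp_l(B.l, kb, lb);
          double val = 0.0;
          for (size_t pa = 0; pa < A.exps.size(); ++pa)
            for (size_t pb = 0; pb < B.exps.size(); ++pb)
              val += A.coefs[pa] * B.coefs[pb]
                   * fn(la, lb, A.exps[pa], B.exps[pb], A.center, B.center);
          M(A.first + ka, B.first + kb) = val;
          M(B.first + kb, A.first + ka) = val;
        }
      }
    }
  return M;
}

// [[Rcpp::export]]
List cpp_int1e(IntegerVector sl, IntegerVector satom, List sexp, List scoef,
               NumericMatrix coords) {
  std::vector<Shell> sh = make_shells(sl, satom, sexp, scoef, coords);
  return List::create(_["S"] = contract1e(sh, overlap_prim),
                      _["T"] = contract1e(sh, kinetic_prim));
}

// potential-energy matrix of point charges: V_mn = sum_c (-q_c) <m|1/|r-C_c||n>
// [[Rcpp::export]]
NumericMatrix cpp_attraction(IntegerVector sl, IntegerVector satom, List sexp, List scoef,
                             NumericMatrix coords, NumericMatrix cpos, NumericVector cq) {
  std::vector<Shell> sh = make_shells(sl, satom, sexp, scoef, coords);
  int n = nbf_total(sh), nc = cq.size();
  NumericMatrix M(n, n);
  int la[3], lb[3];
  double C[3];
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j <= i; ++j) {
      const Shell &A = sh[i], &B = sh[j];
      for (int ka = 0; ka < A.nfun(); ++ka) {
        comp_l(A.l, ka, la);
        for (int kb = 0; kb < B.nfun(); ++kb) {
          comp_l(B.l, kb, lb);
          double val = 0.0;
          for (size_t pa = 0; pa < A.exps.size(); ++pa)
            for (size_t pb = 0; pb < B.exps.size(); ++pb) {
              double cc = A.coefs[pa] * B.coefs[pb];
              for (int c = 0; c < nc; ++c) {
                C[0] = cpos(c, 0); C[1] = cpos(c, 1); C[2] = cpos(c, 2);
                val -= cc * cq[c]
                     * attraction_prim(la, lb, A.exps[pa], B.exps[pb], A.center, B.center, C);
              }
            }
          M(A.first + ka, B.first + kb) = val;
          M(B.first + kb, A.first + ka) = val;
        }
      }
    }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_eri(IntegerVector sl, IntegerVector satom, List sexp, List scoef,
                      NumericMatrix coords) {
  std::vector<Shell> sh = make_shells(sl, satom, sexp, scoef, coords);
  int n = nbf_total(sh);
  size_t N = n;
  NumericVector out(N * N * N * N);  // caller reshapes to n^4 array
  double* G = out.begin();
  int la[3], lb[3], lc[3], ld[3];
  int ns = sh.size();
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j <= i; ++j)
      for (int k = 0; k <= i; ++k)
        for (int l = 0; l <= (k == i ? j : k); ++l) {
          const Shell &A = sh[i], &B = sh[j], &C = sh[k], &D = sh[l];
          for (int ka = 0; ka < A.nfun(); ++ka) {
            comp_l(A.l, ka, la);
            int p = A.first + ka;
            for (int kb = 0; kb < B.nfun(); ++kb) {
              comp_l(B.l, kb, lb);
              int q = B.first + kb;
              for (int kc = 0; kc < C.nfun(); ++kc) {
                comp_l(C.l, kc, lc);
                int r = C.first + kc;
                for (int kd = 0; kd < D.nfun(); ++kd) {
                  comp_l(D.l, kd, ld);
                  int s = D.first + kd;
                  double val = 0.0;
                  for (size_t pa = 0; pa < A.exps.size(); ++pa)
                    for (size_t pb = 0; pb < B.exps.size(); ++pb)
                      for (size_t pc = 0; pc < C.exps.size(); ++pc)
                        for (size_t pd = 0; pd < D.exps.size(); ++pd)
                          val += A.coefs[pa] * B.coefs[pb] * C.coefs[pc] * D.coefs[pd]
                               * eri_prim(la, lb, lc, ld,
                                          A.exps[pa], B.exps[pb], C.exps[pc], D.exps[pd],
                                          A.center, B.center, C.center, D.center);
                  // 8-fold permutational symmetry of real orbitals
                  G[p + N * (q + N * (r + N * (size_t)s))] = val;
                  G[q + N * (p + N * (r + N * (size_t)s))] = val;
                  G[p + N * (q + N * (s + N * (size_t)r))] = val;
                  G[q + N * (p + N * (s + N * (size_t)r))] = val;
                  G[r + N * (s + N * (p + N * (size_t)q))] = val;
                  G[s + N * (r + N * (p + N * (size_t)q))] = val;
                  G[r + N * (s + N * (q + N * (size_t)p))] = val;
                  G[s + N * (r + N * (q + N * (size_t)p))] = val;
                }
              }
            }
          }
        }
  return out;
}

// electron-charge electrostatic potential at arbitrary points:
// phi_e(s) = -sum_{mn} D_mn (m|1/|r-s||n)   (electrons carry charge -1)
// [[Rcpp::export]]
NumericVector cpp_esp_density(IntegerVector sl, IntegerVector satom, List sexp, List scoef,
                              NumericMatrix coords, NumericMatrix points,
                              NumericMatrix D) {
  std::vector<Shell> sh = make_shells(sl, satom, sexp, scoef, coords);
  int np = points.nrow(), ns = sh.size();
  NumericVector phi(np);
  int la[3], lb[3];
  double C[3];
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j <= i; ++j) {
      const Shell &A = sh[i], &B = sh[j];
      for (int ka = 0; ka < A.nfun(); ++ka) {
        comp_l(A.l, ka, la);
        int p = A.first + ka;
        for (int kb = 0; kb < B.nfun(); ++kb) {
          comp_l(B.l, kb, lb);
          int q = B.first + kb;
          // i == j covers every ordered pair once; i > j covers (p,q) only,
          // so fold in the transposed element
          double w = (i == j) ? D(p, q) : D(p, q) + D(q, p);
          if (std::abs(w) < 1e-14) continue;
          for (int c = 0; c < np; ++c) {
            C[0] = points(c, 0); C[1] = points(c, 1); C[2] = points(c, 2);
            double val = 0.0;
            for (size_t pa = 0; pa < A.exps.size(); ++pa)
              for (size_t pb = 0; pb < B.exps.size(); ++pb)
                val += A.coefs[pa] * B.coefs[pb]
                     * attraction_prim(la, lb, A.exps[pa], B.exps[pb],
                                       A.center, B.center, C);
            phi[c] -= w * val;
          }
        }
      }
    }
  return phi;
}

// ---------------------------------------------------------------------------
// center derivatives via the L-shift relation:
// d/dAx <G_A(l)| . > = 2a <G_A(l+1_x)| . > - l_x <G_A(l-1_x)| . >
// valid for any primitive kernel whose A-dependence sits in the Gaussian.

static double d_prim1e(prim1e_fn fn, int wrtA, int dim,
                       const int* la, const int* lb, double a, double b,
                       const double* A, const double* B) {
  int ls[3];
  const int* l0 = wrtA ? la : lb;
  double e = wrtA ? a : b;
  for (int d = 0; d < 3; ++d) ls[d] = l0[d];
  ls[dim] = l0[dim] + 1;
  double val = 2.0 * e * (wrtA ? fn(ls, lb, a, b, A, B) : fn(la, ls, a, b, A, B));
  if (l0[dim] > 0) {
    ls[dim] = l0[dim] - 1;
    val -= l0[dim] * (wrtA ? fn(ls, lb, a, b, A, B) : fn(la, ls, a, b, A, B));
  }
  return val;
}

// derivative of attraction_prim wrt bra/ket center (wrt = 0/1) or charge center (wrt = 2)
static double d_attraction(int wrt, int dim, const int* la, const int* lb,
                           double a, double b, const double* A, const double* B,
                           const double* C) {
  int ls[3];
  if (wrt == 2) {
    // translational invariance: d/dC = -(d/dA + d/dB)
    return -(d_attraction(0, dim, la, lb, a, b, A, B, C)
           + d_attraction(1, dim, la, lb, a, b, A, B, C));
  }
  const int* l0 = wrt == 0 ? la : lb;
  double e = wrt == 0 ? a : b;
  for (int d = 0; d < 3; ++d) ls[d] = l0[d];
  ls[dim] = l0[dim] + 1;
  double val = 2.0 * e * (wrt == 0 ? attraction_prim(ls, lb, a, b, A, B, C)
                                   : attraction_prim(la, ls, a, b, A, B, C));
  if (l0[dim] > 0) {
    ls[dim] = l0[dim] - 1;
    val -= l0[dim] * (wrt == 0 ? attraction_prim(ls, lb, a, b, A, B, C)
                               : attraction_prim(la, ls, a, b, A, B, C));
  }
  return val;
}

// dS, dT, dVbasis (basis-function derivative part of the charge potential) per
// nuclear coordinate, plus dVop: operator (Hellmann-Feynman) part per charge.
// charges = all external point sources (nuclei and/or MM sites).
// [[Rcpp::export]]
List cpp_int1e_deriv(IntegerVector sl, IntegerVector satom, List sexp, List scoef,
                     NumericMatrix coords, NumericMatrix cpos, NumericVector cq) {
  std::vector<Shell> sh = make_shells(sl, satom, sexp, scoef, coords);
  int n = nbf_total(sh), natom = coords.nrow(), nc = cq.size();
  NumericVector dS(Dimension(n, n, 3 * natom));
  NumericVector dT(Dimension(n, n, 3 * natom));
  NumericVector dVb(Dimension(n, n, 3 * natom));
  NumericVector dVop(Dimension(n, n, 3 * nc));
  size_t nn = (size_t)n * n;
  int la[3], lb[3];
  double C[3];
  int ns = sh.size();
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) {
      const Shell &A = sh[i], &B = sh[j];
      for (int ka = 0; ka < A.nfun(); ++ka) {
        comp_l(A.l, ka, la);
        int p = A.first + ka;
        for (int kb = 0; kb < B.nfun(); ++kb) {
          comp_l(B.l, kb, lb);
          int q = B.first + kb;
          for (int dim = 0; dim < 3; ++dim) {
            double vs = 0.0, vt = 0.0, vv = 0.0;
            for (size_t pa = 0; pa < A.exps.size(); ++pa)
              for (size_t pb = 0; pb < B.exps.size(); ++pb) {
                double cc = A.coefs[pa] * B.coefs[pb];
                vs += cc * d_prim1e(overlap_prim, 0, dim, la, lb,
                                    A.exps[pa], B.exps[pb], A.center, B.center);
                vt += cc * d_prim1e(kinetic_prim, 0, dim, la, lb,
                                    A.exps[pa], B.exps[pb], A.center, B.center);
                for (int c = 0; c < nc; ++c) {
                  C[0] = cpos(c, 0); C[1] = cpos(c, 1); C[2] = cpos(c, 2);
                  vv -= cc * cq[c] * d_attraction(1, dim, la, lb,
                                                  A.exps[pa], B.exps[pb],
                                                  A.center, B.center, C);
                }
              }
            // ket-center derivative accumulated on the ket atom; the bra term
            // arrives when the loop visits the transposed pair (full i,j loop)
            size_t off = nn * (3 * B.atom + dim);
            dS[off + p + (size_t)n * q] += vs;
            dS[off + q + (size_t)n * p] += vs;
            dT[off + p + (size_t)n * q] += vt;
            dT[off + q + (size_t)n * p] += vt;
            dVb[off + p + (size_t)n * q] += vv;
            dVb[off + q + (size_t)n * p] += vv;
          }
        }
      }
    }
  // Hellmann-Feynman operator part, one slot per charge coordinate
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j <= i; ++j) {
      const Shell &A = sh[i], &B = sh[j];
      for (int ka = 0; ka < A.nfun(); ++ka) {
        comp_l(A.l, ka, la);
        int p = A.first + ka;
        for (int kb = 0; kb < B.nfun(); ++kb) {
          comp_l(B.l, kb, lb);
          int q = B.first + kb;
          for (int c = 0; c < nc; ++c) {
            C[0] = cpos(c, 0); C[1] = cpos(c, 1); C[2] = cpos(c, 2);
            for (int dim = 0; dim < 3; ++dim) {
              double vv = 0.0;
              for (size_t pa = 0; pa < A.exps.size(); ++pa)
                for (size_t pb = 0; pb < B.exps.size(); ++pb)
                  vv -= A.coefs[pa] * B.coefs[pb] * cq[c]
                      * d_attraction(2, dim, la, lb, A.exps[pa], B.exps[pb],
                                     A.center, B.center, C);
              size_t off = nn * (3 * c + dim);
              dVop[off + p + (size_t)n * q] = vv;
              dVop[off + q + (size_t)n * p] = vv;
            }
          }
        }
      }
    }
  return List::create(_["dS"] = dS, _["dT"] = dT, _["dVbasis"] = dVb, _["dVop"] = dVop);
}

// primitive ERI with the angular momentum of one slot shifted by +/-1 in dim
static double eri_prim_shift(int slot, int dim, int shift,
                             const int* l4[4], const double e4[4], const double* c4[4]) {
  int ls[3];
  const int* l0 = l4[slot];
  for (int d = 0; d < 3; ++d) ls[d] = l0[d];
  ls[dim] = l0[dim] + shift;
  if (ls[dim] < 0) return 0.0;
  const int* lv[4] = { l4[0], l4[1], l4[2], l4[3] };
  lv[slot] = ls;
  return eri_prim(lv[0], lv[1], lv[2], lv[3], e4[0], e4[1], e4[2], e4[3],
                  c4[0], c4[1], c4[2], c4[3]);
}

// full derivative of (pq|rs) wrt all nuclear coordinates: n^4 x (3*natom)
// [[Rcpp::export]]
NumericVector cpp_eri_deriv(IntegerVector sl, IntegerVector satom, List sexp, List scoef,
                            NumericMatrix coords) {
  std::vector<Shell> sh = make_shells(sl, satom, sexp, scoef, coords);
  int n = nbf_total(sh), natom = coords.nrow();
  size_t N = n, n4 = N * N * N * N;
  NumericVector out(Dimension(n * n * n * n, 3 * natom));
  double* G = out.begin();
  int la[3], lb[3], lc[3], ld[3];
  int ns = sh.size();
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j)
      for (int k = 0; k < ns; ++k)
        for (int l = 0; l < ns; ++l) {
          const Shell* S4[4] = { &sh[i], &sh[j], &sh[k], &sh[l] };
          for (int ka = 0; ka < S4[0]->nfun(); ++ka) {
            comp_l(S4[0]->l, ka, la);
            int p = S4[0]->first + ka;
            for (int kb = 0; kb < S4[1]->nfun(); ++kb) {
              comp_l(S4[1]->l, kb, lb);
              int q = S4[1]->first + kb;
              for (int kc = 0; kc < S4[2]->nfun(); ++kc) {
                comp_l(S4[2]->l, kc, lc);
                int r = S4[2]->first + kc;
                for (int kd = 0; kd < S4[3]->nfun(); ++kd) {
                  comp_l(S4[3]->l, kd, ld);
                  int s = S4[3]->first + kd;
                  size_t idx = p + N * (q + N * (r + N * (size_t)s));
                  const int* l4[4] = { la, lb, lc, ld };
                  for (int slot = 0; slot < 4; ++slot)
                    for (int dim = 0; dim < 3; ++dim) {
                      double val = 0.0;
                      for (size_t pa = 0; pa < S4[0]->exps.size(); ++pa)
                        for (size_t pb = 0; pb < S4[1]->exps.size(); ++pb)
                          for (size_t pc = 0; pc < S4[2]->exps.size(); ++pc)
                            for (size_t pd = 0; pd < S4[3]->exps.size(); ++pd) {
                              double cc = S4[0]->coefs[pa] * S4[1]->coefs[pb]
                                        * S4[2]->coefs[pc] * S4[3]->coefs[pd];
                              double e4[4] = { S4[0]->exps[pa], S4[1]->exps[pb],
                                               S4[2]->exps[pc], S4[3]->exps[pd] };
                              const double* c4[4] = { S4[0]->center, S4[1]->center,
                                                      S4[2]->center, S4[3]->center };
                              double dv = 2.0 * e4[slot]
                                        * eri_prim_shift(slot, dim, +1, l4, e4, c4);
                              int l0 = l4[slot][dim];
                              if (l0 > 0)
                                dv -= l0 * eri_prim_shift(slot, dim, -1, l4, e4, c4);
                              val += cc * dv;
                            }
                      G[idx + n4 * (3 * S4[slot]->atom + dim)] += val;
                    }
                }
              }
            }
          }
        }
  return out;
}
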