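// Total-Lagrangian 8-node hexahedra with uncoupled Mooney-Rivlin
// hyperelasticity, W = c1 (I1bar - 3) + c2 (I2bar - 3) + (K/2) (ln J)^2.
// The volumetric term is evaluated at the element-average Jacobian
// (mean dilatation), which keeps the Q1 element usable at the
// near-incompressible bulk-to-shear ratios of the cartilage materials.
// The element tangent is the central finite difference of the exact
// element residual, so it is consistent with the mean-dilatation coupling.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 3x3 helpers on row-major double[9], index 3*i+j
static inline double det3(const double* A) {
  return A[0] * (A[4] * A[8] - A[5] * A[7])
       - A[1] * (A[3] * A[8] - A[5] * A[6])
       + A[2] * (A[3] * A[7] - A[4] * A[6]);
}

static inline void inv3(const double* A, double d, double* Ai) {
  double id = 1.0 / d;
  Ai[0] =  (A[4] * A[8] - A[5] * A[7]) * id;
  Ai[1] = -(A[1] * A[8] - A[2] * A[7]) * id;
  Ai[2] =  (A[1] * A[5] - A[2] * A[4]) * id;
  Ai[3] = -(A[3] * A[8] - A[5] * A[6]) * id;
  Ai[4] =  (A[0] * A[8] - A[2] * A[6]) * id;
  Ai[5] = -(A[0] * A[5] - A[2] * A[3]) * id;
  Ai[6] =  (A[3] * A[7] - A[4] * A[6]) * id;
  Ai[7] = -(A[0] * A[7] - A[1] * A[6]) * id;
  Ai[8] =  (A[0] * A[4] - A[1] * A[3]) * id;
}

// Natural corner signs, standard (VTK) node ordering.
static const double SGN[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};

static void shape_grad_nat(const double* p, double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    double f1 = 1 + SGN[a][0] * p[0];
    double f2 = 1 + SGN[a][1] * p[1];
    double f3 = 1 + SGN[a][2] * p[2];
    dN[a][0] = SGN[a][0] * f2 * f3 / 8.0;
    dN[a][1] = f1 * SGN[a][1] * f3 / 8.0;
    dN[a][2] = f1 * f2 * SGN[a][2] / 8.0;
  }
}

// First Piola-Kirchhoff stress of the isochoric part, given F (row-major).
// Piso = c1 dI1bar/dF + c2 dI2bar/dF. Returns Wiso.
static double piso(const double* F, double J, const double* Finv,
                   double c1, double c2, double* P) {
  double I1 = 0.0;
  for (int k = 0; k < 9; ++k) I1 += F[k] * F[k];
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double I1b = Jm23 * I1;
  double FinvT[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) FinvT[3 * i + j] = Finv[3 * j + i];
  double W = c1 * (I1b - 3.0);
  for (int k = 0; k < 9; ++k)
    P[k] = c1 * (2.0 * Jm23 * F[k] - (2.0 / 3.0) * I1b * FinvT[k]);
  if (c2 != 0.0) {
    // C = F^T F, FC = F C, trC2 = sum C_ij^2
    double C[9], FC[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0.0;
        for (int k = 0; k < 3; ++k) s += F[3 * k + i] * F[3 * k + j];
        C[3 * i + j] = s;
      }
    double trC2 = 0.0;
    for (int k = 0; k < 9; ++k) trC2 += C[k] * C[k];
    double I2 = 0.5 * (I1 * I1 - trC2);
    double Jm43 = Jm23 * Jm23;
    double I2b = Jm43 * I2;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0.0;
        for (int k = 0; k < 3; ++k) s += F[3 * i + k] * C[3 * k + j];
        FC[3 * i + j] = s;
      }
    for (int k = 0; k < 9; ++k)
      P[k] += c2 * (Jm43 * (2.0 * I1 * F[k] - 2.0 * FC[k])
                    - (4.0 / 3.0) * I2b * FinvT[k]);
    W += c2 * (I2b - 3.0);
  }
  return W;
}

// Residual (internal force) of one element. u: 24 local displacements
// (node-major, xyz per node); G: reference shape gradients at the 8 Gauss
// points (gp-major: [gp][node][3]); wd: Gauss weight * detJ0 per gp;
// Ve: reference element volume. Returns false if any Gauss-point J <= 0.
static bool elem_residual(const double* u, const double* G, const double* wd,
                          double Ve, double c1, double c2, double K,
                          double* f, double* energy, double* minJ,
                          double* Jbar_out) {
  double Fgp[8][9], Jgp[8], Pgp[8][9], Fin[8][9];
  double Jbar_num = 0.0, Wiso_sum = 0.0, mJ = 1e300;
  for (int g = 0; g < 8; ++g) {
    const double* Gg = G + (g * 8 * 3);
    double* F = Fgp[g];
    F[0] = F[4] = F[8] = 1.0;
    F[1] = F[2] = F[3] = F[5] = F[6] = F[7] = 0.0;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        double ui = u[3 * a + i];
        F[3 * i + 0] += ui * Gg[3 * a + 0];
        F[3 * i + 1] += ui * Gg[3 * a + 1];
        F[3 * i + 2] += ui * Gg[3 * a + 2];
      }
    double J = det3(F);
    Jgp[g] = J;
    if (J < mJ) mJ = J;
    if (!(J > 0.0)) { *minJ = mJ; return false; }
    inv3(F, J, Fin[g]);
    Wiso_sum += wd[g] * piso(F, J, Fin[g], c1, c2, Pgp[g]);
    Jbar_num += wd[g] * J;
  }
  double Jbar = Jbar_num / Ve;
  if (!(Jbar > 0.0)) { *minJ = mJ; return false; }
  double pbar = K * std::log(Jbar) / Jbar;
  for (int k = 0; k < 24; ++k) f[k] = 0.0;
  for (int g = 0; g < 8; ++g) {
    const double* Gg = G + (g * 8 * 3);
    double PK[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        PK[3 * i + j] = Pgp[g][3 * i + j]
                      + pbar * Jgp[g] * Fin[g][3 * j + i];  // Finv^T
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        f[3 * a + i] += wd[g] * (PK[3 * i + 0] * Gg[3 * a + 0]
                               + PK[3 * i + 1] * Gg[3 * a + 1]
                               + PK[3 * i + 2] * Gg[3 * a + 2]);
  }
  double lj = std::log(Jbar);
  *energy = Wiso_sum + Ve * 0.5 * K * lj * lj;
  *minJ = mJ;
  *Jbar_out = Jbar;
  return true;
}

// [[Rcpp::export]]
List fe_setup_cpp(NumericMatrix nodes, IntegerMatrix elems) {
  int m = elems.nrow();
  NumericVector Gref(m * 8 * 8 * 3), wdet(m * 8), Ve(m);
  NumericVector Gc(m * 8 * 3), detc(m);
  double gp[3], dN[8][3];
  double g = 1.0 / std::sqrt(3.0);
  for (int e = 0; e < m; ++e) {
    double X[8][3];
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) X[a][i] = nodes(n, i);
    }
    double vol = 0.0;
    for (int q = 0; q < 8; ++q) {
      for (int i = 0; i < 3; ++i) gp[i] = SGN[q][i] * g;
      shape_grad_nat(gp, dN);
      double J0[9];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0.0;
          for (int a = 0; a < 8; ++a) s += X[a][i] * dN[a][j];
          J0[3 * i + j] = s;
        }
      double d = det3(J0);
      if (!(d > 0.0))
        stop("inverted reference element %d (detJ = %g at Gauss point %d)",
             e + 1, d, q + 1);
      double J0i[9];
      inv3(J0, d, J0i);
      // dN/dX = dN/dxi * J0^{-1}
      for (int a = 0; a < 8; ++a)
        for (int j = 0; j < 3; ++j)
          Gref[((e * 8 + q) * 8 + a) * 3 + j] =
            dN[a][0] * J0i[3 * 0 + j] + dN[a][1] * J0i[3 * 1 + j]
            + dN[a][2] * J0i[3 * 2 + j];
      wdet[e * 8 + q] = d;
      vol += d;
    }
    Ve[e] = vol;
    // centroid
    gp[0] = gp[1] = gp[2] = 0.0;
    shape_grad_nat(gp, dN);
    double J0[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0.0;
        for (int a = 0; a < 8; ++a) s += X[a][i] * dN[a][j];
        J0[3 * i + j] = s;
      }
    double d = det3(J0);
    if (!(d > 0.0)) stop("inverted reference element %d at centroid", e + 1);
    detc[e] = d;
    double J0i[9];
    inv3(J0, d, J0i);
    for (int a = 0; a < 8; ++a)
      for (int j = 0; j < 3; ++j)
        Gc[(e * 8 + a) * 3 + j] =
          dN[a][0] * J0i[3 * 0 + j] + dN[a][1] * J0i[3 * 1 + j]
          + dN[a][2] * J0i[3 * 2 + j];
  }
  return List::create(_["Gref"] = Gref, _["wdet"] = wdet, _["Ve"] = Ve,
                      _["Gc"] = Gc, _["detc"] = detc);
}

static void gather_u(const NumericMatrix& U, const IntegerMatrix& elems,
                     int e, double* u) {
  for (int a = 0; a < 8; ++a) {
    int n = elems(e, a) - 1;
    for (int i = 0; i < 3; ++i) u[3 * a + i] = U(n, i);
  }
}

// [[Rcpp::export]]
List fe_residual_cpp(NumericMatrix U, IntegerMatrix elems, NumericVector Gref,
                     NumericVector wdet, NumericVector Ve, NumericMatrix mat) {
  int m = elems.nrow(), n = U.nrow();
  NumericMatrix R(n, 3);
  NumericVector Jbar(m);
  double energy = 0.0, minJ = 1e300;
  double u[24], f[24];
  bool ok = true;
  for (int e = 0; e < m; ++e) {
    gather_u(U, elems, e, u);
    double Ee, mJ, Jb;
    bool good = elem_residual(u, &Gref[e * 8 * 8 * 3], &wdet[e * 8], Ve[e],
                              mat(e, 0), mat(e, 1), mat(e, 2),
                              f, &Ee, &mJ, &Jb);
    if (mJ < minJ) minJ = mJ;
    if (!good) { ok = false; continue; }
    energy += Ee;
    Jbar[e] = Jb;
    for (int a = 0; a < 8; ++a) {
      int nd = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) R(nd, i) += f[3 * a + i];
    }
  }
  return List::create(_["R"] = R, _["energy"] = energy, _["minJ"] = minJ,
                      _["Jbar"] = Jbar, _["ok"] = ok);
}

// [[Rcpp::export]]
List fe_tangent_cpp(NumericMatrix U, IntegerMatrix elems, NumericVector Gref,
                    NumericVector wdet, NumericVector Ve, NumericMatrix mat,
                    IntegerVector freemap) {
  int m = elems.nrow();
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t)m * 300); tj.reserve((size_t)m * 300);
  tx.reserve((size_t)m * 300);
  double u[24], up[24], fp[24], fm[24], Ke[24][24];
  double Ee, mJ, Jb;
  for (int e = 0; e < m; ++e) {
    gather_u(U, elems, e, u);
    const double* G = &Gref[e * 8 * 8 * 3];
    const double* wd = &wdet[e * 8];
    double c1 = mat(e, 0), c2 = mat(e, 1), K = mat(e, 2);
    double h = 1e-6 * std::cbrt(Ve[e]);
    for (int l = 0; l < 24; ++l) {
      for (int k = 0; k < 24; ++k) up[k] = u[k];
      up[l] = u[l] + h;
      bool ok1 = elem_residual(up, G, wd, Ve[e], c1, c2, K, fp, &Ee, &mJ, &Jb);
      up[l] = u[l] - h;
      bool ok2 = elem_residual(up, G, wd, Ve[e], c1, c2, K, fm, &Ee, &mJ, &Jb);
      if (!ok1 || !ok2)
        stop("element %d inverted while forming the tangent", e + 1);
      double ih = 0.5 / h;
      for (int k = 0; k < 24; ++k) Ke[k][l] = (fp[k] - fm[k]) * ih;
    }
    // global free-dof indices of the 24 local dofs (-1 if constrained)
    int gdof[24];
    for (int a = 0; a < 8; ++a) {
      int nd = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) gdof[3 * a + i] = freemap[3 * nd + i];
    }
    for (int r = 0; r < 24; ++r) {
      if (gdof[r] < 0) continue;
      for (int c = 0; c < 24; ++c) {
        if (gdof[c] < 0) continue;
        double v = 0.5 * (Ke[r][c] + Ke[c][r]);  // symmetrize FD noise away
        ti.push_back(gdof[r]);
        tj.push_back(gdof[c]);
        tx.push_back(v);
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}

// Centroid deformation gradient, mean-dilatation Cauchy stress, and
// centroid-rule deformed volumes for every element.
// [[Rcpp::export]]
List fe_recover_cpp(NumericMatrix U, IntegerMatrix elems, NumericVector Gref,
                    NumericVector wdet, NumericVector Ve, NumericVector Gc,
                    NumericVector detc, NumericMatrix mat) {
  int m = elems.nrow();
  NumericMatrix Fout(m, 9), Sout(m, 9);
  NumericVector Jbar(m), vol_def(m), vol_ref(m);
  double u[24];
  for (int e = 0; e < m; ++e) {
    gather_u(U, elems, e, u);
    // element-average J over the Gauss points
    double Jnum = 0.0;
    {
      const double* G = &Gref[e * 8 * 8 * 3];
      for (int g = 0; g < 8; ++g) {
        double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
        const double* Gg = G + g * 8 * 3;
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i) {
            double ui = u[3 * a + i];
            F[3 * i + 0] += ui * Gg[3 * a + 0];
            F[3 * i + 1] += ui * Gg[3 * a + 1];
            F[3 * i + 2] += ui * Gg[3 * a + 2];
          }
        Jnum += wdet[e * 8 + g] * det3(F);
      }
    }
    double Jb = Jnum / Ve[e];
    Jbar[e] = Jb;
    // centroid F
    double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    const double* Gce = &Gc[e * 8 * 3];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        double ui = u[3 * a + i];
        F[3 * i + 0] += ui * Gce[3 * a + 0];
        F[3 * i + 1] += ui * Gce[3 * a + 1];
        F[3 * i + 2] += ui * Gce[3 * a + 2];
      }
    double Jc = det3(F);
    for (int k = 0; k < 9; ++k) Fout(e, k) = F[k];
    vol_ref[e] = 8.0 * detc[e];
    vol_def[e] = 8.0 * detc[e] * Jc;
    if (Jc > 0.0 && Jb > 0.0) {
      // sigma from Fbar = (Jbar/Jc)^(1/3) F (so det Fbar = Jbar)
      double s = std::cbrt(Jb / Jc);
      double Fb[9], Fbi[9], P[9];
      for (int k = 0; k < 9; ++k) Fb[k] = s * F[k];
      inv3(Fb, Jb, Fbi);
      piso(Fb, Jb, Fbi, mat(e, 0), mat(e, 1), P);
      double pbar = mat(e, 2) * std::log(Jb) / Jb;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double sij = 0.0;
          for (int k = 0; k < 3; ++k)
            sij += P[3 * i + k] * Fb[3 * j + k];  // P Fb^T
          sij /= Jb;
          if (i == j) sij += pbar;
          Sout(e, 3 * i + j) = sij;
        }
    } else {
      for (int k = 0; k < 9; ++k) Sout(e, k) = NA_REAL;
    }
  }
  return List::create(_["F"] = Fout, _["sigma"] = Sout, _["Jbar"] = Jbar,
                      _["vol_ref"] = vol_ref, _["vol_def"] = vol_def);
}
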