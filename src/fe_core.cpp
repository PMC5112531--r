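// Explicit quasi-static core for the growing-bilayer model.
//
// Total-Lagrangian Q1 elements (quads in 2D, hex8 in 3D), 2^d Gauss points,
// F-bar treatment of the volumetric part to avoid locking at high bulk
// penalty.  Growth enters through the multiplicative split F = A * G with
// G = g * I per element; stress derives from a compressible neo-Hookean
// energy per unit grown volume
//   W(A) = mu/2 * (I1(A) - d - 2 log J_A) + K/2 * (J_A - 1)^2
// so that A = I is stress free and det(A) is driven to 1 by the penalty K.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double GP = 0.57735026918962576451; // 1/sqrt(3)

// ---------------------------------------------------------------- 2D ----

// shape-function derivatives on the bi-unit square, node order CCW:
// (-1,-1),(1,-1),(1,1),(-1,1)
static void shape2d(double xi, double eta, double dN[4][2]) {
  const double xs[4] = {-1, 1, 1, -1}, es[4] = {-1, -1, 1, 1};
  for (int a = 0; a < 4; ++a) {
    dN[a][0] = 0.25 * xs[a] * (1.0 + es[a] * eta);
    dN[a][1] = 0.25 * es[a] * (1.0 + xs[a] * xi);
  }
}

// Precompute reference-configuration quadrature data.
// Returns dNdX (ne x 32: gp*8 + a*2 + i), w (ne x 4), lmin, vol per element.
// [[Rcpp::export]]
List feQuadData2D(NumericMatrix X, IntegerMatrix elems) {
  int ne = elems.nrow();
  NumericMatrix dNdX(32, ne), w(4, ne);
  NumericVector lmin(ne), vol(ne);
  double gx[4] = {-GP, GP, GP, -GP}, ge[4] = {-GP, -GP, GP, GP};
  for (int e = 0; e < ne; ++e) {
    double xe[4][2];
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a);
      xe[a][0] = X(n, 0); xe[a][1] = X(n, 1);
    }
    double lm = R_PosInf;
    for (int a = 0; a < 4; ++a) {
      int b = (a + 1) % 4;
      double dx = xe[b][0] - xe[a][0], dy = xe[b][1] - xe[a][1];
      double l = std::sqrt(dx * dx + dy * dy);
      if (l < lm) lm = l;
    }
    lmin[e] = lm;
    double ve = 0.0;
    for (int gp = 0; gp < 4; ++gp) {
      double dN[4][2];
      shape2d(gx[gp], ge[gp], dN);
      double J[2][2] = {{0, 0}, {0, 0}}; // dX/dxi
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 2; ++i)
          for (int j = 0; j < 2; ++j)
            J[i][j] += xe[a][i] * dN[a][j];
      double detJ = J[0][0] * J[1][1] - J[0][1] * J[1][0];
      if (detJ <= 0) stop("non-positive reference Jacobian in element %d", e + 1);
      double Ji[2][2] = {{J[1][1] / detJ, -J[0][1] / detJ},
                         {-J[1][0] / detJ, J[0][0] / detJ}};
      for (int a = 0; a < 4; ++a) {
        double d0 = dN[a][0] * Ji[0][0] + dN[a][1] * Ji[1][0];
        double d1 = dN[a][0] * Ji[0][1] + dN[a][1] * Ji[1][1];
        dNdX(gp * 8 + a * 2 + 0, e) = d0;
        dNdX(gp * 8 + a * 2 + 1, e) = d1;
      }
      w(gp, e) = detJ;
      ve += detJ;
    }
    vol[e] = ve;
  }
  return List::create(_["dNdX"] = dNdX, _["w"] = w, _["lmin"] = lmin,
                      _["vol"] = vol);
}

// internal force + energy pass; returns strain energy, fills f, tracks
// max |det A - 1|; returns -1 on element inversion (badElem set).
static double force2d(const NumericMatrix& dNdX, const NumericMatrix& w,
                      const IntegerMatrix& elems, const std::vector<double>& x,
                      const NumericVector& g, const NumericVector& mu,
                      double K, std::vector<double>& f, double& maxJdev,
                      int& badElem) {
  int ne = elems.nrow();
  double E = 0.0;
  maxJdev = 0.0; badElem = -1;
  std::fill(f.begin(), f.end(), 0.0);
  const double* D = &dNdX(0, 0);
  const double* W = &w(0, 0);
  const int* E0 = &elems(0, 0);
  for (int e = 0; e < ne; ++e) {
    int nd[4];
    double xe[4][2];
    for (int a = 0; a < 4; ++a) {
      nd[a] = E0[a * ne + e];
      xe[a][0] = x[2 * nd[a]]; xe[a][1] = x[2 * nd[a] + 1];
    }
    const double* De = D + 32 * e;
    const double* We = W + 4 * e;
    double Fg[4][4], Jg[4], wsum = 0.0, Jbar = 0.0;
    for (int gp = 0; gp < 4; ++gp) {
      double F00 = 0, F01 = 0, F10 = 0, F11 = 0;
      for (int a = 0; a < 4; ++a) {
        double d0 = De[gp * 8 + a * 2], d1 = De[gp * 8 + a * 2 + 1];
        F00 += xe[a][0] * d0; F01 += xe[a][0] * d1;
        F10 += xe[a][1] * d0; F11 += xe[a][1] * d1;
      }
      Fg[gp][0] = F00; Fg[gp][1] = F01; Fg[gp][2] = F10; Fg[gp][3] = F11;
      Jg[gp] = F00 * F11 - F01 * F10;
      Jbar += We[gp] * Jg[gp]; wsum += We[gp];
    }
    Jbar /= wsum;
    double ge = g[e], mue = mu[e];
    if (Jbar <= 0) { badElem = e; return -1.0; }
    for (int gp = 0; gp < 4; ++gp) {
      if (Jg[gp] <= 0) { badElem = e; return -1.0; }
      double s = std::sqrt(Jbar / Jg[gp]);
      // elastic tensor A = Fbar / g
      double A00 = s * Fg[gp][0] / ge, A01 = s * Fg[gp][1] / ge;
      double A10 = s * Fg[gp][2] / ge, A11 = s * Fg[gp][3] / ge;
      double Ja = A00 * A11 - A01 * A10;
      if (Ja <= 1e-8) { badElem = e; return -1.0; }
      double dev = std::fabs(Ja - 1.0);
      if (dev > maxJdev) maxJdev = dev;
      // A^{-T}
      double i00 = A11 / Ja, i01 = -A10 / Ja, i10 = -A01 / Ja, i11 = A00 / Ja;
      double kv = K * Ja * (Ja - 1.0);
      // P_A = mu (A - A^{-T}) + K Ja (Ja-1) A^{-T}
      double P00 = mue * (A00 - i00) + kv * i00;
      double P01 = mue * (A01 - i01) + kv * i01;
      double P10 = mue * (A10 - i10) + kv * i10;
      double P11 = mue * (A11 - i11) + kv * i11;
      // reference PK1 = det(G)/g * P_A = g * P_A (2D), times quadrature wt
      double c = ge * We[gp];
      for (int a = 0; a < 4; ++a) {
        double d0 = De[gp * 8 + a * 2], d1 = De[gp * 8 + a * 2 + 1];
        f[2 * nd[a]]     -= c * (P00 * d0 + P01 * d1);
        f[2 * nd[a] + 1] -= c * (P10 * d0 + P11 * d1);
      }
      double I1 = A00 * A00 + A01 * A01 + A10 * A10 + A11 * A11;
      double Wd = 0.5 * mue * (I1 - 2.0 - 2.0 * std::log(Ja)) +
                  0.5 * K * (Ja - 1.0) * (Ja - 1.0);
      E += ge * ge * Wd * We[gp];
    }
  }
  return E;
}

// [[Rcpp::export]]
List feForces2D(NumericMatrix X, IntegerMatrix elems, List quad,
                NumericVector x, NumericVector g, NumericVector mu, double K) {
  NumericMatrix dNdX = quad["dNdX"], w = quad["w"];
  int nn = X.nrow();
  std::vector<double> xs(x.begin(), x.end()), f(2 * nn);
  double maxJdev; int badElem;
  double E = force2d(dNdX, w, elems, xs, g, mu, K, f, maxJdev, badElem);
  if (badElem >= 0) stop("element inversion in element %d", badElem + 1);
  return List::create(_["force"] = NumericVector(f.begin(), f.end()),
                      _["energy"] = E, _["maxJdev"] = maxJdev);
}

// Damped central-difference integration of nsteps with constant growth.
// con: m x (1 + dim) matrix, each row a node id (0-based) and a unit
// direction along which velocity is constrained to zero.
// [[Rcpp::export]]
List feRun2D(NumericMatrix X, IntegerMatrix elems, List quad,
             NumericVector x0, NumericVector v0, NumericVector g,
             NumericVector mu, double K, NumericVector mass,
             NumericMatrix con, double damp, double dt, int nsteps) {
  NumericMatrix dNdX = quad["dNdX"], w = quad["w"];
  int nn = X.nrow(), ncon = con.nrow();
  std::vector<double> x(x0.begin(), x0.end()), v(v0.begin(), v0.end()),
      f(2 * nn);
  double maxJdev = 0.0, E = 0.0, runMaxJdev = 0.0;
  int badElem = -1, failStep = -1;
  double a1 = 1.0 - 0.5 * damp, a2 = 1.0 / (1.0 + 0.5 * damp);
  for (int s = 0; s < nsteps; ++s) {
    E = force2d(dNdX, w, elems, x, g, mu, K, f, maxJdev, badElem);
    if (badElem >= 0) { failStep = s; break; }
    if (maxJdev > runMaxJdev) runMaxJdev = maxJdev;
    for (int n = 0; n < nn; ++n) {
      double im = dt / mass[n];
      v[2 * n]     = a2 * (a1 * v[2 * n]     + im * f[2 * n]);
      v[2 * n + 1] = a2 * (a1 * v[2 * n + 1] + im * f[2 * n + 1]);
    }
    for (int c = 0; c < ncon; ++c) {
      int n = (int)con(c, 0);
      double cx = con(c, 1), cy = con(c, 2);
      double p = v[2 * n] * cx + v[2 * n + 1] * cy;
      v[2 * n] -= p * cx; v[2 * n + 1] -= p * cy;
    }
    for (int i = 0; i < 2 * nn; ++i) x[i] += dt * v[i];
  }
  double ke = 0.0;
  for (int n = 0; n < nn; ++n)
    ke += 0.5 * mass[n] * (v[2 * n] * v[2 * n] + v[2 * n + 1] * v[2 * n + 1]);
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["ke"] = ke, _["se"] = E, _["maxJdev"] = maxJdev,
                      _["maxJdevRun"] = runMaxJdev,
                      _["ok"] = (failStep < 0), _["badElem"] = badElem + 1,
                      _["failStep"] = failStep + 1);
}

// Per-quadrature-point kinematic/stress state (F-bar consistent with the
// integrator).  Columns: elem, gp, F(4), g, A(4), detA, sxx, syy, sxy, p,
// W, lam1, lam2.
// [[Rcpp::export]]
NumericMatrix feState2D(NumericMatrix X, IntegerMatrix elems, List quad,
                        NumericVector x, NumericVector g, NumericVector mu,
                        double K) {
  NumericMatrix dNdX = quad["dNdX"], w = quad["w"];
  int ne = elems.nrow();
  NumericMatrix out(ne * 4, 19);
  for (int e = 0; e < ne; ++e) {
    double xe[4][2];
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a);
      xe[a][0] = x[2 * n]; xe[a][1] = x[2 * n + 1];
    }
    double Fg[4][4], Jg[4], wsum = 0, Jbar = 0;
    for (int gp = 0; gp < 4; ++gp) {
      double F00 = 0, F01 = 0, F10 = 0, F11 = 0;
      for (int a = 0; a < 4; ++a) {
        double d0 = dNdX(gp * 8 + a * 2, e), d1 = dNdX(gp * 8 + a * 2 + 1, e);
        F00 += xe[a][0] * d0; F01 += xe[a][0] * d1;
        F10 += xe[a][1] * d0; F11 += xe[a][1] * d1;
      }
      Fg[gp][0] = F00; Fg[gp][1] = F01; Fg[gp][2] = F10; Fg[gp][3] = F11;
      Jg[gp] = F00 * F11 - F01 * F10;
      Jbar += w(gp, e) * Jg[gp]; wsum += w(gp, e);
    }
    Jbar /= wsum;
    for (int gp = 0; gp < 4; ++gp) {
      double s = std::sqrt(Jbar / Jg[gp]);
      double ge = g[e], mue = mu[e];
      double A00 = s * Fg[gp][0] / ge, A01 = s * Fg[gp][1] / ge;
      double A10 = s * Fg[gp][2] / ge, A11 = s * Fg[gp][3] / ge;
      double Ja = A00 * A11 - A01 * A10;
      // Cauchy stress = (1/Ja) [mu (B - I)] + K (Ja - 1) I,  B = A A^T
      double B00 = A00 * A00 + A01 * A01, B11 = A10 * A10 + A11 * A11;
      double B01 = A00 * A10 + A01 * A11;
      double p = K * (Ja - 1.0);
      double sxx = mue * (B00 - 1.0) / Ja + p;
      double syy = mue * (B11 - 1.0) / Ja + p;
      double sxy = mue * B01 / Ja;
      double I1 = B00 + B11;
      double W = 0.5 * mue * (I1 - 2.0 - 2.0 * std::log(Ja)) +
                 0.5 * K * (Ja - 1.0) * (Ja - 1.0);
      // principal elastic stretches from eigenvalues of B
      double tr = B00 + B11, det = B00 * B11 - B01 * B01;
      double disc = std::sqrt(std::max(0.25 * tr * tr - det, 0.0));
      double l1 = std::sqrt(std::max(0.5 * tr + disc, 0.0));
      double l2 = std::sqrt(std::max(0.5 * tr - disc, 0.0));
      int r = e * 4 + gp;
      out(r, 0) = e + 1; out(r, 1) = gp + 1;
      out(r, 2) = Fg[gp][0] * s; out(r, 3) = Fg[gp][1] * s;
      out(r, 4) = Fg[gp][2] * s; out(r, 5) = Fg[gp][3] * s;
      out(r, 6) = ge;
      out(r, 7) = A00; out(r, 8) = A01; out(r, 9) = A10; out(r, 10) = A11;
      out(r, 11) = Ja;
      out(r, 12) = sxx; out(r, 13) = syy; out(r, 14) = sxy;
      out(r, 15) = p; out(r, 16) = W; out(r, 17) = l1; out(r, 18) = l2;
    }
  }
  return out;
}

// ---------------------------------------------------------------- 3D ----

static void shape3d(double xi, double eta, double ze, double dN[8][3]) {
  const double xs[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double es[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double zs[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int a = 0; a < 8; ++a) {
    dN[a][0] = 0.125 * xs[a] * (1 + es[a] * eta) * (1 + zs[a] * ze);
    dN[a][1] = 0.125 * es[a] * (1 + xs[a] * xi) * (1 + zs[a] * ze);
    dN[a][2] = 0.125 * zs[a] * (1 + xs[a] * xi) * (1 + es[a] * eta);
  }
}

static double det3(const double M[3][3]) {
  return M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
         M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
         M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
}

static void inv3(const double M[3][3], double d, double I[3][3]) {
  I[0][0] = (M[1][1] * M[2][2] - M[1][2] * M[2][1]) / d;
  I[0][1] = (M[0][2] * M[2][1] - M[0][1] * M[2][2]) / d;
  I[0][2] = (M[0][1] * M[1][2] - M[0][2] * M[1][1]) / d;
  I[1][0] = (M[1][2] * M[2][0] - M[1][0] * M[2][2]) / d;
  I[1][1] = (M[0][0] * M[2][2] - M[0][2] * M[2][0]) / d;
  I[1][2] = (M[0][2] * M[1][0] - M[0][0] * M[1][2]) / d;
  I[2][0] = (M[1][0] * M[2][1] - M[1][1] * M[2][0]) / d;
  I[2][1] = (M[0][1] * M[2][0] - M[0][0] * M[2][1]) / d;
  I[2][2] = (M[0][0] * M[1][1] - M[0][1] * M[1][0]) / d;
}

// [[Rcpp::export]]
List feQuadData3D(NumericMatrix X, IntegerMatrix elems) {
  int ne = elems.nrow();
  NumericMatrix dNdX(8 * 24, ne), w(8, ne);
  NumericVector lmin(ne), vol(ne);
  for (int e = 0; e < ne; ++e) {
    double xe[8][3];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) xe[a][i] = X(elems(e, a), i);
    double lm = R_PosInf;
    const int edges[12][2] = {{0, 1}, {1, 2}, {2, 3}, {3, 0}, {4, 5}, {5, 6},
                              {6, 7}, {7, 4}, {0, 4}, {1, 5}, {2, 6}, {3, 7}};
    for (int k = 0; k < 12; ++k) {
      double l = 0;
      for (int i = 0; i < 3; ++i) {
        double d = xe[edges[k][1]][i] - xe[edges[k][0]][i];
        l += d * d;
      }
      l = std::sqrt(l);
      if (l < lm) lm = l;
    }
    lmin[e] = lm;
    double ve = 0.0;
    int gp = 0;
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx, ++gp) {
          double dN[8][3];
          shape3d(kx ? GP : -GP, ky ? GP : -GP, kz ? GP : -GP, dN);
          double J[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
          for (int a = 0; a < 8; ++a)
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j) J[i][j] += xe[a][i] * dN[a][j];
          double dJ = det3(J);
          if (dJ <= 0) stop("non-positive reference Jacobian in element %d", e + 1);
          double Ji[3][3];
          inv3(J, dJ, Ji);
          for (int a = 0; a < 8; ++a)
            for (int j = 0; j < 3; ++j) {
              double d = 0;
              for (int i = 0; i < 3; ++i) d += dN[a][i] * Ji[i][j];
              dNdX(gp * 24 + a * 3 + j, e) = d;
            }
          w(gp, e) = dJ;
          ve += dJ;
        }
    vol[e] = ve;
  }
  return List::create(_["dNdX"] = dNdX, _["w"] = w, _["lmin"] = lmin,
                      _["vol"] = vol);
}

static double force3d(const NumericMatrix& dNdX, const NumericMatrix& w,
                      const IntegerMatrix& elems, const std::vector<double>& x,
                      const NumericVector& g, const NumericVector& mu,
                      double K, std::vector<double>& f, double& maxJdev,
                      int& badElem) {
  int ne = elems.nrow();
  double E = 0.0;
  maxJdev = 0.0; badElem = -1;
  std::fill(f.begin(), f.end(), 0.0);
  const double* D = &dNdX(0, 0);
  const double* W = &w(0, 0);
  for (int e = 0; e < ne; ++e) {
    int nd[8];
    double xe[8][3];
    for (int a = 0; a < 8; ++a) {
      nd[a] = elems(e, a);
      for (int i = 0; i < 3; ++i) xe[a][i] = x[3 * nd[a] + i];
    }
    const double* De = D + 192 * e;
    const double* We = W + 8 * e;
    double Fg[8][3][3], Jg[8], wsum = 0, Jbar = 0;
    for (int gp = 0; gp < 8; ++gp) {
      double F[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            F[i][j] += xe[a][i] * De[gp * 24 + a * 3 + j];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) Fg[gp][i][j] = F[i][j];
      Jg[gp] = det3(F);
      Jbar += We[gp] * Jg[gp]; wsum += We[gp];
    }
    Jbar /= wsum;
    if (Jbar <= 0) { badElem = e; return -1.0; }
    double ge = g[e], mue = mu[e];
    for (int gp = 0; gp < 8; ++gp) {
      if (Jg[gp] <= 0) { badElem = e; return -1.0; }
      double s = std::cbrt(Jbar / Jg[gp]);
      double A[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) A[i][j] = s * Fg[gp][i][j] / ge;
      double Ja = det3(A);
      if (Ja <= 1e-8) { badElem = e; return -1.0; }
      double dev = std::fabs(Ja - 1.0);
      if (dev > maxJdev) maxJdev = dev;
      double Ai[3][3];
      inv3(A, Ja, Ai); // A^{-1}; A^{-T} = transpose
      double kv = K * Ja * (Ja - 1.0);
      double P[3][3], I1 = 0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          P[i][j] = mue * (A[i][j] - Ai[j][i]) + kv * Ai[j][i];
          I1 += A[i][j] * A[i][j];
        }
      // reference PK1 = det(G) * P_A * G^{-T} = g^2 * P_A (3D)
      double c = ge * ge * We[gp];
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double fa = 0;
          for (int j = 0; j < 3; ++j)
            fa += P[i][j] * De[gp * 24 + a * 3 + j];
          f[3 * nd[a] + i] -= c * fa;
        }
      double Wd = 0.5 * mue * (I1 - 3.0 - 2.0 * std::log(Ja)) +
                  0.5 * K * (Ja - 1.0) * (Ja - 1.0);
      E += ge * ge * ge * Wd * We[gp];
    }
  }
  return E;
}

// [[Rcpp::export]]
List feRun3D(NumericMatrix X, IntegerMatrix elems, List quad,
             NumericVector x0, NumericVector v0, NumericVector g,
             NumericVector mu, double K, NumericVector mass,
             NumericMatrix con, double damp, double dt, int nsteps) {
  NumericMatrix dNdX = quad["dNdX"], w = quad["w"];
  int nn = X.nrow(), ncon = con.nrow();
  std::vector<double> x(x0.begin(), x0.end()), v(v0.begin(), v0.end()),
      f(3 * nn);
  double maxJdev = 0.0, E = 0.0, runMaxJdev = 0.0;
  int badElem = -1, failStep = -1;
  double a1 = 1.0 - 0.5 * damp, a2 = 1.0 / (1.0 + 0.5 * damp);
  for (int s = 0; s < nsteps; ++s) {
    E = force3d(dNdX, w, elems, x, g, mu, K, f, maxJdev, badElem);
    if (badElem >= 0) { failStep = s; break; }
    if (maxJdev > runMaxJdev) runMaxJdev = maxJdev;
    for (int n = 0; n < nn; ++n) {
      double im = dt / mass[n];
      for (int i = 0; i < 3; ++i)
        v[3 * n + i] = a2 * (a1 * v[3 * n + i] + im * f[3 * n + i]);
    }
    for (int c = 0; c < ncon; ++c) {
      int n = (int)con(c, 0);
      double cx = con(c, 1), cy = con(c, 2), cz = con(c, 3);
      double p = v[3 * n] * cx + v[3 * n + 1] * cy + v[3 * n + 2] * cz;
      v[3 * n] -= p * cx; v[3 * n + 1] -= p * cy; v[3 * n + 2] -= p * cz;
    }
    for (int i = 0; i < 3 * nn; ++i) x[i] += dt * v[i];
  }
  double ke = 0.0;
  for (int n = 0; n < nn; ++n)
    ke += 0.5 * mass[n] *
          (v[3 * n] * v[3 * n] + v[3 * n + 1] * v[3 * n + 1] +
           v[3 * n + 2] * v[3 * n + 2]);
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["ke"] = ke, _["se"] = E, _["maxJdev"] = maxJdev,
                      _["maxJdevRun"] = runMaxJdev,
                      _["ok"] = (failStep < 0), _["badElem"] = badElem + 1,
                      _["failStep"] = failStep + 1);
}

// Brute-force nearest-vertex distances: for each row of A, the minimum
// Euclidean distance to any row of B.  Used for closest-vertex cortical
// thickness (white -> pial).
// [[Rcpp::export]]
NumericVector nearestVertexDist(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2), best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = B(j, 0) - ax, dy = B(j, 1) - ay, dz = B(j, 2) - az;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
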