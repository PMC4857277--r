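// Element kernels for the plane-strain neo-Hookean solver.
// Strain energy per unit reference volume:
//   W = C10 * (I1bar - 3) + k * (J - 1)^2,  k = 1/D1
// with the plane-strain embedding F = [[F11,F12,0],[F21,F22,0],[0,0,1]],
// I1 = ||F2d||^2 + 1, I1bar = J^{-2/3} I1, J = det(F2d).
// Constant-strain triangles: F, P and the material tangent are uniform per
// element; assembly returns residual and stiffness triplets.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void element_PA(const double F[4], double C10, double k,
                              double P[4], double A[16], bool want_A) {
  // F stored row-major: F11 F12 F21 F22; same for P; A[(iJ)*4+(kL)]
  double J = F[0] * F[3] - F[1] * F[2];
  double I1 = F[0] * F[0] + F[1] * F[1] + F[2] * F[2] + F[3] * F[3] + 1.0;
  double g = std::pow(J, -2.0 / 3.0);
  // F^{-T} row-major
  double Fit[4] = { F[3] / J, -F[2] / J, -F[1] / J, F[0] / J };
  double dev[4];
  for (int a = 0; a < 4; ++a) dev[a] = F[a] - (I1 / 3.0) * Fit[a];
  double vol = 2.0 * k * (J - 1.0) * J;
  for (int a = 0; a < 4; ++a) P[a] = 2.0 * C10 * g * dev[a] + vol * Fit[a];
  if (!want_A) return;
  double c1 = 2.0 * C10 * g;
  double v1 = 2.0 * k * (2.0 * J - 1.0) * J;
  double v2 = 2.0 * k * (J * J - J);
  for (int i = 0; i < 2; ++i) for (int Jj = 0; Jj < 2; ++Jj)
    for (int kk = 0; kk < 2; ++kk) for (int L = 0; L < 2; ++L) {
      int iJ = i * 2 + Jj, kL = kk * 2 + L;
      int kJ = kk * 2 + Jj, iL = i * 2 + L;
      double val = c1 * (-(2.0 / 3.0) * Fit[kL] * dev[iJ]
                         + ((i == kk && Jj == L) ? 1.0 : 0.0)
                         - (2.0 / 3.0) * F[kL] * Fit[iJ]
                         + (I1 / 3.0) * Fit[kJ] * Fit[iL])
                 + v1 * Fit[kL] * Fit[iJ] - v2 * Fit[kJ] * Fit[iL];
      A[iJ * 4 + kL] = val;
    }
}

// [[Rcpp::export]]
List fe_assemble(const arma::mat& nodes, const arma::imat& tri,
                 const arma::vec& u, const arma::vec& C10,
                 const arma::vec& kpen, bool want_K) {
  const int ne = tri.n_rows;
  arma::vec f(2 * nodes.n_rows, arma::fill::zeros);
  arma::ivec Ki, Kj; arma::vec Kx;
  if (want_K) {
    Ki.set_size(36 * ne); Kj.set_size(36 * ne); Kx.set_size(36 * ne);
    Ki.ones(); Kj.ones(); Kx.zeros();
  }
  int bad = 0;
  for (int e = 0; e < ne; ++e) {
    int n0 = tri(e, 0) - 1, n1 = tri(e, 1) - 1, n2 = tri(e, 2) - 1;
    double x0 = nodes(n0, 0), y0 = nodes(n0, 1);
    double x1 = nodes(n1, 0), y1 = nodes(n1, 1);
    double x2 = nodes(n2, 0), y2 = nodes(n2, 1);
    double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    double A0 = 0.5 * det;
    if (A0 <= 0) { ++bad; continue; }
    // shape gradients dN_a/dX
    double B[3][2] = { { (y1 - y2) / det, (x2 - x1) / det },
                       { (y2 - y0) / det, (x0 - x2) / det },
                       { (y0 - y1) / det, (x1 - x0) / det } };
    int nn[3] = { n0, n1, n2 };
    double F[4] = { 1.0, 0.0, 0.0, 1.0 };
    for (int a = 0; a < 3; ++a) {
      double ux = u(2 * nn[a]), uy = u(2 * nn[a] + 1);
      F[0] += ux * B[a][0]; F[1] += ux * B[a][1];
      F[2] += uy * B[a][0]; F[3] += uy * B[a][1];
    }
    double J = F[0] * F[3] - F[1] * F[2];
    if (J <= 1e-8) { ++bad; continue; }
    double P[4], Amat[16];
    element_PA(F, C10(e), kpen(e), P, Amat, want_K);
    for (int a = 0; a < 3; ++a) {
      f(2 * nn[a])     += A0 * (P[0] * B[a][0] + P[1] * B[a][1]);
      f(2 * nn[a] + 1) += A0 * (P[2] * B[a][0] + P[3] * B[a][1]);
    }
    if (want_K) {
      int base = 36 * e, idx = 0;
      for (int a = 0; a < 3; ++a) for (int i = 0; i < 2; ++i)
        for (int b = 0; b < 3; ++b) for (int kk = 0; kk < 2; ++kk) {
          double kab = 0.0;
          for (int Jj = 0; Jj < 2; ++Jj) for (int L = 0; L < 2; ++L)
            kab += Amat[(i * 2 + Jj) * 4 + (kk * 2 + L)] * B[a][Jj] * B[b][L];
          Ki(base + idx) = 2 * nn[a] + i + 1;
          Kj(base + idx) = 2 * nn[b] + kk + 1;
          Kx(base + idx) = A0 * kab;
          ++idx;
        }
    }
  }
  if (want_K)
    return List::create(_["f"] = f, _["i"] = Ki, _["j"] = Kj, _["x"] = Kx,
                        _["bad"] = bad);
  return List::create(_["f"] = f, _["bad"] = bad);
}

// [[Rcpp::export]]
arma::mat fe_stress(const arma::mat& nodes, const arma::imat& tri,
                    const arma::vec& u, const arma::vec& C10,
                    const arma::vec& kpen) {
  const int ne = tri.n_rows;
  arma::mat S(ne, 5); // sxx syy sxy szz vm (Cauchy, kPa)
  for (int e = 0; e < ne; ++e) {
    int n0 = tri(e, 0) - 1, n1 = tri(e, 1) - 1, n2 = tri(e, 2) - 1;
    double x0 = nodes(n0, 0), y0 = nodes(n0, 1);
    double x1 = nodes(n1, 0), y1 = nodes(n1, 1);
    double x2 = nodes(n2, 0), y2 = nodes(n2, 1);
    double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    double B[3][2] = { { (y1 - y2) / det, (x2 - x1) / det },
                       { (y2 - y0) / det, (x0 - x2) / det },
                       { (y0 - y1) / det, (x1 - x0) / det } };
    int nn[3] = { n0, n1, n2 };
    double F[4] = { 1.0, 0.0, 0.0, 1.0 };
    for (int a = 0; a < 3; ++a) {
      double ux = u(2 * nn[a]), uy = u(2 * nn[a] + 1);
      F[0] += ux * B[a][0]; F[1] += ux * B[a][1];
      F[2] += uy * B[a][0]; F[3] += uy * B[a][1];
    }
    double J = F[0] * F[3] - F[1] * F[2];
    double I1 = F[0] * F[0] + F[1] * F[1] + F[2] * F[2] + F[3] * F[3] + 1.0;
    double g = std::pow(J, -2.0 / 3.0);
    // Cauchy = J^-1 P F^T = 2 C10 g (B - I1/3 I)/J + 2 k (J-1) I (3D, B33=1)
    double Bl[3] = { F[0] * F[0] + F[1] * F[1],       // Bxx
                     F[2] * F[2] + F[3] * F[3],       // Byy
                     F[0] * F[2] + F[1] * F[3] };     // Bxy
    double c = 2.0 * C10(e) * g / J, p = 2.0 * kpen(e) * (J - 1.0);
    double sxx = c * (Bl[0] - I1 / 3.0) + p;
    double syy = c * (Bl[1] - I1 / 3.0) + p;
    double sxy = c * Bl[2];
    double szz = c * (1.0 - I1 / 3.0) + p;
    double m = (sxx + syy + szz) / 3.0;
    double vm = std::sqrt(1.5 * ((sxx - m) * (sxx - m) + (syy - m) * (syy - m)
                                 + (szz - m) * (szz - m) + 2.0 * sxy * sxy));
    S(e, 0) = sxx; S(e, 1) = syy; S(e, 2) = sxy; S(e, 3) = szz; S(e, 4) = vm;
  }
  return S;
}
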