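// Total-Lagrangian finite-element kernels for 10-node tetrahedra with a
// compressible neo-Hookean material, W = C10 (J^{-2/3} I1 - 3) + (1/D1)(J-1)^2.
// Elements are straight-sided (midside nodes at exact edge midpoints), so the
// isoparametric map is affine and the Jacobian constant per element; shape
// function derivatives still vary over the 4 Gauss points.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

typedef mat::fixed<10, 3> mat103;
typedef mat::fixed<3, 3> mat33;
typedef mat::fixed<6, 6> mat66;

// TET10 shape-function derivatives w.r.t. (xi, eta, zeta) at barycentric L.
// Node order (VTK quadratic tetra): corners L1..L4, then midsides on edges
// (1,2), (2,3), (1,3), (1,4), (2,4), (3,4).
mat103 dshape(double L1, double L2, double L3, double L4) {
  mat103 dN;
  const double d1[3] = {-1, -1, -1}, d2[3] = {1, 0, 0}, d3[3] = {0, 1, 0}, d4[3] = {0, 0, 1};
  for (int j = 0; j < 3; ++j) {
    dN(0, j) = (4 * L1 - 1) * d1[j];
    dN(1, j) = (4 * L2 - 1) * d2[j];
    dN(2, j) = (4 * L3 - 1) * d3[j];
    dN(3, j) = (4 * L4 - 1) * d4[j];
    dN(4, j) = 4 * (L2 * d1[j] + L1 * d2[j]);
    dN(5, j) = 4 * (L3 * d2[j] + L2 * d3[j]);
    dN(6, j) = 4 * (L3 * d1[j] + L1 * d3[j]);
    dN(7, j) = 4 * (L4 * d1[j] + L1 * d4[j]);
    dN(8, j) = 4 * (L4 * d2[j] + L2 * d4[j]);
    dN(9, j) = 4 * (L4 * d3[j] + L3 * d4[j]);
  }
  return dN;
}

inline void inv3(const mat33 &A, mat33 &Ai, double &detA) {
  detA = A(0,0)*(A(1,1)*A(2,2)-A(1,2)*A(2,1))
       - A(0,1)*(A(1,0)*A(2,2)-A(1,2)*A(2,0))
       + A(0,2)*(A(1,0)*A(2,1)-A(1,1)*A(2,0));
  double id = 1.0 / detA;
  Ai(0,0) =  (A(1,1)*A(2,2)-A(1,2)*A(2,1))*id;
  Ai(0,1) = -(A(0,1)*A(2,2)-A(0,2)*A(2,1))*id;
  Ai(0,2) =  (A(0,1)*A(1,2)-A(0,2)*A(1,1))*id;
  Ai(1,0) = -(A(1,0)*A(2,2)-A(1,2)*A(2,0))*id;
  Ai(1,1) =  (A(0,0)*A(2,2)-A(0,2)*A(2,0))*id;
  Ai(1,2) = -(A(0,0)*A(1,2)-A(0,2)*A(1,0))*id;
  Ai(2,0) =  (A(1,0)*A(2,1)-A(1,1)*A(2,0))*id;
  Ai(2,1) = -(A(0,0)*A(2,1)-A(0,1)*A(2,0))*id;
  Ai(2,2) =  (A(0,0)*A(1,1)-A(0,1)*A(1,0))*id;
}

// PK2 stress and Voigt material tangent of the compressible neo-Hookean
// model at C = F'F. Returns J.
inline double neo_hooke_SD(const mat33 &C, double C10, double D1,
                           mat33 &S, mat66 &Dv, bool want_D) {
  mat33 Ci;
  double detC;
  inv3(C, Ci, detC);
  double J = std::sqrt(detC);
  double I1 = C(0,0) + C(1,1) + C(2,2);
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double kv = 2.0 / D1;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      S(i, j) = 2.0 * C10 * Jm23 * ((i == j ? 1.0 : 0.0) - (I1 / 3.0) * Ci(i, j))
              + kv * (J - 1.0) * J * Ci(i, j);
  if (want_D) {
    const int vi[6] = {0, 1, 2, 0, 1, 0};
    const int vj[6] = {0, 1, 2, 1, 2, 2};
    double c_iso = (4.0 / 3.0) * C10 * Jm23;
    for (int m = 0; m < 6; ++m) {
      int i = vi[m], j = vj[m];
      for (int n = m; n < 6; ++n) {
        int k = vi[n], l = vj[n];
        double CiCi = 0.5 * (Ci(i, k) * Ci(j, l) + Ci(i, l) * Ci(j, k));
        double iso = c_iso * ((I1 / 3.0) * Ci(i, j) * Ci(k, l)
                              - (i == j ? Ci(k, l) : 0.0) - (k == l ? Ci(i, j) : 0.0)
                              + I1 * CiCi);
        double vol = kv * (J * (2.0 * J - 1.0) * Ci(i, j) * Ci(k, l)
                           - 2.0 * J * (J - 1.0) * CiCi);
        Dv(m, n) = Dv(n, m) = iso + vol;
      }
    }
  }
  return J;
}

} // namespace

// Assemble internal force, optional tangent stiffness values (triplet order
// fixed: element-major, 30x30 row-major blocks), and centroid Cauchy
// stresses at displacement U (length 3N, xyz per node).
// [[Rcpp::export]]
Rcpp::List fe_assemble(const arma::mat &nodes, const arma::imat &elem,
                       const arma::vec &C10, const arma::vec &D1,
                       const arma::vec &U, bool want_stiffness,
                       bool want_pattern = true) {
  const int E = elem.n_rows;
  const double qa = 0.5854101966249685, qb = 0.1381966011250105;
  double qp[4][4] = {{qa, qb, qb, qb}, {qb, qa, qb, qb}, {qb, qb, qa, qb}, {qb, qb, qb, qa}};
  const double wq = 1.0 / 24.0;

  std::vector<mat103> dNq;
  for (int q = 0; q < 4; ++q) dNq.push_back(dshape(qp[q][0], qp[q][1], qp[q][2], qp[q][3]));
  mat103 dNc = dshape(0.25, 0.25, 0.25, 0.25);

  vec fint(3 * nodes.n_rows, fill::zeros);
  mat stress(E, 6, fill::zeros);
  double detJmin = datum::inf, detFmin = datum::inf;
  uword ntrip = want_stiffness ? (uword)E * 900 : 0;
  Rcpp::NumericVector Kx(ntrip);
  Rcpp::IntegerVector Ki(want_pattern && want_stiffness ? ntrip : 0),
                      Kj(want_pattern && want_stiffness ? ntrip : 0);

  mat103 Xe, Ue, gradN, fe;
  mat33 Jm, invJ, F, Cg, S;
  mat66 Dv;
  double B[6][30];
  double Ke[30][30];

  for (int e = 0; e < E; ++e) {
    int nid[10];
    for (int a = 0; a < 10; ++a) {
      int n = elem(e, a) - 1;
      nid[a] = n;
      Xe(a, 0) = nodes(n, 0); Xe(a, 1) = nodes(n, 1); Xe(a, 2) = nodes(n, 2);
      Ue(a, 0) = U[3 * n]; Ue(a, 1) = U[3 * n + 1]; Ue(a, 2) = U[3 * n + 2];
    }
    // affine map: Jacobian from the corner tet
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Jm(i, j) = Xe(j + 1, i) - Xe(0, i);
    double detJ;
    inv3(Jm, invJ, detJ);
    detJmin = std::min(detJmin, detJ);
    if (detJ <= 0) continue;
    double w = wq * detJ;
    fe.zeros();
    if (want_stiffness) std::memset(Ke, 0, sizeof(Ke));

    for (int q = 0; q < 4; ++q) {
      gradN = dNq[q] * invJ;                   // 10x3 dN/dX
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = (i == j) ? 1.0 : 0.0;
          for (int a = 0; a < 10; ++a) s += Ue(a, i) * gradN(a, j);
          F(i, j) = s;
        }
      double dF = F(0,0)*(F(1,1)*F(2,2)-F(1,2)*F(2,1))
                - F(0,1)*(F(1,0)*F(2,2)-F(1,2)*F(2,0))
                + F(0,2)*(F(1,0)*F(2,1)-F(1,1)*F(2,0));
      detFmin = std::min(detFmin, dF);
      Cg = F.t() * F;
      neo_hooke_SD(Cg, C10(e), D1(e), S, Dv, want_stiffness);

      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i) {
          int col = 3 * a + i;
          B[0][col] = F(i, 0) * gradN(a, 0);
          B[1][col] = F(i, 1) * gradN(a, 1);
          B[2][col] = F(i, 2) * gradN(a, 2);
          B[3][col] = F(i, 0) * gradN(a, 1) + F(i, 1) * gradN(a, 0);
          B[4][col] = F(i, 1) * gradN(a, 2) + F(i, 2) * gradN(a, 1);
          B[5][col] = F(i, 0) * gradN(a, 2) + F(i, 2) * gradN(a, 0);
        }
      double Sv[6] = {S(0, 0), S(1, 1), S(2, 2), S(0, 1), S(1, 2), S(0, 2)};
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i) {
          int col = 3 * a + i;
          double s = 0;
          for (int m = 0; m < 6; ++m) s += B[m][col] * Sv[m];
          fe(a, i) += s * w;
        }

      if (want_stiffness) {
        double DB[6][30];
        for (int m = 0; m < 6; ++m)
          for (int c = 0; c < 30; ++c) {
            double s = 0;
            for (int n = 0; n < 6; ++n) s += Dv(m, n) * B[n][c];
            DB[m][c] = s * w;
          }
        for (int r = 0; r < 30; ++r)
          for (int c = r; c < 30; ++c) {
            double s = 0;
            for (int m = 0; m < 6; ++m) s += B[m][r] * DB[m][c];
            Ke[r][c] += s;
          }
        // geometric part: (gradN_a . S . gradN_b) on the displacement diagonal
        for (int a = 0; a < 10; ++a) {
          double SgA[3];
          for (int j = 0; j < 3; ++j)
            SgA[j] = S(j, 0) * gradN(a, 0) + S(j, 1) * gradN(a, 1) + S(j, 2) * gradN(a, 2);
          for (int b = a; b < 10; ++b) {
            double g = (gradN(b, 0) * SgA[0] + gradN(b, 1) * SgA[1] + gradN(b, 2) * SgA[2]) * w;
            for (int i = 0; i < 3; ++i) {
              int r = 3 * a + i, c = 3 * b + i;
              if (c >= r) Ke[r][c] += g; else Ke[c][r] += g;
            }
          }
        }
      }
    }

    // centroid Cauchy stress
    {
      gradN = dNc * invJ;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = (i == j) ? 1.0 : 0.0;
          for (int a = 0; a < 10; ++a) s += Ue(a, i) * gradN(a, j);
          F(i, j) = s;
        }
      Cg = F.t() * F;
      double J = neo_hooke_SD(Cg, C10(e), D1(e), S, Dv, false);
      mat33 sig = (F * S * F.t()) / J;
      stress(e, 0) = sig(0, 0); stress(e, 1) = sig(1, 1); stress(e, 2) = sig(2, 2);
      stress(e, 3) = sig(0, 1); stress(e, 4) = sig(1, 2); stress(e, 5) = sig(0, 2);
    }

    for (int a = 0; a < 10; ++a) {
      fint[3 * nid[a]] += fe(a, 0); fint[3 * nid[a] + 1] += fe(a, 1); fint[3 * nid[a] + 2] += fe(a, 2);
    }
    if (want_stiffness) {
      uword tp = (uword)e * 900;
      for (int r = 0; r < 30; ++r)
        for (int c = 0; c < 30; ++c)
          Kx[tp + 30 * r + c] = (c >= r) ? Ke[r][c] : Ke[c][r];
      if (want_pattern) {
        for (int r = 0; r < 30; ++r) {
          int gr = 3 * nid[r / 3] + r % 3 + 1;
          for (int c = 0; c < 30; ++c) {
            Ki[tp + 30 * r + c] = gr;
            Kj[tp + 30 * r + c] = 3 * nid[c / 3] + c % 3 + 1;
          }
        }
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("fint") = fint, Rcpp::Named("stress") = stress,
      Rcpp::Named("detJmin") = detJmin, Rcpp::Named("detFmin") = detFmin,
      Rcpp::Named("Ki") = Ki, Rcpp::Named("Kj") = Kj, Rcpp::Named("Kx") = Kx);
}

// Signed 6*volume (corner Jacobian) and longest edge per element.
// [[Rcpp::export]]
Rcpp::List tet_metrics(const arma::mat &nodes, const arma::imat &elem) {
  const int E = elem.n_rows;
  vec vol6(E), edge(E);
  const int e1[6] = {0, 1, 0, 0, 1, 2};
  const int e2[6] = {1, 2, 2, 3, 3, 3};
  for (int e = 0; e < E; ++e) {
    rowvec a = nodes.row(elem(e, 0) - 1), b = nodes.row(elem(e, 1) - 1),
           c = nodes.row(elem(e, 2) - 1), d = nodes.row(elem(e, 3) - 1);
    vol6(e) = dot(cross((b - a).t(), (c - a).t()), (d - a).t());
    double mx = 0;
    for (int k = 0; k < 6; ++k) {
      rowvec p = nodes.row(elem(e, e1[k]) - 1) - nodes.row(elem(e, e2[k]) - 1);
      mx = std::max(mx, norm(p, 2));
    }
    edge(e) = mx;
  }
  return Rcpp::List::create(Rcpp::Named("vol6") = vol6, Rcpp::Named("max_edge") = edge);
}
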