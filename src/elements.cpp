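// Total-Lagrangian element kernels: 4-node tetrahedra (St. Venant-Kirchhoff),
// 3-node membranes (plane stress, no bending), 2-node trusses with initial
// (prestress) stress.  Each assembler returns sparse-matrix triplets for the
// tangent stiffness (material + geometric), the internal force vector, and
// per-element stress.  Connectivity is 1-based (R convention).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat66 iso_D(double E, double nu) {
  const double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  const double mu  = E / (2.0 * (1.0 + nu));
  arma::mat66 D(arma::fill::zeros);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) D(i, j) = lam;
  for (int i = 0; i < 3; ++i) D(i, i) = lam + 2.0 * mu;
  for (int i = 3; i < 6; ++i) D(i, i) = mu;
  return D;
}

// [[Rcpp::export]]
List assemble_tets_cpp(const arma::mat& X, const arma::imat& conn,
                       const arma::vec& u, const arma::vec& Evec,
                       const arma::vec& nuvec) {
  const int m = conn.n_rows;
  const int ndof = X.n_rows * 3;
  IntegerVector ti(m * 144), tj(m * 144);
  NumericVector tx(m * 144);
  arma::vec fint(ndof, arma::fill::zeros);
  arma::mat stress(m, 6, arma::fill::zeros);   // Cauchy: xx yy zz xy yz zx
  double minJ = arma::datum::inf;
  const arma::mat33 I3(arma::fill::eye);
  arma::mat66 D;
  double Eprev = -1.0, nuprev = -1.0;

  for (int e = 0; e < m; ++e) {
    arma::ivec4 nd;
    for (int a = 0; a < 4; ++a) nd(a) = conn(e, a) - 1;
    arma::mat33 J;  // columns: edge vectors from node 0
    for (int a = 0; a < 3; ++a)
      J.col(a) = (X.row(nd(a + 1)) - X.row(nd(0))).t();
    const double detJ = arma::det(J);
    const double V0 = detJ / 6.0;
    if (V0 <= 0.0) stop("tet element %d has non-positive volume", e + 1);
    arma::mat33 Jinv = arma::inv(J);
    arma::mat::fixed<3, 4> G;                 // columns: grad N_a (reference)
    for (int a = 0; a < 3; ++a) G.col(a + 1) = Jinv.row(a).t();
    G.col(0) = -(G.col(1) + G.col(2) + G.col(3));

    arma::mat::fixed<3, 4> Ue;
    for (int a = 0; a < 4; ++a) Ue.col(a) = u.subvec(3 * nd(a), 3 * nd(a) + 2);
    arma::mat33 F = I3 + Ue * G.t();
    const double Jdet = arma::det(F);
    if (Jdet < minJ) minJ = Jdet;
    arma::mat33 Egl = 0.5 * (F.t() * F - I3);
    arma::vec6 Ev = {Egl(0,0), Egl(1,1), Egl(2,2),
                     2.0*Egl(0,1), 2.0*Egl(1,2), 2.0*Egl(0,2)};
    if (Evec(e) != Eprev || nuvec(e) != nuprev) {
      D = iso_D(Evec(e), nuvec(e));
      Eprev = Evec(e); nuprev = nuvec(e);
    }
    arma::vec6 Sv = D * Ev;
    arma::mat33 S = {{Sv(0), Sv(3), Sv(5)},
                     {Sv(3), Sv(1), Sv(4)},
                     {Sv(5), Sv(4), Sv(2)}};
    arma::mat33 P = F * S;

    for (int a = 0; a < 4; ++a)
      fint.subvec(3 * nd(a), 3 * nd(a) + 2) += V0 * (P * G.col(a));

    // B such that delta(E_voigt) = B * delta(u_e), engineering shear
    arma::mat::fixed<6, 12> B(arma::fill::zeros);
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        const int c = 3 * a + i;
        B(0, c) = F(i, 0) * G(0, a);
        B(1, c) = F(i, 1) * G(1, a);
        B(2, c) = F(i, 2) * G(2, a);
        B(3, c) = F(i, 0) * G(1, a) + F(i, 1) * G(0, a);
        B(4, c) = F(i, 1) * G(2, a) + F(i, 2) * G(1, a);
        B(5, c) = F(i, 0) * G(2, a) + F(i, 2) * G(0, a);
      }
    arma::mat::fixed<12, 12> Ke = V0 * (B.t() * D * B);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        const double g = V0 * arma::as_scalar(G.col(a).t() * S * G.col(b));
        for (int i = 0; i < 3; ++i) Ke(3 * a + i, 3 * b + i) += g;
      }

    arma::mat33 sig = (F * S * F.t()) / Jdet;
    stress(e, 0) = sig(0,0); stress(e, 1) = sig(1,1); stress(e, 2) = sig(2,2);
    stress(e, 3) = sig(0,1); stress(e, 4) = sig(1,2); stress(e, 5) = sig(2,0);

    int k = e * 144;
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        for (int b = 0; b < 4; ++b)
          for (int j = 0; j < 3; ++j) {
            ti[k] = 3 * nd(a) + i + 1;
            tj[k] = 3 * nd(b) + j + 1;
            tx[k] = Ke(3 * a + i, 3 * b + j);
            ++k;
          }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["fint"] = fint, _["stress"] = stress,
                      _["min_detF"] = minJ);
}

// [[Rcpp::export]]
List assemble_membranes_cpp(const arma::mat& X, const arma::imat& conn,
                            const arma::vec& u, const arma::vec& Evec,
                            const arma::vec& nuvec, const arma::vec& thick) {
  const int m = conn.n_rows;
  const int ndof = X.n_rows * 3;
  IntegerVector ti(m * 81), tj(m * 81);
  NumericVector tx(m * 81);
  arma::vec fint(ndof, arma::fill::zeros);
  arma::mat stress(m, 6, arma::fill::zeros);  // 3x3 Cauchy in global frame

  for (int e = 0; e < m; ++e) {
    arma::ivec3 nd;
    for (int a = 0; a < 3; ++a) nd(a) = conn(e, a) - 1;
    arma::vec3 e1 = (X.row(nd(1)) - X.row(nd(0))).t();
    arma::vec3 e2 = (X.row(nd(2)) - X.row(nd(0))).t();
    arma::vec3 nrm = arma::cross(e1, e2);
    const double A0 = 0.5 * arma::norm(nrm);
    if (A0 <= 0.0) stop("membrane element %d is degenerate", e + 1);
    arma::vec3 t1 = arma::normalise(e1);
    arma::vec3 t3 = arma::normalise(nrm);
    arma::vec3 t2 = arma::cross(t3, t1);

    // reference in-plane coordinates and 2-D shape gradients
    arma::mat22 Jl;
    Jl(0,0) = arma::dot(e1, t1); Jl(1,0) = arma::dot(e1, t2);
    Jl(0,1) = arma::dot(e2, t1); Jl(1,1) = arma::dot(e2, t2);
    arma::mat22 Jinv = arma::inv(Jl);
    arma::mat::fixed<2, 3> G2;
    G2.col(1) = Jinv.row(0).t();
    G2.col(2) = Jinv.row(1).t();
    G2.col(0) = -(G2.col(1) + G2.col(2));

    arma::mat::fixed<3, 3> xc;
    for (int a = 0; a < 3; ++a)
      xc.col(a) = X.row(nd(a)).t() + u.subvec(3 * nd(a), 3 * nd(a) + 2);
    arma::mat::fixed<3, 2> F = xc * G2.t();
    arma::mat22 C = F.t() * F;
    arma::mat22 E2 = 0.5 * (C - arma::mat22(arma::fill::eye));
    const double E = Evec(e), nu = nuvec(e), t = thick(e);
    arma::mat33 Dps = {{1.0, nu, 0.0}, {nu, 1.0, 0.0},
                       {0.0, 0.0, (1.0 - nu) / 2.0}};
    Dps *= E / (1.0 - nu * nu);
    arma::vec3 Ev = {E2(0,0), E2(1,1), 2.0 * E2(0,1)};
    arma::vec3 Sv = Dps * Ev;
    arma::mat22 S2 = {{Sv(0), Sv(2)}, {Sv(2), Sv(1)}};

    for (int a = 0; a < 3; ++a)
      fint.subvec(3 * nd(a), 3 * nd(a) + 2) += t * A0 * (F * S2 * G2.col(a));

    arma::mat::fixed<3, 9> B(arma::fill::zeros);
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) {
        const int c = 3 * a + i;
        B(0, c) = F(i, 0) * G2(0, a);
        B(1, c) = F(i, 1) * G2(1, a);
        B(2, c) = F(i, 0) * G2(1, a) + F(i, 1) * G2(0, a);
      }
    arma::mat::fixed<9, 9> Ke = (t * A0) * (B.t() * Dps * B);
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        const double g =
          t * A0 * arma::as_scalar(G2.col(a).t() * S2 * G2.col(b));
        for (int i = 0; i < 3; ++i) Ke(3 * a + i, 3 * b + i) += g;
      }

    // in-plane Cauchy stress pushed to the global frame (rank-2 tensor,
    // zero through-thickness component); area Jacobian sqrt(det C)
    const double J2 = std::sqrt(std::max(arma::det(C), 1e-300));
    arma::mat33 sig = (F * S2 * F.t()) / J2;
    stress(e, 0) = sig(0,0); stress(e, 1) = sig(1,1); stress(e, 2) = sig(2,2);
    stress(e, 3) = sig(0,1); stress(e, 4) = sig(1,2); stress(e, 5) = sig(2,0);

    int k = e * 81;
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i)
        for (int b = 0; b < 3; ++b)
          for (int j = 0; j < 3; ++j) {
            ti[k] = 3 * nd(a) + i + 1;
            tj[k] = 3 * nd(b) + j + 1;
            tx[k] = Ke(3 * a + i, 3 * b + j);
            ++k;
          }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["fint"] = fint, _["stress"] = stress);
}

// [[Rcpp::export]]
List assemble_trusses_cpp(const arma::mat& X, const arma::imat& conn,
                          const arma::vec& u, const arma::vec& Evec,
                          const arma::vec& area, const arma::vec& sig0) {
  const int m = conn.n_rows;
  const int ndof = X.n_rows * 3;
  IntegerVector ti(m * 36), tj(m * 36);
  NumericVector tx(m * 36);
  arma::vec fint(ndof, arma::fill::zeros);
  arma::vec s11(m, arma::fill::zeros);
  const arma::mat33 I3(arma::fill::eye);

  for (int e = 0; e < m; ++e) {
    const int n1 = conn(e, 0) - 1, n2 = conn(e, 1) - 1;
    arma::vec3 d0 = (X.row(n2) - X.row(n1)).t();
    const double L0 = arma::norm(d0);
    if (L0 <= 0.0) stop("truss element %d has zero length", e + 1);
    arma::vec3 dc = d0 + u.subvec(3 * n2, 3 * n2 + 2)
                       - u.subvec(3 * n1, 3 * n1 + 2);
    const double l = arma::norm(dc);
    const double epsG = (l * l - L0 * L0) / (2.0 * L0 * L0);
    const double S = Evec(e) * epsG + sig0(e);  // tension positive
    const double A = area(e);
    s11(e) = S;

    arma::vec3 f2 = (A * S / L0) * dc;
    fint.subvec(3 * n2, 3 * n2 + 2) += f2;
    fint.subvec(3 * n1, 3 * n1 + 2) -= f2;

    arma::mat33 Kb = (A * Evec(e) / (L0 * L0 * L0)) * (dc * dc.t())
                   + (A * S / L0) * I3;
    int k = e * 36;
    const int nds[2] = {n1, n2};
    const double sgn[2] = {-1.0, 1.0};
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            ti[k] = 3 * nds[a] + i + 1;
            tj[k] = 3 * nds[b] + j + 1;
            tx[k] = sgn[a] * sgn[b] * Kb(i, j);
            ++k;
          }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["fint"] = fint, _["s11"] = s11);
}

// [[Rcpp::export]]
NumericVector tet_volumes_cpp(const arma::mat& X, const arma::imat& conn) {
  const int m = conn.n_rows;
  NumericVector v(m);
  for (int e = 0; e < m; ++e) {
    arma::mat33 J;
    for (int a = 0; a < 3; ++a)
      J.col(a) = (X.row(conn(e, a + 1) - 1) - X.row(conn(e, 0) - 1)).t();
    v[e] = arma::det(J) / 6.0;
  }
  return v;
}
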