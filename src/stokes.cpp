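// Dense regularized-Stokeslet kernels and mobility solves.
//
// 2D regularized Stokeslet (Cortez blob), with R = sqrt(r^2 + eps^2):
//   u = (1/4 pi mu) [ -f (ln(R+eps) - eps(R+2eps)/((R+eps) R))
//                     + (f.x) x (R+2eps)/((R+eps)^2 R) ]
// The kernel is finite at r = 0 and matches the singular 2D Stokeslet
// (-I ln r + x x^T / r^2)/(4 pi mu) in the far field.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void reg_kernel(double dx, double dy, double eps,
                              double &h1, double &h2) {
  double r2 = dx * dx + dy * dy;
  double R = std::sqrt(r2 + eps * eps);
  h1 = -std::log(R + eps) + eps * (R + 2.0 * eps) / ((R + eps) * R);
  h2 = (R + 2.0 * eps) / ((R + eps) * (R + eps) * R);
}

// [[Rcpp::export]]
arma::mat assemble_mobility_cpp(const arma::mat &pos, double mu, double eps) {
  const int P = pos.n_rows;
  const double c = 1.0 / (4.0 * M_PI * mu);
  arma::mat M(2 * P, 2 * P);
  double h1, h2;
  for (int i = 0; i < P; ++i) {
    for (int j = i; j < P; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      if (i != j && dx * dx + dy * dy < 1e-12)
        stop("coincident discretization points (singular assembly)");
      reg_kernel(dx, dy, eps, h1, h2);
      double mxx = c * (h1 + h2 * dx * dx);
      double mxy = c * h2 * dx * dy;
      double myy = c * (h1 + h2 * dy * dy);
      M(2 * i, 2 * j) = mxx;     M(2 * i, 2 * j + 1) = mxy;
      M(2 * i + 1, 2 * j) = mxy; M(2 * i + 1, 2 * j + 1) = myy;
      if (i != j) {
        M(2 * j, 2 * i) = mxx;     M(2 * j, 2 * i + 1) = mxy;
        M(2 * j + 1, 2 * i) = mxy; M(2 * j + 1, 2 * i + 1) = myy;
      }
    }
  }
  return M;
}

// Full bordered system: M F - U0 = U_P, sum F = 0.
// [[Rcpp::export]]
List solve_swim_cpp(const arma::mat &pos, const arma::mat &vel,
                    double mu, double eps) {
  const int P = pos.n_rows;
  const int n = 2 * P + 2;
  arma::mat A(n, n, arma::fill::zeros);
  A.submat(0, 0, 2 * P - 1, 2 * P - 1) = assemble_mobility_cpp(pos, mu, eps);
  for (int i = 0; i < P; ++i) {
    A(2 * i, 2 * P) = -1.0;
    A(2 * i + 1, 2 * P + 1) = -1.0;
    A(2 * P, 2 * i) = 1.0;
    A(2 * P + 1, 2 * i + 1) = 1.0;
  }
  arma::vec b(n, arma::fill::zeros);
  for (int i = 0; i < P; ++i) {
    b(2 * i) = vel(i, 0);
    b(2 * i + 1) = vel(i, 1);
  }
  arma::vec sol = arma::solve(A, b, arma::solve_opts::fast);
  arma::mat F(P, 2);
  for (int i = 0; i < P; ++i) {
    F(i, 0) = sol(2 * i);
    F(i, 1) = sol(2 * i + 1);
  }
  arma::vec U0 = sol.subvec(2 * P, 2 * P + 1);
  return List::create(_["forces"] = F, _["U0"] = U0);
}

// Mirror-symmetric half-size solve.  Points come as the top half (y > 0)
// plus on-axis points; the bottom half is the y-mirror of the top half with
// mirrored forces F_bot = (Fx, -Fy).  Unknowns: interleaved top forces,
// axis x-forces (axis Fy = 0 by symmetry), and the swimming speed u0
// (U0_y = 0 by symmetry).  Returns u0.
// [[Rcpp::export]]
double solve_swim_sym_cpp(const arma::mat &top_pos, const arma::mat &top_vel,
                          const arma::mat &axis_pos,
                          const arma::vec &axis_velx,
                          double mu, double eps) {
  const int T = top_pos.n_rows;
  const int A = axis_pos.n_rows;
  const int n = 2 * T + A + 1;
  const double c = 1.0 / (4.0 * M_PI * mu);
  arma::mat S(n, n, arma::fill::zeros);
  arma::vec b(n, arma::fill::zeros);
  double h1, h2;

  for (int i = 0; i < T; ++i) {
    double xi = top_pos(i, 0), yi = top_pos(i, 1);
    for (int j = 0; j < T; ++j) {
      double dx = xi - top_pos(j, 0);
      double dy1 = yi - top_pos(j, 1);   // direct
      double dy2 = yi + top_pos(j, 1);   // image (mirrored source)
      reg_kernel(dx, dy1, eps, h1, h2);
      double axx = h1 + h2 * dx * dx, axy = h2 * dx * dy1;
      double ayy = h1 + h2 * dy1 * dy1;
      reg_kernel(dx, dy2, eps, h1, h2);
      // image force is (Fx, -Fy): columns (xx, -xy; yx, -yy) of the kernel
      double bxx = h1 + h2 * dx * dx, bxy = h2 * dx * dy2;
      double byy = h1 + h2 * dy2 * dy2;
      S(2 * i, 2 * j) = c * (axx + bxx);
      S(2 * i, 2 * j + 1) = c * (axy - bxy);
      S(2 * i + 1, 2 * j) = c * (axy + bxy);
      S(2 * i + 1, 2 * j + 1) = c * (ayy - byy);
    }
    for (int a = 0; a < A; ++a) {
      double dx = xi - axis_pos(a, 0);
      double dy = yi - axis_pos(a, 1);
      reg_kernel(dx, dy, eps, h1, h2);
      S(2 * i, 2 * T + a) = c * (h1 + h2 * dx * dx);
      S(2 * i + 1, 2 * T + a) = c * h2 * dx * dy;
    }
    S(2 * i, n - 1) = -1.0;    // -u0 in the x equation
    b(2 * i) = top_vel(i, 0);
    b(2 * i + 1) = top_vel(i, 1);
  }
  for (int a = 0; a < A; ++a) {
    double xa = axis_pos(a, 0), ya = axis_pos(a, 1);
    int row = 2 * T + a;
    for (int j = 0; j < T; ++j) {
      double dx = xa - top_pos(j, 0);
      double dy1 = ya - top_pos(j, 1);
      double dy2 = ya + top_pos(j, 1);
      reg_kernel(dx, dy1, eps, h1, h2);
      double axx = h1 + h2 * dx * dx, axy = h2 * dx * dy1;
      reg_kernel(dx, dy2, eps, h1, h2);
      double bxx = h1 + h2 * dx * dx, bxy = h2 * dx * dy2;
      S(row, 2 * j) = c * (axx + bxx);
      S(row, 2 * j + 1) = c * (axy - bxy);
    }
    for (int a2 = 0; a2 < A; ++a2) {
      double dx = xa - axis_pos(a2, 0);
      double dy = ya - axis_pos(a2, 1);
      reg_kernel(dx, dy, eps, h1, h2);
      S(row, 2 * T + a2) = c * (h1 + h2 * dx * dx);
    }
    S(row, n - 1) = -1.0;
    b(row) = axis_velx(a);
  }
  // force-free in x: bottom mirrors double the top x-forces
  for (int j = 0; j < T; ++j) S(n - 1, 2 * j) = 2.0;
  for (int a = 0; a < A; ++a) S(n - 1, 2 * T + a) = 1.0;

  arma::vec sol = arma::solve(S, b, arma::solve_opts::fast);
  return sol(n - 1);
}
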