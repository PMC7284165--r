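// Per-voxel linear algebra kernels for the tensor pipeline. Kept in C++
// because cohort-scale Monte-Carlo runs fit tens of thousands of voxels per
// slice across hundreds of slices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat33 unpack6(const arma::mat& D6, arma::uword v) {
  arma::mat33 D;
  D(0, 0) = D6(v, 0); D(1, 1) = D6(v, 1); D(2, 2) = D6(v, 2);
  D(0, 1) = D(1, 0) = D6(v, 3);
  D(0, 2) = D(2, 0) = D6(v, 4);
  D(1, 2) = D(2, 1) = D6(v, 5);
  return D;
}

// Weighted least squares on log-signals, one 6x6 solve per voxel.
// y: V x N log-attenuations, w: V x N weights, B: N x 6 design matrix.
// [[Rcpp::export]]
arma::mat cpp_wls_fit(const arma::mat& y, const arma::mat& w, const arma::mat& B) {
  const arma::uword V = y.n_rows;
  arma::mat out(V, 6);
  for (arma::uword v = 0; v < V; ++v) {
    arma::vec wv = w.row(v).t();
    arma::mat Bw = B.each_col() % wv;              // diag(w) B
    arma::mat A = B.t() * Bw;                      // B' W B
    arma::vec rhs = Bw.t() * y.row(v).t();         // B' W y
    arma::vec d;
    if (!arma::solve(d, A, rhs, arma::solve_opts::likely_sympd + arma::solve_opts::no_approx)) {
      d = arma::pinv(A) * rhs;
    }
    out.row(v) = d.t();
  }
  return out;
}

// Clamp negative eigenvalues to zero (semidefinite projection); returns the
// clamped tensors plus the number of voxels touched.
// [[Rcpp::export]]
List cpp_clamp_psd(const arma::mat& D6) {
  const arma::uword V = D6.n_rows;
  arma::mat out = D6;
  int n_clamped = 0;
  arma::vec eval;
  arma::mat evec;
  for (arma::uword v = 0; v < V; ++v) {
    arma::mat33 D = unpack6(D6, v);
    arma::eig_sym(eval, evec, D);
    if (eval(0) < 0.0) {
      ++n_clamped;
      eval.transform([](double x) { return x < 0.0 ? 0.0 : x; });
      arma::mat33 Dc = evec * arma::diagmat(eval) * evec.t();
      out(v, 0) = Dc(0, 0); out(v, 1) = Dc(1, 1); out(v, 2) = Dc(2, 2);
      out(v, 3) = Dc(0, 1); out(v, 4) = Dc(0, 2); out(v, 5) = Dc(1, 2);
    }
  }
  return List::create(_["D"] = out, _["n_clamped"] = n_clamped);
}

// Eigen metrics per voxel: MD, FA, in-plane principal orientation (deg in
// [0,180)), eigenvalues (descending), minimum eigenvalue sign retained.
// theta is NaN where the principal direction is degenerate (l1 ~ l2) or its
// in-plane projection vanishes.
// [[Rcpp::export]]
arma::mat cpp_tensor_metrics(const arma::mat& D6, double degen_tol) {
  const arma::uword V = D6.n_rows;
  arma::mat out(V, 6); // md, fa, theta, l1, l2, l3
  arma::vec eval;
  arma::mat evec;
  const double rad2deg = 180.0 / M_PI;
  for (arma::uword v = 0; v < V; ++v) {
    arma::mat33 D = unpack6(D6, v);
    arma::eig_sym(eval, evec, D); // ascending
    double l1 = eval(2), l2 = eval(1), l3 = eval(0);
    double md = (l1 + l2 + l3) / 3.0;
    double num = std::sqrt((l1 - md) * (l1 - md) + (l2 - md) * (l2 - md) + (l3 - md) * (l3 - md));
    double den = std::sqrt(l1 * l1 + l2 * l2 + l3 * l3);
    double fa = den > 0.0 ? std::sqrt(1.5) * num / den : 0.0;
    double theta = NA_REAL;
    if (l1 - l2 > degen_tol) {
      double ex = evec(0, 2), ey = evec(1, 2);
      if (std::sqrt(ex * ex + ey * ey) > 1e-12) {
        theta = std::atan2(ey, ex) * rad2deg; // (-180, 180]
        if (theta < 0.0) theta += 180.0;
        if (theta >= 180.0) theta -= 180.0;
      }
    }
    out(v, 0) = md; out(v, 1) = fa; out(v, 2) = theta;
    out(v, 3) = l1; out(v, 4) = l2; out(v, 5) = l3;
  }
  return out;
}
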