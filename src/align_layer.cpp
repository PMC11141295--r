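// Fused Gaussian-kernel MMD terms for one alignment layer.
//
// For the expression-branch representation X and each other-branch
// representation Y (columns = spots), computes the kernel matrices
// K(X,X), K(X,Y), K(Y,Y) once and derives from them both the globally
// weighted (constant 1/N^2) and locally weighted (neighbourhood-pair)
// MMD^2 values, plus the analytic gradients with respect to X and Y under
// the fused weight matrix Ceff. This is the per-epoch hot path of training.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat kernel_mat(const mat& X, const mat& Y, double bw2x2) {
  mat D = -2.0 * (X.t() * Y);
  colvec xs = sum(square(X), 0).t();
  rowvec ys = sum(square(Y), 0);
  D.each_col() += xs;
  D.each_row() += ys;
  D.transform([bw2x2](double v) { return std::exp(-(v > 0.0 ? v : 0.0) / bw2x2); });
  return D;
}

// [[Rcpp::export]]
Rcpp::List align_layer_cpp(const arma::mat& X, Rcpp::List Ys, double wg,
                           const arma::uvec& cl_idx, const arma::vec& clx,
                           Rcpp::Nullable<Rcpp::NumericMatrix> Ceff_mat,
                           double ceff_scalar, const arma::vec& bws,
                           double cc, bool want_grad) {
  const uword d = X.n_rows;
  const uword n = X.n_cols;
  const int npair = Ys.size();
  const bool has_local = cl_idx.n_elem > 0;
  const bool use_cmat = Ceff_mat.isNotNull();
  mat Ceff;
  if (use_cmat) Ceff = Rcpp::as<mat>(Ceff_mat);

  double vg = 0.0, vl = 0.0;
  mat gX(d, n, fill::zeros);
  std::vector<mat> gY(npair);

  for (uword b = 0; b < bws.n_elem; ++b) {
    const double bw2x2 = 2.0 * bws[b] * bws[b];
    const double ib2 = 1.0 / (bws[b] * bws[b]);
    mat Kxx = kernel_mat(X, X, bw2x2);
    const double sKxx = accu(Kxx);
    const double lKxx = has_local ? dot(clx, Kxx.elem(cl_idx)) : 0.0;
    mat gX_xx;
    if (want_grad) {
      mat P = use_cmat ? mat(Ceff % Kxx) : mat(ceff_scalar * Kxx);
      colvec rsP = sum(P, 1);
      gX_xx = 2.0 * ib2 * (X * P - X.each_row() % rsP.t());
    }
    for (int j = 0; j < npair; ++j) {
      mat Y = Rcpp::as<mat>(Ys[j]);
      mat Kxy = kernel_mat(X, Y, bw2x2);
      mat Kyy = kernel_mat(Y, Y, bw2x2);
      vg += wg * (sKxx - cc * accu(Kxy) + accu(Kyy));
      if (has_local)
        vl += lKxx - cc * dot(clx, Kxy.elem(cl_idx)) +
              dot(clx, Kyy.elem(cl_idx));
      if (want_grad) {
        mat Q = use_cmat ? mat(Ceff % Kxy) : mat(ceff_scalar * Kxy);
        mat R = use_cmat ? mat(Ceff % Kyy) : mat(ceff_scalar * Kyy);
        colvec rsQ = sum(Q, 1);
        rowvec csQ = sum(Q, 0);
        colvec rsR = sum(R, 1);
        gX += gX_xx + ib2 * cc * (X.each_row() % rsQ.t() - Y * Q.t());
        mat gYj = ib2 * (2.0 * (Y * R - Y.each_row() % rsR.t()) +
                         cc * (Y.each_row() % csQ - X * Q));
        if (gY[j].n_elem == 0) gY[j] = gYj; else gY[j] += gYj;
      }
    }
  }

  const double nb = static_cast<double>(bws.n_elem);
  Rcpp::List gY_out(npair);
  if (want_grad)
    for (int j = 0; j < npair; ++j) gY_out[j] = mat(gY[j] / nb);
  return Rcpp::List::create(
    Rcpp::Named("vg") = vg / nb,
    Rcpp::Named("vl") = vl / nb,
    Rcpp::Named("gX") = want_grad ? Rcpp::wrap(mat(gX / nb)) : R_NilValue,
    Rcpp::Named("gY") = gY_out);
}
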