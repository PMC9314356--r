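#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-variant logistic regression by iteratively reweighted least squares,
// PLINK-style: one fit per dosage column against a shared covariate design.
//
// C: n x q covariate design (first column should be the intercept)
// G: n x m dosage matrix
// y: binary outcome (resilient = 1)
//
// Status codes: 0 ok, 1 monomorphic, 2 not converged, 3 separation
// (|coefficient| > 20 on the diverging path), 4 singular system.
// [[Rcpp::export]]
List irls_gwas(const arma::mat& C, const arma::mat& G, const arma::vec& y,
               int max_iter = 100, double tol = 1e-8) {
  const arma::uword n = C.n_rows, q = C.n_cols, m = G.n_cols;
  arma::vec beta_out(m, arma::fill::value(NA_REAL));
  arma::vec se_out(m, arma::fill::value(NA_REAL));
  IntegerVector status(m);
  arma::mat X(n, q + 1);
  X.cols(0, q - 1) = C;

  for (arma::uword j = 0; j < m; ++j) {
    arma::vec g = G.col(j);
    if (arma::var(g) <= 0.0) { status[j] = 1; continue; }
    X.col(q) = g;
    arma::vec b(q + 1, arma::fill::zeros);
    int code = 2;
    arma::mat XtWX;
    for (int it = 0; it < max_iter; ++it) {
      arma::vec eta = X * b;
      arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
      arma::vec w = mu % (1.0 - mu);
      // working response
      arma::vec z = eta + (y - mu) / arma::clamp(w, 1e-10, 1.0);
      arma::mat Xw = X.each_col() % w;
      XtWX = X.t() * Xw;
      arma::vec XtWz = Xw.t() * z;
      arma::vec b_new;
      bool ok = arma::solve(b_new, XtWX, XtWz, arma::solve_opts::no_approx);
      if (!ok) { code = 4; break; }
      double delta = arma::abs(b_new - b).max();
      b = b_new;
      if (arma::abs(b).max() > 20.0) { code = 3; break; }
      if (delta < tol) { code = 0; break; }
    }
    status[j] = code;
    if (code == 0) {
      arma::mat cov;
      if (arma::inv_sympd(cov, XtWX)) {
        beta_out(j) = b(q);
        se_out(j) = std::sqrt(cov(q, q));
      } else {
        status[j] = 4;
      }
    }
  }
  return List::create(_["beta"] = beta_out, _["se"] = se_out,
                      _["status"] = status);
}
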