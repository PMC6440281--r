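#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Refit the two-stage mediation model on each bootstrap resample and return
// the product-of-coefficients statistics.
//
// Y (n), X (n), M (n x p), C (n x q, q may be 0); idx (n x B) holds 1-based
// resample row indices (resamples with constant X must have been redrawn by
// the caller). Returns per-resample component products delta* (B x p), their
// sum Delta* (B), and, when include_sme, the single-mediator product
// statistics (B x p) from models that omit the other mediators.
//
// Both stages are ordinary least squares solved via the normal equations;
// the mediator-stage design [1, X, C] is shared across the p mediator
// regressions, and alpha_X is identical between the joint and the
// single-mediator formulations because mediator regressions never involve
// the other mediators.
// [[Rcpp::export]]
Rcpp::List boot_mediation_stats(const arma::vec& Y, const arma::vec& X,
                                const arma::mat& M, const arma::mat& C,
                                const arma::umat& idx, bool include_sme) {
  const uword n = Y.n_elem, p = M.n_cols, q = C.n_cols, B = idx.n_cols;
  if (idx.n_rows != n) Rcpp::stop("idx must have one row per sample");

  mat delta(B, p);
  vec Delta(B);
  mat sme(include_sme ? B : 0, include_sme ? p : 0);

  mat Dmed(n, 2 + q);               // [1, X, C]
  mat Dout(n, 2 + p + q);           // [1, X, M, C]
  mat Dsme(n, 3 + q);               // [1, X, M_j, C]
  Dmed.col(0).ones();
  Dout.col(0).ones();
  Dsme.col(0).ones();

  for (uword b = 0; b < B; ++b) {
    uvec id = idx.col(b) - 1;
    vec Yb = Y(id);
    vec Xb = X(id);
    mat Mb = M.rows(id);

    Dmed.col(1) = Xb;
    Dout.col(1) = Xb;
    if (q > 0) {
      mat Cb = C.rows(id);
      Dmed.cols(2, 1 + q) = Cb;
      Dout.cols(2 + p, 1 + p + q) = Cb;
      Dsme.cols(3, 2 + q) = Cb;
    }
    Dout.cols(2, 1 + p) = Mb;

    mat Amed = solve(Dmed.t() * Dmed, Dmed.t() * Mb);   // (2+q) x p
    rowvec alphaX = Amed.row(1);

    vec bout = solve(Dout.t() * Dout, Dout.t() * Yb);
    rowvec betaM = bout.subvec(2, 1 + p).t();

    delta.row(b) = alphaX % betaM;
    Delta(b) = accu(delta.row(b));

    if (include_sme) {
      Dsme.col(1) = Xb;
      for (uword j = 0; j < p; ++j) {
        Dsme.col(2) = Mb.col(j);
        vec bj = solve(Dsme.t() * Dsme, Dsme.t() * Yb);
        sme(b, j) = alphaX(j) * bj(2);
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("delta") = delta,
                            Rcpp::Named("Delta") = Delta,
                            Rcpp::Named("sme") = sme);
}
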