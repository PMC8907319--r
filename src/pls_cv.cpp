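#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Out-of-fold PLS prediction residuals: for each fold, fit single-response
// NIPALS PLS on the complement (column-centered, no X scaling) and predict
// the held-out rows. Mirrors the R reference implementation pls_cv_resid()
// exactly; that equivalence is asserted in the test suite.
// [[Rcpp::export]]
arma::vec pls_cv_resid_cpp(const arma::mat& X, const arma::vec& y,
                           const arma::ivec& fold_of, const int n_folds,
                           const int ncomp) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec resid(n, arma::fill::zeros);
  for (int k = 1; k <= n_folds; ++k) {
    arma::uvec te = arma::find(fold_of == k);
    arma::uvec tr = arma::find(fold_of != k);
    arma::mat E = X.rows(tr);
    arma::rowvec xbar = arma::mean(E, 0);
    E.each_row() -= xbar;
    arma::vec f = y.elem(tr);
    double ybar = arma::mean(f);
    f -= ybar;
    const arma::uword ntr = tr.n_elem;
    arma::uword a_max = std::min<arma::uword>(
        ncomp, std::min<arma::uword>(ntr - 1, p));
    arma::mat W(p, a_max), P(p, a_max);
    arma::vec Q(a_max);
    arma::uword ad = 0;
    for (arma::uword a = 0; a < a_max; ++a) {
      arma::vec w = E.t() * f;
      double nw = arma::norm(w);
      if (nw < 1e-14) break;
      w /= nw;
      arma::vec t = E * w;
      double t2 = arma::dot(t, t);
      if (t2 < 1e-14) break;
      arma::vec pa = E.t() * t / t2;
      double qa = arma::dot(f, t) / t2;
      E -= t * pa.t();
      f -= qa * t;
      W.col(a) = w;
      P.col(a) = pa;
      Q(a) = qa;
      ad = a + 1;
    }
    if (ad == 0) {
      resid.elem(te) = ybar - y.elem(te);
    } else {
      arma::mat Wa = W.head_cols(ad), Pa = P.head_cols(ad);
      arma::vec B = Wa * arma::solve(Pa.t() * Wa, Q.head(ad));
      arma::vec pred = X.rows(te) * B + (ybar - arma::dot(xbar, B));
      resid.elem(te) = pred - y.elem(te);
    }
  }
  return resid;
}

// Residuals for every latent-variable truncation 1..max_comp in one NIPALS
// pass per fold: column a-1 of the result holds the out-of-fold residuals
// of the a-component model (columns beyond a fold's extractable rank repeat
// the deepest available truncation). Column a-1 therefore matches
// pls_cv_resid_cpp(..., ncomp = a); asserted in the test suite.
// [[Rcpp::export]]
arma::mat pls_cv_resid_all_cpp(const arma::mat& X, const arma::vec& y,
                               const arma::ivec& fold_of, const int n_folds,
                               const int max_comp) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat resid(n, max_comp, arma::fill::zeros);
  for (int k = 1; k <= n_folds; ++k) {
    arma::uvec te = arma::find(fold_of == k);
    arma::uvec tr = arma::find(fold_of != k);
    arma::mat E = X.rows(tr);
    arma::rowvec xbar = arma::mean(E, 0);
    E.each_row() -= xbar;
    arma::vec f = y.elem(tr);
    double ybar = arma::mean(f);
    f -= ybar;
    const arma::uword ntr = tr.n_elem;
    arma::uword a_max = std::min<arma::uword>(
        max_comp, std::min<arma::uword>(ntr - 1, p));
    arma::mat W(p, a_max), P(p, a_max);
    arma::vec Q(a_max);
    arma::uword ad = 0;
    for (arma::uword a = 0; a < a_max; ++a) {
      arma::vec w = E.t() * f;
      double nw = arma::norm(w);
      if (nw < 1e-14) break;
      w /= nw;
      arma::vec t = E * w;
      double t2 = arma::dot(t, t);
      if (t2 < 1e-14) break;
      arma::vec pa = E.t() * t / t2;
      double qa = arma::dot(f, t) / t2;
      E -= t * pa.t();
      f -= qa * t;
      W.col(a) = w;
      P.col(a) = pa;
      Q(a) = qa;
      ad = a + 1;
    }
    arma::mat Xte = X.rows(te);
    arma::vec yte = y.elem(te);
    arma::vec last = ybar - yte;  // 0-component fallback
    for (int a = 0; a < max_comp; ++a) {
      if (static_cast<arma::uword>(a) < ad) {
        arma::mat Wa = W.head_cols(a + 1), Pa = P.head_cols(a + 1);
        arma::vec B = Wa * arma::solve(Pa.t() * Wa, Q.head(a + 1));
        last = Xte * B + (ybar - arma::dot(xbar, B)) - yte;
      }
      resid.submat(te, arma::uvec{static_cast<arma::uword>(a)}) = last;
    }
  }
  return resid;
}
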