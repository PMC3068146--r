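// Batch cross-validated accuracy of the two-class maximum-likelihood
// discriminant over many gene subsets. This is the genetic algorithm's
// fitness hot path: everything random (fold assignment, chromosome
// proposals) happens on the R side, so results are bit-reproducible and
// this code is purely deterministic numerics.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Pooled-covariance Gaussian discriminant accuracy for one train/test
// split, matching the R reference implementation: empirical priors,
// denominator n - 2, ridge eps*trace/p escalating tenfold from 1e-6 until
// the covariance factorises, ties to the lower class.
static double foldAccuracy(const arma::mat& Xs, const arma::ivec& y,
                           const arma::uvec& train, const arma::uvec& test) {
  const arma::uword p = Xs.n_cols;
  arma::uvec tr0, tr1;
  {
    std::vector<arma::uword> i0, i1;
    for (arma::uword i = 0; i < train.n_elem; ++i) {
      if (y[train[i]] == 0) i0.push_back(train[i]);
      else i1.push_back(train[i]);
    }
    tr0 = arma::uvec(i0); tr1 = arma::uvec(i1);
  }
  const double n0 = tr0.n_elem, n1 = tr1.n_elem, n = n0 + n1;
  arma::rowvec mu0 = arma::mean(Xs.rows(tr0), 0);
  arma::rowvec mu1 = arma::mean(Xs.rows(tr1), 0);
  arma::mat C0 = Xs.rows(tr0); C0.each_row() -= mu0;
  arma::mat C1 = Xs.rows(tr1); C1.each_row() -= mu1;
  arma::mat S = (C0.t() * C0 + C1.t() * C1) / (n - 2.0);

  arma::mat R;
  if (!arma::chol(R, S)) {
    double base = arma::trace(S) / p;
    if (base <= 0) base = 1.0;
    double eps = 1e-6;
    bool ok = false;
    for (int it = 0; it < 24; ++it) {
      arma::mat Sr = S + arma::eye(p, p) * (eps * base);
      if (arma::chol(R, Sr)) { ok = true; break; }
      eps *= 10.0;
    }
    if (!ok) stop("pooled covariance could not be regularised");
  }
  // W_c = S^-1 mu_c via the Cholesky factor
  arma::vec w0 = arma::solve(arma::trimatu(R),
                             arma::solve(arma::trimatl(R.t()), mu0.t()));
  arma::vec w1 = arma::solve(arma::trimatu(R),
                             arma::solve(arma::trimatl(R.t()), mu1.t()));
  double c0 = -0.5 * arma::dot(mu0, w0) + std::log(n0 / n);
  double c1 = -0.5 * arma::dot(mu1, w1) + std::log(n1 / n);

  arma::uword correct = 0;
  for (arma::uword i = 0; i < test.n_elem; ++i) {
    arma::rowvec x = Xs.row(test[i]);
    double d0 = arma::dot(x, w0) + c0;
    double d1 = arma::dot(x, w1) + c1;
    int pred = (d1 > d0) ? 1 : 0;  // tie -> lower class index
    if (pred == y[test[i]]) ++correct;
  }
  return static_cast<double>(correct) / test.n_elem;
}

// [[Rcpp::export(name = ".cppBatchCV")]]
NumericVector cppBatchCV(const arma::mat& X, const arma::ivec& y,
                         const arma::imat& folds, const List& subsets) {
  const int nRep = folds.n_cols;
  NumericVector out(subsets.size());
  for (int m = 0; m < subsets.size(); ++m) {
    IntegerVector g = subsets[m];
    arma::uvec genes(g.size());
    for (int j = 0; j < g.size(); ++j) genes[j] = g[j] - 1;  // 1-based in R
    arma::mat Xs = X.cols(genes);
    double acc = 0.0;
    int nFolds = 0;
    for (int r = 0; r < nRep; ++r) {
      int k = folds.col(r).max();
      for (int f = 1; f <= k; ++f) {
        arma::uvec test = arma::find(folds.col(r) == f);
        arma::uvec train = arma::find(folds.col(r) != f);
        acc += foldAccuracy(Xs, y, train, test);
        ++nFolds;
      }
    }
    out[m] = acc / nFolds;
  }
  return out;
}
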