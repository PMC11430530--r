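#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM:
//   min_w 0.5 * ||w||^2 + C * sum_i max(0, 1 - y_i * w.x_i)
// with the bias absorbed as an appended constant feature (so the bias is
// weakly regularized, as in dual coordinate-descent solvers). Problems here
// are tiny (tens of samples, ~10 features), so plain cyclic passes converge
// in a handful of epochs.
static arma::vec svm_dcd(const arma::mat& X, const arma::vec& y, double C,
                         int max_epochs = 300, double tol = 1e-5) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec w(d, arma::fill::zeros);
  arma::vec Qii(n);
  for (arma::uword i = 0; i < n; ++i) Qii[i] = arma::dot(X.row(i), X.row(i));

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double max_pg = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      if (Qii[i] <= 0.0) continue;
      double G = y[i] * arma::dot(w, X.row(i).t()) - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::abs(PG) > max_pg) max_pg = std::abs(PG);
      if (PG != 0.0) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - G / Qii[i], 0.0), C);
        if (a_new != a_old) {
          w += (a_new - a_old) * y[i] * X.row(i).t();
          alpha[i] = a_new;
        }
      }
    }
    if (max_pg < tol) break;
  }
  return w;
}

// Fit the linear SVM once; returns the weight vector with the bias as the
// last element. y must be coded +1 / -1.
// [[Rcpp::export]]
arma::vec linsvm_weights_cpp(const arma::mat& X, const arma::vec& y,
                             double C) {
  arma::mat Xa(X.n_rows, X.n_cols + 1);
  Xa.cols(0, X.n_cols - 1) = X;
  Xa.col(X.n_cols).ones();
  return svm_dcd(Xa, y, C);
}

// One full pass of balanced leave-one-subject-out decoding.
//   X         : n_subjects x n_channels feature matrix
//   y         : +1 / -1 labels, length n_subjects
//   train_idx : n_train x n_folds matrix of 1-based row indices into X
//   test_idx  : length n_folds, 1-based held-out row per fold
// Per fold: z-score channels on the training rows (zero-variance channels
// are zeroed out), fit the SVM, record the held-out decision value, and
// accumulate the Haufe activation pattern cov(X_train_z) * w.
// Returns decisions (n_folds) and the summed Haufe pattern (n_channels).
// [[Rcpp::export]]
List linsvm_loocv_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::umat& train_idx,
                      const arma::uvec& test_idx, double C,
                      bool standardize, bool haufe) {
  const arma::uword n_folds = test_idx.n_elem;
  const arma::uword n_train = train_idx.n_rows;
  const arma::uword d = X.n_cols;
  arma::vec decisions(n_folds);
  arma::vec haufe_sum(d, arma::fill::zeros);

  arma::mat Xt(n_train, d + 1);
  Xt.col(d).ones();
  arma::vec yt(n_train);

  for (arma::uword f = 0; f < n_folds; ++f) {
    for (arma::uword i = 0; i < n_train; ++i) {
      arma::uword r = train_idx(i, f) - 1;
      Xt(i, arma::span(0, d - 1)) = X.row(r);
      yt[i] = y[r];
    }
    arma::rowvec mu(d, arma::fill::zeros), sg(d, arma::fill::ones);
    if (standardize) {
      mu = arma::mean(Xt.cols(0, d - 1), 0);
      sg = arma::stddev(Xt.cols(0, d - 1), 0, 0);  // n-1 denominator
      for (arma::uword j = 0; j < d; ++j) {
        if (sg[j] <= 0.0 || !std::isfinite(sg[j])) {
          // constant channel in this draw: zero it out
          Xt.col(j).zeros();
          sg[j] = 1.0;
          mu[j] = 0.0;
        } else {
          Xt.col(j) = (Xt.col(j) - mu[j]) / sg[j];
        }
      }
    }
    arma::vec w = svm_dcd(Xt, yt, C);

    arma::rowvec xte = X.row(test_idx[f] - 1);
    double dec = w[d];
    for (arma::uword j = 0; j < d; ++j)
      dec += w[j] * ((xte[j] - mu[j]) / sg[j]);
    decisions[f] = dec;

    if (haufe) {
      arma::mat S = arma::cov(Xt.cols(0, d - 1));  // training covariance
      haufe_sum += S * w.head(d);
    }
  }
  return List::create(_["decisions"] = decisions,
                      _["haufe_sum"] = haufe_sum);
}
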