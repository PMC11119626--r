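// Online Kohonen training core.
//
// Unit ordering is row-major: unit u (0-based) sits at grid position
// (row = u / grid_cols, col = u %% grid_cols).  Best-matching-unit ties are
// broken by taking the first strict minimum in that scan order, i.e. lowest
// row, then lowest column.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int find_bmu(const arma::mat& W, const arma::rowvec& x) {
  const arma::uword n_units = W.n_rows;
  double best = arma::datum::inf;
  int bmu = 0;
  for (arma::uword u = 0; u < n_units; ++u) {
    double d = 0.0;
    for (arma::uword j = 0; j < W.n_cols; ++j) {
      const double diff = W(u, j) - x(j);
      d += diff * diff;
      if (d >= best) break;  // partial-sum pruning cannot flip tie order
    }
    if (d < best) {  // strict: first minimum wins
      best = d;
      bmu = static_cast<int>(u);
    }
  }
  return bmu;
}

// Best-matching unit for each row of X (genes x spots), against W
// (units x spots).  Returns 0-based unit indices and squared distances.
// [[Rcpp::export]]
List bmu_all_cpp(const arma::mat& X, const arma::mat& W) {
  const arma::uword n = X.n_rows;
  IntegerVector unit(n);
  NumericVector dist2(n);
  for (arma::uword g = 0; g < n; ++g) {
    const arma::rowvec x = X.row(g);
    const int u = find_bmu(W, x);
    unit[g] = u;
    double d = 0.0;
    for (arma::uword j = 0; j < W.n_cols; ++j) {
      const double diff = W(u, j) - x(j);
      d += diff * diff;
    }
    dist2[g] = d;
  }
  return List::create(_["unit"] = unit, _["dist2"] = dist2);
}

// Sequential (online) SOM training.
//   X      genes x spots training profiles
//   W      units x spots initial codebook (modified copy returned)
//   order  0-based gene index visited at each step (length = total steps)
//   alpha  learning rate per step
//   radius Gaussian neighbourhood radius per step (in grid units)
// [[Rcpp::export]]
arma::mat som_train_cpp(const arma::mat& X, arma::mat W,
                        const IntegerVector& order,
                        const NumericVector& alpha,
                        const NumericVector& radius,
                        const int grid_rows, const int grid_cols) {
  const int n_units = grid_rows * grid_cols;
  if (W.n_rows != static_cast<arma::uword>(n_units))
    stop("codebook rows do not match grid size");
  if (order.size() != alpha.size() || order.size() != radius.size())
    stop("order, alpha and radius must have one entry per training step");

  std::vector<int> urow(n_units), ucol(n_units);
  for (int u = 0; u < n_units; ++u) {
    urow[u] = u / grid_cols;
    ucol[u] = u % grid_cols;
  }

  const int steps = order.size();
  for (int t = 0; t < steps; ++t) {
    const arma::rowvec x = X.row(order[t]);
    const int bmu = find_bmu(W, x);
    const double a = alpha[t];
    const double sig2 = 2.0 * radius[t] * radius[t];
    for (int u = 0; u < n_units; ++u) {
      const double dr = urow[u] - urow[bmu];
      const double dc = ucol[u] - ucol[bmu];
      const double h = std::exp(-(dr * dr + dc * dc) / sig2);
      if (h < 1e-8) continue;  // fixed cutoff keeps runs deterministic
      const double ah = a * h;
      for (arma::uword j = 0; j < W.n_cols; ++j)
        W(u, j) += ah * (x(j) - W(u, j));
    }
  }
  return W;
}
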