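#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for the lasso in Gram ("covariance update") form:
//   min_beta 0.5 * beta' G beta - c' beta + lambda * ||beta||_1
// which is 0.5 * ||y - X beta||^2 + lambda * ||beta||_1 up to a constant when
// G = X'X and c = X'y. Convergence is declared when the largest scaled
// coefficient move |delta_j| * sqrt(G_jj) in a full sweep drops below tol.
// Columns with G_jj == 0 (constant predictors after centering) stay at zero.
// [[Rcpp::export]]
NumericVector cd_lasso_gram(NumericMatrix G, NumericVector c, double lambda,
                            double tol, int max_iter) {
  const int q = G.ncol();
  if (c.size() != q) stop("dimension mismatch between G and c");
  NumericVector beta(q);
  for (int it = 0; it < max_iter; ++it) {
    double maxdelta = 0.0;
    for (int j = 0; j < q; ++j) {
      const double gjj = G(j, j);
      if (gjj <= 0.0) continue;
      double dot = 0.0;
      for (int k = 0; k < q; ++k) dot += G(j, k) * beta[k];
      const double rj = c[j] - dot + gjj * beta[j];
      double bnew = 0.0;
      if (rj > lambda) bnew = (rj - lambda) / gjj;
      else if (rj < -lambda) bnew = (rj + lambda) / gjj;
      const double d = bnew - beta[j];
      if (d != 0.0) {
        beta[j] = bnew;
        const double ad = std::fabs(d) * std::sqrt(gjj);
        if (ad > maxdelta) maxdelta = ad;
      }
    }
    if (maxdelta < tol) break;
  }
  return beta;
}
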