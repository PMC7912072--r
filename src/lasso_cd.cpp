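#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pathwise cyclic coordinate descent for the lasso
//   min (1/2n) ||y - X b||^2 + lambda ||b||_1
// on pre-standardised features, using covariance updates:
//   C = X'X / n (unit diagonal), g = X'(y - ybar) / n.
// The full gradient vector grad = g - C b is maintained incrementally
// (one axpy over a column of C per coordinate change), so coordinate
// reads and KKT screens are O(1) per coefficient. lambda must be
// non-increasing so warm starts carry over. Returns a p x nlambda
// matrix of standardised-scale coefficients.

static inline double soft(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

// [[Rcpp::export]]
NumericMatrix lasso_cd_path(const NumericMatrix& C, const NumericVector& g,
                            const NumericVector& lambda,
                            double tol, int maxit) {
  const int p = g.size();
  const int nl = lambda.size();
  NumericMatrix out(p, nl);
  std::vector<double> beta(p, 0.0);
  std::vector<double> grad(g.begin(), g.end()); // g - C beta, beta = 0
  std::vector<char> active(p, 0);
  const double* Cp = C.begin();                 // column-major, p x p

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    int it = 0;
    for (;;) {
      // iterate on the current active set until stable
      double maxdiff;
      do {
        maxdiff = 0.0;
        ++it;
        for (int j = 0; j < p; ++j) {
          if (!active[j]) continue;
          const double bj = beta[j];
          const double bnew = soft(grad[j] + bj, lam); // C(j,j) = 1
          const double d = bnew - bj;
          if (d != 0.0) {
            beta[j] = bnew;
            const double* col = Cp + (std::size_t)j * p;
            for (int k = 0; k < p; ++k) grad[k] -= col[k] * d;
            const double ad = std::fabs(d);
            if (ad > maxdiff) maxdiff = ad;
          }
        }
      } while (maxdiff >= tol && it < maxit);

      // KKT screen over inactive coordinates (all have beta = 0)
      int violations = 0;
      for (int j = 0; j < p; ++j) {
        if (active[j]) continue;
        if (std::fabs(grad[j]) > lam + tol) {
          active[j] = 1;
          ++violations;
        }
      }
      if (violations == 0 || it >= maxit) break;
    }
    // coordinates shrunk to exactly zero leave the active set
    for (int j = 0; j < p; ++j)
      if (active[j] && beta[j] == 0.0) active[j] = 0;
    for (int j = 0; j < p; ++j) out(j, l) = beta[j];
  }
  return out;
}
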