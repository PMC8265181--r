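// Graphical LASSO by block coordinate descent (Friedman-style), the inner
// engine of the DSPC network module. Maximizes
//   log det(Theta) - tr(S Theta) - lambda * ||Theta||_1 (off-diagonal)
// over positive-definite Theta. Each column update solves a lasso problem
// on the current working covariance by coordinate descent with an
// incrementally maintained residual.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double softThresh(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glassoCpp")]]
arma::mat glassoCpp(const arma::mat& S, double lambda, int maxit,
                    double tol) {
  const int p = S.n_cols;
  mat W = S + lambda * eye(p, p);
  mat B = zeros(p, p);  // lasso coefficients per column

  double offAvg = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) offAvg += std::fabs(S(i, j));
  offAvg /= std::max(1, p * (p - 1) / 2);
  if (offAvg <= 0.0) offAvg = 1.0;

  uvec idx(p - 1);
  for (int it = 0; it < maxit; ++it) {
    mat Wold = W;
    for (int j = 0; j < p; ++j) {
      int t = 0;
      for (int k = 0; k < p; ++k) if (k != j) idx[t++] = k;
      mat W11 = W.submat(idx, idx);
      vec s12(p - 1), beta(p - 1);
      for (int k = 0; k < p - 1; ++k) {
        s12[k] = S(idx[k], j);
        beta[k] = B(idx[k], j);
      }
      vec r = s12 - W11 * beta;  // residual s12 - W11 beta
      for (int cd = 0; cd < 200; ++cd) {
        double delta = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double rk = r[k] + W11(k, k) * beta[k];
          double bn = softThresh(rk, lambda) / W11(k, k);
          double d = bn - beta[k];
          if (d != 0.0) {
            r -= W11.col(k) * d;
            beta[k] = bn;
            double ad = std::fabs(d);
            if (ad > delta) delta = ad;
          }
        }
        if (delta < tol * offAvg) break;
      }
      vec w12 = W11 * beta;
      for (int k = 0; k < p - 1; ++k) {
        W(idx[k], j) = w12[k];
        W(j, idx[k]) = w12[k];
        B(idx[k], j) = beta[k];
      }
    }
    if (accu(abs(W - Wold)) / std::max(1, p * p) < tol * offAvg) break;
  }

  mat Theta = zeros(p, p);
  for (int j = 0; j < p; ++j) {
    int t = 0;
    for (int k = 0; k < p; ++k) if (k != j) idx[t++] = k;
    double dot = 0.0;
    for (int k = 0; k < p - 1; ++k) dot += W(idx[k], j) * B(idx[k], j);
    double t22 = 1.0 / (W(j, j) - dot);
    Theta(j, j) = t22;
    for (int k = 0; k < p - 1; ++k) Theta(idx[k], j) = -B(idx[k], j) * t22;
  }
  return (Theta + Theta.t()) / 2.0;
}
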