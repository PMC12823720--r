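// Exact (O(n^2)) t-distributed stochastic neighbour embedding.
// Perplexity calibration by bisection on the per-point Gaussian precision,
// early exaggeration, momentum with adaptive gains. Deterministic given seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat squared_distances(const mat& X) {
  vec sq = sum(square(X), 1);
  mat D = repmat(sq, 1, X.n_rows) + repmat(sq.t(), X.n_rows, 1) - 2.0 * (X * X.t());
  D.diag().zeros();
  D.elem(find(D < 0)).zeros();
  return D;
}

// Row-wise conditional probabilities p_{j|i} at the requested perplexity.
static mat conditional_p(const mat& D, double perplexity, double tol = 1e-5) {
  const uword n = D.n_rows;
  const double log_perp = std::log(perplexity);
  mat P(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    double beta = 1.0, beta_min = -datum::inf, beta_max = datum::inf;
    rowvec Di = D.row(i);
    rowvec Pi(n);
    double H = 0.0;
    for (int iter = 0; iter < 64; ++iter) {
      Pi = exp(-Di * beta);
      Pi(i) = 0.0;
      double sumP = accu(Pi);
      if (sumP <= 0) sumP = datum::eps;
      // Shannon entropy of the row distribution
      H = std::log(sumP) + beta * accu(Di % Pi) / sumP;
      Pi /= sumP;
      double diff = H - log_perp;
      if (std::abs(diff) < tol) break;
      if (diff > 0) {
        beta_min = beta;
        beta = std::isinf(beta_max) ? beta * 2.0 : (beta + beta_max) / 2.0;
      } else {
        beta_max = beta;
        beta = std::isinf(beta_min) ? beta / 2.0 : (beta + beta_min) / 2.0;
      }
    }
    P.row(i) = Pi;
  }
  return P;
}

// [[Rcpp::export(name = ".tsne_cpp")]]
arma::mat tsne_cpp(const arma::mat& X, double perplexity, int n_iter,
                   double eta, double exaggeration, int exaggeration_iter,
                   int seed) {
  const uword n = X.n_rows;
  mat D = squared_distances(X);
  mat P = conditional_p(D, perplexity);
  P = (P + P.t()) / (2.0 * n);      // symmetrised joint probabilities
  P.elem(find(P < 1e-12)).fill(1e-12);
  P /= accu(P);

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<double> gauss(0.0, 1e-4);
  mat Y(n, 2), dY(n, 2, fill::zeros), gains(n, 2, fill::ones);
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < 2; ++j) Y(i, j) = gauss(rng);

  mat Pex = P * exaggeration;
  const double momentum_early = 0.5, momentum_late = 0.8;
  mat grad(n, 2);
  for (int iter = 0; iter < n_iter; ++iter) {
    const mat& Pcur = (iter < exaggeration_iter) ? Pex : P;
    const double* y0 = Y.colptr(0);
    const double* y1 = Y.colptr(1);
    // Student-t kernel num_ij = 1 / (1 + ||y_i - y_j||^2). The kernel is
    // symmetric, so only pairs i < j are visited; it is cheap enough to
    // recompute in the gradient pass instead of materialising n x n
    // work matrices.
    double sum_num = 0.0;
    for (uword j = 1; j < n; ++j) {
      const double a0 = y0[j], a1 = y1[j];
      for (uword i = 0; i < j; ++i) {
        double d0 = y0[i] - a0, d1 = y1[i] - a1;
        sum_num += 1.0 / (1.0 + d0 * d0 + d1 * d1);
      }
    }
    sum_num *= 2.0;
    if (sum_num <= 0) sum_num = datum::eps;
    const double inv_sum = 1.0 / sum_num;
    // grad_i = 4 * sum_j (P_ij - Q_ij) * num_ij * (y_i - y_j)
    grad.zeros();
    double* g0 = grad.colptr(0);
    double* g1 = grad.colptr(1);
    for (uword j = 1; j < n; ++j) {
      const double a0 = y0[j], a1 = y1[j];
      const double* pj = Pcur.colptr(j);
      for (uword i = 0; i < j; ++i) {
        double d0 = y0[i] - a0, d1 = y1[i] - a1;
        double v = 1.0 / (1.0 + d0 * d0 + d1 * d1);
        double m = 4.0 * (pj[i] - v * inv_sum) * v;
        g0[i] += m * d0; g0[j] -= m * d0;
        g1[i] += m * d1; g1[j] -= m * d1;
      }
    }

    int switch_iter = n_iter < 500 ? n_iter / 2 : 250;
    double momentum = (iter < switch_iter) ? momentum_early : momentum_late;
    for (uword k = 0; k < 2 * n; ++k) {
      double g = (grad(k) > 0) == (dY(k) > 0) ? gains(k) * 0.8
                                              : gains(k) + 0.2;
      gains(k) = g < 0.01 ? 0.01 : g;
      dY(k) = momentum * dY(k) - eta * gains(k) * grad(k);
    }
    Y += dY;
    Y.each_row() -= mean(Y, 0);
  }
  return Y;
}
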