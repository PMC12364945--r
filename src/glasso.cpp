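// Graphical lasso via blockwise coordinate descent (Friedman-style).
// The diagonal is not penalized: the objective is
//   log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |theta_ij|,
// so the working covariance W keeps diag(W) = diag(S) throughout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One lasso sub-problem by coordinate descent:
//   min_beta 0.5 beta' W11 beta - s12' beta + lambda ||beta||_1
static void lasso_cd(const mat &W11, const vec &s12, vec &beta,
                     double lambda, double inner_tol, int inner_maxit) {
  const uword q = s12.n_elem;
  for (int it = 0; it < inner_maxit; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < q; ++k) {
      double old = beta(k);
      // residual gradient excluding coordinate k
      double num = s12(k) - dot(W11.col(k), beta) + W11(k, k) * old;
      double b = soft(num, lambda) / W11(k, k);
      beta(k) = b;
      double d = std::abs(b - old);
      if (d > dmax) dmax = d;
    }
    if (dmax < inner_tol) break;
  }
}

// Single glasso fit with optional warm starts (W, B modified in place).
// Returns true on convergence.
static bool glasso_core(const mat &S, double lambda, double tol, int maxit,
                        mat &W, mat &B) {
  const uword p = S.n_rows;
  // convergence scale: mean absolute off-diagonal of S
  double sbar = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) sbar += std::abs(S(i, j));
  sbar /= (double)(p * (p - 1));
  double thr = tol * std::max(sbar, 1e-12);

  uvec all = regspace<uvec>(0, p - 1);
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec rest = find(all != j);
      mat W11 = W.submat(rest, rest);
      vec s12 = S.col(j);
      s12 = s12.elem(rest);
      vec beta = B.col(j);
      beta = beta.elem(rest);
      lasso_cd(W11, s12, beta, lambda, thr * 0.01, 1000);
      vec w12 = W11 * beta;
      for (uword k = 0; k < rest.n_elem; ++k) {
        double d = std::abs(W(rest(k), j) - w12(k));
        if (d > dmax) dmax = d;
        W(rest(k), j) = w12(k);
        W(j, rest(k)) = w12(k);
        B(rest(k), j) = beta(k);
      }
    }
    if (dmax < thr) return true;
  }
  return false;
}

static mat theta_from_wb(const mat &S, const mat &W, const mat &B) {
  const uword p = S.n_rows;
  mat Theta(p, p, fill::zeros);
  uvec all = regspace<uvec>(0, p - 1);
  for (uword j = 0; j < p; ++j) {
    uvec rest = find(all != j);
    vec beta = B.col(j);
    beta = beta.elem(rest);
    vec w12 = W.col(j);
    w12 = w12.elem(rest);
    double tjj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = tjj;
    for (uword k = 0; k < rest.n_elem; ++k) {
      Theta(rest(k), j) = -beta(k) * tjj;
    }
  }
  return 0.5 * (Theta + Theta.t());
}

// [[Rcpp::export(name = ".glasso_fit_cpp")]]
Rcpp::List glasso_fit_cpp(const arma::mat &S, double lambda,
                          double tol = 1e-4, int maxit = 200) {
  mat W = S;
  mat B(S.n_rows, S.n_cols, fill::zeros);
  bool conv = glasso_core(S, lambda, tol, maxit, W, B);
  mat Theta = theta_from_wb(S, W, B);
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("converged") = conv);
}

// Warm-started path; lambdas must be sorted decreasing.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat &S, const arma::vec &lambdas,
                           double tol = 1e-4, int maxit = 200) {
  const uword p = S.n_rows, K = lambdas.n_elem;
  cube thetas(p, p, K);
  Rcpp::LogicalVector conv(K);
  mat W = S;
  mat B(p, p, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    conv[k] = glasso_core(S, lambdas(k), tol, maxit, W, B);
    thetas.slice(k) = theta_from_wb(S, W, B);
  }
  return Rcpp::List::create(Rcpp::Named("thetas") = thetas,
                            Rcpp::Named("converged") = conv);
}
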