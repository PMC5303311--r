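// Block coordinate descent for L1-penalized precision matrix estimation with
// an element-wise penalty matrix Lambda (Lambda_ij = lambda * (1 - w_ij)),
// and the per-node lasso used by Meinshausen-Buhlmann neighbor selection.
//
// The column subproblem follows the usual graphical-lasso decomposition:
// holding the current covariance estimate Sig fixed except for row/column j,
// the update solves  min_b 0.5 b' Sig11 b - s12' b + sum_k Lambda_kj |b_k|
// by coordinate descent, then Sig12 <- Sig11 b.  The diagonal of Sig stays
// at S_ii (+ Lambda_ii when the diagonal is penalized) throughout, which is
// the KKT-fixed point of the penalized likelihood.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Coordinate descent for one column subproblem.  `V` plays the role of
// Sig11 (embedded in the full matrix, row/col j skipped), `target` supplies
// the linear term (column j of S), `pen` the per-coordinate penalties.
// beta is a full p-vector with beta[j] pinned to zero.
static void cd_column(const mat& V, const mat& target, const mat& pen,
                      const int j, vec& beta, const double thr,
                      const int max_pass) {
  const int p = V.n_rows;
  vec q(p, fill::zeros);            // q = V * beta, maintained incrementally
  for (int k = 0; k < p; ++k)
    if (beta[k] != 0.0) q += beta[k] * V.col(k);

  std::vector<int> active;
  active.reserve(32);

  bool full_pass = true;
  for (int pass = 0; pass < max_pass; ++pass) {
    double maxdel = 0.0;
    if (full_pass) active.clear();
    const int m = full_pass ? p : (int)active.size();
    for (int idx = 0; idx < m; ++idx) {
      const int k = full_pass ? idx : active[idx];
      if (k == j) continue;
      const double vkk = V(k, k);
      const double bk = beta[k];
      const double grad = target(k, j) - q[k] + vkk * bk;
      const double bnew = soft(grad, pen(k, j)) / vkk;
      const double del = bnew - bk;
      if (del != 0.0) {
        beta[k] = bnew;
        q += del * V.col(k);
        const double ad = std::fabs(del);
        if (ad > maxdel) maxdel = ad;
      }
      if (full_pass && beta[k] != 0.0) active.push_back(k);
    }
    if (maxdel < thr) {
      if (full_pass) break;         // converged on a verified full pass
      full_pass = true;             // active set stable; verify on all coords
    } else {
      full_pass = false;
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_wglasso(const arma::mat& S, const arma::mat& Lambda,
                       const bool pen_diag, const double tol,
                       const int max_iter,
                       Rcpp::Nullable<Rcpp::NumericMatrix> Sigma0,
                       Rcpp::Nullable<Rcpp::NumericMatrix> B0) {
  const int p = S.n_rows;
  vec dfix = S.diag();
  if (pen_diag) dfix += Lambda.diag();

  mat Sig;
  if (Sigma0.isNotNull()) Sig = Rcpp::as<mat>(Sigma0);
  else Sig = S;
  Sig.diag() = dfix;

  mat B(p, p, fill::zeros);
  if (B0.isNotNull()) B = Rcpp::as<mat>(B0);

  const int n_off = p * (p - 1);
  double soff = 0.0;
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i)
      if (i != j) soff += std::fabs(S(i, j));
  soff = (n_off > 0) ? soff / n_off : 0.0;
  const double thr = tol * (soff > 0.0 ? soff : 1.0);
  const double inner_thr = thr / 10.0;

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      vec beta = B.col(j);
      beta[j] = 0.0;
      cd_column(Sig, S, Lambda, j, beta, inner_thr, 1000);
      B.col(j) = beta;
      // Sig12 <- Sig11 * beta (sparse product over nonzero beta)
      vec sig12(p, fill::zeros);
      for (int k = 0; k < p; ++k)
        if (beta[k] != 0.0) sig12 += beta[k] * Sig.col(k);
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        delta += std::fabs(sig12[i] - Sig(i, j));
        Sig(i, j) = sig12[i];
        Sig(j, i) = sig12[i];
      }
      Sig(j, j) = dfix[j];
    }
    if (n_off == 0 || delta / n_off < thr) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  // Recover Theta from the regression coefficients.
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    const vec beta = B.col(j);
    const double denom = Sig(j, j) - dot(Sig.col(j), beta);
    const double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (int i = 0; i < p; ++i)
      if (i != j && beta[i] != 0.0) Theta(i, j) = -beta[i] * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());

  // Penalized negative log-likelihood at Theta.
  double obj = NA_REAL;
  double ldet;
  double sign;
  if (log_det(ldet, sign, Theta) && sign > 0.0) {
    mat L = Lambda;
    if (!pen_diag) L.diag().zeros();
    obj = -ldet + accu(S % Theta) + accu(L % abs(Theta));
  }

  return Rcpp::List::create(
      Rcpp::Named("theta") = Theta,
      Rcpp::Named("sigma") = Sig,
      Rcpp::Named("beta") = B,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("objective") = obj);
}

// Per-node lasso on the Gram matrix G = X'X (columns of X centered, unit
// sum of squares).  Column j of the returned matrix holds the coefficients
// of the regression of variable j on all others at penalty lam.
// [[Rcpp::export]]
arma::mat cpp_ns_coef(const arma::mat& G, const double lam,
                      const double thr, const int max_pass,
                      Rcpp::Nullable<Rcpp::NumericMatrix> B0) {
  const int p = G.n_rows;
  mat B(p, p, fill::zeros);
  if (B0.isNotNull()) B = Rcpp::as<mat>(B0);
  mat pen(p, p);
  pen.fill(lam);
  for (int j = 0; j < p; ++j) {
    vec beta = B.col(j);
    beta[j] = 0.0;
    cd_column(G, G, pen, j, beta, thr, max_pass);
    B.col(j) = beta;
  }
  return B;
}
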