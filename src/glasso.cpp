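// Graphical lasso: L1-penalized (off-diagonal only) Gaussian precision
// estimation by blockwise coordinate descent, with an EBIC-selected path.
//
// Convergence is monitored through the duality gap
//   gap = tr(S K) + lambda * ||K||_{1,off} - p,
// which is zero at the optimum for the off-diagonal-penalized problem.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Coordinate descent for  min_b  0.5 b'Vb - s'b + lambda ||b||_1  where the
// quadratic term V is the current W with row/column `col` logically removed:
// beta(col) is pinned to zero so full-column dot products need no copies.
// One full sweep, then active-set sweeps over the nonzero coordinates.
static void lasso_cd(const mat& W, const vec& scol, vec& beta, uword col,
                     double lambda, int maxit, double tol) {
  const uword p = scol.n_elem;
  beta(col) = 0.0;
  bool full_sweep = true;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (uword j = 0; j < p; ++j) {
      if (j == col) continue;
      const double old = beta(j);
      if (!full_sweep && old == 0.0) continue;
      const double r = scol(j) - dot(W.col(j), beta) + W(j, j) * old;
      double b = 0.0;
      if (r > lambda)
        b = (r - lambda) / W(j, j);
      else if (r < -lambda)
        b = (r + lambda) / W(j, j);
      beta(j) = b;
      const double d = std::fabs(b - old);
      if (d > maxdiff) maxdiff = d;
    }
    if (maxdiff < tol) {
      if (full_sweep) break;      // converged on a verified full sweep
      full_sweep = true;          // active set stable: verify on all coords
    } else {
      full_sweep = false;         // iterate the active set
    }
  }
}

// Reconstruct precision K from the current covariance estimate W and the
// per-column regression coefficients B (exact zeros preserved from B).
static bool precision_from_B(const mat& W, const mat& B, mat& K) {
  const uword p = W.n_rows;
  for (uword j = 0; j < p; ++j) {
    double denom = W(j, j);
    for (uword i = 0; i < p; ++i)
      if (i != j) denom -= W(i, j) * B(i, j);
    if (denom <= 1e-12) return false;
    const double kjj = 1.0 / denom;
    K(j, j) = kjj;
    for (uword i = 0; i < p; ++i)
      if (i != j) K(i, j) = -B(i, j) * kjj;
  }
  K = 0.5 * (K + K.t());  // symmetrize numerical asymmetry
  return true;
}

static double duality_gap(const mat& S, const mat& K, double lambda) {
  const uword p = S.n_rows;
  double gap = accu(S % K) - (double)p;
  for (uword j = 0; j < p; ++j)
    for (uword i = 0; i < p; ++i)
      if (i != j) gap += lambda * std::fabs(K(i, j));
  return gap;
}

// One glasso solve with warm starts carried in W and B.
static bool glasso_solve(const mat& S, double lambda, mat& W, mat& B, mat& K,
                         int maxit, double gap_tol, double& gap, int& iters) {
  const uword p = S.n_rows;
  const int lasso_maxit = 1000;
  const double lasso_tol = 1e-9;
  bool ok = false;
  gap = datum::inf;
  vec beta(p), w12(p);
  for (iters = 0; iters < maxit; ++iters) {
    for (uword j = 0; j < p; ++j) {
      beta = B.col(j);
      lasso_cd(W, S.col(j), beta, j, lambda, lasso_maxit, lasso_tol);
      w12 = W * beta;  // beta(j) == 0, so column j of W never contributes
      for (uword i = 0; i < p; ++i) {
        if (i == j) continue;
        W(i, j) = w12(i);
        W(j, i) = w12(i);
        B(i, j) = beta(i);
      }
    }
    ok = precision_from_B(W, B, K);
    if (!ok) return false;
    gap = duality_gap(S, K, lambda);
    if (std::fabs(gap) < gap_tol) return true;
  }
  return ok;  // ran out of iterations; caller inspects gap
}

// Gaussian profile log-likelihood (n/2)(log det K - tr(SK)); constants dropped.
static double gauss_loglik(const mat& S, const mat& K, double n) {
  double ldet, sign;
  log_det(ldet, sign, K);
  return 0.5 * n * (ldet - accu(S % K));
}

static int edge_count(const mat& P, double edge_tol) {
  const uword p = P.n_rows;
  int E = 0;
  for (uword j = 1; j < p; ++j)
    for (uword i = 0; i < j; ++i)
      if (std::fabs(P(i, j)) > edge_tol) ++E;
  return E;
}

// partial_ij = -K_ij / sqrt(K_ii K_jj), zero diagonal
static mat partial_from_precision(const mat& K) {
  vec d = 1.0 / sqrt(K.diag());
  mat P = -K;
  P.each_col() %= d;
  P.each_row() %= d.t();
  P.diag().zeros();
  P = 0.5 * (P + P.t());
  return P;
}

// [[Rcpp::export]]
Rcpp::List glasso_single_cpp(const arma::mat& S, double lambda,
                             int maxit = 200, double gap_tol = 1e-6) {
  const uword p = S.n_rows;
  mat W = S, B = zeros(p, p), K = zeros(p, p);
  double gap;
  int iters;
  bool ok = glasso_solve(S, lambda, W, B, K, maxit, gap_tol, gap, iters);
  mat P = partial_from_precision(K);
  return Rcpp::List::create(
      Rcpp::Named("precision") = K, Rcpp::Named("cov") = W,
      Rcpp::Named("partial") = P, Rcpp::Named("gap") = gap,
      Rcpp::Named("iters") = iters + 1,
      Rcpp::Named("converged") = ok && std::fabs(gap) < gap_tol);
}

// Fit the path over descending lambdas (warm starts), score each fit by
// EBIC = -2 loglik + E log(n) + 4 E gamma log(p), return all path summaries
// plus the selected (minimum-EBIC; ties to the earlier = sparser fit) model.
// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double n, double gamma, int maxit = 200,
                           double gap_tol = 1e-6, double edge_tol = 1e-10) {
  const uword p = S.n_rows;
  const uword L = lambdas.n_elem;
  mat W = S, B = zeros(p, p), K = zeros(p, p);
  vec ebic(L), loglik(L), gaps(L);
  ivec E(L);
  Rcpp::LogicalVector conv(L);
  mat bestK;
  double best_ebic = datum::inf, best_lambda = NA_REAL;
  int best_idx = -1;

  for (uword l = 0; l < L; ++l) {
    double gap;
    int iters;
    bool ok = glasso_solve(S, lambdas(l), W, B, K, maxit, gap_tol, gap, iters);
    gaps(l) = gap;
    conv(l) = ok && std::fabs(gap) < gap_tol;
    if (!ok) {
      loglik(l) = datum::nan;
      ebic(l) = datum::inf;
      E(l) = NA_INTEGER;
      continue;
    }
    mat P = partial_from_precision(K);
    const int e = edge_count(P, edge_tol);
    const double ll = gauss_loglik(S, K, n);
    loglik(l) = ll;
    E(l) = e;
    ebic(l) = -2.0 * ll + e * std::log(n) + 4.0 * e * gamma * std::log((double)p);
    if (ebic(l) < best_ebic) {  // strict: ties stay with larger lambda
      best_ebic = ebic(l);
      best_idx = (int)l;
      best_lambda = lambdas(l);
      bestK = K;
    }
  }
  if (best_idx < 0) Rcpp::stop("graphical lasso failed at every lambda on the path");
  mat bestP = partial_from_precision(bestK);
  return Rcpp::List::create(
      Rcpp::Named("lambda") = lambdas, Rcpp::Named("ebic") = ebic,
      Rcpp::Named("loglik") = loglik, Rcpp::Named("n_edges") = E,
      Rcpp::Named("gap") = gaps, Rcpp::Named("converged") = conv,
      Rcpp::Named("best_index") = best_idx + 1,
      Rcpp::Named("best_lambda") = best_lambda,
      Rcpp::Named("best_precision") = bestK,
      Rcpp::Named("best_partial") = bestP,
      Rcpp::Named("best_ebic") = best_ebic);
}
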