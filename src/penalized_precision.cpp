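// Penalized precision-matrix solvers.
//
// Both estimators maximize the Gaussian log-likelihood
//   log det(P) - tr(S P)
// minus a penalty on the OFF-DIAGONAL entries of P only:
//   glasso:  lambda1 * sum_{i!=j} |P_ij|
//   gridge:  lambda2 * sum_{i!=j} P_ij^2
// The diagonal is never penalized, so at the optimum the fitted
// covariance W = P^{-1} satisfies diag(W) = diag(S) exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Partial correlations from a precision matrix: -P_ij / sqrt(P_ii P_jj),
// diagonal forced to zero, exact symmetry enforced.
static mat prec_to_parcor(const mat& P) {
  vec d = 1.0 / sqrt(P.diag());
  mat R = -P;
  R.each_col() %= d;
  R.each_row() %= d.t();
  R = 0.5 * (R + R.t());
  R.diag().zeros();
  return R;
}

// Block coordinate-descent graphical lasso (row/column sweeps over the
// fitted covariance W, lasso subproblem per column solved by coordinate
// descent).  Warm-startable through W and B (matrix of column betas).
static void glasso_one(const mat& S, double lambda, double tol, int maxit,
                       int inner_maxit, mat& W, mat& B, int& iters) {
  const uword p = S.n_rows;
  W.diag() = S.diag();            // unpenalized diagonal
  iters = 0;
  if (lambda < 0) Rcpp::stop("lambda1 must be >= 0");
  vec beta(p), grad(p);
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (uword j = 0; j < p; ++j) {
      // lasso subproblem over the full vector with entry j pinned at 0:
      // beta(i != j) solves min 1/2 b' W11 b - s12' b + lambda |b|_1,
      // where W11 is W without row/column j.
      beta = B.col(j);
      beta(j) = 0.0;
      grad = W * beta;            // rows != j give W11 %*% b
      // coordinate descent with active-set sweeps: full passes establish
      // the working set, cheap passes iterate over nonzero coordinates.
      std::vector<uword> act;
      bool full = true;
      for (int inner = 0; inner < inner_maxit; ++inner) {
        double del = 0.0;
        if (full) {
          act.clear();
          for (uword m = 0; m < p; ++m) {
            if (m == j) continue;
            double old = beta(m);
            double r = S(m, j) - (grad(m) - W(m, m) * old);
            double bnew = soft(r, lambda) / W(m, m);
            if (bnew != old) {
              beta(m) = bnew;
              grad += W.col(m) * (bnew - old);
              del = std::max(del, std::fabs(bnew - old));
            }
            if (beta(m) != 0.0) act.push_back(m);
          }
          if (del < tol) break;
          full = false;
        } else {
          for (uword m : act) {
            double old = beta(m);
            double r = S(m, j) - (grad(m) - W(m, m) * old);
            double bnew = soft(r, lambda) / W(m, m);
            if (bnew != old) {
              beta(m) = bnew;
              grad += W.col(m) * (bnew - old);
              del = std::max(del, std::fabs(bnew - old));
            }
          }
          if (del < tol) full = true;  // verify with a full sweep
        }
      }
      grad = W * beta;            // w12 on entries != j
      for (uword m = 0; m < p; ++m) {
        if (m == j) continue;
        double d = std::fabs(W(m, j) - grad(m));
        if (d > maxdiff) maxdiff = d;
        W(m, j) = grad(m);
        W(j, m) = grad(m);
        B(m, j) = beta(m);
      }
    }
    ++iters;
    if (maxdiff < tol) break;
  }
}

// Recover the precision matrix from converged (W, B).
static mat glasso_precision(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat P(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double quad = 0.0;
    for (uword i = 0; i < p; ++i) if (i != j) quad += W(i, j) * B(i, j);
    double pjj = 1.0 / (W(j, j) - quad);
    P(j, j) = pjj;
    for (uword i = 0; i < p; ++i) if (i != j) P(i, j) = -B(i, j) * pjj;
  }
  return 0.5 * (P + P.t());
}

// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol, int maxit, int inner_maxit) {
  const uword p = S.n_rows, nl = lambdas.n_elem;
  // solve from the largest penalty down, warm-starting
  uvec ord = sort_index(lambdas, "descend");
  cube parcor(p, p, nl, fill::zeros);
  cube precision(p, p, nl, fill::zeros);
  ivec iters(nl, fill::zeros);
  mat W = S, B(p, p, fill::zeros);
  for (uword s = 0; s < nl; ++s) {
    uword j = ord(s);
    int it = 0;
    glasso_one(S, lambdas(j), tol, maxit, inner_maxit, W, B, it);
    if (it >= maxit)
      Rcpp::warning("graphical lasso reached the iteration cap (lambda=%g)",
                    lambdas(j));
    mat P = glasso_precision(W, B);
    precision.slice(j) = P;
    parcor.slice(j) = prec_to_parcor(P);
    iters(j) = it;
  }
  return Rcpp::List::create(Rcpp::Named("parcor") = parcor,
                            Rcpp::Named("precision") = precision,
                            Rcpp::Named("iters") = iters);
}

// Ridge-penalized precision by an MM fixed point: the concave term
// -lambda * sum_i P_ii^2 of the off-diagonal-only penalty is linearized
// at the current iterate, and the resulting full-Frobenius-penalty
// subproblem has a closed-form eigenvalue solution.
// One MM subproblem solve: closed-form optimum of the full-Frobenius
// surrogate at linearization point d = diag(P).
static mat gridge_map(const mat& S, double lambda, const vec& d) {
  mat A = S;
  A.diag() -= 2.0 * lambda * d;
  vec a; mat V;
  eig_sym(a, V, A, "dc");
  vec phi = (-a + sqrt(square(a) + 8.0 * lambda)) / (4.0 * lambda);
  return V * diagmat(phi) * V.t();
}

// The MM fixed point only involves diag(P), so iterate on that p-vector
// with SQUAREM extrapolation to accelerate the (linear-rate) plain
// iteration.
static void gridge_one(const mat& S, double lambda, double tol, int maxit,
                       mat& P, int& iters) {
  iters = 0;
  if (lambda < 0) Rcpp::stop("lambda2 must be >= 0");
  if (lambda == 0) {
    P = inv_sympd(S);
    return;
  }
  vec d0 = P.diag();
  while (iters < maxit) {
    mat P1 = gridge_map(S, lambda, d0);
    ++iters;
    vec d1 = P1.diag();
    if (abs(d1 - d0).max() < tol) { P = P1; return; }
    mat P2 = gridge_map(S, lambda, d1);
    ++iters;
    vec d2 = P2.diag();
    if (abs(d2 - d1).max() < tol) { P = P2; return; }
    vec r = d1 - d0;
    vec v = d2 - 2.0 * d1 + d0;
    double alpha = -std::sqrt(dot(r, r) / std::max(dot(v, v), 1e-300));
    if (alpha > -1.0) alpha = -1.0;
    vec dx = d0 - 2.0 * alpha * r + alpha * alpha * v;
    if (!dx.is_finite()) dx = d2;
    mat P3 = gridge_map(S, lambda, dx);
    ++iters;
    if (!P3.is_finite()) { d0 = d2; P = P2; continue; }
    d0 = P3.diag();
    P = P3;
  }
  Rcpp::warning("graphical ridge reached the iteration cap (lambda=%g)",
                lambda);
}

// [[Rcpp::export]]
Rcpp::List gridge_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol, int maxit) {
  const uword p = S.n_rows, nl = lambdas.n_elem;
  uvec ord = sort_index(lambdas, "descend");
  cube parcor(p, p, nl, fill::zeros);
  cube precision(p, p, nl, fill::zeros);
  ivec iters(nl, fill::zeros);
  mat P = eye(p, p);
  for (uword s = 0; s < nl; ++s) {
    uword j = ord(s);
    int it = 0;
    gridge_one(S, lambdas(j), tol, maxit, P, it);
    precision.slice(j) = P;
    parcor.slice(j) = prec_to_parcor(P);
    iters(j) = it;
  }
  return Rcpp::List::create(Rcpp::Named("parcor") = parcor,
                            Rcpp::Named("precision") = precision,
                            Rcpp::Named("iters") = iters);
}
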