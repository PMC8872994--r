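#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares for one right-hand side.
// A is m x n (m >= n, full column rank), b length m. Returns x >= 0 minimising
// ||A x - b||_2.
static vec nnls_single(const mat& A, const vec& b, double tol) {
  const uword n = A.n_cols;
  uvec passive(n, fill::zeros);  // 1 = in passive (free) set
  vec x(n, fill::zeros);
  vec w = A.t() * (b - A * x);

  const uword max_iter = 3 * n;
  uword iter = 0;
  while (true) {
    // termination: all variables passive, or no positive gradient outside
    uvec zset = find(passive == 0);
    if (zset.n_elem == 0) break;
    vec wz = w.elem(zset);
    uword imax_local;
    double wmax = wz.max(imax_local);
    if (wmax <= tol) break;
    passive(zset(imax_local)) = 1;

    while (true) {
      uvec p = find(passive == 1);
      vec zp = solve(A.cols(p), b, solve_opts::fast);
      if (zp.min() > 0) {
        x.zeros();
        x.elem(p) = zp;
        break;
      }
      // step toward zp until a passive variable hits zero
      vec xp = x.elem(p);
      double alpha = datum::inf;
      for (uword k = 0; k < p.n_elem; ++k) {
        if (zp(k) <= 0) {
          double a = xp(k) / (xp(k) - zp(k));
          if (a < alpha) alpha = a;
        }
      }
      x.elem(p) = xp + alpha * (zp - xp);
      for (uword k = 0; k < p.n_elem; ++k) {
        if (x(p(k)) <= tol) { passive(p(k)) = 0; x(p(k)) = 0; }
      }
      if (++iter > max_iter) break;
    }
    w = A.t() * (b - A * x);
    if (++iter > max_iter) break;
  }
  return x;
}

//' @title Non-negative least squares for many right-hand sides
//' @description Solves min ||A x - y||^2 s.t. x >= 0 column-by-column.
//' @param A design matrix (channels x components)
//' @param Y observations (channels x pixels)
//' @return components x pixels matrix of non-negative coefficients
//' @keywords internal
// [[Rcpp::export]]
arma::mat nnls_multi(const arma::mat& A, const arma::mat& Y) {
  const uword n = A.n_cols, N = Y.n_cols;
  mat X(n, N, fill::zeros);

  // Fast path: unconstrained solution via precomputed factorisation; only
  // pixels with a negative coefficient need the active-set solver.
  mat AtA = A.t() * A;
  mat AtY = A.t() * Y;
  mat X0 = solve(AtA, AtY, solve_opts::likely_sympd);
  double tol = 1e-10 * norm(A, "fro");
  for (uword j = 0; j < N; ++j) {
    vec x0 = X0.col(j);
    if (x0.min() >= 0) {
      X.col(j) = x0;
    } else {
      X.col(j) = nnls_single(A, Y.col(j), tol);
    }
  }
  return X;
}
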