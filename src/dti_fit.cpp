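// Voxel-wise diffusion tensor estimation: ordinary, weighted, and robust
// iteratively reweighted least squares on log-signals.
//
// The design matrix X is N x 7: a column of ones (ln S0) and the negated
// b-weighted second-moment direction terms. `freq` carries non-negative
// frequency weights per volume (bootstrap multiplicities); freq = 0 drops a
// volume from the fit entirely.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec wsolve(const mat& X, const vec& y, const vec& w, bool& ok) {
  mat Xw = X.each_col() % w;
  mat A = X.t() * Xw;
  vec b = Xw.t() * y;
  vec beta;
  ok = solve(beta, A, b, solve_opts::no_approx);
  if (!ok) {
    beta = pinv(A) * b;
    ok = beta.is_finite();
  }
  return beta;
}

// [[Rcpp::export(name = ".dti_fit_engine")]]
Rcpp::List dti_fit_engine(const arma::mat& logS,  // N x V
                          const arma::mat& X,     // N x 7
                          const arma::vec& freq,  // N
                          const int method,       // 0 lls, 1 wls, 2 robust
                          const int wls_iter,
                          const int max_iter,
                          const double tol,
                          const double outlier_cutoff) {
  const uword N = X.n_rows, P = X.n_cols, V = logS.n_cols;
  mat coef(P, V, fill::zeros);
  mat wfinal(N, V, fill::ones);
  umat outl(N, V, fill::zeros);
  ivec iters(V, fill::zeros);
  uvec conv(V, fill::ones);

  for (uword v = 0; v < V; ++v) {
    vec y = logS.col(v);
    bool ok = true;
    vec beta = wsolve(X, y, freq, ok); // LLS
    if (!ok) { conv(v) = 0; continue; }

    if (method >= 1) { // WLS: weights = squared predicted signals
      for (int it = 0; it < wls_iter; ++it) {
        vec w = freq % exp(2.0 * (X * beta));
        beta = wsolve(X, y, w, ok);
        if (!ok) break;
      }
      if (!ok) { conv(v) = 0; continue; }
    }

    if (method == 2) { // robust IRLS: WLS x Geman-McClure on scaled residuals
      vec rw(N, fill::ones);
      int it = 0;
      bool converged = false;
      for (it = 0; it < max_iter; ++it) {
        vec pred = X * beta;
        vec r = y - pred;
        // MAD scale over volumes actually in the fit
        uvec act = find(freq > 0);
        vec ra = r.elem(act);
        double s = 1.4826 * median(abs(ra - median(ra)));
        if (s < 1e-12) { rw.ones(); converged = true; break; }
        // Geman-McClure weight with tuning constant c = 3: clean volumes
        // (|r| within ~3 MAD-sigma) keep weight > 0.5, gross outliers are
        // crushed; the 0.1 outlier cutoff then corresponds to |r| > 4.4 sigma
        vec u = r / (3.0 * s);
        rw = 1.0 / square(1.0 + square(u));
        vec w = freq % exp(2.0 * pred) % rw;
        vec beta_new = wsolve(X, y, w, ok);
        if (!ok) break;
        double step = max(abs(beta_new.subvec(1, P - 1) - beta.subvec(1, P - 1)));
        beta = beta_new;
        if (step < tol) { converged = true; ++it; break; }
      }
      iters(v) = it;
      conv(v) = (ok && converged) ? 1 : 0;
      wfinal.col(v) = rw;
      outl.col(v) = (rw < outlier_cutoff);
    }
    coef.col(v) = beta;
    if (method == 1) {
      vec w = exp(2.0 * (X * beta));
      wfinal.col(v) = w / w.max();
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("coef") = coef,
    Rcpp::Named("weights") = wfinal,
    Rcpp::Named("outliers") = outl,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("converged") = conv
  );
}
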