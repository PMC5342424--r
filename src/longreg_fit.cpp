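#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Iteratively reweighted closed-form solver for the longitudinal sparse
// regression
//
//   min_W  sum_t ||X_t W_t - Y||_F^2
//        + theta1 * sum_k sqrt( sum_t ||W_t^k - Wbar^k||^2 + eps )
//        + theta2 * tr( (W(1) W(1)' + eps I)^{1/2} )
//
// where W(1) = [W_1 ... W_T] is the coefficient tensor unfolded along the
// feature dimension and Wbar = (1/T) sum_t W_t.  Each sweep recomputes the
// reweighting matrices from the current W and then solves, for every time
// point, the SPD system
//
//   (X_t' X_t + theta1 D + theta2 Dbb) W_t = X_t' Y + theta1 D Wbar
//
// with D_kk = 1 / (2 sqrt(g_k + eps)) and Dbb = (1/2)(W(1)W(1)' + eps I)^{-1/2}.
// The sweep exactly minimizes a majorizing surrogate of the eps-smoothed
// objective, so the recorded objective trace is non-increasing.

static double objective_terms(const cube& X, const mat& Y, const cube& W,
                              double theta1, double theta2, double epsilon,
                              const vec& g, const vec& lam_eps) {
  double rss = 0.0;
  for (uword t = 0; t < X.n_slices; ++t)
    rss += accu(square(X.slice(t) * W.slice(t) - Y));
  double grp = accu(sqrt(g + epsilon));
  double nuc = accu(sqrt(lam_eps));
  return rss + theta1 * grp + theta2 * nuc;
}

// [[Rcpp::export]]
Rcpp::List fit_longreg_cpp(const arma::cube& X, const arma::mat& Y,
                           double theta1, double theta2,
                           int max_iter, double tol, double epsilon,
                           double ridge_init,
                           const arma::uvec& checkpoints) {
  const uword d = X.n_cols, T = X.n_slices;

  std::vector<mat> XtX(T), XtY(T);
  for (uword t = 0; t < T; ++t) {
    XtX[t] = X.slice(t).t() * X.slice(t);
    XtY[t] = X.slice(t).t() * Y;
  }

  // deterministic per-time ridge initialization
  cube W(d, Y.n_cols, T);
  for (uword t = 0; t < T; ++t) {
    mat A = XtX[t];
    A.diag() += ridge_init;
    mat Wt;
    bool ok = solve(Wt, symmatu(A), XtY[t],
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok)
      Rcpp::stop("initial per-time system is singular; use ridge_init > 0");
    W.slice(t) = Wt;
  }

  std::vector<double> obj;
  obj.reserve(max_iter + 1);
  Rcpp::List snaps;
  std::vector<std::string> snap_names;
  vec lam_final;
  int iters = 0;
  bool converged = false;

  for (int it = 1; it <= max_iter + 1; ++it) {
    // reweighting state of the current W
    mat Wbar = mean(W, 2);
    vec g(d, fill::zeros);
    mat WWt(d, d, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      g += sum(square(W.slice(t) - Wbar), 1);
      WWt += W.slice(t) * W.slice(t).t();
    }
    vec lam;
    mat V;
    if (!eig_sym(lam, V, symmatu(WWt)))
      Rcpp::stop("eigendecomposition of W(1) W(1)' failed");
    vec lam_eps = clamp(lam, 0.0, datum::inf) + epsilon;

    obj.push_back(objective_terms(X, Y, W, theta1, theta2, epsilon, g, lam_eps));
    lam_final = lam_eps;

    if (it == max_iter + 1) break;
    if (tol > 0 && it >= 2) {
      double prev = obj[it - 2], cur = obj[it - 1];
      if (std::abs(prev - cur) / std::max(1.0, std::abs(prev)) < tol) {
        converged = true;
        break;
      }
    }

    vec Ddiag = 1.0 / (2.0 * sqrt(g + epsilon));
    mat Dbb = V * diagmat(0.5 / sqrt(lam_eps)) * V.t();

    for (uword t = 0; t < T; ++t) {
      mat A = XtX[t] + theta2 * Dbb;
      A.diag() += theta1 * Ddiag;
      mat RHS = XtY[t] + theta1 * (Wbar.each_col() % Ddiag);
      mat Wt;
      bool ok = solve(Wt, symmatu(A), RHS,
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok)
        Rcpp::stop("singular system at time %d: with theta1 = theta2 = 0 a "
                   "rank-deficient X_t'X_t cannot be inverted; use "
                   "regularization or ridge_init > 0", (int)(t + 1));
      W.slice(t) = Wt;
    }
    iters = it;

    if (any(checkpoints == (uword)it)) {
      snaps.push_back(Rcpp::wrap(W));
      snap_names.push_back(std::to_string(it));
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("objective") = obj,
      Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("singular_values") =
          arma::sort(sqrt(clamp(lam_final - epsilon, 0.0, datum::inf)),
                     "descend"),
      Rcpp::Named("snapshots") = snaps);
  out["snapshot_iters"] = snap_names;
  return out;
}
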