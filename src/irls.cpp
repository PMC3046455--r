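#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double logistic_loglik(const vec& y, const vec& eta) {
  // sum_i [ y_i * eta_i - log(1 + exp(eta_i)) ], overflow-safe
  double ll = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    double sp = (e > 30.0) ? e : std::log1p(std::exp(e));
    ll += y[i] * e - sp;
  }
  return ll;
}

// Iteratively reweighted least squares for binary logistic regression.
//
// Convergence: max |score component| < tol. Step-halving is applied when a
// full Newton step decreases the log-likelihood. Divergence of any
// coefficient beyond beta_cap with a non-vanishing score is flagged as
// (quasi-)complete separation; a singular weighted information matrix is
// flagged as collinearity. Status codes: 0 converged, 1 max iterations,
// 2 separation, 3 collinear.
//
// [[Rcpp::export]]
Rcpp::List irls_logit_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::vec& start,
                          double tol, int maxit, double beta_cap,
                          bool want_cov) {
  const uword p = X.n_cols;
  vec beta = start;
  vec eta = X * beta;
  double ll = logistic_loglik(y, eta);
  int status = 1;
  int it = 0;
  double smax = datum::inf;

  for (it = 0; it < maxit; ++it) {
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec score = X.t() * (y - mu);
    smax = abs(score).max();
    if (smax < tol) { status = 0; break; }
    if (abs(beta).max() > beta_cap) { status = 2; break; }

    vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
    mat XtWX = X.t() * (X.each_col() % w);
    vec delta;
    bool ok = solve(delta, XtWX, score,
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) { status = 3; break; }

    // accept any step that does not decrease the log-likelihood beyond its
    // own rounding noise; otherwise halve (guards against overshooting far
    // from the optimum without stalling Newton steps near it)
    const double ll_slack = 1e-9 * (std::fabs(ll) + 1.0);
    double step = 1.0;
    bool improved = false;
    for (int h = 0; h < 40; ++h) {
      vec cand = beta + step * delta;
      vec eta_c = X * cand;
      double ll_c = logistic_loglik(y, eta_c);
      if (ll_c >= ll - ll_slack) {
        beta = cand; eta = eta_c; ll = ll_c; improved = true; break;
      }
      step *= 0.5;
    }
    if (!improved) {
      // no ascent direction left at this scale: accept current point as
      // a stationary-enough solution unless the score is clearly nonzero
      status = (smax < std::sqrt(tol)) ? 0 : 1;
      break;
    }
  }

  if (status == 1 && smax < tol) status = 0;
  if (status <= 1 && abs(beta).max() > beta_cap && smax >= tol) status = 2;

  mat cov;
  if (want_cov && status <= 1) {
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
    mat XtWX = X.t() * (X.each_col() % w);
    bool ok = inv_sympd(cov, XtWX);
    if (!ok) {
      bool ok2 = pinv(cov, XtWX);
      if (!ok2) { cov = mat(p, p, fill::value(datum::nan)); status = 3; }
    }
    cov = 0.5 * (cov + cov.t());
  } else {
    cov = mat(0, 0);
  }

  return Rcpp::List::create(
    Rcpp::Named("coefficients") = beta,
    Rcpp::Named("cov") = cov,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("status") = status,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("max_score") = smax);
}

// Fit the same (full, null) design pair for many outcome vectors and return
// the likelihood-ratio statistics. Used by the bootstrap/permutation min-p
// machinery, where only the outcome changes across replicates. Outcomes are
// supplied as an n x B 0/1 matrix. Replicates where either fit does not
// converge get NA.
//
// [[Rcpp::export]]
Rcpp::NumericVector lrt_batch_cpp(const arma::mat& Xfull, const arma::mat& Xnull,
                                  const arma::mat& Y,
                                  const arma::vec& start_full,
                                  const arma::vec& start_null,
                                  double tol, int maxit, double beta_cap) {
  const uword B = Y.n_cols;
  Rcpp::NumericVector out(B);
  for (uword b = 0; b < B; ++b) {
    vec y = Y.col(b);
    Rcpp::List f1 = irls_logit_cpp(Xfull, y, start_full, tol, maxit,
                                   beta_cap, false);
    Rcpp::List f0 = irls_logit_cpp(Xnull, y, start_null, tol, maxit,
                                   beta_cap, false);
    int s1 = f1["status"], s0 = f0["status"];
    if (s1 != 0 || s0 != 0) { out[b] = NA_REAL; continue; }
    double stat = 2.0 * (Rcpp::as<double>(f1["loglik"]) -
                         Rcpp::as<double>(f0["loglik"]));
    out[b] = stat > 0.0 ? stat : 0.0;
  }
  return out;
}
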