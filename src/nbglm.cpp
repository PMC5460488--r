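// Batch IRLS fitting of negative-binomial log-linear models with fixed
// per-gene dispersion, shared design matrix and offsets.  One small WLS
// solve per iteration per gene; all genes in one C++ loop.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double nb_deviance(const vec& y, const vec& mu, double theta) {
  double dev = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    double yi = y[i], mui = mu[i];
    double a = (yi > 0.0) ? yi * std::log(yi / mui) : 0.0;
    double b = (yi + theta) * std::log((yi + theta) / (mui + theta));
    dev += 2.0 * (a - b);
  }
  return dev;
}

// Y: samples x genes counts; X: samples x p design; offset: samples;
// theta: per-gene NB size (1/dispersion).  Returns per-gene deviance,
// convergence flag, and (optionally) coefficients with Wald SEs.
// [[Rcpp::export]]
Rcpp::List nbglm_fit_batch(const arma::mat& Y, const arma::mat& X,
                           const arma::vec& offset, const arma::vec& theta,
                           bool want_coef = false, int maxit = 60,
                           double tol = 1e-8) {
  const uword n = Y.n_rows, G = Y.n_cols, p = X.n_cols;
  vec deviance(G, fill::value(datum::nan));
  Rcpp::LogicalVector converged(G);
  mat coef, se;
  if (want_coef) {
    coef.set_size(p, G); coef.fill(datum::nan);
    se.set_size(p, G);   se.fill(datum::nan);
  }

  for (uword g = 0; g < G; ++g) {
    vec y = Y.col(g);
    double th = theta[g];
    // initialise at a damped version of the observed counts
    double ybar = mean(y);
    if (ybar <= 0.0) { converged[g] = false; continue; }
    vec mu = (y + ybar) / 2.0;
    vec eta = log(mu);
    double dev = nb_deviance(y, mu, th);
    bool ok = false;
    vec beta(p, fill::zeros);
    mat XtWX(p, p);
    for (int it = 0; it < maxit; ++it) {
      vec w = mu / (1.0 + mu / th);          // mu^2 / (mu + mu^2/theta)
      vec z = (eta - offset) + (y - mu) / mu;
      mat Xw = X.each_col() % w;
      XtWX = X.t() * Xw;
      vec Xtwz = Xw.t() * z;
      bool solved = solve(beta, XtWX, Xtwz, solve_opts::likely_sympd + solve_opts::no_approx);
      if (!solved) { ok = false; break; }
      eta = offset + X * beta;
      eta = clamp(eta, -30.0, 30.0);
      mu = exp(eta);
      double devnew = nb_deviance(y, mu, th);
      if (std::abs(devnew - dev) < tol * (std::abs(devnew) + 0.1)) {
        dev = devnew; ok = true; break;
      }
      dev = devnew;
    }
    converged[g] = ok;
    if (ok) {
      deviance[g] = dev;
      if (want_coef) {
        mat cov;
        if (inv_sympd(cov, XtWX)) {
          coef.col(g) = beta;
          se.col(g) = sqrt(cov.diag());
        }
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("deviance") = deviance,
    Rcpp::Named("converged") = converged);
  if (want_coef) {
    out["coef"] = coef;
    out["se"] = se;
  }
  return out;
}
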