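// Gaussian-conjugate Gibbs sampler for the weighted Bayesian linear model
// with independent Gaussian random-effect blocks:
//
//   y_i ~ N(x_i' beta + sum_r u_r[g_r(i)], sigma^2 / w_i)
//   beta_j ~ N(0, s_beta^2)            (s_beta = Inf gives a flat prior)
//   u_r[g] ~ N(0, tau_r^2)
//   sigma, tau_r ~ half-Normal(0, c^2)
//
// Row weights w_i multiply each row's log-likelihood contribution
// (pseudo-likelihood).  beta and each random-effect block have conjugate
// Gaussian full conditionals; the standard deviations are updated by
// univariate slice sampling on the log scale.  Conditional (Rao-
// Blackwellised) means of beta are stored alongside the draws.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Univariate slice sampler (Neal 2003, stepping out + shrinkage) on a
// bounded interval [lb, ub].
template <typename F>
static double slice_sample(F logf, double x0, double width, double lb,
                           double ub) {
  double f0 = logf(x0);
  double yslice = f0 - R::rexp(1.0);
  double L = x0 - width * R::unif_rand();
  double Rg = L + width;
  int m = 50;
  while (m-- > 0 && L > lb && logf(L) > yslice) L -= width;
  if (L < lb) L = lb;
  m = 50;
  while (m-- > 0 && Rg < ub && logf(Rg) > yslice) Rg += width;
  if (Rg > ub) Rg = ub;
  for (int k = 0; k < 100; ++k) {
    double x1 = L + (Rg - L) * R::unif_rand();
    if (logf(x1) >= yslice) return x1;
    if (x1 < x0) L = x1; else Rg = x1;
  }
  return x0;  // degenerate slice: keep the current value
}

// [[Rcpp::export]]
Rcpp::List gibbs_lmm_cpp(const arma::vec& y, const arma::mat& X,
                         const arma::vec& w, const Rcpp::List& re_index,
                         const Rcpp::IntegerVector& re_nlevels,
                         int n_iter, int n_warmup, double prior_sd_coef,
                         double prior_sd_sigma, double prior_sd_re) {
  const uword n = y.n_elem, p = X.n_cols;
  const int R_blocks = re_index.size();
  const double coef_prec =
      std::isfinite(prior_sd_coef) ? 1.0 / (prior_sd_coef * prior_sd_coef)
                                   : 0.0;
  const double th_lb = std::log(1e-6), th_ub = std::log(1e6);

  mat XtWX = X.t() * (X.each_col() % w);
  const double wsum = accu(w);

  // random-effect bookkeeping
  std::vector<uvec> idx(R_blocks);
  std::vector<vec> sumw(R_blocks);
  std::vector<vec> u(R_blocks);
  vec tau(R_blocks > 0 ? R_blocks : 1, fill::ones);
  for (int r = 0; r < R_blocks; ++r) {
    Rcpp::IntegerVector gi = re_index[r];
    idx[r].set_size(n);
    for (uword i = 0; i < n; ++i) idx[r][i] = gi[i] - 1;
    sumw[r] = zeros<vec>(re_nlevels[r]);
    for (uword i = 0; i < n; ++i) sumw[r][idx[r][i]] += w[i];
    u[r] = zeros<vec>(re_nlevels[r]);
  }

  // initial values: ridge least squares, residual SD
  mat A0 = XtWX + (coef_prec + 1e-8) * eye<mat>(p, p);
  vec beta = solve(A0, X.t() * (w % y), solve_opts::likely_sympd);
  vec eta = X * beta;
  double sse = accu(w % square(y - eta));
  double sigma = std::max(std::sqrt(sse / std::max(wsum, 1.0)), 1e-3);

  const int n_keep = n_iter - n_warmup;
  mat beta_draws(n_keep, p), beta_cmean(n_keep, p);
  vec sigma_draws(n_keep);
  mat tau_draws(n_keep, std::max(R_blocks, 1));
  std::vector<mat> u_draws(R_blocks);
  for (int r = 0; r < R_blocks; ++r)
    u_draws[r].set_size(n_keep, re_nlevels[r]);

  vec re_all = zeros<vec>(n);

  for (int it = 0; it < n_iter; ++it) {
    double sig2 = sigma * sigma;

    // beta | rest
    re_all.zeros();
    for (int r = 0; r < R_blocks; ++r)
      for (uword i = 0; i < n; ++i) re_all[i] += u[r][idx[r][i]];
    vec rhs = X.t() * (w % (y - re_all)) / sig2;
    mat A = XtWX / sig2;
    A.diag() += coef_prec;
    mat Rch = chol(A);
    vec bmean = solve(trimatu(Rch), solve(trimatl(Rch.t()), rhs));
    vec z(p);
    for (uword j = 0; j < p; ++j) z[j] = R::norm_rand();
    beta = bmean + solve(trimatu(Rch), z);
    eta = X * beta;

    // random-effect blocks | rest
    vec res = y - eta - re_all;
    for (int r = 0; r < R_blocks; ++r) {
      const uvec& g = idx[r];
      vec S = zeros<vec>(u[r].n_elem);
      for (uword i = 0; i < n; ++i) {
        res[i] += u[r][g[i]];            // remove own block from residual
        S[g[i]] += w[i] * res[i];
      }
      double tau2 = tau[r] * tau[r];
      for (uword k = 0; k < u[r].n_elem; ++k) {
        double prec = sumw[r][k] / sig2 + 1.0 / tau2;
        double m = (S[k] / sig2) / prec;
        u[r][k] = m + R::norm_rand() / std::sqrt(prec);
      }
      for (uword i = 0; i < n; ++i) res[i] -= u[r][g[i]];
    }

    // sigma | rest  (slice on log scale; half-Normal(0, c^2) prior)
    double ssr = accu(w % square(res));
    {
      const double c2 = prior_sd_sigma * prior_sd_sigma;
      auto logf = [&](double th) {
        double pr = std::isfinite(prior_sd_sigma)
                        ? -std::exp(2.0 * th) / (2.0 * c2) : 0.0;
        return -(wsum - 1.0) * th - ssr * std::exp(-2.0 * th) / 2.0 + pr;
      };
      sigma = std::exp(slice_sample(logf, std::log(sigma), 1.0, th_lb, th_ub));
    }

    // tau_r | rest
    for (int r = 0; r < R_blocks; ++r) {
      double ssu = accu(square(u[r]));
      double L = static_cast<double>(u[r].n_elem);
      const double c2 = prior_sd_re * prior_sd_re;
      auto logf = [&](double th) {
        double pr = std::isfinite(prior_sd_re)
                        ? -std::exp(2.0 * th) / (2.0 * c2) : 0.0;
        return -(L - 1.0) * th - ssu * std::exp(-2.0 * th) / 2.0 + pr;
      };
      tau[r] = std::exp(slice_sample(logf, std::log(tau[r]), 1.0, th_lb,
                                     th_ub));
    }

    if (it >= n_warmup) {
      int k = it - n_warmup;
      beta_draws.row(k) = beta.t();
      beta_cmean.row(k) = bmean.t();
      sigma_draws[k] = sigma;
      for (int r = 0; r < R_blocks; ++r) {
        tau_draws(k, r) = tau[r];
        u_draws[r].row(k) = u[r].t();
      }
    }
  }

  Rcpp::List u_out(R_blocks);
  for (int r = 0; r < R_blocks; ++r) u_out[r] = u_draws[r];
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta_draws,
      Rcpp::Named("beta_condmean") = beta_cmean,
      Rcpp::Named("sigma") = sigma_draws,
      Rcpp::Named("tau") = tau_draws,
      Rcpp::Named("u") = u_out);
}
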