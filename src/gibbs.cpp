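#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gibbs sampler for the Gaussian multi-kernel model
//
//   y = X beta + sum_k U_k b_k + e,   b_k ~ N(0, s2[k] * D_k),
//   e ~ N(0, s2e * I)
//
// where each random term's kernel has been eigendecomposed as
// K_k = U_k diag(d_k) U_k' with orthonormal columns (U_k' U_k = I), so
// every full conditional for b_k is diagonal.  beta carries a flat prior
// (ridge 1e-8 relative jitter on X'X for rank safety); variances carry
// scaled-inverse-chi-square priors s2 ~ S0 / chisq(df0).  Entries of y
// flagged missing are imputed from N(fitted, s2e) each iteration; the
// reported prediction is the running posterior mean of the fitted value
// (the conditional mean of the imputed draw).
//
// All randomness comes from R's RNG, so set.seed() on the R side makes
// the whole run reproducible.
//
// [[Rcpp::export]]
Rcpp::List gibbs_kernel_sampler(const arma::vec& y0,
                                const arma::uvec& miss,      // 0/1 per record
                                const arma::mat& X,
                                const Rcpp::List& U_list,
                                const Rcpp::List& d_list,
                                int n_iter, int burn_in, int thin,
                                double df0, const arma::vec& S0,
                                double dfe0, double S0e,
                                bool fix_variances,
                                const arma::vec& s2_init,
                                double s2e_init) {
  const int n = y0.n_elem;
  const int K = U_list.size();
  const int p = X.n_cols;

  if (n_iter <= burn_in)
    Rcpp::stop("n_iter must exceed burn_in");

  std::vector<mat> U(K);
  std::vector<vec> d(K);
  for (int k = 0; k < K; ++k) {
    U[k] = Rcpp::as<mat>(U_list[k]);
    d[k] = Rcpp::as<vec>(d_list[k]);
  }

  // flat-prior beta: precompute Cholesky of X'X (+ tiny relative ridge)
  mat XtX = X.t() * X;
  double ridge = 1e-8 * std::max(1.0, XtX.diag().max());
  XtX.diag() += ridge;
  mat R_chol = chol(XtX);  // upper: XtX = R'R

  uvec miss_idx = find(miss == 1);
  uvec obs_idx  = find(miss == 0);
  if (obs_idx.n_elem == 0) Rcpp::stop("all records are masked");

  vec y = y0;
  double ybar = mean(y.elem(obs_idx));
  y.elem(miss_idx).fill(ybar);

  vec beta(p, fill::zeros);
  beta(0) = ybar;  // column 1 is the intercept by construction
  std::vector<vec> b(K), g(K);
  for (int k = 0; k < K; ++k) {
    b[k] = vec(d[k].n_elem, fill::zeros);
    g[k] = vec(n, fill::zeros);
  }
  vec s2 = s2_init;
  double s2e = s2e_init;

  vec e = y - X * beta;

  // accumulators (posterior means and spread of stored samples)
  vec beta_sum(p, fill::zeros);
  std::vector<vec> g_sum(K, vec(n, fill::zeros));
  vec s2_sum(K, fill::zeros), s2_sumsq(K, fill::zeros);
  double s2e_sum = 0.0, s2e_sumsq = 0.0;
  vec fit_sum(n, fill::zeros), fit_sumsq(n, fill::zeros);
  int n_saved = 0;

  Rcpp::RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects (flat prior) ---
    e += X * beta;
    vec rhs = X.t() * e;
    vec bmean = solve(trimatu(R_chol), solve(trimatl(R_chol.t()), rhs));
    vec z(p);
    for (int j = 0; j < p; ++j) z(j) = norm_rand();
    beta = bmean + std::sqrt(s2e) * solve(trimatu(R_chol), z);
    e -= X * beta;

    // --- kernel terms ---
    for (int k = 0; k < K; ++k) {
      const int r = d[k].n_elem;
      e += g[k];
      vec v = U[k].t() * e;
      double ssk = 0.0;
      for (int j = 0; j < r; ++j) {
        double cj = 1.0 / (1.0 / s2e + 1.0 / (s2(k) * d[k](j)));
        double bj = cj * v(j) / s2e + std::sqrt(cj) * norm_rand();
        b[k](j) = bj;
        ssk += bj * bj / d[k](j);
      }
      g[k] = U[k] * b[k];
      e -= g[k];
      if (!fix_variances) {
        s2(k) = (S0(k) + ssk) / R::rchisq(df0 + r);
        if (!std::isfinite(s2(k)) || s2(k) <= 0.0)
          Rcpp::stop("divergent variance draw for kernel term %d", k + 1);
      }
    }

    // --- residual variance ---
    if (!fix_variances) {
      s2e = (S0e + dot(e, e)) / R::rchisq(dfe0 + n);
      if (!std::isfinite(s2e) || s2e <= 0.0)
        Rcpp::stop("divergent residual variance draw");
    }

    // --- impute masked records ---
    double sde = std::sqrt(s2e);
    for (uword ii = 0; ii < miss_idx.n_elem; ++ii) {
      uword i = miss_idx(ii);
      double fit_i = y(i) - e(i);
      double ynew = fit_i + sde * norm_rand();
      y(i) = ynew;
      e(i) = ynew - fit_i;
    }

    // --- accumulate ---
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      vec fit = y - e;
      beta_sum += beta;
      for (int k = 0; k < K; ++k) g_sum[k] += g[k];
      s2_sum += s2; s2_sumsq += s2 % s2;
      s2e_sum += s2e; s2e_sumsq += s2e * s2e;
      fit_sum += fit; fit_sumsq += fit % fit;
      ++n_saved;
    }
  }

  double ns = static_cast<double>(n_saved);
  Rcpp::List g_means(K);
  for (int k = 0; k < K; ++k) g_means[k] = g_sum[k] / ns;
  vec s2_mean = s2_sum / ns;
  vec s2_sd = sqrt(clamp(s2_sumsq / ns - s2_mean % s2_mean, 0.0, datum::inf));
  double s2e_mean = s2e_sum / ns;
  double s2e_sd = std::sqrt(std::max(0.0, s2e_sumsq / ns - s2e_mean * s2e_mean));
  vec fit_mean = fit_sum / ns;
  vec fit_sd = sqrt(clamp(fit_sumsq / ns - fit_mean % fit_mean, 0.0, datum::inf));

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta_sum / ns,
    Rcpp::Named("effects") = g_means,
    Rcpp::Named("s2") = s2_mean,
    Rcpp::Named("s2_sd") = s2_sd,
    Rcpp::Named("s2e") = s2e_mean,
    Rcpp::Named("s2e_sd") = s2e_sd,
    Rcpp::Named("fitted") = fit_mean,
    Rcpp::Named("fitted_sd") = fit_sd,
    Rcpp::Named("n_saved") = n_saved);
}
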