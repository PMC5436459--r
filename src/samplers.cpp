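#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inverse-Gaussian draw, Michael/Schucany/Haas. Uses R's RNG so that
// set.seed() in the calling R session makes chains reproducible.
static double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0 || !R_finite(x)) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Single-site Gibbs sampler for the marker-effect model
//   y = 1*mu + X g + e,  e ~ N(0, sigma2_e I)
// model = 0: BayesA  — g_j ~ N(0, sigma2_j), sigma2_j ~ scaled-inv-chi2(df, S)
// model = 1: BL      — g_j ~ N(0, sigma2_e * tau2_j), tau2_j ~ Exp(lambda2/2),
//                      lambda2 ~ Gamma(shape, rate) (optional)
// fix_* arguments are test hooks: NA (or length-0 tau2) leaves the variances
// stochastic; a finite value freezes them so the conditional mean of g can be
// checked against the (weighted-)ridge closed form.
// [[Rcpp::export(name = ".gibbs_marker_sampler")]]
List gibbs_marker_sampler(const NumericMatrix& X, const NumericVector& y,
                          int n_iter, int burn_in, int model,
                          double df_marker, double scale_marker, double df_e,
                          double scale_e, double lambda2_shape,
                          double lambda2_rate, double lambda2_init,
                          bool sample_lambda2, double fix_sigma2_marker,
                          double fix_sigma2_e, NumericVector fix_tau2,
                          bool keep_samples, int sample_thin) {
  const int n = X.nrow(), m = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");

  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  const bool fixed_g_var = R_finite(fix_sigma2_marker);
  const bool fixed_e_var = R_finite(fix_sigma2_e);
  const bool fixed_tau2 = fix_tau2.size() > 0;

  double ybar = mean(y);
  double vy = 0.0;
  for (int i = 0; i < n; ++i) vy += (y[i] - ybar) * (y[i] - ybar);
  vy = (n > 1) ? vy / (n - 1) : 1.0;
  if (vy <= 0.0) vy = 1.0;

  double mu = ybar;
  double sigma2_e = fixed_e_var ? fix_sigma2_e : 0.5 * vy;
  double lambda2 = lambda2_init;
  std::vector<double> g(m, 0.0), sigma2_g(m), tau2(m);
  for (int j = 0; j < m; ++j) {
    sigma2_g[j] = fixed_g_var ? fix_sigma2_marker : scale_marker;
    tau2[j] = fixed_tau2 ? fix_tau2[j % fix_tau2.size()] : 1.0;
  }
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> g_sum(m, 0.0), g_sumsq(m, 0.0);
  double mu_sum = 0.0, s2e_sum = 0.0, lambda2_sum = 0.0;
  std::vector<double> s2g_sum(m, 0.0);
  int n_kept = 0;

  int n_samples = keep_samples ? (n_iter - burn_in + sample_thin - 1) / sample_thin : 0;
  NumericMatrix g_samples(keep_samples ? n_samples : 0, keep_samples ? m : 0);
  NumericVector mu_samples(keep_samples ? n_samples : 0);
  int sample_row = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // intercept, flat prior
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += e[i] + mu;
    double mu_new = acc / n + R::norm_rand() * std::sqrt(sigma2_e / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // marker effects, fixed index order for reproducibility
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) { g[j] = 0.0; continue; }
      const double* xj = &X(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      rhs += xtx[j] * g[j];
      double prior_prec =
          (model == 0) ? sigma2_e / sigma2_g[j] : 1.0 / tau2[j];
      double C = xtx[j] + prior_prec;
      double gnew = rhs / C + R::norm_rand() * std::sqrt(sigma2_e / C);
      double diff = gnew - g[j];
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * diff;
      g[j] = gnew;
    }

    // marker-specific variances / scale mixtures
    if (model == 0) {
      if (!fixed_g_var)
        for (int j = 0; j < m; ++j)
          sigma2_g[j] = (df_marker * scale_marker + g[j] * g[j]) /
                        R::rchisq(df_marker + 1.0);
    } else {
      if (!fixed_tau2) {
        for (int j = 0; j < m; ++j) {
          double g2 = g[j] * g[j];
          if (g2 < 1e-14) g2 = 1e-14;
          double itau = rinvgauss(std::sqrt(lambda2 * sigma2_e / g2), lambda2);
          tau2[j] = 1.0 / itau;
        }
      }
      if (sample_lambda2) {
        double sum_tau2 = 0.0;
        for (int j = 0; j < m; ++j) sum_tau2 += tau2[j];
        lambda2 = R::rgamma(lambda2_shape + m,
                            1.0 / (lambda2_rate + 0.5 * sum_tau2));
      }
    }

    // residual variance
    if (!fixed_e_var) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += e[i] * e[i];
      double df_post = df_e + n;
      if (model == 1) {  // the BL prior on g involves sigma2_e
        for (int j = 0; j < m; ++j) ss += g[j] * g[j] / tau2[j];
        df_post += m;
      }
      sigma2_e = (df_e * scale_e + ss) / R::rchisq(df_post);
    }

    if (!R_finite(sigma2_e) || !R_finite(mu))
      stop("Gibbs chain diverged (non-finite state at iteration %d)", it + 1);

    if (it >= burn_in) {
      ++n_kept;
      mu_sum += mu;
      s2e_sum += sigma2_e;
      lambda2_sum += lambda2;
      for (int j = 0; j < m; ++j) {
        g_sum[j] += g[j];
        g_sumsq[j] += g[j] * g[j];
        s2g_sum[j] += (model == 0) ? sigma2_g[j] : tau2[j];
      }
      if (keep_samples && (it - burn_in) % sample_thin == 0 &&
          sample_row < n_samples) {
        for (int j = 0; j < m; ++j) g_samples(sample_row, j) = g[j];
        mu_samples[sample_row] = mu;
        ++sample_row;
      }
    }
  }

  NumericVector g_mean(m), g_sd(m), s2g_mean(m);
  for (int j = 0; j < m; ++j) {
    g_mean[j] = g_sum[j] / n_kept;
    double v = g_sumsq[j] / n_kept - g_mean[j] * g_mean[j];
    g_sd[j] = std::sqrt(v > 0.0 ? v : 0.0);
    s2g_mean[j] = s2g_sum[j] / n_kept;
  }

  List out = List::create(
      _["g_mean"] = g_mean, _["g_sd"] = g_sd, _["mu_mean"] = mu_sum / n_kept,
      _["sigma2_e_mean"] = s2e_sum / n_kept, _["scale_mean"] = s2g_mean,
      _["lambda2_mean"] = lambda2_sum / n_kept, _["n_kept"] = n_kept);
  if (keep_samples) {
    out["g_samples"] = g_samples;
    out["mu_samples"] = mu_samples;
  }
  return out;
}
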