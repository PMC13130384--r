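#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Log posterior (up to a constant) for the independent logistic
// efficacy/toxicity models with normal priors.  counts has one row per
// dose: n, y_eff, y_tox.  theta = (mu_eff, beta_eff1, beta_eff2,
// mu_tox, beta_tox).
static double log_post(const double *th,
                       const NumericMatrix &counts,
                       const NumericVector &fd,
                       const NumericVector &pmean,
                       const NumericVector &psd) {
  double lp = 0.0;
  for (int p = 0; p < 5; ++p) {
    double z = (th[p] - pmean[p]) / psd[p];
    lp -= 0.5 * z * z;
  }
  int k = counts.nrow();
  for (int j = 0; j < k; ++j) {
    double n = counts(j, 0);
    if (n == 0.0) continue;
    double f = fd[j];
    double etaE = th[0] + th[1] * f + th[2] * f * f;
    double etaT = th[3] + th[4] * f;
    lp += counts(j, 1) * etaE - n * softplus(etaE);
    lp += counts(j, 2) * etaT - n * softplus(etaT);
  }
  return lp;
}

// Componentwise random-walk Metropolis with batch-adaptive proposal
// scales during burn-in (diminishing adaptation towards a 0.44
// per-component acceptance rate).  Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".rwm_sampler")]]
List rwm_sampler(NumericMatrix counts, NumericVector fd,
                 NumericVector prior_mean, NumericVector prior_sd,
                 NumericVector init, LogicalVector free_param,
                 int n_keep, int n_burn) {
  const int P = 5;
  double th[5];
  for (int p = 0; p < P; ++p) th[p] = init[p];

  NumericVector scale(P);
  for (int p = 0; p < P; ++p) scale[p] = prior_sd[p];

  NumericMatrix draws(n_keep, P);
  IntegerVector acc(P), tries(P);
  IntegerVector batch_acc(P);
  int batch_len = 50, batch_num = 0, in_batch = 0;

  double lp = log_post(th, counts, fd, prior_mean, prior_sd);
  int total = n_burn + n_keep;

  for (int it = 0; it < total; ++it) {
    for (int p = 0; p < P; ++p) {
      if (!free_param[p]) continue;
      double old = th[p];
      th[p] = old + R::norm_rand() * scale[p];
      double lp_new = log_post(th, counts, fd, prior_mean, prior_sd);
      if (std::log(R::unif_rand()) < lp_new - lp) {
        lp = lp_new;
        if (it >= n_burn) acc[p]++;
        batch_acc[p]++;
      } else {
        th[p] = old;
      }
      if (it >= n_burn) tries[p]++;
    }
    if (it < n_burn && ++in_batch == batch_len) {
      batch_num++;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch_num));
      for (int p = 0; p < P; ++p) {
        if (!free_param[p]) continue;
        double rate = (double)batch_acc[p] / batch_len;
        scale[p] *= std::exp(rate > 0.44 ? delta : -delta);
        batch_acc[p] = 0;
      }
      in_batch = 0;
    }
    if (it >= n_burn)
      for (int p = 0; p < P; ++p) draws(it - n_burn, p) = th[p];
  }

  NumericVector rate(P);
  for (int p = 0; p < P; ++p)
    rate[p] = tries[p] > 0 ? (double)acc[p] / tries[p] : NA_REAL;

  return List::create(_["draws"] = draws, _["accept_rate"] = rate,
                      _["scale"] = scale);
}
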