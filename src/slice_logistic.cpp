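#include <Rcpp.h>
using namespace Rcpp;

// Weighted Bernoulli log likelihood with logistic link, evaluated with
// coordinate j of the weight vector moved to `wj`, given the linear
// predictor `eta` cached at the current weights.  s[i] = +1 for outcome 1,
// -1 for outcome 0; wt[i] counts collapsed duplicate rows.
static double loglik_coord(const NumericMatrix& X, const std::vector<double>& s,
                           const std::vector<double>& wt,
                           const std::vector<double>& eta, int j,
                           double wj_cur, double wj) {
  const int n = X.nrow();
  const double d = wj - wj_cur;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double z = s[i] * (eta[i] + d * X(i, j));
    // log sigmoid(z), stable for large |z|
    ll += wt[i] * ((z < 0.0) ? z - log1p(exp(z)) : -log1p(exp(-z)));
  }
  return ll;
}

// One chain of coordinate-wise stepping-out/shrinkage slice sampling for a
// logistic regression with independent normal(0, prior_sd) priors on the
// weights.  Uses R's RNG (seed via set.seed before the call).  Rows may be
// weighted (collapsed duplicates).  Returns an (n_keep x p) matrix of
// retained draws: after `burn_in` full coordinate scans, every `thin`-th
// state is kept.
// [[Rcpp::export(name = ".slice_logistic_chain")]]
NumericMatrix slice_logistic_chain(NumericMatrix X, IntegerVector y,
                                   NumericVector weight,
                                   NumericVector prior_sd, NumericVector init,
                                   int burn_in, int thin, int n_keep,
                                   NumericVector step_width, int max_steps) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> s(n), wt(n);
  for (int i = 0; i < n; ++i) {
    s[i] = y[i] == 1 ? 1.0 : -1.0;
    wt[i] = weight[i];
  }

  std::vector<double> w(p), eta(n, 0.0);
  for (int j = 0; j < p; ++j) w[j] = init[j];
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * w[j];
    eta[i] = e;
  }
  // current log likelihood, carried across coordinate updates
  double ll_cur = loglik_coord(X, s, wt, eta, 0, w[0], w[0]);

  NumericMatrix out(n_keep, p);
  const int total = burn_in + thin * n_keep;
  int kept = 0;

  for (int it = 1; it <= total; ++it) {
    for (int j = 0; j < p; ++j) {
      const double sd = prior_sd[j];
      const double wdt = step_width[j];
      const double x0 = w[j];
      double f0 = ll_cur + R::dnorm(x0, 0.0, sd, 1);
      double logy = f0 - R::exp_rand();
      // stepping out
      double L = x0 - wdt * R::unif_rand();
      double R_ = L + wdt;
      int k = 0;
      while (loglik_coord(X, s, wt, eta, j, x0, L) +
               R::dnorm(L, 0.0, sd, 1) > logy) {
        L -= wdt;
        if (++k > max_steps)
          stop("slice interval expansion exceeded %d steps (left edge %g); the target may be improper",
               max_steps, L);
      }
      k = 0;
      while (loglik_coord(X, s, wt, eta, j, x0, R_) +
               R::dnorm(R_, 0.0, sd, 1) > logy) {
        R_ += wdt;
        if (++k > max_steps)
          stop("slice interval expansion exceeded %d steps (right edge %g); the target may be improper",
               max_steps, R_);
      }
      // shrinkage
      double x1, ll1;
      for (;;) {
        x1 = L + (R_ - L) * R::unif_rand();
        ll1 = loglik_coord(X, s, wt, eta, j, x0, x1);
        if (ll1 + R::dnorm(x1, 0.0, sd, 1) >= logy) break;
        if (x1 < x0) L = x1; else R_ = x1;
        if (R_ - L < 1e-300) { x1 = x0; ll1 = ll_cur; break; }
      }
      // accept: update cached linear predictor and log likelihood
      double d = x1 - x0;
      if (d != 0.0) for (int i = 0; i < n; ++i) eta[i] += d * X(i, j);
      w[j] = x1;
      ll_cur = ll1;
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < p; ++j) out(kept, j) = w[j];
      ++kept;
    }
  }
  return out;
}
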