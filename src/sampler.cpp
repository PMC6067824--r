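#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double z) {
  if (z > 35.0) return z;
  if (z < -35.0) return std::exp(z);
  return std::log1p(std::exp(z));
}

static inline double invlogit(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// One MCMC chain for the logistic model with an underreported binary
// exposure: systematic-scan Gibbs over (latent D | rest), theta, s, then
// random-walk Metropolis on each coefficient. Perfect specificity: d is
// never updated where r == 1. X holds the J covariates (no exposure, no
// intercept); eta_base tracks beta0 + X * beta so each coefficient update
// touches only the rows where its column is nonzero.
// [[Rcpp::export]]
List run_chain_cpp(IntegerVector A, IntegerVector R, NumericMatrix X,
                   double a_theta, double b_theta, double a_s, double b_s,
                   double m0, double v0, double mb, double vb,
                   NumericVector init_coef, double init_theta, double init_s,
                   IntegerVector init_d, NumericVector init_scales,
                   int burn_in, int n_samples, int thin,
                   bool augment, bool update_coefs) {
  const int n = A.size();
  const int J = X.ncol();
  const int P = J + 2;  // intercept, exposure effect, J covariates

  std::vector<double> coef(init_coef.begin(), init_coef.end());
  double theta = init_theta, s = init_s;
  std::vector<int> d(init_d.begin(), init_d.end());

  // rows where each covariate column is 1 (binary columns only)
  std::vector<bool> is_binary(J);
  std::vector< std::vector<int> > ones(J);
  for (int j = 0; j < J; ++j) {
    bool bin = true;
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      if (v != 0.0 && v != 1.0) { bin = false; break; }
    }
    is_binary[j] = bin;
    if (bin) {
      for (int i = 0; i < n; ++i) if (X(i, j) == 1.0) ones[j].push_back(i);
    }
  }
  std::vector<int> idxR0;
  int nR1 = 0;
  for (int i = 0; i < n; ++i) { if (R[i] == 0) idxR0.push_back(i); else ++nR1; }

  std::vector<double> eta_base(n);
  for (int i = 0; i < n; ++i) {
    double e = coef[0];
    for (int j = 0; j < J; ++j) e += X(i, j) * coef[2 + j];
    eta_base[i] = e;
  }
  std::vector<int> idx_d;
  for (int i = 0; i < n; ++i) if (d[i] == 1) idx_d.push_back(i);

  std::vector<double> scales(init_scales.begin(), init_scales.end());
  std::vector<int> acc_win(P, 0), acc_post(P, 0);
  const int adapt_window = 50;
  const double target = 0.35;

  const int n_keep = n_samples / thin;
  NumericMatrix draws(n_keep, P + 3);  // coefs, theta, s, latent_count
  std::vector<double> d_sum(n, 0.0);   // running sum -> posterior P(D_i = 1)
  int keep = 0;
  int latent_count = 0;
  if (augment) {
    latent_count = 0;
    for (size_t k = 0; k < idxR0.size(); ++k) latent_count += d[idxR0[k]];
  }

  const int total = burn_in + n_samples;
  for (int iter = 1; iter <= total; ++iter) {
    if (augment) {
      // latent D for unreported patients
      const double b1 = coef[1];
      const double w_pref = theta * (1.0 - s);
      latent_count = 0;
      for (size_t k = 0; k < idxR0.size(); ++k) {
        const int i = idxR0[k];
        const double p1 = invlogit(eta_base[i] + b1);
        const double p0 = invlogit(eta_base[i]);
        const double L1 = A[i] ? p1 : 1.0 - p1;
        const double L0 = A[i] ? p0 : 1.0 - p0;
        const double w1 = w_pref * L1;
        const double pr = w1 / (w1 + (1.0 - theta) * L0);
        d[i] = (unif_rand() < pr) ? 1 : 0;
        latent_count += d[i];
      }
      idx_d.clear();
      for (int i = 0; i < n; ++i) if (d[i] == 1) idx_d.push_back(i);
      const int sum_d = nR1 + latent_count;
      theta = R::rbeta(a_theta + sum_d, b_theta + (n - sum_d));
      s = R::rbeta(a_s + nR1, b_s + latent_count);
    }

    if (update_coefs) {
      for (int c = 0; c < P; ++c) {
        const double cur = coef[c];
        const double delta = scales[c] * norm_rand();
        const double m = (c == 0) ? m0 : mb;
        const double v = (c == 0) ? v0 : vb;
        double lp = -((cur + delta - m) * (cur + delta - m) -
                      (cur - m) * (cur - m)) / (2.0 * v);
        if (c == 0) {
          const double b1 = coef[1];
          for (int i = 0; i < n; ++i) {
            const double eta = eta_base[i] + (d[i] ? b1 : 0.0);
            lp += A[i] * delta - softplus(eta + delta) + softplus(eta);
          }
        } else if (c == 1) {
          for (size_t k = 0; k < idx_d.size(); ++k) {
            const int i = idx_d[k];
            const double eta = eta_base[i] + cur;
            lp += A[i] * delta - softplus(eta + delta) + softplus(eta);
          }
        } else {
          const int j = c - 2;
          const double b1 = coef[1];
          if (is_binary[j]) {
            for (size_t k = 0; k < ones[j].size(); ++k) {
              const int i = ones[j][k];
              const double eta = eta_base[i] + (d[i] ? b1 : 0.0);
              lp += A[i] * delta - softplus(eta + delta) + softplus(eta);
            }
          } else {
            for (int i = 0; i < n; ++i) {
              const double x = X(i, j);
              if (x == 0.0) continue;
              const double eta = eta_base[i] + (d[i] ? b1 : 0.0);
              const double dx = delta * x;
              lp += A[i] * dx - softplus(eta + dx) + softplus(eta);
            }
          }
        }
        if (std::log(unif_rand()) < lp) {
          coef[c] = cur + delta;
          if (c == 0) {
            for (int i = 0; i < n; ++i) eta_base[i] += delta;
          } else if (c >= 2) {
            const int j = c - 2;
            if (is_binary[j]) {
              for (size_t k = 0; k < ones[j].size(); ++k)
                eta_base[ones[j][k]] += delta;
            } else {
              for (int i = 0; i < n; ++i) eta_base[i] += delta * X(i, j);
            }
          }
          if (iter <= burn_in) ++acc_win[c]; else ++acc_post[c];
        }
      }
      // proposal-scale adaptation, burn-in only (frozen afterwards so the
      // post-burn-in kernel leaves the target invariant)
      if (iter <= burn_in && iter % adapt_window == 0) {
        for (int c = 0; c < P; ++c) {
          const double rate = acc_win[c] / double(adapt_window);
          scales[c] *= std::exp(rate - target);
          if (scales[c] < 1e-4) scales[c] = 1e-4;
          if (scales[c] > 10.0) scales[c] = 10.0;
          acc_win[c] = 0;
        }
      }
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      for (int c = 0; c < P; ++c) draws(keep, c) = coef[c];
      draws(keep, P) = theta;
      draws(keep, P + 1) = s;
      draws(keep, P + 2) = latent_count;
      for (int i = 0; i < n; ++i) d_sum[i] += d[i];
      ++keep;
    }
  }

  NumericVector acc_rate(P), out_scales(P);
  for (int c = 0; c < P; ++c) {
    acc_rate[c] = n_samples > 0 ? acc_post[c] / double(n_samples) : NA_REAL;
    out_scales[c] = scales[c];
  }
  NumericVector d_mean(n);
  for (int i = 0; i < n; ++i) d_mean[i] = n_keep > 0 ? d_sum[i] / n_keep : NA_REAL;
  return List::create(_["draws"] = draws, _["accept_rate"] = acc_rate,
                      _["scales"] = out_scales, _["d_mean"] = d_mean);
}
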