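// Metropolis-within-Gibbs sampler for the negative binomial abundance model
// with Bernoulli indicator (Kuo-Mallick spike-and-slab) variable selection
// under strong heredity, plus zero-inflated Poisson / negative binomial
// comparison variants.
//
// Parameterization: y_i ~ NegBinom(p_i, r), p_i = r/(r + mu_i),
// log mu = beta0 + X * (gamma_adj * delta); beta_k = gamma_adj_k * delta_k.
// Priors: beta0 ~ N(mean, sd), delta_k ~ N(0, sqrt(sigma)) (variance sigma),
// sigma ~ InvGamma(shape, rate) (conjugate), gamma_k ~ Bern(pi),
// r ~ Unif(0, r_upper), zero-inflation weight w ~ Unif(0, 1).
//
// Uses R's RNG throughout so that set.seed() in R makes a chain
// bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int n, K, family;                 // family: 0 NB, 1 ZIP, 2 ZINB
  const int *y;
  const double *X;                  // column-major n x (K+1), col 0 intercept
  std::vector<int> yidx;            // index into unique-count table
  std::vector<double> uy;           // unique counts (as double)
  double sum_lgyfact;               // sum lgamma(y_i + 1)
  std::vector<double> lgy1;         // lgamma(y_i + 1)

  // cached pieces that depend only on r
  double r_cached = -1.0;
  double Sr_cached = 0.0;           // n r log r + sum_i [lgamma(y_i+r) - lgamma(r)]

  const double *col(int k) const { return X + (size_t)n * k; }

  void build_tables(const IntegerVector &yv) {
    n = yv.size();
    std::map<int, int> seen;
    yidx.resize(n);
    lgy1.resize(n);
    sum_lgyfact = 0.0;
    for (int i = 0; i < n; ++i) {
      auto it = seen.find(yv[i]);
      if (it == seen.end()) {
        int id = (int)uy.size();
        seen.emplace(yv[i], id);
        uy.push_back((double)yv[i]);
        yidx[i] = id;
      } else {
        yidx[i] = it->second;
      }
      lgy1[i] = R::lgammafn(yv[i] + 1.0);
      sum_lgyfact += lgy1[i];
    }
  }

  double Sr(double r) {
    if (r == r_cached) return Sr_cached;
    double lgr = R::lgammafn(r);
    std::vector<double> tab(uy.size());
    for (size_t u = 0; u < uy.size(); ++u)
      tab[u] = R::lgammafn(uy[u] + r) - lgr;
    double s = n * r * std::log(r);
    for (int i = 0; i < n; ++i) s += tab[yidx[i]];
    r_cached = r;
    Sr_cached = s;
    return s;
  }

  // full log likelihood at linear predictor eta
  double loglik(const std::vector<double> &eta, double r, double w) {
    double ll = 0.0;
    if (family == 0) {            // NB
      for (int i = 0; i < n; ++i) {
        double t = std::log(r + std::exp(eta[i]));
        ll += y[i] * eta[i] - (y[i] + r) * t;
      }
      ll += Sr(r) - sum_lgyfact;
    } else if (family == 1) {     // ZIP
      double l1mw = std::log1p(-w);
      for (int i = 0; i < n; ++i) {
        double mu = std::exp(eta[i]);
        if (y[i] == 0)
          ll += std::log(w + (1.0 - w) * std::exp(-mu));
        else
          ll += l1mw + y[i] * eta[i] - mu - lgy1[i];
      }
    } else {                      // ZINB
      double l1mw = std::log1p(-w);
      double lgr = R::lgammafn(r);
      double rlogr = r * std::log(r);
      for (int i = 0; i < n; ++i) {
        double mu = std::exp(eta[i]);
        double lp0 = r * (std::log(r) - std::log(r + mu));
        if (y[i] == 0) {
          ll += std::log(w + (1.0 - w) * std::exp(lp0));
        } else {
          double lnb = R::lgammafn(y[i] + r) - lgr - lgy1[i] + rlogr -
                       (y[i] + r) * std::log(r + mu) + y[i] * eta[i];
          ll += l1mw + lnb;
        }
      }
    }
    if (!std::isfinite(ll)) ll = -INFINITY;
    return ll;
  }
};

} // namespace

// [[Rcpp::export(name = ".nbssvs_chain")]]
List nbssvs_chain(IntegerVector y, NumericMatrix X, List parents, int family,
                  double beta0_mean, double beta0_sd, double sigma_shape,
                  double sigma_rate, double pi_incl, double r_upper,
                  int n_adapt, int n_burn, int n_iter, int thin,
                  double beta0_init, NumericVector delta_init,
                  IntegerVector gamma_init, double sigma_init, double r_init,
                  double w_init) {
  const int n = y.size();
  const int K = X.ncol() - 1;
  if (parents.size() != K) stop("parents list must have one entry per term");
  if (thin < 1) stop("thin must be >= 1");

  Model M;
  M.family = family;
  M.y = INTEGER(y);
  M.X = REAL(X);
  M.K = K;
  M.build_tables(y);

  // heredity structure: parents and children (0-based)
  std::vector<std::vector<int>> par(K), child(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector pk = parents[k];
    for (int j = 0; j < pk.size(); ++j) {
      int p = pk[j];
      if (p < 0 || p >= K) stop("parent index out of range");
      par[k].push_back(p);
      child[p].push_back(k);
    }
  }

  // state
  double beta0 = beta0_init, sigma = sigma_init, r = r_init, w = w_init;
  std::vector<double> delta(delta_init.begin(), delta_init.end());
  std::vector<int> gamma(gamma_init.begin(), gamma_init.end());
  const bool update_gamma = (pi_incl > 0.0 && pi_incl < 1.0);
  if (pi_incl <= 0.0) std::fill(gamma.begin(), gamma.end(), 0);
  if (pi_incl >= 1.0) std::fill(gamma.begin(), gamma.end(), 1);
  const double log_prior_odds = update_gamma ?
      std::log(pi_incl) - std::log1p(-pi_incl) : 0.0;

  std::vector<int> gadj(K);
  std::vector<double> b(K);
  auto recompute_gadj = [&]() {
    for (int k = 0; k < K; ++k) {
      int g = gamma[k];
      for (int p : par[k]) g *= gamma[p];
      gadj[k] = g;
      b[k] = g ? delta[k] : 0.0;
    }
  };
  recompute_gadj();

  std::vector<double> eta(n), eta_prop(n);
  auto recompute_eta = [&]() {
    const double *ic = M.col(0);
    for (int i = 0; i < n; ++i) eta[i] = beta0 * ic[i];
    for (int k = 0; k < K; ++k) {
      if (b[k] == 0.0) continue;
      const double *xk = M.col(k + 1);
      for (int i = 0; i < n; ++i) eta[i] += b[k] * xk[i];
    }
  };
  recompute_eta();

  double ll_cur = M.loglik(eta, r, w);

  // proposal scales and acceptance bookkeeping
  double s_beta0 = 0.1, s_r = 0.3, s_w = 0.5;
  std::vector<double> s_delta(K, 0.2);
  long acc_b0 = 0, try_b0 = 0, acc_r = 0, try_r = 0, acc_w = 0, try_w = 0;
  std::vector<long> acc_d(K, 0), try_d(K, 0);
  auto tune = [](double &s, long acc, long tries) {
    if (tries < 10) return;
    double rate = (double)acc / tries;
    if (rate < 0.2) s *= 0.7;
    else if (rate > 0.5) s *= 1.4;
    if (s < 1e-4) s = 1e-4;
    if (s > 50.0) s = 50.0;
  };

  const int n_total = n_adapt + n_burn + n_iter;
  const int n_keep = n_iter / thin;
  // columns: beta0 | delta(K) | gamma(K) | sigma | r | w | loglik
  NumericMatrix out(n_keep, 1 + 2 * K + 4);
  int kept = 0;

  RNGScope scope;

  for (int it = 0; it < n_total; ++it) {
    // --- beta0: random-walk MH ---
    {
      double prop = beta0 + s_beta0 * R::norm_rand();
      double shift = prop - beta0;
      for (int i = 0; i < n; ++i) eta_prop[i] = eta[i] + shift;
      double ll_new = M.loglik(eta_prop, r, w);
      double lacc = ll_new - ll_cur +
        R::dnorm(prop, beta0_mean, beta0_sd, 1) -
        R::dnorm(beta0, beta0_mean, beta0_sd, 1);
      ++try_b0;
      if (std::log(R::unif_rand()) < lacc) {
        beta0 = prop;
        std::swap(eta, eta_prop);
        ll_cur = ll_new;
        ++acc_b0;
      }
    }

    // --- delta_k: MH when active, prior refresh when gated out ---
    double sd_slab = std::sqrt(sigma);
    for (int k = 0; k < K; ++k) {
      if (gadj[k]) {
        double prop = delta[k] + s_delta[k] * R::norm_rand();
        double diff = prop - delta[k];
        const double *xk = M.col(k + 1);
        for (int i = 0; i < n; ++i) eta_prop[i] = eta[i] + diff * xk[i];
        double ll_new = M.loglik(eta_prop, r, w);
        double lacc = ll_new - ll_cur +
          (delta[k] * delta[k] - prop * prop) / (2.0 * sigma);
        ++try_d[k];
        if (std::log(R::unif_rand()) < lacc) {
          delta[k] = prop;
          b[k] = prop;
          std::swap(eta, eta_prop);
          ll_cur = ll_new;
          ++acc_d[k];
        }
      } else {
        // full conditional of an excluded coefficient is its slab prior
        delta[k] = sd_slab * R::norm_rand();
      }
    }

    // --- gamma_k: Bernoulli full conditional under heredity ---
    if (update_gamma) {
      for (int k = 0; k < K; ++k) {
        // terms whose adjusted indicator can change with gamma_k
        // (k itself plus its children)
        int cur = gamma[k];
        gamma[k] = 1 - cur;
        // compute new gadj / b for affected terms and eta difference
        std::copy(eta.begin(), eta.end(), eta_prop.begin());
        std::vector<std::pair<int, double>> changes;  // (term, new b)
        auto consider = [&](int j) {
          int g = gamma[j];
          for (int p : par[j]) g *= gamma[p];
          double bn = g ? delta[j] : 0.0;
          if (bn != b[j]) {
            const double *xj = M.col(j + 1);
            double diff = bn - b[j];
            for (int i = 0; i < n; ++i) eta_prop[i] += diff * xj[i];
            changes.emplace_back(j, bn);
          }
        };
        consider(k);
        for (int c : child[k]) consider(c);
        double ll_flip = M.loglik(eta_prop, r, w);
        // log odds of gamma_k = 1 over gamma_k = 0
        double l1 = cur ? ll_cur : ll_flip;
        double l0 = cur ? ll_flip : ll_cur;
        double lodds = log_prior_odds + l1 - l0;
        int newg = (R::unif_rand() < 1.0 / (1.0 + std::exp(-lodds))) ? 1 : 0;
        if (newg == gamma[k]) {
          // flip state adopted
          for (auto &ch : changes) b[ch.first] = ch.second;
          for (int j : child[k]) { int g = gamma[j]; for (int p : par[j]) g *= gamma[p]; gadj[j] = g; }
          { int g = gamma[k]; for (int p : par[k]) g *= gamma[p]; gadj[k] = g; }
          std::swap(eta, eta_prop);
          ll_cur = ll_flip;
        } else {
          gamma[k] = cur;  // revert
        }
      }
    }

    // --- sigma: conjugate inverse-gamma given all delta ---
    {
      double ssq = 0.0;
      for (int k = 0; k < K; ++k) ssq += delta[k] * delta[k];
      double shape = sigma_shape + 0.5 * K;
      double rate = sigma_rate + 0.5 * ssq;
      sigma = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    // --- r: random walk on log r, prior Unif(0, r_upper) ---
    if (family != 1) {
      double prop = r * std::exp(s_r * R::norm_rand());
      ++try_r;
      if (prop < r_upper) {
        double ll_new = M.loglik(eta, prop, w);
        double lacc = ll_new - ll_cur + std::log(prop) - std::log(r);
        if (std::log(R::unif_rand()) < lacc) {
          r = prop;
          ll_cur = ll_new;
          ++acc_r;
        }
      }
    }

    // --- w: random walk on logit w, prior Unif(0, 1) ---
    if (family != 0) {
      double lw = std::log(w) - std::log1p(-w) + s_w * R::norm_rand();
      double prop = 1.0 / (1.0 + std::exp(-lw));
      double ll_new = M.loglik(eta, r, prop);
      double lacc = ll_new - ll_cur +
        std::log(prop * (1.0 - prop)) - std::log(w * (1.0 - w));
      ++try_w;
      if (std::log(R::unif_rand()) < lacc) {
        w = prop;
        ll_cur = ll_new;
        ++acc_w;
      }
    }

    // --- adaptation (discarded phase only) ---
    if (it < n_adapt && (it + 1) % 50 == 0) {
      tune(s_beta0, acc_b0, try_b0); acc_b0 = try_b0 = 0;
      tune(s_r, acc_r, try_r); acc_r = try_r = 0;
      tune(s_w, acc_w, try_w); acc_w = try_w = 0;
      for (int k = 0; k < K; ++k) {
        tune(s_delta[k], acc_d[k], try_d[k]);
        acc_d[k] = try_d[k] = 0;
      }
    }
    if (it == n_adapt - 1) {  // freeze scales; restart acceptance counters
      acc_b0 = try_b0 = acc_r = try_r = acc_w = try_w = 0;
      for (int k = 0; k < K; ++k) acc_d[k] = try_d[k] = 0;
    }

    // periodic exact recomputation to cap incremental round-off
    if ((it + 1) % 500 == 0) {
      recompute_eta();
      ll_cur = M.loglik(eta, r, w);
    }

    // --- store ---
    if (it >= n_adapt + n_burn) {
      int j = it - n_adapt - n_burn;
      if (j % thin == 0 && kept < n_keep) {
        out(kept, 0) = beta0;
        for (int k = 0; k < K; ++k) out(kept, 1 + k) = delta[k];
        for (int k = 0; k < K; ++k) out(kept, 1 + K + k) = gamma[k];
        out(kept, 1 + 2 * K) = sigma;
        out(kept, 1 + 2 * K + 1) = r;
        out(kept, 1 + 2 * K + 2) = w;
        out(kept, 1 + 2 * K + 3) = ll_cur;
        ++kept;
      }
    }
  }

  double ar_b0 = try_b0 ? (double)acc_b0 / try_b0 : NA_REAL;
  double ar_r = try_r ? (double)acc_r / try_r : NA_REAL;
  double ar_w = try_w ? (double)acc_w / try_w : NA_REAL;
  NumericVector ar_d(K);
  for (int k = 0; k < K; ++k)
    ar_d[k] = try_d[k] ? (double)acc_d[k] / try_d[k] : NA_REAL;

  return List::create(_["draws"] = out,
                      _["accept"] = List::create(_["beta0"] = ar_b0,
                                                 _["delta"] = ar_d,
                                                 _["r"] = ar_r, _["w"] = ar_w),
                      _["scales"] = List::create(_["beta0"] = s_beta0,
                                                 _["delta"] = NumericVector(s_delta.begin(), s_delta.end()),
                                                 _["r"] = s_r, _["w"] = s_w));
}
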