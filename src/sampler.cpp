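#include <Rcpp.h>
#include "wiener.h"
using namespace Rcpp;

// Hierarchical sampler for the strategy-mixture drift-diffusion model.
//
// model_type: 0 = simple DDM (one strategy, no item effects)
//             1 = single-strategy DDM with item retrieval difficulty
//             2 = full two-strategy (retrieval vs counting) mixture
//
// Per-participant parameter columns:
//   model 2: 0 rho0, 1 drho, 2 dM0, 3 dMd, 4 dC0, 5 dCd, 6 a0, 7 ad,
//            8 tau, 9 tc_pre, 10 tc_post
//   model 0/1: 0 d0, 1 dd, 2 a0, 3 ad, 4 tau
// Change columns (drho, dMd, ...) hold the pre-to-post shift; session
// values are pre + session * change.
//
// The optional joint block regresses a per-participant brain change score
// on the cohort-centered change parameters (drho, dMd, dCd, ad, dtc) with
// N(0,1) priors on the slopes (Savage-Dickey reference prior).

static const double NEG_INF = -1e300;
static const double WERR = 1e-8;

struct Model {
  int type, P, K, n;
  IntegerVector part, sess, item, up;
  NumericVector rt;
  IntegerVector nk;
  int nppar, ngr;
  std::vector< std::vector<int> > by_part, by_item;
  bool has_items;
};

static double trial_ll(const Model &m, int t, const double *th,
                       const std::vector<double> &rhok) {
  int s = m.sess[t];
  double f;
  if (m.type == 2) {
    double rho_s = th[0] + s * th[1];
    double rk = rhok[m.item[t]];
    double dM = (th[2] + s * th[3]) / (1.0 + std::exp(rk));
    double dC = (th[4] + s * th[5]) / (double)m.nk[m.item[t]];
    double al = th[6] + s * th[7];
    double tau = th[8];
    double tc = s ? th[10] : th[9];
    double pM = 1.0 / (1.0 + std::exp(-(rho_s - rk)));
    f = pM * dwiener_raw(m.rt[t], al, dM, tau, 0.5, m.up[t], WERR) +
        (1.0 - pM) * dwiener_raw(m.rt[t], al, dC, tau + tc, 0.5, m.up[t], WERR);
  } else {
    double v = th[0] + s * th[1];
    if (m.type == 1) v /= (1.0 + std::exp(rhok[m.item[t]]));
    double al = th[2] + s * th[3];
    f = dwiener_raw(m.rt[t], al, v, th[4], 0.5, m.up[t], WERR);
  }
  return (f > 0.0) ? std::log(f) : NEG_INF;
}

static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

// [[Rcpp::export]]
List fit_chain_cpp(IntegerVector part, IntegerVector sess, IntegerVector item,
                   NumericVector rt, IntegerVector up, IntegerVector nk,
                   int P, int K, int model_type,
                   NumericMatrix theta_init, NumericVector rhok_init,
                   int n_iter, int n_burn, int thin,
                   List ctrl, NumericVector ddiv, bool compute_waic) {
  RNGScope scope;
  Model m;
  m.type = model_type; m.P = P; m.K = K; m.n = rt.size();
  m.part = part; m.sess = sess; m.item = item; m.up = up;
  m.rt = rt; m.nk = nk;
  m.has_items = (model_type >= 1);
  m.nppar = (model_type == 2) ? 11 : 5;
  m.ngr = (model_type == 2) ? 8 : 4;

  m.by_part.assign(P, std::vector<int>());
  m.by_item.assign(std::max(K, 1), std::vector<int>());
  for (int t = 0; t < m.n; ++t) {
    m.by_part[part[t]].push_back(t);
    if (m.has_items) m.by_item[item[t]].push_back(t);
  }

  const double mu0_sd = as<double>(ctrl["mu0_sd"]);
  const double sd_lo = as<double>(ctrl["sd_lo"]);
  const double sd_hi = as<double>(ctrl["sd_hi"]);
  const double tau_lo = as<double>(ctrl["tau_lo"]);
  const double tau_hi = as<double>(ctrl["tau_hi"]);
  const double tc_hi = as<double>(ctrl["tc_hi"]);
  const double beta_prior_sd = as<double>(ctrl["beta_prior_sd"]);

  const bool joint = (ddiv.size() == P) && (model_type == 2);
  const int nppar = m.nppar, ngr = m.ngr;

  // state
  std::vector<double> theta(P * nppar);
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < nppar; ++j) theta[i * nppar + j] = theta_init(i, j);
  std::vector<double> rhok(std::max(K, 1), 0.0);
  if (m.has_items) for (int k = 0; k < K; ++k) rhok[k] = rhok_init[k];
  std::vector<double> mu(ngr, 0.0), sd(ngr, 0.5);
  for (int g = 0; g < ngr; ++g) {
    double s0 = 0.0;
    for (int i = 0; i < P; ++i) s0 += theta[i * nppar + g];
    mu[g] = s0 / P;
  }
  double muk = 0.0, sdk = 1.0;
  std::vector<double> beta(5, 0.0);
  double b0 = 0.0, sigma = 0.5;
  if (joint) {
    double s0 = 0.0, s2 = 0.0;
    for (int i = 0; i < P; ++i) s0 += ddiv[i];
    b0 = s0 / P;
    for (int i = 0; i < P; ++i) s2 += (ddiv[i] - b0) * (ddiv[i] - b0);
    sigma = std::max(0.05, std::sqrt(s2 / std::max(P - 1, 1)));
  }


  // cached per-trial log-likelihood
  std::vector<double> ll_trial(m.n), ll_part(P, 0.0), scratch;
  for (int t = 0; t < m.n; ++t) {
    ll_trial[t] = trial_ll(m, t, &theta[part[t] * nppar], rhok);
    ll_part[part[t]] += ll_trial[t];
  }

  // joint regression log-likelihood given current state
  auto reg_loglik = [&](int swap_i, int swap_j, double swap_val) -> double {
    // evaluate with theta(swap_i, swap_j) replaced by swap_val (or swap_i<0)
    std::vector<double> xp(P * 5);
    for (int i = 0; i < P; ++i) {
      const double *th = &theta[i * nppar];
      double v[11];
      for (int j = 0; j < nppar; ++j) v[j] = th[j];
      if (i == swap_i) v[swap_j] = swap_val;
      xp[i * 5 + 0] = v[1];
      xp[i * 5 + 1] = v[3];
      xp[i * 5 + 2] = v[5];
      xp[i * 5 + 3] = v[7];
      xp[i * 5 + 4] = v[10] - v[9];
    }
    double cm[5] = {0, 0, 0, 0, 0};
    for (int i = 0; i < P; ++i)
      for (int p = 0; p < 5; ++p) cm[p] += xp[i * 5 + p];
    for (int p = 0; p < 5; ++p) cm[p] /= P;
    double ll = 0.0;
    for (int i = 0; i < P; ++i) {
      double pred = b0;
      for (int p = 0; p < 5; ++p) pred += beta[p] * (xp[i * 5 + p] - cm[p]);
      double r = (ddiv[i] - pred) / sigma;
      ll += -0.5 * r * r - std::log(sigma);
    }
    return ll;
  };
  double cur_reg_ll = joint ? reg_loglik(-1, -1, 0.0) : 0.0;

  // support check for a proposed value of theta(i, j)
  auto supported = [&](const double *th, int j, double val) -> bool {
    double v[11];
    for (int q = 0; q < nppar; ++q) v[q] = th[q];
    v[j] = val;
    if (m.type == 2) {
      if (v[2] <= 0 || v[2] + v[3] <= 0) return false;
      if (v[4] <= 0 || v[4] + v[5] <= 0) return false;
      if (v[6] <= 0 || v[6] + v[7] <= 0) return false;
      if (v[8] <= tau_lo || v[8] >= tau_hi) return false;
      if (v[9] < 0 || v[9] > tc_hi || v[10] < 0 || v[10] > tc_hi) return false;
    } else {
      if (v[0] <= 0 || v[0] + v[1] <= 0) return false;
      if (v[2] <= 0 || v[2] + v[3] <= 0) return false;
      if (v[4] <= tau_lo || v[4] >= tau_hi) return false;
    }
    return true;
  };

  // adaptation
  std::vector<double> sc_theta(P * nppar, 0.15), sc_item(std::max(K, 1), 0.15),
      sc_sd(ngr, 0.15);
  double sc_sdk = 0.15, sc_sigma = 0.15;
  std::vector<int> acc_theta(P * nppar, 0), acc_item(std::max(K, 1), 0),
      acc_sd(ngr, 0);
  int acc_sdk = 0, acc_sigma = 0;
  const int win = 50;
  int win_no = 0;

  // storage
  int n_keep = (n_iter - n_burn) / thin;
  int totpar = P * nppar + (m.has_items ? K : 0) + 2 * ngr +
               (m.has_items ? 2 : 0) + (joint ? 7 : 0);
  NumericMatrix draws(n_keep, totpar);
  int keep_row = 0;

  // WAIC accumulators (Welford + streaming log-sum-exp)
  std::vector<double> w_lse, w_mean, w_m2;
  int w_count = 0;
  if (compute_waic) {
    w_lse.assign(m.n, NEG_INF);
    w_mean.assign(m.n, 0.0);
    w_m2.assign(m.n, 0.0);
  }

  for (int it = 0; it < n_iter; ++it) {
    // --- participant parameters ---
    for (int i = 0; i < P; ++i) {
      double *th = &theta[i * nppar];
      const std::vector<int> &tr = m.by_part[i];
      scratch.resize(tr.size());
      for (int j = 0; j < nppar; ++j) {
        int idx = i * nppar + j;
        double cur = th[j];
        double prop = cur + sc_theta[idx] * norm_rand();
        if (!supported(th, j, prop)) continue;
        double lr = 0.0;
        if (j < ngr) lr += dnorm_log(prop, mu[j], sd[j]) -
                           dnorm_log(cur, mu[j], sd[j]);
        // likelihood over this participant's trials
        th[j] = prop;
        double new_ll = 0.0;
        for (size_t q = 0; q < tr.size(); ++q) {
          scratch[q] = trial_ll(m, tr[q], th, rhok);
          new_ll += scratch[q];
        }
        th[j] = cur;
        lr += new_ll - ll_part[i];
        double new_reg = cur_reg_ll;
        if (joint && (j == 1 || j == 3 || j == 5 || j == 7 || j == 9 || j == 10)) {
          new_reg = reg_loglik(i, j, prop);
          lr += new_reg - cur_reg_ll;
        }
        if (lr > 0 || std::log(unif_rand()) < lr) {
          th[j] = prop;
          ll_part[i] = new_ll;
          for (size_t q = 0; q < tr.size(); ++q) ll_trial[tr[q]] = scratch[q];
          cur_reg_ll = new_reg;
          acc_theta[idx]++;
        }
      }
    }

    // --- item difficulties ---
    if (m.has_items) {
      for (int k = 0; k < K; ++k) {
        const std::vector<int> &tr = m.by_item[k];
        double cur = rhok[k];
        double prop = cur + sc_item[k] * norm_rand();
        double lr = dnorm_log(prop, muk, sdk) - dnorm_log(cur, muk, sdk);
        scratch.resize(tr.size());
        rhok[k] = prop;
        double new_ll = 0.0, old_ll = 0.0;
        for (size_t q = 0; q < tr.size(); ++q) {
          int t = tr[q];
          scratch[q] = trial_ll(m, t, &theta[part[t] * nppar], rhok);
          new_ll += scratch[q];
          old_ll += ll_trial[t];
        }
        rhok[k] = cur;
        lr += new_ll - old_ll;
        if (lr > 0 || std::log(unif_rand()) < lr) {
          rhok[k] = prop;
          for (size_t q = 0; q < tr.size(); ++q) {
            int t = tr[q];
            ll_part[part[t]] += scratch[q] - ll_trial[t];
            ll_trial[t] = scratch[q];
          }
          acc_item[k]++;
        }
      }
    }

    // --- hyperparameters ---
    for (int g = 0; g < ngr; ++g) {
      // conjugate update for the location
      double sx = 0.0;
      for (int i = 0; i < P; ++i) sx += theta[i * nppar + g];
      double prec = P / (sd[g] * sd[g]) + 1.0 / (mu0_sd * mu0_sd);
      double mean = (sx / (sd[g] * sd[g])) / prec;
      mu[g] = mean + norm_rand() / std::sqrt(prec);
      // random-walk update for the scale (uniform prior)
      double cur = sd[g], prop = cur + sc_sd[g] * norm_rand();
      if (prop > sd_lo && prop < sd_hi) {
        double lr = 0.0;
        for (int i = 0; i < P; ++i) {
          double x = theta[i * nppar + g];
          lr += dnorm_log(x, mu[g], prop) - dnorm_log(x, mu[g], cur);
        }
        if (lr > 0 || std::log(unif_rand()) < lr) { sd[g] = prop; acc_sd[g]++; }
      }
    }
    if (m.has_items) {
      // item-difficulty location fixed at zero: the standard item-response
      // anchoring that separates individual propensity from item difficulty
      muk = 0.0;
      double cur = sdk, prop = cur + sc_sdk * norm_rand();
      if (prop > sd_lo && prop < sd_hi) {
        double lr = 0.0;
        for (int k = 0; k < K; ++k)
          lr += dnorm_log(rhok[k], muk, prop) - dnorm_log(rhok[k], muk, cur);
        if (lr > 0 || std::log(unif_rand()) < lr) { sdk = prop; acc_sdk++; }
      }
    }

    // --- joint regression block ---
    if (joint) {
      // centered predictors from current state
      std::vector<double> xc(P * 5);
      for (int i = 0; i < P; ++i) {
        const double *th = &theta[i * nppar];
        xc[i * 5 + 0] = th[1]; xc[i * 5 + 1] = th[3]; xc[i * 5 + 2] = th[5];
        xc[i * 5 + 3] = th[7]; xc[i * 5 + 4] = th[10] - th[9];
      }
      for (int p = 0; p < 5; ++p) {
        double cmp = 0.0;
        for (int i = 0; i < P; ++i) cmp += xc[i * 5 + p];
        cmp /= P;
        for (int i = 0; i < P; ++i) xc[i * 5 + p] -= cmp;
      }
      double s2 = sigma * sigma;
      // intercept (normal prior sd 10)
      {
        double sr = 0.0;
        for (int i = 0; i < P; ++i) {
          double r = ddiv[i];
          for (int p = 0; p < 5; ++p) r -= beta[p] * xc[i * 5 + p];
          sr += r;
        }
        double prec = P / s2 + 1.0 / 100.0;
        b0 = (sr / s2) / prec + norm_rand() / std::sqrt(prec);
      }
      // slopes, coordinate-wise conjugate normal
      for (int p = 0; p < 5; ++p) {
        double sxx = 0.0, sxr = 0.0;
        for (int i = 0; i < P; ++i) {
          double r = ddiv[i] - b0;
          for (int q = 0; q < 5; ++q)
            if (q != p) r -= beta[q] * xc[i * 5 + q];
          sxx += xc[i * 5 + p] * xc[i * 5 + p];
          sxr += xc[i * 5 + p] * r;
        }
        double prec = sxx / s2 + 1.0 / (beta_prior_sd * beta_prior_sd);
        beta[p] = (sxr / s2) / prec + norm_rand() / std::sqrt(prec);
      }
      // residual scale, random walk with uniform prior
      {
        cur_reg_ll = reg_loglik(-1, -1, 0.0);
        double cur = sigma, prop = cur + sc_sigma * norm_rand();
        if (prop > sd_lo && prop < sd_hi) {
          double old_ll = cur_reg_ll;
          sigma = prop;
          double new_ll = reg_loglik(-1, -1, 0.0);
          double lr = new_ll - old_ll;
          if (lr > 0 || std::log(unif_rand()) < lr) {
            cur_reg_ll = new_ll; acc_sigma++;
          } else sigma = cur;
        }
      }
    }

    // --- adaptation during burn-in ---
    if (it < n_burn && ((it + 1) % win) == 0) {
      win_no++;
      double step = 1.0 / std::sqrt((double)win_no);
      auto tune = [&](double &s, int &a) {
        double rate = (double)a / win;
        s *= std::exp(step * (rate - 0.44));
        s = std::min(std::max(s, 1e-4), 10.0);
        a = 0;
      };
      for (size_t q = 0; q < sc_theta.size(); ++q) tune(sc_theta[q], acc_theta[q]);
      if (m.has_items)
        for (int k = 0; k < K; ++k) tune(sc_item[k], acc_item[k]);
      for (int g = 0; g < ngr; ++g) tune(sc_sd[g], acc_sd[g]);
      if (m.has_items) tune(sc_sdk, acc_sdk);
      if (joint) tune(sc_sigma, acc_sigma);
    }

    // --- record ---
    if (it >= n_burn && ((it - n_burn) % thin) == 0) {
      int c = 0;
      for (int i = 0; i < P; ++i)
        for (int j = 0; j < nppar; ++j) draws(keep_row, c++) = theta[i * nppar + j];
      if (m.has_items) for (int k = 0; k < K; ++k) draws(keep_row, c++) = rhok[k];
      for (int g = 0; g < ngr; ++g) {
        draws(keep_row, c++) = mu[g];
        draws(keep_row, c++) = sd[g];
      }
      if (m.has_items) { draws(keep_row, c++) = muk; draws(keep_row, c++) = sdk; }
      if (joint) {
        draws(keep_row, c++) = b0;
        for (int p = 0; p < 5; ++p) draws(keep_row, c++) = beta[p];
        draws(keep_row, c++) = sigma;
      }
      keep_row++;
      if (compute_waic) {
        w_count++;
        for (int t = 0; t < m.n; ++t) {
          double ll = ll_trial[t];
          // streaming log-sum-exp
          if (ll > w_lse[t])
            w_lse[t] = ll + std::log1p(std::exp(w_lse[t] - ll));
          else
            w_lse[t] = w_lse[t] + std::log1p(std::exp(ll - w_lse[t]));
          double d = ll - w_mean[t];
          w_mean[t] += d / w_count;
          w_m2[t] += d * (ll - w_mean[t]);
        }
      }
    }
  }

  List out = List::create(_["draws"] = draws, _["n_keep"] = n_keep);
  if (compute_waic) {
    out["waic_lse"] = NumericVector(w_lse.begin(), w_lse.end());
    out["waic_mean"] = NumericVector(w_mean.begin(), w_mean.end());
    out["waic_m2"] = NumericVector(w_m2.begin(), w_m2.end());
    out["waic_count"] = w_count;
  }
  return out;
}
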