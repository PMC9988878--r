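// Fast backend for the moral-conflict bandit models: sequential
// Rescorla-Wagner likelihood evaluation and an adaptive
// Metropolis-within-Gibbs sampler for the non-centered hierarchical model.
//
// Data layout (shared by all entry points): trials are flattened in
// subject-major, block-major, trial-major order.
//   choice      : chosen symbol per trial (1 or 2)
//   outm, outs  : value-coded revealed outcomes (+1 / -1 / 0)
//   block_ptr   : length B+1, 0-based start of each block in the trial arrays
//   block_drop  : length B, 0 = none, 1 = money removed, 2 = shock removed
//   subj_block_ptr : length N+1, 0-based start block of each subject
// Trial indices within a block are implicit (1-based position); the dropout
// transition fires before the 11th trial of a dropout block.
//
// Model codes: 0 = M0, 1 = M1, 2 = M2Out, 3 = M2Dec, 4 = M2DO.
// Parameter vectors (constrained scale):
//   M0: tau | M1: wf, lr, tau | M2Out/M2Dec: wf, lr_m, lr_s, tau
//   M2DO: wf, lr_m, lr_s, tau, alpha

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double norm_cdf(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

static inline int n_params(int model) {
  switch (model) {
    case 0: return 1;
    case 1: return 3;
    case 4: return 5;
    default: return 4;
  }
}

// subset codes: 1 = learning trials (position <= 10), 2 = trial 11 only, 3 = all
static inline bool keep_trial(int subset, int pos1) {
  if (subset == 1) return pos1 <= 10;
  if (subset == 2) return pos1 == 11;
  return true;
}

// Sequential log-likelihood of one subject's choices. If pw != nullptr the
// per-trial log probabilities of the included trials are written there (in
// order); returns the summed log-likelihood of the included trials.
static double subject_loglik(int model, const double *p,
                             const int *choice, const double *outm,
                             const double *outs, const int *block_ptr,
                             const int *block_drop, int b_first, int b_last,
                             int subset, double *pw, int *pw_n) {
  double total = 0.0;
  int npw = 0;
  const double tau = (model == 0) ? p[0]
                   : (model == 1) ? p[2]
                   : p[3];
  const double wf = (model == 0) ? 0.5 : p[0];
  const double alpha = (model == 4) ? p[4] : 1.0;

  for (int b = b_first; b < b_last; ++b) {
    const int t0 = block_ptr[b], t1 = block_ptr[b + 1];
    const int drop = block_drop[b];
    double evm[2] = {0.0, 0.0}, evs[2] = {0.0, 0.0}, ev[2] = {0.0, 0.0};
    double wf_eff = wf;
    bool dropped = false;

    for (int t = t0; t < t1; ++t) {
      const int pos1 = t - t0 + 1;
      if (drop != 0 && pos1 == 11) {
        dropped = true;
        wf_eff = (drop == 2) ? 1.0 : 0.0; // shocks removed -> money only
        if (model >= 2) {                 // M2 family: zero the removed EV
          if (drop == 1) { evm[0] = evm[1] = 0.0; }
          else           { evs[0] = evs[1] = 0.0; }
        }
      }
      // decision utilities
      double v0, v1;
      if (model == 0) {
        v0 = v1 = 0.0;
      } else if (model == 1) {
        v0 = ev[0]; v1 = ev[1];
      } else {
        double wm, ws;
        if (dropped) { wm = wf_eff; ws = 1.0 - wf_eff; }
        else if (model == 2) { wm = 1.0; ws = 1.0; }
        else if (model == 3) { wm = wf; ws = 1.0 - wf; }
        else { wm = std::pow(wf, 1.0 - alpha); ws = std::pow(1.0 - wf, 1.0 - alpha); }
        v0 = wm * evm[0] + ws * evs[0];
        v1 = wm * evm[1] + ws * evs[1];
      }
      // stabilized two-option softmax
      const double u0 = tau * v0, u1 = tau * v1;
      const double m = (u0 > u1) ? u0 : u1;
      const double denom = std::exp(u0 - m) + std::exp(u1 - m);
      const int c = choice[t] - 1;
      const double logp = ((c == 0) ? (u0 - m) : (u1 - m)) - std::log(denom);
      if (keep_trial(subset, pos1)) {
        total += logp;
        if (pw) pw[npw] = logp;
        ++npw;
      }
      // Rescorla-Wagner update of the chosen symbol
      const double om = outm[t], os = outs[t];
      if (model == 1) {
        const double pe = (wf_eff * om + (1.0 - wf_eff) * os) - ev[c];
        ev[c] += p[1] * pe;
      } else if (model >= 2) {
        double mm, ms; // outcome multipliers (M2Dec never scales outcomes)
        if (model == 3) { mm = 1.0; ms = 1.0; }
        else if (dropped) { mm = wf_eff; ms = 1.0 - wf_eff; }
        else if (model == 2) { mm = wf; ms = 1.0 - wf; }
        else { mm = std::pow(wf, alpha); ms = std::pow(1.0 - wf, alpha); }
        const double pem = mm * om - evm[c];
        const double pes = ms * os - evs[c];
        evm[c] += p[1] * pem;
        evs[c] += p[2] * pes;
      }
    }
  }
  if (pw_n) *pw_n = npw;
  return total;
}

// [[Rcpp::export]]
NumericVector cpp_pointwise_loglik(int model, NumericVector pars,
                                   IntegerVector choice, NumericVector outm,
                                   NumericVector outs, IntegerVector block_ptr,
                                   IntegerVector block_drop, int subset) {
  const int B = block_drop.size();
  const int ntr = choice.size();
  std::vector<double> buf(ntr);
  int n = 0;
  subject_loglik(model, pars.begin(), choice.begin(), outm.begin(),
                 outs.begin(), block_ptr.begin(), block_drop.begin(), 0, B,
                 subset, buf.data(), &n);
  return NumericVector(buf.begin(), buf.begin() + n);
}

// theta: draws x subjects x params array (constrained scale), flattened with
// dim = c(S, N, P). Returns an S x n_included matrix of log-likelihoods.
// [[Rcpp::export]]
NumericMatrix cpp_loglik_matrix(int model, NumericVector theta, int n_draws,
                                int n_subj, IntegerVector choice,
                                NumericVector outm, NumericVector outs,
                                IntegerVector block_ptr,
                                IntegerVector block_drop,
                                IntegerVector subj_block_ptr, int subset) {
  const int P = n_params(model);
  // count included trials
  int n_inc = 0;
  for (int b = 0; b < block_drop.size(); ++b) {
    const int len = block_ptr[b + 1] - block_ptr[b];
    for (int pos = 1; pos <= len; ++pos)
      if (keep_trial(subset, pos)) ++n_inc;
  }
  NumericMatrix out(n_draws, n_inc);
  std::vector<double> pars(P), pw(n_inc);
  for (int s = 0; s < n_draws; ++s) {
    int col = 0;
    for (int i = 0; i < n_subj; ++i) {
      for (int p = 0; p < P; ++p)
        pars[p] = theta[s + (double)n_draws * (i + (double)n_subj * p)];
      int npw = 0;
      subject_loglik(model, pars.data(), choice.begin(), outm.begin(),
                     outs.begin(), block_ptr.begin(), block_drop.begin(),
                     subj_block_ptr[i], subj_block_ptr[i + 1], subset,
                     pw.data(), &npw);
      for (int k = 0; k < npw; ++k) out(s, col++) = pw[k];
    }
  }
  return out;
}

// ---- hierarchical sampler ---------------------------------------------------

struct Constrain {
  // kind 0: Phi(u) in (0,1); kind 1: 5*Phi(u) in (0,5)
  static double apply(double u, int kind) {
    const double v = norm_cdf(u);
    return kind == 1 ? 5.0 * v : v;
  }
};

static inline int par_kind(int model, int p) {
  // tau position: M0 -> 0, M1 -> 2, otherwise 3
  const int tau_pos = (model == 0) ? 0 : (model == 1) ? 2 : 3;
  return (p == tau_pos) ? 1 : 0;
}

// One chain of adaptive Metropolis-within-Gibbs on the non-centered
// hierarchy: mu_p ~ N(0,1), sigma_p ~ half-Normal(0, sigma_scale),
// z_ip ~ N(0,1), theta_ip = constrain(mu_p + sigma_p * z_ip).
// Uses R's RNG so set.seed() in R makes chains reproducible.
// [[Rcpp::export]]
List cpp_mcmc_chain(int model, IntegerVector choice, NumericVector outm,
                    NumericVector outs, IntegerVector block_ptr,
                    IntegerVector block_drop, IntegerVector subj_block_ptr,
                    int n_warmup, int n_keep, int thin, double sigma_scale,
                    int subset) {
  const int P = n_params(model);
  const int N = subj_block_ptr.size() - 1;
  const int B = block_drop.size();
  (void)B;

  std::vector<double> mu(P, 0.0), lsig(P, std::log(0.1));
  std::vector<double> z(N * P, 0.0);
  std::vector<double> theta(N * P);
  std::vector<double> cur_ll(N);

  auto theta_of = [&](int i, int p) {
    return Constrain::apply(mu[p] + std::exp(lsig[p]) * z[i * P + p],
                            par_kind(model, p));
  };
  auto subj_ll = [&](int i, const double *pars) {
    return subject_loglik(model, pars, choice.begin(), outm.begin(),
                          outs.begin(), block_ptr.begin(), block_drop.begin(),
                          subj_block_ptr[i], subj_block_ptr[i + 1], subset,
                          nullptr, nullptr);
  };

  for (int i = 0; i < N; ++i) {
    for (int p = 0; p < P; ++p) theta[i * P + p] = theta_of(i, p);
    cur_ll[i] = subj_ll(i, &theta[i * P]);
  }

  // proposal scales with batch adaptation toward 0.44 acceptance
  std::vector<double> sc_z(P, 0.5), sc_mu(P, 0.2), sc_ls(P, 0.4);
  std::vector<double> sc_tr(P, 0.3), sc_rs(P, 0.3);
  std::vector<double> acc_z(P, 0.0), acc_mu(P, 0.0), acc_ls(P, 0.0);
  std::vector<double> try_z(P, 0.0), try_mu(P, 0.0), try_ls(P, 0.0);
  std::vector<double> acc_tr(P, 0.0), acc_rs(P, 0.0);
  std::vector<double> try_tr(P, 0.0), try_rs(P, 0.0);
  const int batch = 25;

  if (thin < 1) thin = 1;
  const int n_iter = n_warmup + n_keep * thin;
  NumericMatrix mu_draws(n_keep, P), sig_draws(n_keep, P);
  NumericVector theta_draws((double)n_keep * N * P);
  theta_draws.attr("dim") = IntegerVector::create(n_keep, N, P);

  std::vector<double> prop(P), new_theta(N);

  for (int it = 0; it < n_iter; ++it) {
    // --- subject offsets z_ip (two sweeps: the subject-level conditionals
    // are the slowest-mixing part of the chain) -------------------------
    for (int zrep = 0; zrep < 2; ++zrep)
    for (int i = 0; i < N; ++i) {
      for (int p = 0; p < P; ++p) {
        const double z_old = z[i * P + p];
        const double z_new = z_old + sc_z[p] * norm_rand();
        for (int q = 0; q < P; ++q) prop[q] = theta[i * P + q];
        z[i * P + p] = z_new;
        prop[p] = theta_of(i, p);
        const double ll_new = subj_ll(i, prop.data());
        const double dlp = -0.5 * (z_new * z_new - z_old * z_old) +
                           (ll_new - cur_ll[i]);
        try_z[p] += 1.0;
        if (std::log(unif_rand()) < dlp) {
          theta[i * P + p] = prop[p];
          cur_ll[i] = ll_new;
          acc_z[p] += 1.0;
        } else {
          z[i * P + p] = z_old;
        }
      }
    }
    // --- group location mu_p and log-scale ------------------------------
    // repeated sub-sweeps: group updates are cheap relative to the subject
    // sweep and the hierarchy mixes slowest
    for (int hrep = 0; hrep < 3; ++hrep) {
    for (int rep = 0; rep < 2; ++rep) {
      for (int p = 0; p < P; ++p) {
        double old_val, d_prior;
        if (rep == 0) {
          old_val = mu[p];
          mu[p] = old_val + sc_mu[p] * norm_rand();
          d_prior = -0.5 * (mu[p] * mu[p] - old_val * old_val);
          try_mu[p] += 1.0;
        } else {
          old_val = lsig[p];
          lsig[p] = old_val + sc_ls[p] * norm_rand();
          const double s_new = std::exp(lsig[p]), s_old = std::exp(old_val);
          d_prior = -0.5 * (s_new * s_new - s_old * s_old) /
                        (sigma_scale * sigma_scale) +
                    (lsig[p] - old_val); // Jacobian of log transform
          try_ls[p] += 1.0;
        }
        double d_ll = 0.0;
        std::vector<double> ll_new(N);
        for (int i = 0; i < N; ++i) {
          for (int q = 0; q < P; ++q) prop[q] = theta[i * P + q];
          prop[p] = theta_of(i, p);
          new_theta[i] = prop[p];
          ll_new[i] = subj_ll(i, prop.data());
          d_ll += ll_new[i] - cur_ll[i];
        }
        if (std::log(unif_rand()) < d_prior + d_ll) {
          for (int i = 0; i < N; ++i) {
            theta[i * P + p] = new_theta[i];
            cur_ll[i] = ll_new[i];
          }
          if (rep == 0) acc_mu[p] += 1.0; else acc_ls[p] += 1.0;
        } else {
          if (rep == 0) mu[p] = old_val; else lsig[p] = old_val;
        }
      }
    }
    // --- likelihood-invariant reparameterization moves -------------------
    // the non-centered hierarchy leaves (mu, z) and (sigma, z) on narrow
    // ridges once the data pin down theta; these moves slide along the
    // ridges (theta, and hence the likelihood, is exactly unchanged) and
    // are accepted on the priors alone
    for (int p = 0; p < P; ++p) {
      const double sig = std::exp(lsig[p]);
      // translation: mu -> mu + e, z_i -> z_i - e / sigma
      {
        const double e = sc_tr[p] * norm_rand();
        double dlp = -0.5 * ((mu[p] + e) * (mu[p] + e) - mu[p] * mu[p]);
        for (int i = 0; i < N; ++i) {
          const double zo = z[i * P + p], zn = zo - e / sig;
          dlp += -0.5 * (zn * zn - zo * zo);
        }
        try_tr[p] += 1.0;
        if (std::log(unif_rand()) < dlp) {
          mu[p] += e;
          for (int i = 0; i < N; ++i) z[i * P + p] -= e / sig;
          acc_tr[p] += 1.0;
        }
      }
      // rescale: log sigma -> log sigma + h, z_i -> z_i * exp(-h)
      {
        const double h = sc_rs[p] * norm_rand();
        const double s_old = std::exp(lsig[p]), s_new = std::exp(lsig[p] + h);
        double dlp = -0.5 * (s_new * s_new - s_old * s_old) /
                         (sigma_scale * sigma_scale) +
                     h - (double)N * h; // lsig Jacobian + z-scaling Jacobian
        const double f = std::exp(-h);
        for (int i = 0; i < N; ++i) {
          const double zo = z[i * P + p], zn = zo * f;
          dlp += -0.5 * (zn * zn - zo * zo);
        }
        try_rs[p] += 1.0;
        if (std::log(unif_rand()) < dlp) {
          lsig[p] += h;
          for (int i = 0; i < N; ++i) z[i * P + p] *= f;
          acc_rs[p] += 1.0;
        }
      }
    }
    } // hrep
    // --- warmup adaptation ----------------------------------------------
    if (it < n_warmup && (it + 1) % batch == 0) {
      for (int p = 0; p < P; ++p) {
        auto tune = [](double &sc, double &acc, double &tries, double target) {
          if (tries > 0) {
            sc *= std::exp(0.8 * (acc / tries - target));
            sc = std::min(std::max(sc, 1e-3), 10.0);
          }
          acc = tries = 0.0;
        };
        tune(sc_z[p], acc_z[p], try_z[p], 0.44);
        tune(sc_mu[p], acc_mu[p], try_mu[p], 0.30);
        tune(sc_ls[p], acc_ls[p], try_ls[p], 0.30);
        tune(sc_tr[p], acc_tr[p], try_tr[p], 0.44);
        tune(sc_rs[p], acc_rs[p], try_rs[p], 0.44);
      }
    }
    // --- store -----------------------------------------------------------
    if (it >= n_warmup && (it - n_warmup) % thin == 0) {
      const int s = (it - n_warmup) / thin;
      for (int p = 0; p < P; ++p) {
        mu_draws(s, p) = mu[p];
        sig_draws(s, p) = std::exp(lsig[p]);
      }
      for (int i = 0; i < N; ++i)
        for (int p = 0; p < P; ++p)
          theta_draws[s + (double)n_keep * (i + (double)N * p)] =
              theta[i * P + p];
    }
  }

  return List::create(_["mu"] = mu_draws, _["sigma"] = sig_draws,
                      _["theta"] = theta_draws);
}

// Simulate choices of one agent over pre-drawn schedules for both symbols.
// sched_outm / sched_outs are (trial x symbol) flattened: entry 2*t + s.
// Returns chosen symbol (1/2) and the revealed outcomes per trial.
// [[Rcpp::export]]
List cpp_simulate_blocks(int model, NumericVector pars,
                         NumericVector sched_outm, NumericVector sched_outs,
                         IntegerVector block_len, IntegerVector block_drop) {
  const int P = n_params(model);
  const int nb = block_len.size();
  int ntot = 0;
  for (int b = 0; b < nb; ++b) ntot += block_len[b];
  IntegerVector choice(ntot);
  NumericVector rev_m(ntot), rev_s(ntot);
  NumericMatrix ev_m_final(nb, 2), ev_s_final(nb, 2);

  const double tau = (model == 0) ? pars[0] : (model == 1) ? pars[2] : pars[3];
  const double wf = (model == 0) ? 0.5 : pars[0];
  const double alpha = (model == 4) ? pars[4] : 1.0;
  (void)P;

  int t_glob = 0, t_sched = 0;
  for (int b = 0; b < nb; ++b) {
    double evm[2] = {0, 0}, evs[2] = {0, 0}, ev[2] = {0, 0};
    double wf_eff = wf;
    bool dropped = false;
    const int drop = block_drop[b];
    for (int pos = 1; pos <= block_len[b]; ++pos, ++t_glob, ++t_sched) {
      if (drop != 0 && pos == 11) {
        dropped = true;
        wf_eff = (drop == 2) ? 1.0 : 0.0;
        if (model >= 2) {
          if (drop == 1) { evm[0] = evm[1] = 0.0; }
          else           { evs[0] = evs[1] = 0.0; }
        }
      }
      double v0, v1;
      if (model == 0) { v0 = v1 = 0.0; }
      else if (model == 1) { v0 = ev[0]; v1 = ev[1]; }
      else {
        double wm, ws;
        if (dropped) { wm = wf_eff; ws = 1.0 - wf_eff; }
        else if (model == 2) { wm = 1.0; ws = 1.0; }
        else if (model == 3) { wm = wf; ws = 1.0 - wf; }
        else { wm = std::pow(wf, 1.0 - alpha); ws = std::pow(1.0 - wf, 1.0 - alpha); }
        v0 = wm * evm[0] + ws * evs[0];
        v1 = wm * evm[1] + ws * evs[1];
      }
      const double u0 = tau * v0, u1 = tau * v1;
      const double m = (u0 > u1) ? u0 : u1;
      const double p0 = std::exp(u0 - m) / (std::exp(u0 - m) + std::exp(u1 - m));
      const int c = (unif_rand() < p0) ? 0 : 1;
      choice[t_glob] = c + 1;
      const double om = sched_outm[2 * t_sched + c];
      const double os = sched_outs[2 * t_sched + c];
      rev_m[t_glob] = om;
      rev_s[t_glob] = os;
      if (model == 1) {
        const double pe = (wf_eff * om + (1.0 - wf_eff) * os) - ev[c];
        ev[c] += pars[1] * pe;
      } else if (model >= 2) {
        double mm, ms;
        if (model == 3) { mm = 1.0; ms = 1.0; }
        else if (dropped) { mm = wf_eff; ms = 1.0 - wf_eff; }
        else if (model == 2) { mm = wf; ms = 1.0 - wf; }
        else { mm = std::pow(wf, alpha); ms = std::pow(1.0 - wf, alpha); }
        evm[c] += pars[1] * (mm * om - evm[c]);
        evs[c] += pars[2] * (ms * os - evs[c]);
      }
      if (pos == block_len[b]) { // final state of the block, for reports
        ev_m_final(b, 0) = evm[0]; ev_m_final(b, 1) = evm[1];
        ev_s_final(b, 0) = evs[0]; ev_s_final(b, 1) = evs[1];
      }
    }
  }
  return List::create(_["choice"] = choice, _["out_money"] = rev_m,
                      _["out_shock"] = rev_s, _["ev_m_final"] = ev_m_final,
                      _["ev_s_final"] = ev_s_final);
}
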