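#include <Rcpp.h>
using namespace Rcpp;

// Trial-level likelihoods for the three decision models on a two-arm bandit.
// Rewards are coded 0/1; choices are 0/1 arm indices.

static inline void check_coding(const IntegerVector& choice,
                                const IntegerVector& reward) {
  if (choice.size() != reward.size())
    stop("choice and reward must have equal length");
  for (R_xlen_t t = 0; t < choice.size(); ++t) {
    if (choice[t] != 0 && choice[t] != 1) stop("choices must be coded 0/1");
    if (reward[t] != 0 && reward[t] != 1) stop("rewards must be coded 0/1");
  }
}

// Rescorla-Wagner: Q[c] <- Q[c] + alpha * (r - Q[c]); softmax(beta * Q).
// Returns per-trial log choice probabilities, the Q trajectory (value of each
// arm *before* the trial's update), and the RPE series r_t - Q_t^c.
// [[Rcpp::export]]
List rw_trace_cpp(double alpha, double beta,
                  IntegerVector choice, IntegerVector reward,
                  double q0 = 0.5) {
  check_coding(choice, reward);
  const int T = choice.size();
  NumericVector logp(T), rpe(T), qch(T);
  NumericMatrix Q(T, 2);
  double q[2] = {q0, q0};
  for (int t = 0; t < T; ++t) {
    Q(t, 0) = q[0]; Q(t, 1) = q[1];
    const int c = choice[t];
    // log softmax, numerically stable
    const double d = beta * (q[1 - c] - q[c]);
    logp[t] = -R::log1pexp(d);
    qch[t] = q[c];
    rpe[t] = reward[t] - q[c];
    q[c] += alpha * rpe[t];
  }
  return List::create(_["logp"] = logp, _["Q"] = Q,
                      _["rpe"] = rpe, _["q_chosen"] = qch);
}

// [[Rcpp::export]]
NumericMatrix rw_pointwise_cpp(NumericVector alpha, NumericVector beta,
                               IntegerVector choice, IntegerVector reward,
                               double q0 = 0.5) {
  check_coding(choice, reward);
  const int T = choice.size(), D = alpha.size();
  if (beta.size() != D) stop("alpha and beta draws must align");
  NumericMatrix out(D, T);
  for (int i = 0; i < D; ++i) {
    double q[2] = {q0, q0};
    for (int t = 0; t < T; ++t) {
      const int c = choice[t];
      out(i, t) = -R::log1pexp(beta[i] * (q[1 - c] - q[c]));
      q[c] += alpha[i] * (reward[t] - q[c]);
    }
  }
  return out;
}

// Win-stay/lose-shift with adherence probability eps; first trial at 0.5.
// [[Rcpp::export]]
NumericVector wsls_pointwise_one_cpp(double eps,
                                     IntegerVector choice,
                                     IntegerVector reward) {
  check_coding(choice, reward);
  const int T = choice.size();
  NumericVector logp(T);
  logp[0] = std::log(0.5);
  for (int t = 1; t < T; ++t) {
    const int rule = reward[t - 1] == 1 ? choice[t - 1] : 1 - choice[t - 1];
    logp[t] = std::log(choice[t] == rule ? eps : 1.0 - eps);
  }
  return logp;
}

// [[Rcpp::export]]
NumericMatrix wsls_pointwise_cpp(NumericVector eps,
                                 IntegerVector choice, IntegerVector reward) {
  check_coding(choice, reward);
  const int T = choice.size(), D = eps.size();
  NumericMatrix out(D, T);
  for (int i = 0; i < D; ++i) {
    out(i, 0) = std::log(0.5);
    for (int t = 1; t < T; ++t) {
      const int rule = reward[t - 1] == 1 ? choice[t - 1] : 1 - choice[t - 1];
      out(i, t) = std::log(choice[t] == rule ? eps[i] : 1.0 - eps[i]);
    }
  }
  return out;
}

// Two-hidden-state Bayesian filter. State s = 0 means arm 0 is currently the
// high-reward arm. Action probability is the transitioned prior probability
// that the chosen arm is state-correct (probability matching); the posterior
// is then updated with the reward likelihood and mixed by the transition
// matrix before the next trial.
// [[Rcpp::export]]
List bayes_trace_cpp(double p_reward, double p_switch,
                     IntegerVector choice, IntegerVector reward) {
  check_coding(choice, reward);
  const int T = choice.size();
  NumericVector logp(T);
  NumericMatrix prior(T, 2), posterior(T, 2);
  double pri[2] = {0.5, 0.5};
  for (int t = 0; t < T; ++t) {
    prior(t, 0) = pri[0]; prior(t, 1) = pri[1];
    const int c = choice[t];
    logp[t] = std::log(pri[c]);
    // reward likelihood given state: chosen arm correct in state s == c
    double lik[2];
    for (int s = 0; s < 2; ++s) {
      const double pr = (c == s) ? p_reward : 1.0 - p_reward;
      lik[s] = reward[t] == 1 ? pr : 1.0 - pr;
    }
    double post[2] = {pri[0] * lik[0], pri[1] * lik[1]};
    const double norm = post[0] + post[1];
    post[0] /= norm; post[1] /= norm;
    posterior(t, 0) = post[0]; posterior(t, 1) = post[1];
    pri[0] = (1.0 - p_switch) * post[0] + p_switch * post[1];
    pri[1] = (1.0 - p_switch) * post[1] + p_switch * post[0];
  }
  return List::create(_["logp"] = logp, _["prior"] = prior,
                      _["posterior"] = posterior);
}

// [[Rcpp::export]]
NumericMatrix bayes_pointwise_cpp(NumericVector p_reward,
                                  NumericVector p_switch,
                                  IntegerVector choice,
                                  IntegerVector reward) {
  check_coding(choice, reward);
  const int T = choice.size(), D = p_reward.size();
  if (p_switch.size() != D) stop("p_reward and p_switch draws must align");
  NumericMatrix out(D, T);
  for (int i = 0; i < D; ++i) {
    double pri[2] = {0.5, 0.5};
    for (int t = 0; t < T; ++t) {
      const int c = choice[t];
      out(i, t) = std::log(pri[c]);
      double lik[2];
      for (int s = 0; s < 2; ++s) {
        const double pr = (c == s) ? p_reward[i] : 1.0 - p_reward[i];
        lik[s] = reward[t] == 1 ? pr : 1.0 - pr;
      }
      double post0 = pri[0] * lik[0], post1 = pri[1] * lik[1];
      const double norm = post0 + post1;
      post0 /= norm; post1 /= norm;
      pri[0] = (1.0 - p_switch[i]) * post0 + p_switch[i] * post1;
      pri[1] = (1.0 - p_switch[i]) * post1 + p_switch[i] * post0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Adaptive Metropolis sampler for the per-subject decision models.
// Parameters are sampled on an unconstrained scale:
//   RW:    theta = (logit(alpha), log(beta))     alpha~Beta(1,1), beta~HN(10)
//   WSLS:  theta = logit(eps)                    eps~Beta(1,1)
//   BAYES: theta = (logit(2 p_r - 1), logit(2 p_s))
//          p_reward~U(0.5,1), p_switch~U(0,0.5)
// Log-priors include the change-of-variable Jacobians. Uses R's RNG so that
// set.seed() in the caller controls reproducibility.
// ---------------------------------------------------------------------------

static double rl_logpost(int model, const std::vector<double>& th,
                         const IntegerVector& choice,
                         const IntegerVector& reward, double beta_sd) {
  double lp = 0.0;
  if (model == 0) { // RW
    const double alpha = 1.0 / (1.0 + std::exp(-th[0]));
    const double beta = std::exp(th[1]);
    // logit jacobian: log(alpha (1-alpha)); half-normal prior on beta + log jac
    lp += std::log(alpha) + std::log1p(-alpha);
    lp += -0.5 * beta * beta / (beta_sd * beta_sd) + th[1];
    double q[2] = {0.5, 0.5};
    for (int t = 0; t < choice.size(); ++t) {
      const int c = choice[t];
      lp += -R::log1pexp(beta * (q[1 - c] - q[c]));
      q[c] += alpha * (reward[t] - q[c]);
    }
  } else if (model == 1) { // WSLS
    const double eps = 1.0 / (1.0 + std::exp(-th[0]));
    lp += std::log(eps) + std::log1p(-eps);
    lp += std::log(0.5);
    for (int t = 1; t < choice.size(); ++t) {
      const int rule = reward[t - 1] == 1 ? choice[t - 1] : 1 - choice[t - 1];
      lp += std::log(choice[t] == rule ? eps : 1.0 - eps);
    }
  } else { // BAYES
    const double u1 = 1.0 / (1.0 + std::exp(-th[0]));
    const double u2 = 1.0 / (1.0 + std::exp(-th[1]));
    const double p_reward = 0.5 + 0.5 * u1;
    const double p_switch = 0.5 * u2;
    lp += std::log(u1) + std::log1p(-u1);
    lp += std::log(u2) + std::log1p(-u2);
    double pri[2] = {0.5, 0.5};
    for (int t = 0; t < choice.size(); ++t) {
      const int c = choice[t];
      lp += std::log(pri[c]);
      double lik[2];
      for (int s = 0; s < 2; ++s) {
        const double pr = (c == s) ? p_reward : 1.0 - p_reward;
        lik[s] = reward[t] == 1 ? pr : 1.0 - pr;
      }
      double post0 = pri[0] * lik[0], post1 = pri[1] * lik[1];
      const double norm = post0 + post1;
      post0 /= norm; post1 /= norm;
      pri[0] = (1.0 - p_switch) * post0 + p_switch * post1;
      pri[1] = (1.0 - p_switch) * post1 + p_switch * post0;
    }
  }
  return lp;
}

// [[Rcpp::export]]
List rl_mcmc_cpp(int model, IntegerVector choice, IntegerVector reward,
                 int n_chains, int n_warmup, int n_iter,
                 double beta_sd = 10.0) {
  check_coding(choice, reward);
  const int d = (model == 1) ? 1 : 2;
  RNGScope scope;
  List chains(n_chains);
  NumericVector accept(n_chains);
  for (int ch = 0; ch < n_chains; ++ch) {
    std::vector<double> th(d), prop(d);
    for (int j = 0; j < d; ++j) th[j] = R::rnorm(0.0, 1.0);
    double lp = rl_logpost(model, th, choice, reward, beta_sd);
    // adaptive scale (Robbins-Monro on log sd, target 0.3) with empirical
    // covariance mixing once enough warmup samples accrue
    std::vector<double> psd(d, 0.5);
    std::vector<double> m(d, 0.0), m2(d * d, 0.0);
    int nacc = 0, ntot = 0, nseen = 0;
    // Cholesky factor of proposal covariance (lower), start diagonal
    std::vector<double> L(d * d, 0.0);
    for (int j = 0; j < d; ++j) L[j * d + j] = psd[j];
    double lscale = 0.0;
    NumericMatrix draws(n_iter, d);
    for (int it = 0; it < n_warmup + n_iter; ++it) {
      // propose via L * z * exp(lscale)
      std::vector<double> z(d);
      for (int j = 0; j < d; ++j) z[j] = R::rnorm(0.0, 1.0);
      for (int j = 0; j < d; ++j) {
        double s = 0.0;
        for (int k = 0; k <= j; ++k) s += L[j * d + k] * z[k];
        prop[j] = th[j] + std::exp(lscale) * s;
      }
      const double lpp = rl_logpost(model, prop, choice, reward, beta_sd);
      const bool acc = std::log(R::unif_rand()) < lpp - lp;
      if (acc) { th = prop; lp = lpp; }
      if (it < n_warmup) {
        nacc += acc; ntot += 1;
        const double g = std::pow((double)(it + 1), -0.6);
        lscale += g * ((acc ? 1.0 : 0.0) - 0.3);
        // accumulate empirical moments
        nseen += 1;
        for (int j = 0; j < d; ++j) {
          const double delta = th[j] - m[j];
          m[j] += delta / nseen;
          for (int k = 0; k <= j; ++k)
            m2[j * d + k] += delta * (th[k] - m[k]);
        }
        if (nseen >= 200 && (it + 1) % 100 == 0) {
          // refresh Cholesky of 2.38^2/d * Sigma_hat + jitter
          std::vector<double> S(d * d, 0.0);
          const double f = 2.38 * 2.38 / d / (nseen - 1);
          for (int j = 0; j < d; ++j)
            for (int k = 0; k <= j; ++k)
              S[j * d + k] = f * m2[j * d + k] + (j == k ? 1e-6 : 0.0);
          // manual Cholesky (d <= 2)
          bool ok = true;
          std::vector<double> Lnew(d * d, 0.0);
          for (int j = 0; j < d && ok; ++j) {
            double s = S[j * d + j];
            for (int k = 0; k < j; ++k) s -= Lnew[j * d + k] * Lnew[j * d + k];
            if (s <= 0) { ok = false; break; }
            Lnew[j * d + j] = std::sqrt(s);
            for (int i2 = j + 1; i2 < d; ++i2) {
              double sij = S[i2 * d + j];
              for (int k = 0; k < j; ++k)
                sij -= Lnew[i2 * d + k] * Lnew[j * d + k];
              Lnew[i2 * d + j] = sij / Lnew[j * d + j];
            }
          }
          if (ok) { L = Lnew; lscale = 0.0; }
        }
      } else {
        const int row = it - n_warmup;
        if (model == 0) {
          draws(row, 0) = 1.0 / (1.0 + std::exp(-th[0]));
          draws(row, 1) = std::exp(th[1]);
        } else if (model == 1) {
          draws(row, 0) = 1.0 / (1.0 + std::exp(-th[0]));
        } else {
          draws(row, 0) = 0.5 + 0.5 / (1.0 + std::exp(-th[0]));
          draws(row, 1) = 0.5 / (1.0 + std::exp(-th[1]));
        }
      }
    }
    accept[ch] = ntot > 0 ? (double)nacc / ntot : NA_REAL;
    chains[ch] = draws;
  }
  return List::create(_["chains"] = chains, _["warmup_accept"] = accept);
}
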