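#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Wiener first-passage-time density for a unit-variance diffusion between
// absorbing boundaries at 0 and a, starting at relative position z (in units
// of a), drift v, non-decision time t0. The density of absorption at the
// LOWER boundary is evaluated through the standardized density
// f(u | 0, 1, w), u = (t - t0)/a^2, w = z, using the dual (small-time /
// large-time) series with term counts chosen from the requested error bound;
// the series with fewer terms is used. Upper-boundary density follows from
// the reflection v -> -v, w -> 1 - w.

static double wfpt_f_standard(double u, double w, double err) {
  // number of terms for the large-time series
  double kl;
  if (M_PI * u * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * err) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }
  // number of terms for the small-time series
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * std::sqrt(2.0 * M_PI * u) * err));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  double f;
  if (ks < kl) { // small-time expansion
    const int K = (int)std::ceil(ks);
    f = 0.0;
    for (int k = -((K - 1) / 2); k <= (int)std::ceil((K - 1) / 2.0); ++k) {
      const double wk = w + 2.0 * k;
      f += wk * std::exp(-wk * wk / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else { // large-time expansion
    const int K = (int)std::ceil(kl);
    f = 0.0;
    for (int k = 1; k <= K; ++k)
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) *
           std::sin(k * M_PI * w);
    f *= M_PI;
  }
  return f;
}

static double wfpt_logdens(double rt, int upper, double v, double a,
                           double z, double t0, double err = 1e-10) {
  const double t = rt - t0;
  if (t <= 0.0) return R_NegInf;
  double vv = v, w = z;
  if (upper) { vv = -v; w = 1.0 - z; }
  const double u = t / (a * a);
  const double f = wfpt_f_standard(u, w, err);
  if (f <= 0.0) return R_NegInf;
  return std::log(f) - 2.0 * std::log(a) - vv * a * w - vv * vv * t / 2.0;
}

// [[Rcpp::export]]
NumericVector wfpt_logdensity_cpp(NumericVector rt, IntegerVector upper,
                                  NumericVector v, double a, double z,
                                  double t0, double err = 1e-10) {
  const R_xlen_t n = rt.size();
  if (upper.size() != n || v.size() != n) stop("rt, upper, v must align");
  if (a <= 0 || z <= 0 || z >= 1 || t0 < 0) stop("invalid DDM parameters");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = wfpt_logdens(rt[i], upper[i], v[i], a, z, t0, err);
  return out;
}

// Force evaluation through one named series, for cross-checking the two
// expansions against each other in the crossover region.
// [[Rcpp::export]]
double wfpt_density_series_cpp(double rt, int upper, double v, double a,
                               double z, double t0, std::string series,
                               int n_terms = 50) {
  const double t = rt - t0;
  if (t <= 0.0) return 0.0;
  double vv = v, w = z;
  if (upper) { vv = -v; w = 1.0 - z; }
  const double u = t / (a * a);
  double f = 0.0;
  if (series == "small") {
    for (int k = -n_terms; k <= n_terms; ++k) {
      const double wk = w + 2.0 * k;
      f += wk * std::exp(-wk * wk / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    for (int k = 1; k <= n_terms; ++k)
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) *
           std::sin(k * M_PI * w);
    f *= M_PI;
  }
  if (f < 0) f = 0;
  return f / (a * a) * std::exp(-vv * a * w - vv * vv * t / 2.0);
}

// Euler-Maruyama forward simulation of the diffusion; returns first-passage
// times and boundaries (1 = upper, 0 = lower, NA if not absorbed by max_t).
// Uses a dedicated 64-bit generator so that very long simulations stay fast;
// the seed argument makes them reproducible.
// [[Rcpp::export]]
List simulate_ddm_paths_cpp(NumericVector v, double a, double z, double t0,
                            double dt, double max_t, int seed) {
  const R_xlen_t n = v.size();
  NumericVector rt(n);
  IntegerVector boundary(n);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> norm(0.0, 1.0);
  const double sdt = std::sqrt(dt);
  const long max_steps = (long)std::ceil(max_t / dt);
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = z * a;
    long step = 0;
    int b = NA_INTEGER;
    while (step < max_steps) {
      x += v[i] * dt + sdt * norm(rng);
      ++step;
      if (x >= a) { b = 1; break; }
      if (x <= 0.0) { b = 0; break; }
    }
    boundary[i] = b;
    rt[i] = (b == NA_INTEGER) ? NA_REAL : t0 + step * dt;
  }
  return List::create(_["rt"] = rt, _["boundary"] = boundary);
}

// ---------------------------------------------------------------------------
// Metropolis-within-Gibbs sampler for the hierarchical drift regression:
//   drift_ij = u_int[i] + u_slope[i] * x_ij
//   u_int[i]   ~ N(mu_int,   sigma_int)
//   u_slope[i] ~ N(mu_slope, sigma_slope)
//   a, z, t0 pooled across subjects.
// Priors: mu_* ~ N(0, 2); sigma_* ~ half-N(1); a ~ Gamma(2, rate 1.5);
// z ~ Beta(2, 2); t0 ~ U(t0_lo, t0_hi). mu_* have conjugate Gibbs updates;
// everything else is adaptive Metropolis on transformed scales.
// ---------------------------------------------------------------------------

struct DDMData {
  NumericVector rt;
  IntegerVector upper, subj; // subj 0-based
  NumericVector x;
  int n_subj;
  std::vector<std::vector<int> > rows; // rows per subject
};

static double subj_loglik(const DDMData& dat, int i, double ui, double si,
                          double a, double z, double t0) {
  double ll = 0.0;
  for (size_t k = 0; k < dat.rows[i].size(); ++k) {
    const int r = dat.rows[i][k];
    ll += wfpt_logdens(dat.rt[r], dat.upper[r], ui + si * dat.x[r], a, z, t0,
                       1e-7);
    if (!R_finite(ll)) return R_NegInf;
  }
  return ll;
}

static double full_loglik(const DDMData& dat, const std::vector<double>& ui,
                          const std::vector<double>& si, double a, double z,
                          double t0) {
  double ll = 0.0;
  for (int i = 0; i < dat.n_subj; ++i) {
    ll += subj_loglik(dat, i, ui[i], si[i], a, z, t0);
    if (!R_finite(ll)) return R_NegInf;
  }
  return ll;
}

// [[Rcpp::export]]
List ddm_hier_mcmc_cpp(NumericVector rt, IntegerVector upper,
                       IntegerVector subj, NumericVector x, int n_subj,
                       int n_warmup, int n_iter,
                       double t0_lo, double t0_hi) {
  DDMData dat;
  dat.rt = rt; dat.upper = upper; dat.subj = subj; dat.x = x;
  dat.n_subj = n_subj;
  dat.rows.resize(n_subj);
  for (R_xlen_t r = 0; r < rt.size(); ++r) {
    if (subj[r] < 0 || subj[r] >= n_subj) stop("subject index out of range");
    dat.rows[subj[r]].push_back(r);
  }
  RNGScope scope;
  // state
  double mu_int = 0.5, mu_slope = 0.0;
  double sigma_int = 0.3, sigma_slope = 0.1;
  double a = 1.5, z = 0.5;
  double t0 = t0_lo + 0.5 * (t0_hi - t0_lo);
  std::vector<double> ui(n_subj, mu_int), si(n_subj, 0.0);
  // adaptive proposal scales
  std::vector<double> ls_subj(n_subj, std::log(0.15));
  double ls_a = std::log(0.05), ls_z = std::log(0.05), ls_t = std::log(0.02),
         ls_si = std::log(0.3), ls_ss = std::log(0.3),
         ls_asis_si = std::log(0.3), ls_asis_ss = std::log(0.3),
         ls_mu_i = std::log(0.1), ls_mu_s = std::log(0.1);
  // cached likelihood per subject
  std::vector<double> ll_subj(n_subj);
  for (int i = 0; i < n_subj; ++i)
    ll_subj[i] = subj_loglik(dat, i, ui[i], si[i], a, z, t0);

  const int n_keep = n_iter;
  const int n_par = 7 + 2 * n_subj;
  NumericMatrix draws(n_keep, n_par);

  auto adapt = [](double& ls, bool acc, int it) {
    const double g = std::pow((double)(it + 1), -0.6);
    ls += g * ((acc ? 1.0 : 0.0) - 0.44);
  };

  for (int it = 0; it < n_warmup + n_iter; ++it) {
    // --- subject effects: joint (intercept, slope) random-walk per subject
    for (int i = 0; i < n_subj; ++i) {
      const double step = std::exp(ls_subj[i]);
      const double pu = ui[i] + step * R::norm_rand();
      const double ps = si[i] + step * 0.5 * R::norm_rand();
      const double llp = subj_loglik(dat, i, pu, ps, a, z, t0);
      const double lr = llp - ll_subj[i] +
        R::dnorm(pu, mu_int, sigma_int, 1) - R::dnorm(ui[i], mu_int, sigma_int, 1) +
        R::dnorm(ps, mu_slope, sigma_slope, 1) - R::dnorm(si[i], mu_slope, sigma_slope, 1);
      const bool acc = std::log(R::unif_rand()) < lr;
      if (acc) { ui[i] = pu; si[i] = ps; ll_subj[i] = llp; }
      if (it < n_warmup) adapt(ls_subj[i], acc, it);
    }
    // --- group means: conjugate Gibbs (prior N(0, 2))
    {
      const double prior_prec = 1.0 / (2.0 * 2.0);
      double s = 0.0;
      for (int i = 0; i < n_subj; ++i) s += ui[i];
      double prec = prior_prec + n_subj / (sigma_int * sigma_int);
      mu_int = R::rnorm((s / (sigma_int * sigma_int)) / prec,
                        std::sqrt(1.0 / prec));
      s = 0.0;
      for (int i = 0; i < n_subj; ++i) s += si[i];
      prec = prior_prec + n_subj / (sigma_slope * sigma_slope);
      mu_slope = R::rnorm((s / (sigma_slope * sigma_slope)) / prec,
                          std::sqrt(1.0 / prec));
    }
    // --- group SDs: MH on log scale, half-normal(1) prior
    for (int which = 0; which < 2; ++which) {
      double& sig = which == 0 ? sigma_int : sigma_slope;
      double& ls = which == 0 ? ls_si : ls_ss;
      const double mu = which == 0 ? mu_int : mu_slope;
      const std::vector<double>& u = which == 0 ? ui : si;
      const double prop = sig * std::exp(std::exp(ls) * R::norm_rand());
      double lr = 0.0;
      for (int i = 0; i < n_subj; ++i)
        lr += R::dnorm(u[i], mu, prop, 1) - R::dnorm(u[i], mu, sig, 1);
      lr += -0.5 * (prop * prop - sig * sig); // half-normal(1) kernel
      lr += std::log(prop) - std::log(sig);   // log-scale Jacobian
      const bool acc = std::log(R::unif_rand()) < lr;
      if (acc) sig = prop;
      if (it < n_warmup) adapt(ls, acc, it);
    }
    // --- interweaved translation updates for the group means: move the mean
    // and all subject effects rigidly, so the mean mixes through the data
    // rather than only through the (slowly moving) subject effects.
    for (int which = 0; which < 2; ++which) {
      double& mu = which == 0 ? mu_int : mu_slope;
      double& ls = which == 0 ? ls_mu_i : ls_mu_s;
      std::vector<double>& u = which == 0 ? ui : si;
      const double shift = std::exp(ls) * R::norm_rand();
      std::vector<double> unew(n_subj), llnew(n_subj);
      double lr = R::dnorm(mu + shift, 0.0, 2.0, 1) -
                  R::dnorm(mu, 0.0, 2.0, 1);
      bool finite = true;
      for (int i = 0; i < n_subj; ++i) {
        unew[i] = u[i] + shift;
        llnew[i] = which == 0
          ? subj_loglik(dat, i, unew[i], si[i], a, z, t0)
          : subj_loglik(dat, i, ui[i], unew[i], a, z, t0);
        if (!R_finite(llnew[i])) { finite = false; break; }
        lr += llnew[i] - ll_subj[i];
      }
      const bool acc = finite && std::log(R::unif_rand()) < lr;
      if (acc) {
        mu += shift;
        u = unew;
        ll_subj = llnew;
      }
      if (it < n_warmup) adapt(ls, acc, it);
    }
    // --- interweaved (non-centered) SD updates: rescale subject effects
    // around the group mean while proposing sigma, so that sigma feels the
    // data likelihood directly; removes the funnel when sigma is near zero.
    for (int which = 0; which < 2; ++which) {
      double& sig = which == 0 ? sigma_int : sigma_slope;
      double& ls = which == 0 ? ls_asis_si : ls_asis_ss;
      const double mu = which == 0 ? mu_int : mu_slope;
      std::vector<double>& u = which == 0 ? ui : si;
      const double prop = sig * std::exp(std::exp(ls) * R::norm_rand());
      std::vector<double> unew(n_subj), llnew(n_subj);
      double lr = 0.0;
      for (int i = 0; i < n_subj; ++i)
        unew[i] = mu + (prop / sig) * (u[i] - mu);
      bool finite = true;
      for (int i = 0; i < n_subj; ++i) {
        llnew[i] = which == 0
          ? subj_loglik(dat, i, unew[i], si[i], a, z, t0)
          : subj_loglik(dat, i, ui[i], unew[i], a, z, t0);
        if (!R_finite(llnew[i])) { finite = false; break; }
        lr += llnew[i] - ll_subj[i];
      }
      // half-normal(1) prior ratio plus the log-scale proposal Jacobian;
      // the centered-prior and rescaling Jacobians cancel up to sigma'/sigma
      lr += -0.5 * (prop * prop - sig * sig);
      lr += std::log(prop) - std::log(sig);
      const bool acc = finite && std::log(R::unif_rand()) < lr;
      if (acc) {
        sig = prop;
        u = unew;
        ll_subj = llnew;
      }
      if (it < n_warmup) adapt(ls, acc, it);
    }
    // --- pooled a (log scale; Gamma(2, 1.5) prior)
    {
      const double prop = a * std::exp(std::exp(ls_a) * R::norm_rand());
      double lr = R::dgamma(prop, 2.0, 1.0 / 1.5, 1) -
                  R::dgamma(a, 2.0, 1.0 / 1.5, 1) +
                  std::log(prop) - std::log(a);
      double llp = full_loglik(dat, ui, si, prop, z, t0);
      double llc = 0.0;
      for (int i = 0; i < n_subj; ++i) llc += ll_subj[i];
      lr += llp - llc;
      const bool acc = R_finite(llp) && std::log(R::unif_rand()) < lr;
      if (acc) {
        a = prop;
        for (int i = 0; i < n_subj; ++i)
          ll_subj[i] = subj_loglik(dat, i, ui[i], si[i], a, z, t0);
      }
      if (it < n_warmup) adapt(ls_a, acc, it);
    }
    // --- pooled z (logit scale; Beta(2,2) prior)
    {
      const double lz = std::log(z / (1.0 - z)) +
                        std::exp(ls_z) * R::norm_rand();
      const double prop = 1.0 / (1.0 + std::exp(-lz));
      double lr = R::dbeta(prop, 2.0, 2.0, 1) - R::dbeta(z, 2.0, 2.0, 1) +
                  std::log(prop * (1 - prop)) - std::log(z * (1 - z));
      double llp = full_loglik(dat, ui, si, a, prop, t0);
      double llc = 0.0;
      for (int i = 0; i < n_subj; ++i) llc += ll_subj[i];
      lr += llp - llc;
      const bool acc = R_finite(llp) && std::log(R::unif_rand()) < lr;
      if (acc) {
        z = prop;
        for (int i = 0; i < n_subj; ++i)
          ll_subj[i] = subj_loglik(dat, i, ui[i], si[i], a, z, t0);
      }
      if (it < n_warmup) adapt(ls_z, acc, it);
    }
    // --- pooled t0 (logit over (t0_lo, t0_hi); uniform prior)
    {
      const double w = (t0 - t0_lo) / (t0_hi - t0_lo);
      const double lw = std::log(w / (1.0 - w)) +
                        std::exp(ls_t) * R::norm_rand();
      const double wp = 1.0 / (1.0 + std::exp(-lw));
      const double prop = t0_lo + wp * (t0_hi - t0_lo);
      double lr = std::log(wp * (1 - wp)) - std::log(w * (1 - w));
      double llp = full_loglik(dat, ui, si, a, z, prop);
      double llc = 0.0;
      for (int i = 0; i < n_subj; ++i) llc += ll_subj[i];
      lr += llp - llc;
      const bool acc = R_finite(llp) && std::log(R::unif_rand()) < lr;
      if (acc) {
        t0 = prop;
        for (int i = 0; i < n_subj; ++i)
          ll_subj[i] = subj_loglik(dat, i, ui[i], si[i], a, z, t0);
      }
      if (it < n_warmup) adapt(ls_t, acc, it);
    }
    if (it >= n_warmup) {
      const int row = it - n_warmup;
      draws(row, 0) = mu_int; draws(row, 1) = mu_slope;
      draws(row, 2) = sigma_int; draws(row, 3) = sigma_slope;
      draws(row, 4) = a; draws(row, 5) = z; draws(row, 6) = t0;
      for (int i = 0; i < n_subj; ++i) {
        draws(row, 7 + i) = ui[i];
        draws(row, 7 + n_subj + i) = si[i];
      }
    }
  }
  return List::create(_["draws"] = draws);
}

// Pointwise log-likelihood over posterior draws (for WAIC).
// [[Rcpp::export]]
NumericMatrix ddm_hier_pointwise_cpp(NumericMatrix draws, NumericVector rt,
                                     IntegerVector upper, IntegerVector subj,
                                     NumericVector x, int n_subj) {
  const int D = draws.nrow();
  const R_xlen_t N = rt.size();
  NumericMatrix out(D, N);
  for (int dIdx = 0; dIdx < D; ++dIdx) {
    const double a = draws(dIdx, 4), z = draws(dIdx, 5), t0 = draws(dIdx, 6);
    for (R_xlen_t r = 0; r < N; ++r) {
      const int i = subj[r];
      const double v = draws(dIdx, 7 + i) + draws(dIdx, 7 + n_subj + i) * x[r];
      out(dIdx, r) = wfpt_logdens(rt[r], upper[r], v, a, z, t0, 1e-7);
    }
  }
  return out;
}
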