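// Metropolis-within-Gibbs samplers for the two change-point models.
//
// Both samplers share the spike-and-slab change-point structure: tau = 0
// encodes "no change" (all observations from state 1); tau in {2..T} puts
// terms with time index t < tau in state 1 and t >= tau in state 2. The
// tau update is an exact categorical draw from its full conditional,
// computed in O(T) per sweep via prefix sums of state-1 per-term
// log-densities and suffix sums of state-2 terms.
//
// Random numbers come from R's RNG (RNGScope), so set.seed() in R gives
// full reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

// ---- small helpers ---------------------------------------------------------

// adaptive random-walk step-size state (log scale), Robbins-Monro toward a
// 0.44 acceptance rate; adaptation runs during burn-in only.
struct AdaptRW {
  double ls;     // log proposal sd
  int n;         // proposals made
  AdaptRW(double init_sd = 0.1) : ls(std::log(init_sd)), n(0) {}
  double sd() const { return std::exp(ls); }
  void adapt(bool accepted, bool burning) {
    ++n;
    if (burning) {
      double gain = std::min(0.25, 3.0 / std::sqrt((double)n));
      ls += gain * ((accepted ? 1.0 : 0.0) - 0.44);
      if (ls < -12.0) ls = -12.0;
      if (ls > 12.0) ls = 12.0;
    }
  }
};

static inline double wrap_pi(double a) {
  double out = a - 2.0 * M_PI * std::floor(a / (2.0 * M_PI) + 0.5);
  if (out <= -M_PI) out = M_PI;
  return out;
}

// draw tau from log-weights: index 0 <-> tau = 0, index k-1 <-> tau = k+1
// (slab values 2..T). lw has length T (1 spike + T-1 slab entries).
static int draw_tau(const std::vector<double>& lw) {
  double m = R_NegInf;
  for (double v : lw) if (v > m) m = v;
  if (!R_FINITE(m)) stop("change-point full conditional is degenerate (all -Inf).");
  double tot = 0.0;
  std::vector<double> p(lw.size());
  for (size_t i = 0; i < lw.size(); ++i) { p[i] = std::exp(lw[i] - m); tot += p[i]; }
  double u = unif_rand() * tot, c = 0.0;
  for (size_t i = 0; i < lw.size(); ++i) {
    c += p[i];
    if (u <= c) return (i == 0) ? 0 : (int)i + 1;
  }
  return (int)lw.size();  // tau = T (numerical edge)
}

static inline double wc_lpdf(double a, double gamma, double kappa) {
  return std::log1p(-kappa * kappa) - LOG2PI -
         std::log1p(kappa * kappa - 2.0 * kappa * std::cos(a - gamma));
}

// ---- LCPM ------------------------------------------------------------------

// per-term log-densities l1[t], l2[t] for t = 2..T stored at index t-2.
// eta_t = rho * y_{t-1} + (1 - rho) * mu_state ; Sigma = sigma^2 I.
static void lcpm_terms(const NumericMatrix& y, double mu1x, double mu1y,
                       double mu2x, double mu2y, double sigma, double rho,
                       std::vector<double>& l1, std::vector<double>& l2) {
  int T = y.nrow();
  double ls = std::log(sigma), inv2 = 0.5 / (sigma * sigma);
  for (int t = 1; t < T; ++t) {
    double bx = rho * y(t - 1, 0), by = rho * y(t - 1, 1);
    double d1x = y(t, 0) - (bx + (1 - rho) * mu1x);
    double d1y = y(t, 1) - (by + (1 - rho) * mu1y);
    double d2x = y(t, 0) - (bx + (1 - rho) * mu2x);
    double d2y = y(t, 1) - (by + (1 - rho) * mu2y);
    l1[t - 1] = -LOG2PI - 2.0 * ls - inv2 * (d1x * d1x + d1y * d1y);
    l2[t - 1] = -LOG2PI - 2.0 * ls - inv2 * (d2x * d2x + d2y * d2y);
  }
}

// total log-likelihood at a given tau from per-term vectors
static double loglik_at_tau(const std::vector<double>& l1,
                            const std::vector<double>& l2, int tau) {
  int n = l1.size();           // terms t = 2..T, index t-2
  double s = 0.0;
  int cut = (tau == 0) ? n : (tau - 2);  // terms with index < cut are state 1
  for (int j = 0; j < n; ++j) s += (j < cut) ? l1[j] : l2[j];
  return s;
}

// [[Rcpp::export]]
List lcpm_mcmc_cpp(NumericMatrix y, double w, double sigma_max, double mu_sd,
                   double rho_min, double rho_max, int n_iter, int n_burn,
                   int thin, NumericVector init, bool sample_continuous,
                   int fixed_tau, bool prior_only) {
  int T = y.nrow();
  if (T < 4) stop("need at least 4 locations to fit the LCPM.");
  RNGScope scope;

  double mu1x = init[0], mu1y = init[1], mu2x = init[2], mu2y = init[3];
  double sigma = init[4], rho = init[5];
  int tau = (int)init[6];

  int n_terms = T - 1;
  std::vector<double> l1(n_terms), l2(n_terms), lw(T);
  double lw_spike = std::log(w), lw_slab = std::log1p(-w) - std::log((double)(T - 1));

  AdaptRW ad_sigma(0.1), ad_rho(0.5);
  int n_keep = n_iter / thin;
  NumericMatrix draws(n_keep, 8);
  int row = 0, total = n_burn + n_iter;

  for (int it = 0; it < total; ++it) {
    bool burning = it < n_burn;

    if (prior_only) {
      mu1x = norm_rand() * mu_sd; mu1y = norm_rand() * mu_sd;
      mu2x = norm_rand() * mu_sd; mu2y = norm_rand() * mu_sd;
      sigma = unif_rand() * sigma_max;
      rho = rho_min + unif_rand() * (rho_max - rho_min);
      if (fixed_tau < 0) {
        if (unif_rand() < w) tau = 0;
        else tau = 2 + (int)std::floor(unif_rand() * (T - 1));
        if (tau > T) tau = T;
      }
    } else {
      // --- tau: exact categorical draw from its full conditional
      lcpm_terms(y, mu1x, mu1y, mu2x, mu2y, sigma, rho, l1, l2);
      if (fixed_tau >= 0) {
        tau = fixed_tau;
      } else {
        // prefix sums of state-1 terms, suffix sums of state-2 terms
        std::vector<double> pre(n_terms + 1, 0.0), suf(n_terms + 1, 0.0);
        for (int j = 0; j < n_terms; ++j) pre[j + 1] = pre[j] + l1[j];
        for (int j = n_terms - 1; j >= 0; --j) suf[j] = suf[j + 1] + l2[j];
        lw[0] = lw_spike + pre[n_terms];
        for (int k = 2; k <= T; ++k) lw[k - 1] = lw_slab + pre[k - 2] + suf[k - 2];
        tau = draw_tau(lw);
      }

      // Label-swap move connecting the spike with its relabeled twin
      // tau = 2 (state 1 empty, identical likelihood with the state
      // parameters exchanged). Without it the Gibbs chain can absorb at
      // tau = 2 while the empty state's parameters drift in the prior,
      // grossly overstating P(tau = 2), whose exact posterior ratio to
      // P(tau = 0) is the prior odds (1 - w) / ((T - 1) w).
      if (sample_continuous && fixed_tau < 0 && (tau == 0 || tau == 2)) {
        double la = (tau == 0) ? (lw_slab - lw_spike) : (lw_spike - lw_slab);
        if (la >= 0 || std::log(unif_rand()) < la) {
          std::swap(mu1x, mu2x);
          std::swap(mu1y, mu2y);
          tau = (tau == 0) ? 2 : 0;
        }
      }

      if (sample_continuous) {
        // --- mu1, mu2: conjugate bivariate-normal draws (independent coords)
        // r_t = y_t - rho*y_{t-1} ~ N((1-rho)*mu_state, sigma^2 I)
        int cut = (tau == 0) ? T : tau;  // t in 2..cut-1 state 1, t in cut..T state 2
        double c1 = 1.0 - rho, prec_pr = 1.0 / (mu_sd * mu_sd);
        for (int state = 0; state < 2; ++state) {
          int lo = (state == 0) ? 1 : cut - 1;   // row index of t (0-based): t-1
          int hi = (state == 0) ? cut - 1 : T;   // exclusive bound on t-1... see below
          // state 1: t = 2..cut-1  -> rows t-1 = 1..cut-2
          // state 2: t = cut..T    -> rows t-1 = cut-1..T-1
          int r_lo = (state == 0) ? 1 : cut - 1;
          int r_hi = (state == 0) ? cut - 1 : T - 1;  // inclusive
          (void)lo; (void)hi;
          double sx = 0.0, sy = 0.0; int ns = 0;
          if (!(state == 1 && tau == 0)) {
            for (int r = r_lo; r <= r_hi; ++r) {
              sx += y(r, 0) - rho * y(r - 1, 0);
              sy += y(r, 1) - rho * y(r - 1, 1);
              ++ns;
            }
          }
          double mx, my;
          if (ns == 0) {  // empty state: full conditional is the prior
            mx = norm_rand() * mu_sd; my = norm_rand() * mu_sd;
          } else {
            double prec = ns * c1 * c1 / (sigma * sigma) + prec_pr;
            double sd = std::sqrt(1.0 / prec);
            mx = (c1 * sx / (sigma * sigma)) / prec + norm_rand() * sd;
            my = (c1 * sy / (sigma * sigma)) / prec + norm_rand() * sd;
          }
          if (state == 0) { mu1x = mx; mu1y = my; } else { mu2x = mx; mu2y = my; }
        }

        // --- sigma: adaptive random walk on log(sigma), prior U(0, sigma_max)
        lcpm_terms(y, mu1x, mu1y, mu2x, mu2y, sigma, rho, l1, l2);
        double cur_ll = loglik_at_tau(l1, l2, tau);
        {
          double prop = sigma * std::exp(norm_rand() * ad_sigma.sd());
          bool acc = false;
          if (prop > 0 && prop < sigma_max) {
            std::vector<double> p1(n_terms), p2(n_terms);
            lcpm_terms(y, mu1x, mu1y, mu2x, mu2y, prop, rho, p1, p2);
            double prop_ll = loglik_at_tau(p1, p2, tau);
            // log-scale RW: Jacobian ratio prop/sigma
            double lr = prop_ll - cur_ll + std::log(prop) - std::log(sigma);
            if (std::log(unif_rand()) < lr) {
              sigma = prop; cur_ll = prop_ll; l1 = p1; l2 = p2; acc = true;
            }
          }
          ad_sigma.adapt(acc, burning);
        }

        // --- rho: adaptive random walk on logit scale over (rho_min, rho_max)
        {
          double range = rho_max - rho_min;
          double p0 = (rho - rho_min) / range;
          double z = std::log(p0 / (1.0 - p0)) + norm_rand() * ad_rho.sd();
          double p1r = 1.0 / (1.0 + std::exp(-z));
          double prop = rho_min + range * p1r;
          std::vector<double> q1(n_terms), q2(n_terms);
          lcpm_terms(y, mu1x, mu1y, mu2x, mu2y, sigma, prop, q1, q2);
          double prop_ll = loglik_at_tau(q1, q2, tau);
          double lr = prop_ll - cur_ll +
            std::log(p1r * (1.0 - p1r)) - std::log(p0 * (1.0 - p0));
          bool acc = std::log(unif_rand()) < lr;
          if (acc) { rho = prop; cur_ll = prop_ll; l1 = q1; l2 = q2; }
          ad_rho.adapt(acc, burning);
        }
      }
    }

    if (!burning && ((it - n_burn) % thin == thin - 1)) {
      double ll = NA_REAL;
      if (!prior_only) {
        lcpm_terms(y, mu1x, mu1y, mu2x, mu2y, sigma, rho, l1, l2);
        ll = loglik_at_tau(l1, l2, tau);
      }
      draws(row, 0) = mu1x; draws(row, 1) = mu1y;
      draws(row, 2) = mu2x; draws(row, 3) = mu2y;
      draws(row, 4) = sigma; draws(row, 5) = rho;
      draws(row, 6) = tau; draws(row, 7) = ll;
      ++row;
    }
  }
  colnames(draws) = CharacterVector::create("mu1_x", "mu1_y", "mu2_x", "mu2_y",
                                            "sigma", "rho", "tau", "loglik");
  return List::create(_["draws"] = draws,
                      _["accept_sd"] = NumericVector::create(ad_sigma.sd(), ad_rho.sd()));
}

// ---- MMCPM -----------------------------------------------------------------

struct MMState {
  double gamma[2], kappa[2];
  double alpha[2], beta[2];   // weibull shape/scale
  double lambda[2];           // exponential rate
};

// Precomputed data transforms shared by all likelihood evaluations:
// log steps (with prefix sums), step prefix sums, cos/sin of angles and a
// validity mask (with prefix counts). These make every per-term density
// one exp / one log1p.
struct MMData {
  int n;
  std::vector<double> step, ls, cum_ls, cum_s, ca, sa;
  std::vector<int> valid, cum_v;
  MMData(const NumericVector& st, const NumericVector& an) {
    n = st.size();
    step.resize(n); ls.resize(n); ca.resize(n); sa.resize(n); valid.resize(n);
    cum_ls.assign(n + 1, 0.0); cum_s.assign(n + 1, 0.0); cum_v.assign(n + 1, 0);
    for (int j = 0; j < n; ++j) {
      step[j] = st[j]; ls[j] = std::log(st[j]);
      if (ISNAN(an[j])) { valid[j] = 0; ca[j] = sa[j] = 0.0; }
      else { valid[j] = 1; ca[j] = std::cos(an[j]); sa[j] = std::sin(an[j]); }
      cum_ls[j + 1] = cum_ls[j] + ls[j];
      cum_s[j + 1] = cum_s[j] + step[j];
      cum_v[j + 1] = cum_v[j] + valid[j];
    }
  }
};

// sum of wrapped Cauchy log-densities over term indices [j0, j1)
static double angle_ll(const MMData& d, int j0, int j1, double gamma,
                       double kappa) {
  int nv = d.cum_v[j1] - d.cum_v[j0];
  if (nv == 0) return 0.0;
  double cg = std::cos(gamma), sg = std::sin(gamma), k2 = kappa * kappa;
  double acc = 0.0;
  for (int j = j0; j < j1; ++j)
    if (d.valid[j])
      acc += std::log1p(k2 - 2.0 * kappa * (d.ca[j] * cg + d.sa[j] * sg));
  return nv * (std::log1p(-k2) - LOG2PI) - acc;
}

// sum of Weibull(shape alpha, scale beta) log-densities over [j0, j1)
static double step_ll_weibull(const MMData& d, int j0, int j1, double alpha,
                              double beta) {
  int m = j1 - j0;
  if (m == 0) return 0.0;
  double lb = std::log(beta), acc = 0.0;
  for (int j = j0; j < j1; ++j) acc += std::exp(alpha * (d.ls[j] - lb));
  return m * (std::log(alpha) - alpha * lb) +
         (alpha - 1.0) * (d.cum_ls[j1] - d.cum_ls[j0]) - acc;
}

// sum of exponential(rate lambda) log-densities over [j0, j1): O(1)
static double step_ll_exp(const MMData& d, int j0, int j1, double lambda) {
  int m = j1 - j0;
  return m * std::log(lambda) - lambda * (d.cum_s[j1] - d.cum_s[j0]);
}

// per-term joint log-density at t = 2..T (index t-2) for each state
static void mm_terms(const MMData& d, int family, const MMState& s,
                     std::vector<double>& l1, std::vector<double>& l2) {
  double cg[2], sg[2], k2[2], wc0[2], lb[2], wb0[2];
  for (int i = 0; i < 2; ++i) {
    cg[i] = std::cos(s.gamma[i]); sg[i] = std::sin(s.gamma[i]);
    k2[i] = s.kappa[i] * s.kappa[i];
    wc0[i] = std::log1p(-k2[i]) - LOG2PI;
    if (family == 0) {
      lb[i] = std::log(s.beta[i]);
      wb0[i] = std::log(s.alpha[i]) - s.alpha[i] * lb[i];
    }
  }
  for (int j = 0; j < d.n; ++j) {
    double v1, v2;
    if (family == 0) {
      v1 = wb0[0] + (s.alpha[0] - 1.0) * d.ls[j] -
           std::exp(s.alpha[0] * (d.ls[j] - lb[0]));
      v2 = wb0[1] + (s.alpha[1] - 1.0) * d.ls[j] -
           std::exp(s.alpha[1] * (d.ls[j] - lb[1]));
    } else {
      v1 = std::log(s.lambda[0]) - s.lambda[0] * d.step[j];
      v2 = std::log(s.lambda[1]) - s.lambda[1] * d.step[j];
    }
    if (d.valid[j]) {
      v1 += wc0[0] - std::log1p(k2[0] - 2.0 * s.kappa[0] *
                                (d.ca[j] * cg[0] + d.sa[j] * sg[0]));
      v2 += wc0[1] - std::log1p(k2[1] - 2.0 * s.kappa[1] *
                                (d.ca[j] * cg[1] + d.sa[j] * sg[1]));
    }
    l1[j] = v1; l2[j] = v2;
  }
}

// [[Rcpp::export]]
List mmcpm_mcmc_cpp(NumericVector step, NumericVector angle, int family,
                    double w, double beta_max,
                    double alpha_prior_shape, double alpha_prior_rate,
                    double lambda_prior_shape, double lambda_prior_rate,
                    int n_iter, int n_burn, int thin, NumericVector init,
                    bool sample_continuous, int fixed_tau, bool prior_only) {
  int n = step.size();       // terms t = 2..T at index t-2
  int T = n + 1;             // number of locations
  if (n < 3) stop("need at least 4 usable metric terms to fit the MMCPM.");
  for (int j = 0; j < n; ++j)
    if (!(step[j] > 0) || ISNAN(step[j]))
      stop("step lengths must be positive; clean zero-length steps upstream.");
  RNGScope scope;
  MMData d(step, angle);

  MMState s;
  s.gamma[0] = init[0]; s.kappa[0] = init[1];
  s.gamma[1] = init[2]; s.kappa[1] = init[3];
  s.alpha[0] = init[4]; s.beta[0] = init[5];
  s.alpha[1] = init[6]; s.beta[1] = init[7];
  s.lambda[0] = init[8]; s.lambda[1] = init[9];
  int tau = (int)init[10];

  std::vector<double> l1(n), l2(n), lw(T);
  double lw_spike = std::log(w), lw_slab = std::log1p(-w) - std::log((double)(T - 1));

  AdaptRW ad_gamma[2] = {AdaptRW(0.2), AdaptRW(0.2)};
  AdaptRW ad_kappa[2] = {AdaptRW(0.1), AdaptRW(0.1)};
  AdaptRW ad_alpha[2] = {AdaptRW(0.1), AdaptRW(0.1)};
  AdaptRW ad_beta[2]  = {AdaptRW(5.0), AdaptRW(5.0)};

  int n_keep = n_iter / thin;
  NumericMatrix draws(n_keep, 12);
  int row = 0, total = n_burn + n_iter;

  for (int it = 0; it < total; ++it) {
    bool burning = it < n_burn;

    if (prior_only) {
      for (int i = 0; i < 2; ++i) {
        s.gamma[i] = -M_PI + unif_rand() * 2.0 * M_PI;
        s.kappa[i] = unif_rand();
        s.alpha[i] = R::rgamma(alpha_prior_shape, 1.0 / alpha_prior_rate);
        s.beta[i]  = unif_rand() * beta_max;
        s.lambda[i] = R::rgamma(lambda_prior_shape, 1.0 / lambda_prior_rate);
      }
      if (fixed_tau < 0) {
        if (unif_rand() < w) tau = 0;
        else { tau = 2 + (int)std::floor(unif_rand() * (T - 1)); if (tau > T) tau = T; }
      }
    } else {
      // --- tau update
      mm_terms(d, family, s, l1, l2);
      if (fixed_tau >= 0) {
        tau = fixed_tau;
      } else {
        std::vector<double> pre(n + 1, 0.0), suf(n + 1, 0.0);
        for (int j = 0; j < n; ++j) pre[j + 1] = pre[j] + l1[j];
        for (int j = n - 1; j >= 0; --j) suf[j] = suf[j + 1] + l2[j];
        lw[0] = lw_spike + pre[n];
        for (int k = 2; k <= T; ++k) lw[k - 1] = lw_slab + pre[k - 2] + suf[k - 2];
        tau = draw_tau(lw);
      }

      // label-swap move between tau = 0 and its relabeled twin tau = 2
      // (see the LCPM sampler for the rationale)
      if (sample_continuous && fixed_tau < 0 && (tau == 0 || tau == 2)) {
        double la = (tau == 0) ? (lw_slab - lw_spike) : (lw_spike - lw_slab);
        if (la >= 0 || std::log(unif_rand()) < la) {
          std::swap(s.gamma[0], s.gamma[1]);
          std::swap(s.kappa[0], s.kappa[1]);
          std::swap(s.alpha[0], s.alpha[1]);
          std::swap(s.beta[0], s.beta[1]);
          std::swap(s.lambda[0], s.lambda[1]);
          tau = (tau == 0) ? 2 : 0;
        }
      }

      if (sample_continuous) {
        // term indices: state 1 = [0, cut), state 2 = [cut, n)
        int cut = (tau == 0) ? n : (tau - 2);
        for (int i = 0; i < 2; ++i) {
          int j0 = (i == 0) ? 0 : cut;
          int j1 = (i == 0) ? cut : n;
          bool empty = j0 >= j1;

          // gamma_i: wrapped random walk; uniform circular prior cancels
          {
            double prop = wrap_pi(s.gamma[i] + norm_rand() * ad_gamma[i].sd());
            bool acc;
            if (empty) {
              acc = true;  // target is the (flat) prior
            } else {
              double lr = angle_ll(d, j0, j1, prop, s.kappa[i]) -
                          angle_ll(d, j0, j1, s.gamma[i], s.kappa[i]);
              acc = std::log(unif_rand()) < lr;
            }
            if (acc) s.gamma[i] = prop;
            ad_gamma[i].adapt(acc, burning);
          }
          // kappa_i: random walk on (0, 1), uniform prior
          {
            double prop = s.kappa[i] + norm_rand() * ad_kappa[i].sd();
            bool acc = false;
            if (prop > 0 && prop < 1) {
              if (empty) {
                acc = true;
              } else {
                double lr = angle_ll(d, j0, j1, s.gamma[i], prop) -
                            angle_ll(d, j0, j1, s.gamma[i], s.kappa[i]);
                acc = std::log(unif_rand()) < lr;
              }
            }
            if (acc) s.kappa[i] = prop;
            ad_kappa[i].adapt(acc, burning);
          }

          if (family == 0) {
            // alpha_i: log-scale random walk, Gamma(shape, rate) prior
            {
              double prop = s.alpha[i] * std::exp(norm_rand() * ad_alpha[i].sd());
              double lpr = (alpha_prior_shape - 1.0) *
                             (std::log(prop) - std::log(s.alpha[i])) -
                           alpha_prior_rate * (prop - s.alpha[i]) +
                           std::log(prop) - std::log(s.alpha[i]);  // + Jacobian
              double lr = lpr;
              if (!empty)
                lr += step_ll_weibull(d, j0, j1, prop, s.beta[i]) -
                      step_ll_weibull(d, j0, j1, s.alpha[i], s.beta[i]);
              bool acc = std::log(unif_rand()) < lr;
              if (acc) s.alpha[i] = prop;
              ad_alpha[i].adapt(acc, burning);
            }
            // beta_i: random walk on (0, beta_max), uniform prior
            {
              double prop = s.beta[i] + norm_rand() * ad_beta[i].sd();
              bool acc = false;
              if (prop > 0 && prop < beta_max) {
                if (empty) {
                  acc = true;
                } else {
                  double lr = step_ll_weibull(d, j0, j1, s.alpha[i], prop) -
                              step_ll_weibull(d, j0, j1, s.alpha[i], s.beta[i]);
                  acc = std::log(unif_rand()) < lr;
                }
              }
              if (acc) s.beta[i] = prop;
              ad_beta[i].adapt(acc, burning);
            }
          } else {
            // lambda_i: conjugate Gamma full conditional
            double ssum = d.cum_s[j1] - d.cum_s[j0];
            int ns = j1 - j0;
            s.lambda[i] = R::rgamma(lambda_prior_shape + ns,
                                    1.0 / (lambda_prior_rate + ssum));
          }
        }
      }
    }

    if (!burning && ((it - n_burn) % thin == thin - 1)) {
      double ll = NA_REAL;
      if (!prior_only) {
        mm_terms(d, family, s, l1, l2);
        ll = loglik_at_tau(l1, l2, tau);
      }
      draws(row, 0) = s.gamma[0]; draws(row, 1) = s.kappa[0];
      draws(row, 2) = s.gamma[1]; draws(row, 3) = s.kappa[1];
      draws(row, 4) = s.alpha[0]; draws(row, 5) = s.beta[0];
      draws(row, 6) = s.alpha[1]; draws(row, 7) = s.beta[1];
      draws(row, 8) = s.lambda[0]; draws(row, 9) = s.lambda[1];
      draws(row, 10) = tau; draws(row, 11) = ll;
      ++row;
    }
  }
  colnames(draws) = CharacterVector::create(
      "gamma1", "kappa1", "gamma2", "kappa2", "alpha1", "beta1", "alpha2",
      "beta2", "lambda1", "lambda2", "tau", "loglik");
  return List::create(_["draws"] = draws);
}
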