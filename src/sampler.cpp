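#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the production-suitability
// state-space model.
//
//   Y_t  ~ N( V * ES_t / (ES_t + K), delta )
//   ES_t = 1/HD_t + a/R_t + b/C_t + c/T_t + d/W_t + e*S_t + f*N_t + g*Q_t
//   HD_t | HD_{t-1} ~ N(HD_{t-1}, tau),  HD_1 = 1 fixed
//
// Conjugate Gibbs updates: V (likelihood linear in V under a normal
// prior), and the precisions 1/delta and 1/tau (gamma-normal conjugacy).
// Random-walk Metropolis updates with batchwise scale adaptation:
// K, the seven effect coefficients, and each latent HD_t site.
// Proposals outside the support (negative coefficients, HD below the
// floor) are rejected outright, which is a valid Metropolis move for a
// target that is zero there.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct State {
  double V, K;
  std::vector<double> coef;   // a..g
  double delta, tau;          // variances
  std::vector<double> hd;     // length n, hd[0] == 1
};

// z_j: the per-year multiplier of coefficient j in ES
// (reciprocal covariate for a..d, plain covariate for e..g)
static void coef_design(const NumericMatrix& cov,
                        std::vector< std::vector<double> >& z) {
  int n = cov.nrow();
  z.assign(7, std::vector<double>(n));
  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < 4; ++j) z[j][t] = 1.0 / cov(t, j);
    for (int j = 4; j < 7; ++j) z[j][t] = cov(t, j);
  }
}

static void compute_es(const State& s,
                       const std::vector< std::vector<double> >& z,
                       std::vector<double>& es) {
  int n = (int) s.hd.size();
  es.assign(n, 0.0);
  for (int t = 0; t < n; ++t) {
    double v = 1.0 / s.hd[t];
    for (int j = 0; j < 7; ++j) v += s.coef[j] * z[j][t];
    es[t] = v;
  }
}

static inline double curve_mean(double V, double K, double es) {
  return V * es / (es + K);
}

// residual sum of squares of y about the curve means
static double rss(const NumericVector& y, const State& s,
                  const std::vector<double>& es) {
  double out = 0.0;
  for (int t = 0; t < (int) es.size(); ++t) {
    double r = y[t] - curve_mean(s.V, s.K, es[t]);
    out += r * r;
  }
  return out;
}

// [[Rcpp::export(name = ".psm_mcmc_cpp")]]
List psm_mcmc_cpp(NumericVector y, NumericMatrix cov, List prior,
                  List init, List control) {
  int n = y.size();
  if (cov.nrow() != n || cov.ncol() != 7)
    stop("internal: covariate matrix must be n x 7");

  double v_mean = prior["v_mean"], v_sd = prior["v_sd"];
  double coef_shape = prior["coef_shape"], coef_rate = prior["coef_rate"];
  double obs_shape = prior["obs_prec_shape"], obs_rate = prior["obs_prec_rate"];
  double rw_shape = prior["rw_prec_shape"], rw_rate = prior["rw_prec_rate"];

  int iterations = control["iterations"];
  int thin = control["thin"];
  int adapt_iters = control["adapt_iters"];
  bool use_lik = control["use_likelihood"];
  double hd_floor = control["hd_floor"];
  LogicalVector upd = control["update"];  // V,K,coefs,delta,tau,hd

  State s;
  s.V = init["V"]; s.K = init["K"];
  NumericVector ic = init["coefs"];
  s.coef.assign(ic.begin(), ic.end());
  s.delta = init["delta"]; s.tau = init["tau"];
  NumericVector ih = init["hd"];
  s.hd.assign(ih.begin(), ih.end());
  if (s.hd[0] != 1.0) stop("internal: HD must start at 1");

  std::vector< std::vector<double> > z;
  coef_design(cov, z);
  std::vector<double> es;
  compute_es(s, z, es);
  for (int t = 0; t < n; ++t)
    if (!(es[t] > 0)) stop("non-positive suitability at initialization");

  // log prior density of a nonnegative coefficient (gamma, unnormalized
  // terms kept: full density so diagnostics stay interpretable)
  auto lcoef = [&](double x) {
    if (x < 0) return NEG_INF;
    return R::dgamma(x, coef_shape, 1.0 / coef_rate, 1);
  };

  // likelihood contribution of one year
  auto llik_t = [&](double mu, double yt) {
    double r = yt - mu;
    return -0.5 * r * r / s.delta;
  };

  // adaptive proposal scales: K, a..g, HD_2..HD_n, (V,K) ridge,
  // (K, a..g) scale move
  int n_scales = 8 + (n - 1) + 2;
  std::vector<double> lsc(n_scales, log(0.1));
  std::vector<int> acc(n_scales, 0), tries(n_scales, 0);
  std::vector<long> acc_total(n_scales, 0), tries_total(n_scales, 0);
  const int batch = 50;
  int batch_no = 1;

  int keep = iterations / thin;
  int ncol = 11 + n;  // V,K,a..g,delta,tau,HD_1..HD_n
  NumericMatrix draws(keep, ncol);
  int row = 0;

  for (int it = 1; it <= iterations; ++it) {
    bool adapting = it <= adapt_iters;

    // --- V: conjugate normal ---
    if (upd[0]) {
      if (use_lik) {
        double sw2 = 0.0, swy = 0.0;
        for (int t = 0; t < n; ++t) {
          double w = es[t] / (es[t] + s.K);
          sw2 += w * w;
          swy += w * y[t];
        }
        double prec = 1.0 / (v_sd * v_sd) + sw2 / s.delta;
        double mean = (v_mean / (v_sd * v_sd) + swy / s.delta) / prec;
        s.V = R::rnorm(mean, sqrt(1.0 / prec));
      } else {
        s.V = R::rnorm(v_mean, v_sd);
      }
    }

    // --- K: random-walk Metropolis ---
    if (upd[1]) {
      int si = 0;
      ++tries[si];
      double prop = R::rnorm(s.K, exp(lsc[si]));
      if (prop >= 0) {
        double la = lcoef(prop) - lcoef(s.K);
        if (use_lik) {
          for (int t = 0; t < n; ++t)
            la += llik_t(curve_mean(s.V, prop, es[t]), y[t]) -
                  llik_t(curve_mean(s.V, s.K, es[t]), y[t]);
        }
        if (la >= 0 || R::runif(0, 1) < exp(la)) { s.K = prop; ++acc[si]; }
      }
    }

    // --- joint (V, K) ridge move: multiply both by e^c ---
    // The curve is near scale-invariant in (V, K) when K is large
    // relative to ES (mu ~ V*ES/K), so single-site updates crawl along
    // a ridge; this log-scale move travels it directly.
    if (upd[0] && upd[1]) {
      for (int rep = 0; rep < 3 && s.V > 0 && s.K > 0; ++rep) {
        int si = 8 + (n - 1);
        ++tries[si];
        double c = R::rnorm(0.0, exp(lsc[si]));
        double Vp = s.V * exp(c), Kp = s.K * exp(c);
        double la = 2.0 * c;  // log-Jacobian of the multiplicative proposal
        la += lcoef(Kp) - lcoef(s.K);
        la += -0.5 * (Vp - v_mean) * (Vp - v_mean) / (v_sd * v_sd)
              + 0.5 * (s.V - v_mean) * (s.V - v_mean) / (v_sd * v_sd);
        if (use_lik) {
          for (int t = 0; t < n; ++t)
            la += llik_t(curve_mean(Vp, Kp, es[t]), y[t]) -
                  llik_t(curve_mean(s.V, s.K, es[t]), y[t]);
        }
        if (la >= 0 || R::runif(0, 1) < exp(la)) {
          s.V = Vp; s.K = Kp; ++acc[si];
        }
      }
    }

    // --- joint (K, a..g) scale move ---
    // Scaling K together with every coefficient leaves the curve nearly
    // unchanged in years where the covariate part dominates 1/HD.
    if (upd[1] && upd[2] && s.K > 0) {
      int si = 8 + (n - 1) + 1;
      ++tries[si];
      double c = R::rnorm(0.0, exp(lsc[si]));
      double g = exp(c);
      double Kp = s.K * g;
      double la = 8.0 * c;  // Jacobian: K and seven coefficients
      la += lcoef(Kp) - lcoef(s.K);
      for (int j = 0; j < 7; ++j)
        la += lcoef(s.coef[j] * g) - lcoef(s.coef[j]);
      std::vector<double> es_new(n);
      bool ok = true;
      for (int t = 0; t < n; ++t) {
        double covpart = es[t] - 1.0 / s.hd[t];
        es_new[t] = 1.0 / s.hd[t] + g * covpart;
        if (!(es_new[t] > 0)) { ok = false; break; }
      }
      if (ok) {
        if (use_lik) {
          for (int t = 0; t < n; ++t)
            la += llik_t(curve_mean(s.V, Kp, es_new[t]), y[t]) -
                  llik_t(curve_mean(s.V, s.K, es[t]), y[t]);
        }
        if (la >= 0 || R::runif(0, 1) < exp(la)) {
          s.K = Kp;
          for (int j = 0; j < 7; ++j) s.coef[j] *= g;
          es = es_new;
          ++acc[si];
        }
      }
    }

    // --- a..g: random-walk Metropolis, ES updated incrementally ---
    for (int j = 0; j < 7; ++j) {
      if (!upd[2]) break;
      int si = 1 + j;
      ++tries[si];
      double prop = R::rnorm(s.coef[j], exp(lsc[si]));
      if (prop < 0) continue;
      double dcoef = prop - s.coef[j];
      double la = lcoef(prop) - lcoef(s.coef[j]);
      if (use_lik) {
        for (int t = 0; t < n; ++t) {
          double es_new = es[t] + dcoef * z[j][t];
          la += llik_t(curve_mean(s.V, s.K, es_new), y[t]) -
                llik_t(curve_mean(s.V, s.K, es[t]), y[t]);
        }
      }
      if (la >= 0 || R::runif(0, 1) < exp(la)) {
        s.coef[j] = prop;
        for (int t = 0; t < n; ++t) es[t] += dcoef * z[j][t];
        ++acc[si];
      }
    }

    // --- delta: conjugate gamma on the precision ---
    if (upd[3]) {
      double shape = obs_shape, rate = obs_rate;
      if (use_lik) {
        shape += 0.5 * n;
        rate += 0.5 * rss(y, s, es);
      }
      s.delta = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    // --- tau: conjugate gamma on the precision (smoothness prior) ---
    if (upd[4]) {
      double ssq = 0.0;
      for (int t = 1; t < n; ++t) {
        double d = s.hd[t] - s.hd[t - 1];
        ssq += d * d;
      }
      s.tau = 1.0 / R::rgamma(rw_shape + 0.5 * (n - 1),
                              1.0 / (rw_rate + 0.5 * ssq));
    }

    // --- HD_2..HD_n: single-site random-walk Metropolis ---
    if (upd[5]) {
      for (int t = 1; t < n; ++t) {
        int si = 8 + (t - 1);
        ++tries[si];
        double cur = s.hd[t];
        double prop = R::rnorm(cur, exp(lsc[si]));
        if (prop < hd_floor) continue;
        double la = 0.0;
        // smoothness terms with both neighbours
        double dl = prop - s.hd[t - 1], dl0 = cur - s.hd[t - 1];
        la += -0.5 * (dl * dl - dl0 * dl0) / s.tau;
        if (t + 1 < n) {
          double dr = s.hd[t + 1] - prop, dr0 = s.hd[t + 1] - cur;
          la += -0.5 * (dr * dr - dr0 * dr0) / s.tau;
        }
        double es_new = es[t] - 1.0 / cur + 1.0 / prop;
        if (!(es_new > 0)) continue;
        if (use_lik)
          la += llik_t(curve_mean(s.V, s.K, es_new), y[t]) -
                llik_t(curve_mean(s.V, s.K, es[t]), y[t]);
        if (la >= 0 || R::runif(0, 1) < exp(la)) {
          s.hd[t] = prop;
          es[t] = es_new;
          ++acc[si];
        }
      }
    }

    // --- batchwise Robbins-Monro scale adaptation (burn-in only) ---
    if (adapting && it % batch == 0) {
      double step = std::min(0.05, 1.0 / sqrt((double) batch_no));
      for (int si = 0; si < n_scales; ++si) {
        if (tries[si] == 0) continue;
        double rate_acc = (double) acc[si] / tries[si];
        lsc[si] += (rate_acc > 0.44 ? step : -step);
        acc_total[si] += acc[si];
        tries_total[si] += tries[si];
        acc[si] = 0;
        tries[si] = 0;
      }
      ++batch_no;
    }

    if (it % thin == 0 && row < keep) {
      draws(row, 0) = s.V;
      draws(row, 1) = s.K;
      for (int j = 0; j < 7; ++j) draws(row, 2 + j) = s.coef[j];
      draws(row, 9) = s.delta;
      draws(row, 10) = s.tau;
      for (int t = 0; t < n; ++t) draws(row, 11 + t) = s.hd[t];
      ++row;
    }

    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  // fold any unflushed batch counts into the totals
  for (int si = 0; si < n_scales; ++si) {
    acc_total[si] += acc[si];
    tries_total[si] += tries[si];
  }
  NumericVector acc_rate(n_scales);
  for (int si = 0; si < n_scales; ++si)
    acc_rate[si] = tries_total[si] > 0 ?
      (double) acc_total[si] / tries_total[si] : NA_REAL;

  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate);
}
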