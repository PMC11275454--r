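// Marginalized likelihood and adaptive random-walk sampler for the
// seasonal dynamic occupancy model.  The latent use states are summed out
// by a two-state forward recursion per site, so the sampler only sees
// continuous parameters.  Random area effects are handled in the
// non-centered parameterization (offset = sd * u, u ~ N(0,1)) and the
// scales on the log scale with their Jacobian, which removes the
// funnel-shaped geometry that plagues centred random effects.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double softplus(double x) {
  // log(1 + exp(x)), stable
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct ModelData {
  NumericMatrix Xpsi;    // n x kpsi
  NumericMatrix Xtrans;  // 2n x kg (rows 1..n summer, n+1..2n winter)
  NumericMatrix Xp;      // 2n x kp
  IntegerVector area;    // n, 0-based
  int n_areas, n, TT;
  IntegerVector trans_winter; // TT-1, 0/1 label of origin season
  NumericMatrix zdays;   // n x TT: total effort over non-detection months
  IntegerVector det_i, det_t;  // 0-based site/season of each detection month
  NumericVector det_days;
  IntegerMatrix det_any; // n x TT
  int kpsi, kg, kp;

  explicit ModelData(const List& md)
    : Xpsi(as<NumericMatrix>(md["Xpsi"])),
      Xtrans(as<NumericMatrix>(md["Xtrans"])),
      Xp(as<NumericMatrix>(md["Xp"])),
      area(as<IntegerVector>(md["area0"])),
      n_areas(as<int>(md["n_areas"])),
      n(Xpsi.nrow()),
      TT(as<int>(md["n_seasons"])),
      trans_winter(as<IntegerVector>(md["trans_winter"])),
      zdays(as<NumericMatrix>(md["zdays"])),
      det_i(as<IntegerVector>(md["det_i"])),
      det_t(as<IntegerVector>(md["det_t"])),
      det_days(as<NumericVector>(md["det_days"])),
      det_any(as<IntegerMatrix>(md["det_any"])),
      kpsi(Xpsi.ncol()), kg(Xtrans.ncol()), kp(Xp.ncol()) {}

  int dim() const { return kpsi + 2 * kg + kp + 4 + 4 * n_areas; }
};

// theta layout: beta_psi | beta_gamma | beta_eps | beta_p |
//               log_sd[4] | u_raw[4 * n_areas] (psi, gamma, eps, p blocks)
static double loglik_full(const std::vector<double>& th, const ModelData& D,
                          const IntegerVector& season_winter) {
  const int n = D.n, TT = D.TT;
  const double* bp = th.data();
  const double* bg = bp + D.kpsi;
  const double* be = bg + D.kg;
  const double* bd = be + D.kg;
  const double* lsd = bd + D.kp;
  const double* u = lsd + 4;
  double sd[4];
  for (int k = 0; k < 4; ++k) sd[k] = std::exp(lsd[k]);

  std::vector<double> lpsi(n), lg(2 * n), le(2 * n), l1mp(2 * n);
  for (int i = 0; i < n; ++i) {
    double a = 0.0;
    for (int c = 0; c < D.kpsi; ++c) a += D.Xpsi(i, c) * bp[c];
    lpsi[i] = a + sd[0] * u[D.area[i]];
  }
  for (int r = 0; r < 2 * n; ++r) {
    int i = r % n;
    double ag = 0.0, ae = 0.0, ap = 0.0;
    for (int c = 0; c < D.kg; ++c) {
      double x = D.Xtrans(r, c);
      ag += x * bg[c];
      ae += x * be[c];
    }
    for (int c = 0; c < D.kp; ++c) ap += D.Xp(r, c) * bd[c];
    lg[r] = ag + sd[1] * u[D.n_areas + D.area[i]];
    le[r] = ae + sd[2] * u[2 * D.n_areas + D.area[i]];
    l1mp[r] = -softplus(ap + sd[3] * u[3 * D.n_areas + D.area[i]]);
  }

  std::vector<double> loge1(n * TT, 0.0);
  for (int t = 0; t < TT; ++t) {
    int off = season_winter[t] * n;
    for (int i = 0; i < n; ++i)
      loge1[i + n * t] = D.zdays(i, t) * l1mp[off + i];
  }
  for (int m = 0; m < D.det_i.size(); ++m) {
    int i = D.det_i[m], t = D.det_t[m];
    double l1 = D.det_days[m] * l1mp[season_winter[t] * n + i];
    // log(p*) = log(1 - exp(days * log(1-p)))
    loge1[i + n * t] += std::log(-std::expm1(l1));
  }

  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double la1 = -softplus(-lpsi[i]) + loge1[i];
    double la0 = D.det_any(i, 0) ? R_NegInf : -softplus(lpsi[i]);
    for (int t = 1; t < TT; ++t) {
      int r = D.trans_winter[t - 1] * n + i;
      double lgam = -softplus(-lg[r]), l1mg = -softplus(lg[r]);
      double leps = -softplus(-le[r]), l1me = -softplus(le[r]);
      double n1 = lse2(la1 + l1me, la0 + lgam) + loge1[i + n * t];
      double n0 = D.det_any(i, t) ? R_NegInf
                                  : lse2(la1 + leps, la0 + l1mg);
      la1 = n1; la0 = n0;
    }
    total += lse2(la1, la0);
  }
  return total;
}

// prior = (logistic scale on intercepts, normal sd on slopes,
//          half-normal scale on random-effect sds)
static double log_prior(const std::vector<double>& th, const ModelData& D,
                        const NumericVector& prior) {
  const double LOG_2PI = 1.8378770664093454836;
  const double s_int = prior[0], s_coef = prior[1], s_sd = prior[2];
  double lp = 0.0;
  int kcum[4] = {0, D.kpsi, D.kpsi + D.kg, D.kpsi + 2 * D.kg};
  int nb = D.kpsi + 2 * D.kg + D.kp;
  for (int j = 0; j < nb; ++j) {
    bool is_int = (j == kcum[0] || j == kcum[1] || j == kcum[2] ||
                   j == kcum[3]);
    double x = th[j];
    if (is_int) {
      double xs = x / s_int;                     // logistic(0, s)
      lp += -xs - 2.0 * softplus(-xs) - std::log(s_int);
    } else {
      lp += -0.5 * LOG_2PI - std::log(s_coef)
            - 0.5 * (x / s_coef) * (x / s_coef);
    }
  }
  for (int k = 0; k < 4; ++k) {
    double s = th[nb + k];
    double sd = std::exp(s);
    // half-normal(s_sd) on sd, plus Jacobian of the log transform
    lp += std::log(2.0) - 0.5 * LOG_2PI - std::log(s_sd)
          - 0.5 * (sd / s_sd) * (sd / s_sd) + s;
  }
  for (int j = nb + 4; j < (int)th.size(); ++j) {
    double x = th[j];
    lp += -0.5 * LOG_2PI - 0.5 * x * x;          // u_raw ~ N(0, 1)
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_loglik(NumericVector theta, List md) {
  ModelData D(md);
  std::vector<double> th(theta.begin(), theta.end());
  if ((int)th.size() != D.dim()) stop("theta has wrong length");
  return loglik_full(th, D, as<IntegerVector>(md["season_winter"]));
}

// [[Rcpp::export]]
double cpp_log_target(NumericVector theta, List md) {
  ModelData D(md);
  std::vector<double> th(theta.begin(), theta.end());
  if ((int)th.size() != D.dim()) stop("theta has wrong length");
  return loglik_full(th, D, as<IntegerVector>(md["season_winter"])) +
         log_prior(th, D, as<NumericVector>(md["prior"]));
}

// in-place lower Cholesky of A (d x d, row-major); returns false if not PD
static bool cholesky(std::vector<double>& A, int d) {
  for (int j = 0; j < d; ++j) {
    double s = A[j * d + j];
    for (int k = 0; k < j; ++k) s -= A[j * d + k] * A[j * d + k];
    if (s <= 0.0) return false;
    double Ljj = std::sqrt(s);
    A[j * d + j] = Ljj;
    for (int i = j + 1; i < d; ++i) {
      double v = A[i * d + j];
      for (int k = 0; k < j; ++k) v -= A[i * d + k] * A[j * d + k];
      A[i * d + j] = v / Ljj;
    }
    for (int k = j + 1; k < d; ++k) A[j * d + k] = 0.0;
  }
  return true;
}

// Blockwise adaptive random-walk Metropolis.  One iteration is a full
// sweep over the parameter blocks (one block per linear predictor:
// its coefficients, log random-effect scale and area offsets jointly);
// each block carries its own empirical proposal covariance and a
// Robbins-Monro-tuned scale targeting 25% acceptance.  Adaptation is
// frozen at the end of burn-in.  Uses R's RNG, so set.seed() makes runs
// reproducible.
struct Block {
  std::vector<int> idx;
  std::vector<double> mean, M2, L;
  double ls;
  bool haveL = false;
  long tries = 0, accepts = 0;
};

// [[Rcpp::export]]
List cpp_sample(List md, NumericVector init, int n_iter, int n_burnin,
                int thin, List block_idx) {
  ModelData D(md);
  IntegerVector season_winter = as<IntegerVector>(md["season_winter"]);
  NumericVector prior = as<NumericVector>(md["prior"]);
  const int d = D.dim();
  if (init.size() != d) stop("init has wrong length");
  if (n_burnin >= n_iter) stop("burn-in must be smaller than iterations");
  const int S = (n_iter - n_burnin) / thin;

  std::vector<Block> blocks;
  for (int b = 0; b < block_idx.size(); ++b) {
    Block blk;
    IntegerVector iv = block_idx[b];   // 0-based
    blk.idx.assign(iv.begin(), iv.end());
    int m = blk.idx.size();
    blk.mean.assign(m, 0.0);
    blk.M2.assign((size_t)m * m, 0.0);
    blk.L.assign((size_t)m * m, 0.0);
    blk.ls = std::log(2.38 / std::sqrt((double)m));
    blocks.push_back(blk);
  }

  std::vector<double> theta(init.begin(), init.end());
  double lp = loglik_full(theta, D, season_winter) + log_prior(theta, D, prior);
  if (!std::isfinite(lp)) stop("non-finite log posterior at initial values");

  NumericMatrix draws(S, d);
  long n_acc = 0, n_post = 0;
  int stored = 0;
  std::vector<double> prop(d);

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    for (size_t b = 0; b < blocks.size(); ++b) {
      Block& blk = blocks[b];
      const int m = blk.idx.size();
      std::vector<double> z(m);
      for (int j = 0; j < m; ++j) z[j] = norm_rand();
      prop = theta;
      double scale = std::exp(blk.ls);
      if (blk.haveL) {
        for (int i = 0; i < m; ++i) {
          double s = 0.0;
          for (int k = 0; k <= i; ++k) s += blk.L[(size_t)i * m + k] * z[k];
          prop[blk.idx[i]] += scale * s;
        }
      } else {
        double sd0 = 0.1 / std::sqrt((double)m);
        for (int i = 0; i < m; ++i) prop[blk.idx[i]] += sd0 * z[i];
      }
      double lp_new = loglik_full(prop, D, season_winter)
                      + log_prior(prop, D, prior);
      double lr = lp_new - lp;
      double alpha = std::isfinite(lp_new)
        ? (lr >= 0.0 ? 1.0 : std::exp(lr)) : 0.0;
      if (unif_rand() < alpha) {
        theta = prop;
        lp = lp_new;
        if (it > n_burnin) ++n_acc;
      }
      if (it > n_burnin) ++n_post;

      if (it <= n_burnin) {
        // per-block running moments of the current state
        std::vector<double> delta(m);
        for (int j = 0; j < m; ++j) delta[j] = theta[blk.idx[j]] - blk.mean[j];
        for (int j = 0; j < m; ++j) blk.mean[j] += delta[j] / it;
        for (int i = 0; i < m; ++i) {
          double di = theta[blk.idx[i]] - blk.mean[i];
          double* row = &blk.M2[(size_t)i * m];
          for (int j = 0; j <= i; ++j) row[j] += di * delta[j];
        }
        double gam = 1.0 / std::pow((double)it, 0.6);
        if (gam > 0.05) gam = 0.05;
        blk.ls += gam * (alpha - 0.25);
        if (it >= 2 * m + 10 && it % 100 == 0) {
          std::vector<double> C((size_t)m * m);
          for (int i = 0; i < m; ++i)
            for (int j = 0; j <= i; ++j) {
              double v = blk.M2[(size_t)i * m + j] / (it - 1);
              C[(size_t)i * m + j] = v;
              C[(size_t)j * m + i] = v;
            }
          for (int i = 0; i < m; ++i) C[(size_t)i * m + i] += 1e-8;
          if (cholesky(C, m)) {
            blk.L = C;
            blk.haveL = true;
          }
        }
      }
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
    if (it > n_burnin && (it - n_burnin) % thin == 0 && stored < S) {
      for (int j = 0; j < d; ++j) draws(stored, j) = theta[j];
      ++stored;
    }
  }
  return List::create(_["draws"] = draws,
                      _["accept"] = n_post ? (double)n_acc / n_post : NA_REAL);
}
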