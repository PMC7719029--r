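// Trial-level likelihood of the ex-Gaussian race model with go-failure and
// trigger-failure mixtures. Three runners: matching go, mismatching go, stop.
// Kept in C++ because the hierarchical sampler evaluates it millions of times.
#include <Rcpp.h>
#include <map>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
using namespace Rcpp;

// Underflowing likelihood factors are floored anyway; computing with
// subnormal doubles would only cost microcode assists in the hot loops.
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int ftz, daz;
  FlushDenormals() {
    ftz = _MM_GET_FLUSH_ZERO_MODE();
    daz = _MM_GET_DENORMALS_ZERO_MODE();
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() {
    _MM_SET_FLUSH_ZERO_MODE(ftz);
    _MM_SET_DENORMALS_ZERO_MODE(daz);
  }
#endif
};

static const double LOG_FLOOR = -745.0; // ~ log(smallest normal double)
static const double LOG_SQRT_2PI = 0.9189385332046727;

// standard normal CDF via erfc: accurate to ~1e-15 and much faster than the
// general-purpose pnorm in the quadrature loop
static inline double phi_cdf(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// log Phi(x); erfc underflows near -37.5, below that use the asymptotic
// expansion log phi(x) - log|x| + log(1 - 1/x^2 + 3/x^4)
static inline double log_phi(double x) {
  if (x >= 8.3) return 0.0; // 1 - Phi < 1e-16
  if (x > -37.0) {
    return std::log(phi_cdf(x));
  }
  double x2 = x * x;
  return -0.5 * x2 - LOG_SQRT_2PI - std::log(-x) +
    std::log1p(-1.0 / x2 + 3.0 / (x2 * x2));
}

static inline double exg_logpdf(double t, double mu, double sigma, double tau) {
  double k = (mu - t) / tau + sigma * sigma / (2.0 * tau * tau);
  return -std::log(tau) + k + log_phi((t - mu) / sigma - sigma / tau);
}

static inline double exg_surv(double t, double mu, double sigma, double tau) {
  double u = (t - mu) / sigma;
  if (u <= -8.3) return 1.0; // Phi(-u) = 1 to machine precision
  double k = (mu - t) / tau + sigma * sigma / (2.0 * tau * tau) +
    log_phi(u - sigma / tau);
  // flush underflowing terms to zero: subnormal intermediates would both be
  // meaningless and catastrophically slow in the quadrature loop
  double s = phi_cdf(-u) + (k < -700.0 ? 0.0 : std::exp(k));
  if (s < 1e-300) s = 0.0;
  if (s > 1.0) s = 1.0;
  return s;
}

// P(stop runner finishes before both go runners | all started), i.e.
// integral f_stop(v) S_match(d+v) S_mismatch(d+v) dv over the effective
// support of the stop runner's finishing time, by Gauss-Legendre on
// [mu_s - 10 sigma_s, mu_s + 15 (sigma_s + tau_s)] (mass outside is < 3e-7
// and is further damped by the go survivals).
struct StopIntegrator {
  std::vector<double> v, fw; // node positions and f_stop(v) * weight * range
  double m1, s1, t1, m2, s2, t2;
  std::map<double, double> cache;
  StopIntegrator(const NumericVector& x01, const NumericVector& w01,
                 const double* p) {
    double ms = p[6], ss = p[7], ts = p[8];
    m1 = p[0]; s1 = p[1]; t1 = p[2];
    m2 = p[3]; s2 = p[4]; t2 = p[5];
    double L = ms - 10.0 * ss;
    double U = ms + 15.0 * (ss + ts);
    int n = x01.size();
    v.resize(n); fw.resize(n);
    for (int j = 0; j < n; ++j) {
      v[j] = L + (U - L) * x01[j];
      double lp = exg_logpdf(v[j], ms, ss, ts);
      fw[j] = lp < -700.0 ? 0.0 : std::exp(lp) * w01[j] * (U - L);
      if (fw[j] < 1e-300) fw[j] = 0.0;
    }
  }
  double operator()(double d) {
    std::map<double, double>::iterator it = cache.find(d);
    if (it != cache.end()) return it->second;
    double acc = 0.0;
    for (size_t j = 0; j < v.size(); ++j) {
      if (fw[j] == 0.0) continue;
      double a = fw[j] * exg_surv(d + v[j], m1, s1, t1);
      if (a < 1e-300) continue;
      a *= exg_surv(d + v[j], m2, s2, t2);
      if (a >= 1e-300) acc += a;
    }
    if (acc < 1e-300) acc = 0.0;
    if (acc > 1.0) acc = 1.0;
    cache[d] = acc;
    return acc;
  }
};

// One trial. type: 0 go, 1 stop/no-go. responded/match as 0/1 flags.
// p: the 11 canonical parameters, probabilities on natural scale.
static double trial_ll(int type, int responded, int match, double rt,
                       double ssd, const double* p, StopIntegrator& I,
                       int& n_floor) {
  double ptf = p[9], pgf = p[10];
  double ll;
  if (type == 0) { // go trial
    if (!responded) {
      ll = std::log(pgf);
    } else {
      double lpdf, lsurv;
      if (match) {
        lpdf = exg_logpdf(rt, p[0], p[1], p[2]);
        lsurv = std::log(exg_surv(rt, p[3], p[4], p[5]));
      } else {
        lpdf = exg_logpdf(rt, p[3], p[4], p[5]);
        lsurv = std::log(exg_surv(rt, p[0], p[1], p[2]));
      }
      ll = std::log1p(-pgf) + lpdf + lsurv;
    }
  } else { // stop or no-go trial at delay ssd
    if (responded) {
      double lpdf, lsurv;
      if (match) {
        lpdf = exg_logpdf(rt, p[0], p[1], p[2]);
        lsurv = std::log(exg_surv(rt, p[3], p[4], p[5]));
      } else {
        lpdf = exg_logpdf(rt, p[3], p[4], p[5]);
        lsurv = std::log(exg_surv(rt, p[0], p[1], p[2]));
      }
      // survival of the stop runner at rt - ssd is 1 when rt <= ssd
      double sstop = exg_surv(rt - ssd, p[6], p[7], p[8]);
      ll = std::log1p(-pgf) + lpdf + lsurv +
        std::log(ptf + (1.0 - ptf) * sstop);
    } else {
      double pwin = I(ssd);
      ll = std::log(pgf + (1.0 - pgf) * (1.0 - ptf) * pwin);
    }
  }
  if (!std::isfinite(ll) || ll < LOG_FLOOR) {
    ll = LOG_FLOOR;
    ++n_floor;
  }
  return ll;
}

// [[Rcpp::export]]
List trial_loglik_cpp(IntegerVector type, IntegerVector responded,
                      IntegerVector match, NumericVector rt,
                      NumericVector ssd, NumericVector params,
                      NumericVector x01, NumericVector w01) {
  FlushDenormals guard;
  int n = type.size();
  NumericVector out(n);
  const double* p = REAL(params);
  StopIntegrator I(x01, w01, p);
  int n_floor = 0;
  for (int i = 0; i < n; ++i) {
    out[i] = trial_ll(type[i], responded[i], match[i], rt[i], ssd[i], p, I,
                      n_floor);
  }
  return List::create(_["loglik"] = out, _["n_floor"] = n_floor);
}

// Summed session log-likelihood for many parameter vectors at once (rows of
// `params`); this is the sampler's hot path.
// [[Rcpp::export]]
List session_loglik_multi_cpp(IntegerVector type, IntegerVector responded,
                              IntegerVector match, NumericVector rt,
                              NumericVector ssd, NumericMatrix params,
                              NumericVector x01, NumericVector w01) {
  FlushDenormals guard;
  int n = type.size(), m = params.nrow();
  NumericVector out(m);
  IntegerVector floors(m);
  std::vector<double> p(11);
  for (int r = 0; r < m; ++r) {
    for (int j = 0; j < 11; ++j) p[j] = params(r, j);
    StopIntegrator I(x01, w01, p.data());
    double acc = 0.0;
    int n_floor = 0;
    for (int i = 0; i < n; ++i) {
      acc += trial_ll(type[i], responded[i], match[i], rt[i], ssd[i],
                      p.data(), I, n_floor);
    }
    out[r] = acc;
    floors[r] = n_floor;
  }
  return List::create(_["loglik"] = out, _["n_floor"] = floors);
}
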