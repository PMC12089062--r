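#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Marginal log-likelihood for one morph at one site: latent abundance
// N ~ Poisson(lambda) is summed out over N = cmax..n_max, where cmax is the
// largest observed count (smaller N have zero likelihood) and n_max is the
// smallest N whose Poisson upper tail is below tail_tol (with a floor).
// A nonnegative n_max_cap either replaces the automatic rule (cap_exact,
// the user asked for that truncation point) or bounds it from above (a
// safety ceiling during sampling). Counts are Binomial(N, p_j); daily
// camera detections are Bernoulli(1 - (1 - p_d)^N).
static double site_morph_marginal(double lambda,
                                  const std::vector<double>& cnt,
                                  const std::vector<double>& p_cnt,
                                  double log_q0_sum,
                                  const std::vector<double>& q_one,
                                  int n_max_floor,
                                  double tail_tol,
                                  int n_max_cap,
                                  bool cap_exact) {
  if (!(lambda > 0.0)) stop("lambda must be positive");
  int cmax = 0;
  for (size_t j = 0; j < cnt.size(); ++j)
    if (cnt[j] > cmax) cmax = (int)cnt[j];

  int n_max = (int)R::qpois(1.0 - tail_tol, lambda, 1, 0);
  if (n_max < n_max_floor) n_max = n_max_floor;
  if (n_max_cap >= 0) {
    if (n_max_cap < cmax) stop("n_max below the maximum observed count");
    n_max = cap_exact ? n_max_cap : std::min(n_max, n_max_cap);
  }
  if (n_max < cmax) n_max = cmax;
  if (n_max > 1000000) stop("lambda too large for latent enumeration; cap n_max");

  const size_t n_one = q_one.size();
  const size_t n_cnt = cnt.size();

  // log k! for k = 0..n_max
  std::vector<double> lfac(n_max + 1);
  lfac[0] = 0.0;
  for (int k = 1; k <= n_max; ++k) lfac[k] = lfac[k - 1] + std::log((double)k);

  // per-count constants: c*log(p) - c*log(1-p) - log(c!)
  double cnt_const = 0.0, sum_log1mp = 0.0;
  std::vector<int> cint;
  cint.reserve(n_cnt);
  bool impossible = false, any_p1 = false;
  for (size_t j = 0; j < n_cnt; ++j) {
    double p = p_cnt[j], c = cnt[j];
    if (p <= 0.0) {
      if (c > 0) impossible = true;   // count > 0 with p = 0
    } else if (p >= 1.0) {
      any_p1 = true;                  // dbinom(c; N, 1) = 1 iff c == N
    } else {
      cnt_const += c * std::log(p) - c * std::log1p(-p) - lfac[(int)c];
      sum_log1mp += std::log1p(-p);
      cint.push_back((int)c);
    }
  }
  if (impossible) return R_NegInf;

  const double loglam = std::log(lambda);
  const int n_terms = n_max - cmax + 1;

  // camera-hit term per N: log prod_d (1 - q_d^N), accumulated day-major so
  // the per-N running products stay in cache; renormalized periodically to
  // dodge underflow
  std::vector<double> cam_prod(n_terms, 1.0), cam_log(n_terms, 0.0);
  if (n_one) {
    for (size_t d = 0; d < n_one; ++d) {
      const double q = q_one[d];
      double qp = std::pow(q, (double)cmax);
      for (int t = 0; t < n_terms; ++t) {
        cam_prod[t] *= (1.0 - qp);
        qp *= q;
      }
      if ((d & 31u) == 31u || d + 1 == n_one) {
        for (int t = 0; t < n_terms; ++t) {
          if (cam_prod[t] < 1e-280) {
            cam_log[t] += (cam_prod[t] > 0.0) ? std::log(cam_prod[t]) : R_NegInf;
            cam_prod[t] = 1.0;
          }
        }
      }
    }
    for (int t = 0; t < n_terms; ++t) cam_log[t] += std::log(cam_prod[t]);
  }

  std::vector<double> terms;
  terms.reserve(n_terms);
  double tmax = R_NegInf;
  for (int N = cmax; N <= n_max; ++N) {
    double lp = -lambda + N * loglam - lfac[N];
    if (any_p1) {
      // every p=1 count must equal N exactly
      bool ok = true;
      for (size_t j = 0; j < n_cnt; ++j)
        if (p_cnt[j] >= 1.0 && (int)cnt[j] != N) { ok = false; break; }
      if (!ok) lp = R_NegInf;
    }
    if (R_finite(lp)) {
      double s = cnt_const + N * (sum_log1mp + log_q0_sum);
      for (size_t j = 0; j < cint.size(); ++j)
        s += lfac[N] - lfac[N - cint[j]];
      lp += s + cam_log[N - cmax];
    }
    terms.push_back(lp);
    if (lp > tmax) tmax = lp;
  }
  if (!R_finite(tmax)) return R_NegInf;
  double s = 0.0;
  for (size_t i = 0; i < terms.size(); ++i)
    if (R_finite(terms[i])) s += std::exp(terms[i] - tmax);
  return tmax + std::log(s);
}

// One-morph marginal log-likelihood across all sites. Record vectors are
// indexed by 1-based site id; lambda has one entry per site.
// [[Rcpp::export(name = ".morph_loglik_cpp")]]
double morph_loglik_cpp(NumericVector lambda,
                        IntegerVector cnt_site, NumericVector cnt,
                        NumericVector p_cnt,
                        IntegerVector cam_site, IntegerVector cam_det,
                        NumericVector p_cam,
                        int n_max_floor, double tail_tol, int n_max_cap,
                        bool cap_exact) {
  int S = lambda.size();
  std::vector<std::vector<double> > s_cnt(S), s_pcnt(S), s_qone(S);
  std::vector<double> s_lq0(S, 0.0);
  std::vector<int> s_forceN0(S, 0);  // a p=1 day with no detection forces N=0
  for (int r = 0; r < cnt_site.size(); ++r) {
    int i = cnt_site[r] - 1;
    if (i < 0 || i >= S) stop("count record refers to unknown site");
    s_cnt[i].push_back(cnt[r]);
    s_pcnt[i].push_back(p_cnt[r]);
  }
  for (int r = 0; r < cam_site.size(); ++r) {
    int i = cam_site[r] - 1;
    if (i < 0 || i >= S) stop("camera record refers to unknown site");
    double q = 1.0 - p_cam[r];
    if (cam_det[r] == 1) {
      s_qone[i].push_back(q);
    } else {
      if (q <= 0.0) s_forceN0[i] = 1;
      else s_lq0[i] += std::log(q);
    }
  }
  double total = 0.0;
  for (int i = 0; i < S; ++i) {
    double ll;
    if (lambda[i] < 0.0) stop("lambda must be nonnegative");
    if (lambda[i] == 0.0) {
      // Poisson mass collapses onto N = 0: likelihood 1 iff nothing observed
      bool empty = s_qone[i].empty();
      for (size_t j = 0; j < s_cnt[i].size(); ++j)
        if (s_cnt[i][j] > 0) empty = false;
      ll = empty ? 0.0 : R_NegInf;
    } else if (s_forceN0[i]) {
      bool ok = s_qone[i].empty();
      for (size_t j = 0; j < s_cnt[i].size(); ++j)
        if (s_cnt[i][j] > 0) ok = false;
      ll = ok ? R::dpois(0.0, lambda[i], 1) : R_NegInf;
    } else {
      ll = site_morph_marginal(lambda[i], s_cnt[i], s_pcnt[i], s_lq0[i],
                               s_qone[i], n_max_floor, tail_tol, n_max_cap,
                               cap_exact);
    }
    if (!R_finite(ll)) return R_NegInf;
    total += ll;
  }
  return total;
}

// Fitting fast path: records pre-sorted by site with offset vectors
// (cnt_off, cam_off of length S+1), detection probabilities computed
// in place from the quadratic-temperature logit. Semantics are identical
// to morph_loglik_cpp; tests cross-check the two entry points.
// [[Rcpp::export(name = ".morph_loglik_fit_cpp")]]
double morph_loglik_fit_cpp(NumericVector lambda,
                            IntegerVector cnt_off, NumericVector cnt,
                            NumericVector t_cnt, NumericVector t2_cnt,
                            IntegerVector cam_off, IntegerVector cam_det,
                            NumericVector t_cam, NumericVector t2_cam,
                            double a0, double a1, double a2,
                            int n_max_floor, double tail_tol,
                            int n_max_cap) {
  int S = lambda.size();
  if (cnt_off.size() != S + 1 || cam_off.size() != S + 1)
    stop("offset vectors must have length S + 1");
  std::vector<double> s_cnt, s_pcnt, q_one;
  double total = 0.0;
  for (int i = 0; i < S; ++i) {
    if (!(lambda[i] > 0.0)) {
      // mass collapses onto N = 0
      bool empty = true;
      for (int r = cnt_off[i]; r < cnt_off[i + 1]; ++r)
        if (cnt[r] > 0) empty = false;
      for (int r = cam_off[i]; r < cam_off[i + 1]; ++r)
        if (cam_det[r] == 1) empty = false;
      if (lambda[i] < 0.0) stop("lambda must be nonnegative");
      if (!empty) return R_NegInf;
      continue;  // log-likelihood contribution 0
    }
    s_cnt.clear(); s_pcnt.clear(); q_one.clear();
    for (int r = cnt_off[i]; r < cnt_off[i + 1]; ++r) {
      s_cnt.push_back(cnt[r]);
      double eta = a0 + a1 * t_cnt[r] + a2 * t2_cnt[r];
      s_pcnt.push_back(1.0 / (1.0 + std::exp(-eta)));
    }
    double lq0 = 0.0;
    bool forceN0 = false;
    for (int r = cam_off[i]; r < cam_off[i + 1]; ++r) {
      double eta = a0 + a1 * t_cam[r] + a2 * t2_cam[r];
      double p = 1.0 / (1.0 + std::exp(-eta));
      double q = 1.0 - p;
      if (cam_det[r] == 1) q_one.push_back(q);
      else {
        if (q <= 0.0) forceN0 = true;
        else lq0 += std::log(q);
      }
    }
    double ll;
    if (forceN0) {
      bool ok = q_one.empty();
      for (size_t j = 0; j < s_cnt.size(); ++j)
        if (s_cnt[j] > 0) ok = false;
      ll = ok ? R::dpois(0.0, lambda[i], 1) : R_NegInf;
    } else {
      ll = site_morph_marginal(lambda[i], s_cnt, s_pcnt, lq0, q_one,
                               n_max_floor, tail_tol, n_max_cap, false);
    }
    if (!R_finite(ll)) return R_NegInf;
    total += ll;
  }
  return total;
}
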