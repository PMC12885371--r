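#include <Rcpp.h>
#include <deque>
#include <array>
using namespace Rcpp;

// Trial-loop engine shared by all model variants. Mirrors the exported R
// primitives (elig_step, tab_prediction_errors, tab_update,
// normalize_values, choice_probabilities) exactly; the R engine is the
// reference and tests assert bitwise agreement.
//
// pair_a/pair_b/choice are 0-based stimulus ids; choice -1 = omitted.
// window: trailing z-normalization window; 0 = no scaling, -1 = whole task.
// [[Rcpp::export(name = "ca_engine_cpp")]]
List ca_engine_cpp(IntegerVector pair_a, IntegerVector pair_b,
                   IntegerVector choice, NumericVector imm, NumericVector del,
                   NumericVector total, int condition_disjoint,
                   NumericVector par, int window, int skip_absent,
                   int want_traj = 1) {
  const int n = pair_a.size();
  const double a_e = par[0], l_e = par[1], b_e = par[2];
  const double a_t = par[3], l_t = par[4], b_t = par[5];

  std::array<double, 8> v{}, e{}, q0{}, q2{};
  std::deque<std::array<double, 8>> buf_e, buf_t;
  double sum_e = 0, ss_e = 0, sum_t = 0, ss_t = 0;  // running pooled moments

  const int tn = want_traj ? n + 1 : 1;
  NumericMatrix V(tn, 8), E(tn, 8), Q0(tn, 8), Q2(tn, 8);
  NumericVector pA(n, NA_REAL), pCh(n, NA_REAL);

  auto push = [&](std::deque<std::array<double, 8>>& buf, double& sum,
                  double& ss, const std::array<double, 8>& x) {
    buf.push_back(x);
    for (double xi : x) { sum += xi; ss += xi * xi; }
    if (window > 0 && (int)buf.size() > window) {
      for (double xi : buf.front()) { sum -= xi; ss -= xi * xi; }
      buf.pop_front();
    }
  };

  for (int i = 0; i < n; ++i) {
    if (want_traj) {
      for (int k = 0; k < 8; ++k) {
        V(i, k) = v[k]; E(i, k) = e[k]; Q0(i, k) = q0[k]; Q2(i, k) = q2[k];
      }
    }
    std::array<double, 8> x_e = v, x_t;
    for (int k = 0; k < 8; ++k) x_t[k] = q0[k] + q2[k];

    const int oa = pair_a[i], ob = pair_b[i];
    double ze_a = x_e[oa], ze_b = x_e[ob], zt_a = x_t[oa], zt_b = x_t[ob];
    if (window != 0 && !buf_e.empty()) {
      const double cnt = 8.0 * buf_e.size();
      double m = sum_e / cnt;
      double var = ss_e / cnt - m * m;
      double s = var > 0 ? std::sqrt(var) : 0.0;
      if (s == 0) s = 1.0;
      ze_a = (ze_a - m) / s; ze_b = (ze_b - m) / s;
      m = sum_t / cnt;
      var = ss_t / cnt - m * m;
      s = var > 0 ? std::sqrt(var) : 0.0;
      if (s == 0) s = 1.0;
      zt_a = (zt_a - m) / s; zt_b = (zt_b - m) / s;
    }
    double ua = b_e * ze_a + b_t * zt_a, ub = b_e * ze_b + b_t * zt_b;
    const double umax = ua > ub ? ua : ub;
    const double ea = std::exp(ua - umax), eb = std::exp(ub - umax);
    const double pa = ea / (ea + eb);
    pA[i] = pa;

    const int ch = choice[i];
    if (ch >= 0) {
      pCh[i] = (ch == oa) ? pa : 1.0 - pa;
      const double r_tot = ISNAN(total[i]) ? 0.0 : total[i];
      // eligibility step: delta from pre-update value, replacing trace
      const double delta = r_tot - v[ch];
      for (int k = 0; k < 8; ++k) e[k] *= l_e;
      e[ch] = 1.0;
      for (int k = 0; k < 8; ++k) v[k] += a_e * delta * e[k];
      // tabular double update
      const int a2 = (i >= 2) ? choice[i - 2] : -1;
      if (condition_disjoint == 0) {
        q0[ch] += a_t * (r_tot - q0[ch]);
        if (a2 >= 0) q2[a2] += a_t * l_t * (r_tot - q2[a2]);
      } else {
        if (!(skip_absent && ISNAN(imm[i]))) {
          const double r0 = ISNAN(imm[i]) ? 0.0 : imm[i];
          q0[ch] += a_t * (r0 - q0[ch]);
        }
        if (a2 >= 0 && !(skip_absent && ISNAN(del[i]))) {
          const double r2 = ISNAN(del[i]) ? 0.0 : del[i];
          q2[a2] += a_t * l_t * (r2 - q2[a2]);
        }
      }
    } else {
      for (int k = 0; k < 8; ++k) e[k] *= l_e;
    }
    if (window != 0) {
      push(buf_e, sum_e, ss_e, x_e);
      push(buf_t, sum_t, ss_t, x_t);
    }
  }
  if (want_traj) {
    for (int k = 0; k < 8; ++k) {
      V(n, k) = v[k]; E(n, k) = e[k]; Q0(n, k) = q0[k]; Q2(n, k) = q2[k];
    }
  }
  return List::create(_["p_a"] = pA, _["p_choice"] = pCh, _["v"] = V,
                      _["e"] = E, _["q0"] = Q0, _["q2"] = Q2);
}
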