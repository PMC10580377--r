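#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
#include <algorithm>
using namespace Rcpp;

// Penalized changepoint detection under an exponential observation model.
//
// Segment cost: twice the negative maximised exponential log-likelihood with
// additive constants dropped, C(a, b] = 2 m (log S - log m) where m = b - a
// and S is the sum of observations a+1..b. Constants cancel across
// segmentations, so objective comparisons are unaffected.
//
// Objective convention: F(n) = sum of segment costs + beta * (#changepoints),
// i.e. the unsplit fit carries no penalty. Tie-break everywhere: among equal
// objectives prefer fewer changepoints, then the earliest split point. The
// pure-R optimal-partitioning oracle applies the same rule.

namespace {

struct Prefix {
  std::vector<double> cs;   // cs[i] = sum of first i observations
  std::vector<double> lnm;  // lnm[m] = log(m)
  explicit Prefix(const NumericVector& x) {
    const int n = x.size();
    cs.assign(n + 1, 0.0);
    lnm.assign(n + 1, 0.0);
    for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
    for (int m = 1; m <= n; ++m) lnm[m] = std::log(static_cast<double>(m));
  }
  // cost of segment (a, b], requires b > a
  inline double cost(int a, int b) const {
    const double m = static_cast<double>(b - a);
    return 2.0 * m * (std::log(cs[b] - cs[a]) - lnm[b - a]);
  }
};

List result_of(const std::vector<int>& cps, double objective) {
  return List::create(_["changepoints"] = wrap(cps),
                      _["objective"] = objective);
}

std::vector<int> backtrack(const std::vector<int>& last, int n) {
  std::vector<int> cps;
  for (int t = n; t > 0; t = last[t]) cps.push_back(t);
  std::reverse(cps.begin(), cps.end());
  return cps;
}

// candidate cost evaluation: vp[i] = F(tau_i) + C(tau_i, t); SIMD-dispatched
// at runtime, with a portable scalar fallback
__attribute__((target_clones("avx2", "default")))
static void pelt_costs(const int* tp, const double* cp, const double* fp,
                       double* vp, size_t nc, int t, double cst) {
  for (size_t i = 0; i < nc; ++i) {
    const double m = static_cast<double>(t - tp[i]);
    vp[i] = fp[i] + 2.0 * m * std::log((cst - cp[i]) / m);
  }
}

__attribute__((target_clones("avx2", "default")))
static double vec_min(const double* vp, size_t nc) {
  double vmin = DBL_MAX;
  for (size_t i = 0; i < nc; ++i) vmin = vp[i] < vmin ? vp[i] : vmin;
  return vmin;
}

__attribute__((target_clones("avx2", "default")))
static size_t count_kept(const double* vp, size_t nc, double thr) {
  size_t k = 0;
  for (size_t i = 0; i < nc; ++i) k += vp[i] <= thr ? 1 : 0;
  return k;
}

}  // namespace

// PELT: exact minimiser of the penalized objective; pruning constant K = 0 is
// valid because splitting a segment never increases the raw exponential cost
// (log-sum inequality), so C(a,b) <= C(a,t) + C(t,b).
//
// With a minimal segment length m > 1 the textbook prune is unsafe for
// horizons s with s - t < m (the decomposition through t is inadmissible
// there), so a candidate is only removed once the prune condition has held
// for m consecutive steps; while flagged it keeps competing, and at any
// step where it would be optimal the condition necessarily resets.
// [[Rcpp::export]]
List cpp_pelt_exp(NumericVector x, double beta, int minseg) {
  const int n = x.size();
  Prefix pf(x);
  if (n < 2 * minseg) {
    std::vector<int> cps(1, n);
    return result_of(cps, pf.cost(0, n));
  }
  std::vector<double> F(n + 1);
  std::vector<int> last(n + 1, 0), ncp(n + 1, 0);
  F[0] = -beta;
  // packed candidate arrays keep the hot loop contiguous
  std::vector<int> ctau, cstreak;
  std::vector<double> ccs, cF, v;
  ctau.reserve(n); cstreak.reserve(n);
  ccs.reserve(n); cF.reserve(n); v.resize(n + 2);
  ctau.push_back(0); ccs.push_back(0.0); cF.push_back(F[0]);
  cstreak.push_back(0);
  for (int t = minseg; t <= n; ++t) {
    const int tn = t - minseg;
    if (tn >= minseg) {
      ctau.push_back(tn); ccs.push_back(pf.cs[tn]); cF.push_back(F[tn]);
      cstreak.push_back(0);
    }
    const size_t nc = ctau.size();
    const double cst = pf.cs[t];
    const int* tp = ctau.data();
    double* vp = v.data();
    pelt_costs(tp, ccs.data(), cF.data(), vp, nc, t, cst);
    const double vmin = vec_min(vp, nc);
    // resolve ties (equal objective) by fewer changepoints, then earliest tau
    double best = DBL_MAX;
    int bncp = 0, btau = 0;
    for (size_t i = 0; i < nc; ++i) {
      if (vp[i] != vmin) continue;
      const int tau = tp[i];
      const int c = ncp[tau] + (tau > 0 ? 1 : 0);
      if (best == DBL_MAX || c < bncp || (c == bncp && tau < btau)) {
        best = vmin; bncp = c; btau = tau;
      }
    }
    F[t] = vmin + beta;  // tau = 0 carries F(0) = -beta: unsplit fit unpenalized
    last[t] = btau; ncp[t] = bncp;
    const size_t hit = nc - count_kept(vp, nc, F[t]);
    if (hit > 0) {
      size_t k = 0;
      for (size_t i = 0; i < nc; ++i) {
        const int streak = vp[i] > F[t] ? cstreak[i] + 1 : 0;
        if (streak < minseg) {
          ctau[k] = ctau[i]; ccs[k] = ccs[i]; cF[k] = cF[i];
          cstreak[k] = streak;
          ++k;
        }
      }
      ctau.resize(k); ccs.resize(k); cF.resize(k); cstreak.resize(k);
    }
  }
  return result_of(backtrack(last, n), F[n]);
}

// Segment neighbourhoods: exact dynamic programme over segmentations with
// exactly q segments, q = 1..Q; returns the q minimising cost + beta (q - 1).
// [[Rcpp::export]]
List cpp_segneigh_exp(NumericVector x, double beta, int minseg, int maxseg) {
  const int n = x.size();
  Prefix pf(x);
  if (n < 2 * minseg || maxseg <= 1) {
    std::vector<int> cps(1, n);
    return result_of(cps, pf.cost(0, n));
  }
  const int Q = std::min(maxseg, n / minseg);
  // L[q][t]: minimal cost of splitting 1..t into exactly q segments
  std::vector<std::vector<double>> L(Q + 1,
      std::vector<double>(n + 1, DBL_MAX));
  std::vector<std::vector<int>> back(Q + 1, std::vector<int>(n + 1, 0));
  for (int t = minseg; t <= n; ++t) L[1][t] = pf.cost(0, t);
  for (int q = 2; q <= Q; ++q) {
    for (int t = q * minseg; t <= n; ++t) {
      double best = DBL_MAX; int btau = 0;
      for (int tau = (q - 1) * minseg; tau <= t - minseg; ++tau) {
        if (L[q - 1][tau] == DBL_MAX) continue;
        const double val = L[q - 1][tau] + pf.cost(tau, t);
        if (val < best) { best = val; btau = tau; }
      }
      L[q][t] = best; back[q][t] = btau;
    }
  }
  double best = L[1][n]; int bq = 1;
  for (int q = 2; q <= Q; ++q) {
    if (L[q][n] == DBL_MAX) continue;
    const double val = L[q][n] + beta * (q - 1);
    if (val < best) { best = val; bq = q; }
  }
  std::vector<int> cps;
  int t = n;
  for (int q = bq; q >= 1; --q) {
    cps.push_back(t);
    t = back[q][t];
  }
  std::reverse(cps.begin(), cps.end());
  return result_of(cps, best);
}

// At most one change: best single split if it beats the unsplit fit by more
// than the penalty.
// [[Rcpp::export]]
List cpp_amoc_exp(NumericVector x, double beta, int minseg) {
  const int n = x.size();
  Prefix pf(x);
  const double whole = pf.cost(0, n);
  double best = whole; int btau = 0;
  if (n >= 2 * minseg) {
    for (int tau = minseg; tau <= n - minseg; ++tau) {
      const double val = pf.cost(0, tau) + pf.cost(tau, n) + beta;
      if (val < best) { best = val; btau = tau; }
    }
  }
  std::vector<int> cps;
  if (btau > 0) cps.push_back(btau);
  cps.push_back(n);
  return result_of(cps, best);
}

// Binary segmentation: greedy recursive best-single-split; a split is
// accepted while the penalized objective improves and the segment budget
// allows. Ties go to the earliest split point.
// [[Rcpp::export]]
List cpp_binseg_exp(NumericVector x, double beta, int minseg, int maxseg) {
  const int n = x.size();
  Prefix pf(x);
  std::vector<int> bounds;  // segment end indices, kept sorted; last = n
  bounds.push_back(n);
  double objective = pf.cost(0, n);
  if (n < 2 * minseg || maxseg <= 1) return result_of(bounds, objective);
  while (static_cast<int>(bounds.size()) < maxseg) {
    double bestgain = 0.0; int besttau = -1;
    int a = 0;
    for (size_t s = 0; s < bounds.size(); ++s) {
      const int b = bounds[s];
      if (b - a >= 2 * minseg) {
        const double unsplit = pf.cost(a, b);
        for (int tau = a + minseg; tau <= b - minseg; ++tau) {
          const double gain = unsplit - pf.cost(a, tau) - pf.cost(tau, b);
          if (gain > bestgain) { bestgain = gain; besttau = tau; }
        }
      }
      a = b;
    }
    if (besttau < 0 || bestgain <= beta) break;
    bounds.insert(std::upper_bound(bounds.begin(), bounds.end(), besttau),
                  besttau);
    objective += beta - bestgain;
  }
  return result_of(bounds, objective);
}
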