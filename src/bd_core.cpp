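#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Event-driven (Gillespie) simulation of a constant-rate birth-death tree,
// started from n_start lineages (2 = crown start) and run for a fixed
// duration `age`. Uses R's RNG so set.seed() governs reproducibility.
//
// Returns the censoring status, the number of extant tips, and -- for a
// crown start whose both daughters leave extant descendants -- the
// branching times (ages before present, descending, first element = crown
// age) and total edge length s of the reconstructed (extant-only) tree.
// When keep_complete is true the full lineage records are returned so the
// complete tree (with extinct lineages) can be rebuilt in R.
//
// status codes: 0 = extinct (crown did not survive), 1 = cherry (n = 2),
//               2 = usable (n > 2).
// [[Rcpp::export(name = ".sim_crown_cpp")]]
List sim_crown_cpp(double lambda, double mu, double age, int n_start = 2,
                   bool keep_complete = false) {
  if (age <= 0.0) stop("clade age must be positive");
  if (lambda < 0.0 || mu < 0.0) stop("rates must be nonnegative");
  std::vector<int> parent;   // parent lineage index, -1 for initial lineages
  std::vector<double> tb;    // birth time (elapsed since start)
  std::vector<double> te;    // end time (death, speciation, or `age`)
  std::vector<int> ev;       // 0 alive at age, 1 extinct, 2 speciated
  std::vector<int> active;
  parent.reserve(64); tb.reserve(64); te.reserve(64); ev.reserve(64);
  for (int i = 0; i < n_start; ++i) {
    parent.push_back(-1); tb.push_back(0.0); te.push_back(-1.0);
    ev.push_back(0); active.push_back(i);
  }
  const double per = lambda + mu;
  double tnow = 0.0;
  if (per > 0.0) {
    while (!active.empty()) {
      tnow += exp_rand() / (per * (double)active.size());
      if (tnow >= age) break;
      int k = (int)(unif_rand() * (double)active.size());
      if (k >= (int)active.size()) k = (int)active.size() - 1;
      const int lin = active[k];
      te[lin] = tnow;
      if (unif_rand() * per < lambda) {   // speciation
        ev[lin] = 2;
        const int c1 = (int)parent.size(), c2 = c1 + 1;
        parent.push_back(lin); tb.push_back(tnow); te.push_back(-1.0); ev.push_back(0);
        parent.push_back(lin); tb.push_back(tnow); te.push_back(-1.0); ev.push_back(0);
        active[k] = c1;
        active.push_back(c2);
      } else {                            // extinction
        ev[lin] = 1;
        active[k] = active.back();
        active.pop_back();
      }
      if (parent.size() > 20000000u) stop("simulated tree exceeded 2e7 lineages");
    }
  }
  const int L = (int)parent.size();
  for (int i = 0; i < L; ++i) if (ev[i] == 0) te[i] = age;

  // children always have a larger index than their parent, so one reverse
  // sweep propagates 'has extant descendant' flags and per-parent counts
  std::vector<char> has_ext(L, 0);
  std::vector<int> cnt_ext(L, 0);
  int n_ext = 0;
  for (int i = L - 1; i >= 0; --i) {
    if (ev[i] == 0) { has_ext[i] = 1; ++n_ext; }
    if (has_ext[i] && parent[i] >= 0) {
      has_ext[parent[i]] = 1;
      ++cnt_ext[parent[i]];
    }
  }
  bool crown_ok;
  if (n_start == 2) crown_ok = has_ext[0] && has_ext[1];
  else crown_ok = n_ext > 0;
  int status;
  if (!crown_ok || n_ext == 0) status = 0;
  else if (n_ext <= 2) status = 1;
  else status = 2;

  NumericVector times;
  double s_rec = NA_REAL;
  if (n_start == 2 && crown_ok) {
    std::vector<double> bt;
    bt.reserve(n_ext);
    bt.push_back(age);  // crown node
    for (int i = 0; i < L; ++i)
      if (ev[i] == 2 && cnt_ext[i] == 2) bt.push_back(age - te[i]);
    std::sort(bt.begin(), bt.end(), std::greater<double>());
    times = NumericVector(bt.begin(), bt.end());
    // total edge length of the reconstructed tree: k+1 lineages exist
    // between the k-th and (k+1)-th branching ages
    s_rec = 0.0;
    const int K = (int)bt.size();
    for (int k = 0; k < K; ++k) {
      const double nxt = (k + 1 < K) ? bt[k + 1] : 0.0;
      s_rec += (double)(k + 2) * (bt[k] - nxt);
    }
  }
  List out = List::create(
    _["status"] = status, _["n_extant"] = n_ext,
    _["times"] = times, _["s"] = s_rec);
  if (keep_complete) {
    out["parent"] = IntegerVector(parent.begin(), parent.end());
    out["birth"] = NumericVector(tb.begin(), tb.end());
    out["end"] = NumericVector(te.begin(), te.end());
    out["event"] = IntegerVector(ev.begin(), ev.end());
  }
  return out;
}

// Branch-product birth-death log-likelihood of a reconstructed tree,
// evaluated from its branching times (ages, descending; times[0] = crown
// age), total edge length s and tip count n. The product over the 2m
// branch segments telescopes to a function of the node ages only, which is
// what is computed here. condition: 0 none, 1 crown survival, 2 n > 2.
// Near-critical rates dispatch to the critical branching form.
// [[Rcpp::export(name = ".bd_ll_times_cpp")]]
double bd_ll_times_cpp(double lambda, double mu, NumericVector times,
                       double s, int n, int condition) {
  if (lambda <= 0.0 || mu < 0.0) return R_NegInf;
  const int m = n - 1;
  if (times.size() != m) stop("expected n - 1 branching times");
  const double t1 = times[0];
  const double r = lambda - mu;
  const double llam = std::log(lambda);
  double ll;
  if (std::fabs(r) < 1e-9 * std::max(lambda, mu)) {
    // critical branching process (lambda == mu)
    double acc = 0.0;
    for (int j = 1; j < m; ++j) acc += 2.0 * std::log1p(lambda * times[j]);
    ll = -acc - 4.0 * std::log1p(lambda * t1);
    if (condition == 0) return ll + (double)m * llam;
    const double one_m_p0 = 1.0 / (1.0 + lambda * t1);
    if (condition == 1)
      return ll + (double)(m - 1) * llam - 2.0 * std::log(one_m_p0);
    const double p1 = one_m_p0 * one_m_p0;
    const double pgt2 = one_m_p0 * one_m_p0 - p1 * p1;
    if (pgt2 <= 0.0) return R_NegInf;
    return ll + (double)(m - 1) * llam - std::log(pgt2);
  }
  // general case; lambda - mu*exp(-r t) written as r - mu*expm1(-r t)
  const double lr = std::log(std::fabs(r));
  double acc = 0.0;
  for (int j = 1; j < m; ++j) {
    const double D = r - mu * std::expm1(-r * times[j]);
    acc += 2.0 * std::log(std::fabs(D));
  }
  const double D1 = r - mu * std::expm1(-r * t1);
  ll = -r * s + 2.0 * (double)n * lr - acc - 4.0 * std::log(std::fabs(D1));
  if (!std::isfinite(ll)) return R_NegInf;
  if (condition == 0) return ll + (double)m * llam;
  const double one_m_p0 = r / D1;  // 1 - P0(t1)
  if (condition == 1)
    return ll + (double)(m - 1) * llam - 2.0 * std::log(std::fabs(one_m_p0));
  const double p1 = r * r * std::exp(-r * t1) / (D1 * D1);
  const double pgt2 = one_m_p0 * one_m_p0 - p1 * p1;
  if (pgt2 <= 0.0) return R_NegInf;
  return ll + (double)(m - 1) * llam - std::log(pgt2);
}
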