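#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Structure weight of a bin pair (i, j), 0-based, i < j:
//   b_i * b_j * active_ratio^{same active domain}
//   * border_attenuation^{# domain borders crossed}
//   * site_attenuation^{min(# insulating sites strictly between, cap)}
// "Strictly between" means sites in bins i < s < j: a contact does not count
// its own endpoints as crossed. Anchor-loop enrichment is handled in R by
// Poisson superposition.
static inline double pair_weight(int i, int j,
                                 const double* b,
                                 const int* dom,
                                 const int* act,
                                 const int* bcum,
                                 const int* icum,
                                 double active_ratio,
                                 const std::vector<double>& bpow,
                                 const std::vector<double>& spow,
                                 int cap, int max_ins_d) {
  double w = b[i] * b[j];
  if (dom[i] == dom[j]) {
    if (act[i]) w *= active_ratio;
  } else {
    w *= bpow[bcum[j] - bcum[i]];
  }
  if (j - i <= max_ins_d) {
    int ins = icum[j - 1] - icum[i];
    if (ins > 0) w *= spow[ins > cap ? cap : ins];
  }
  return w;
}

// Per-distance sums of lambda0(d) * weight, lambda0(d) = d^exponent (d in bins).
// [[Rcpp::export]]
NumericVector structure_sums_cpp(NumericVector b, IntegerVector dom_id,
                                 IntegerVector dom_active,
                                 IntegerVector border_cum, IntegerVector ins_cum,
                                 double exponent, double active_ratio,
                                 double border_att, double site_att,
                                 int max_cross, int max_ins_d) {
  int n = b.size();
  NumericVector S(n > 1 ? n - 1 : 0);
  int maxb = n ? border_cum[n - 1] : 0;
  std::vector<double> bpow(maxb + 1), spow(max_cross + 1);
  for (int k = 0; k <= maxb; ++k) bpow[k] = std::pow(border_att, k);
  for (int k = 0; k <= max_cross; ++k) spow[k] = std::pow(site_att, k);
  const double* pb = REAL(b);
  const int* dom = INTEGER(dom_id);
  const int* act = INTEGER(dom_active);
  const int* bc = INTEGER(border_cum);
  const int* ic = INTEGER(ins_cum);
  for (int d = 1; d < n; ++d) {
    double lam0 = std::pow((double)d, exponent);
    double s = 0.0;
    for (int i = 0; i + d < n; ++i)
      s += pair_weight(i, i + d, pb, dom, act, bc, ic,
                       active_ratio, bpow, spow, max_cross, max_ins_d);
    S[d - 1] = lam0 * s;
  }
  return S;
}

// Sample Poisson contact counts under the base model, scale factor s
// (expected count of cell (i,j) = s * d^exponent * weight). Returns sparse
// triplets with 1-based bin indices, i <= j.
// [[Rcpp::export]]
List sample_contacts_cpp(NumericVector b, IntegerVector dom_id,
                         IntegerVector dom_active,
                         IntegerVector border_cum, IntegerVector ins_cum,
                         double exponent, double active_ratio,
                         double border_att, double site_att,
                         int max_cross, int max_ins_d, double s) {
  int n = b.size();
  int maxb = n ? border_cum[n - 1] : 0;
  std::vector<double> bpow(maxb + 1), spow(max_cross + 1);
  for (int k = 0; k <= maxb; ++k) bpow[k] = std::pow(border_att, k);
  for (int k = 0; k <= max_cross; ++k) spow[k] = std::pow(site_att, k);
  const double* pb = REAL(b);
  const int* dom = INTEGER(dom_id);
  const int* act = INTEGER(dom_active);
  const int* bc = INTEGER(border_cum);
  const int* ic = INTEGER(ins_cum);

  std::vector<int> out_i, out_j, out_c;
  std::vector<double> cum(n);
  std::vector<int> hits;
  for (int d = 1; d < n && s > 0; ++d) {
    int m = n - d;
    double lam0 = s * std::pow((double)d, exponent);
    double tot = 0.0;
    for (int i = 0; i < m; ++i) {
      tot += pair_weight(i, i + d, pb, dom, act, bc, ic,
                         active_ratio, bpow, spow, max_cross, max_ins_d);
      cum[i] = tot;
    }
    double lambda_d = lam0 * tot;
    if (lambda_d <= 0) continue;
    int N = (int) R::rpois(lambda_d);
    if (N <= 0) continue;
    hits.clear();
    hits.reserve(N);
    for (int k = 0; k < N; ++k) {
      double u = unif_rand() * tot;
      int idx = (int)(std::upper_bound(cum.begin(), cum.begin() + m, u)
                      - cum.begin());
      if (idx >= m) idx = m - 1;
      hits.push_back(idx);
    }
    std::sort(hits.begin(), hits.end());
    for (size_t k = 0; k < hits.size();) {
      size_t k2 = k;
      while (k2 < hits.size() && hits[k2] == hits[k]) ++k2;
      out_i.push_back(hits[k] + 1);
      out_j.push_back(hits[k] + 1 + d);
      out_c.push_back((int)(k2 - k));
      k = k2;
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["count"] = wrap(out_c));
}
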