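#include <Rcpp.h>
using namespace Rcpp;

// Simplified XP-CLR site likelihoods.
//
// Latent test-population frequency under neutral drift:
//   p2 ~ Normal(p1, omega * p1 * (1 - p1)) truncated to (0, 1), the clipped
//   tails becoming point masses at the boundaries.
// Sweep of scale s centred at distance d: a sampled lineage escapes the
// sweep with probability c = 1 - exp(-rho * d / s); non-escaping lineages
// carry the hitchhiking allele (alt with probability p1, ref otherwise), so
// the observed-frequency transform is
//   p2' = 1 - c + c * p2   (alt rode the sweep)
//   p2' = c * p2           (ref rode the sweep)
// and k2 ~ Binomial(n2, p2').  c = 1 recovers the null exactly; c = 0
// degenerates to point masses p1 at 1 and 1 - p1 at 0.
// Everything is accumulated in log space (log-sum-exp), so admissible
// inputs never return -inf.

namespace {

double lbinom(int k, int n, double q, double lch) {
  if (q <= 0.0) return k == 0 ? 0.0 : R_NegInf;
  if (q >= 1.0) return k == n ? 0.0 : R_NegInf;
  return lch + k * std::log(q) + (n - k) * std::log1p(-q);
}

} // namespace

// Per-site sweep-model log-likelihoods for one value of s.
// k2: observed alt counts; n2: test haplotype count; p1: reference
// frequencies (0 < p1 < 1); dist: bp distances to the putative sweep site;
// Q: midpoint quadrature nodes over (0, 1).
// [[Rcpp::export]]
NumericVector cpp_xpclr_loglik(IntegerVector k2, int n2, NumericVector p1,
                               NumericVector dist, double omega, double rho,
                               double s, int Q) {
  int S = k2.size();
  NumericVector out(S);
  std::vector<double> terms;
  terms.reserve(2 * Q + 4);
  double lQ = std::log((double)Q);
  for (int i = 0; i < S; ++i) {
    double sd = std::sqrt(omega * p1[i] * (1.0 - p1[i]));
    double mass0 = R::pnorm(0.0, p1[i], sd, 1, 0);
    double mass1 = R::pnorm(1.0, p1[i], sd, 0, 0);
    double cc = 1.0 - std::exp(-rho * dist[i] / s);
    if (cc > 1.0) cc = 1.0;
    double lch = R::lchoose(n2, k2[i]);
    double lp1 = std::log(p1[i]), l1mp1 = std::log1p(-p1[i]);
    terms.clear();
    for (int m = 0; m < Q; ++m) {
      double x = (m + 0.5) / Q;
      double ldens = R::dnorm(x, p1[i], sd, 1) - lQ;
      terms.push_back(lp1 + ldens +
                      lbinom(k2[i], n2, 1.0 - cc + cc * x, lch));
      terms.push_back(l1mp1 + ldens + lbinom(k2[i], n2, cc * x, lch));
    }
    if (mass0 > 0.0) {
      double lm0 = std::log(mass0);
      terms.push_back(lp1 + lm0 + lbinom(k2[i], n2, 1.0 - cc, lch));
      terms.push_back(l1mp1 + lm0 + lbinom(k2[i], n2, 0.0, lch));
    }
    if (mass1 > 0.0) {
      double lm1 = std::log(mass1);
      terms.push_back(lp1 + lm1 + lbinom(k2[i], n2, 1.0, lch));
      terms.push_back(l1mp1 + lm1 + lbinom(k2[i], n2, cc, lch));
    }
    double mx = R_NegInf;
    for (double t : terms) if (t > mx) mx = t;
    double acc = 0.0;
    for (double t : terms) if (R_finite(t)) acc += std::exp(t - mx);
    out[i] = mx + std::log(acc);
  }
  return out;
}
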