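#include <Rcpp.h>
using namespace Rcpp;

// Haplotype-homozygosity machinery for EHH / iHH / XP-EHH.
//
// EHH at an offset site x (population-level, over all n haplotypes) is
//   sum_g C(m_g, 2) / C(n, 2)
// where m_g are the multiplicities of the distinct haplotype strings
// spanning core..x inclusive.  Groups are maintained incrementally: at each
// step the grouping is refined by the next site's alleles, so one step costs
// O(n).  The decay curve is anchored at (distance 0, EHH 1) for the
// trapezoidal integral iHH.

namespace {

// refine grouping `g` (values in 0..n_groups-1) by binary column `col`;
// returns new number of groups and updates g in place
int refine(std::vector<int> &g, const int *col, int n, int n_groups,
           std::vector<int> &remap) {
  // combined key = 2 * g + allele, then renumber compactly
  remap.assign(2 * n_groups, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int key = 2 * g[i] + (col[i] ? 1 : 0);
    if (remap[key] < 0) remap[key] = next++;
    g[i] = remap[key];
  }
  return next;
}

double homozygosity(const std::vector<int> &g, int n, int n_groups,
                    std::vector<int> &cnt) {
  cnt.assign(n_groups, 0);
  for (int i = 0; i < n; ++i) cnt[g[i]]++;
  double pairs = 0.0;
  for (int k = 0; k < n_groups; ++k)
    pairs += 0.5 * cnt[k] * (cnt[k] - 1.0);
  return pairs / (0.5 * n * (n - 1.0));
}

} // namespace

// One-population EHH decay curve from a core site in one direction.
// H: n x S 0/1 matrix (haplotypes of one population), pos: bp positions,
// core: 0-based site index, dir: +1 (right) or -1 (left).
// Returns offsets (bp distances, starting at 0) and ehh values (starting
// at 1); subsequent points are at the offset sites, strings spanning
// core..x inclusive.  Truncated after the first value < cutoff or when the
// distance exceeds max_span.
// [[Rcpp::export]]
List cpp_ehh_curve(IntegerMatrix H, NumericVector pos, int core, int dir,
                   double cutoff, double max_span) {
  int n = H.nrow(), S = H.ncol();
  std::vector<int> g(n, 0), remap, cnt;
  std::vector<double> offs, ehh;
  offs.push_back(0.0);
  ehh.push_back(1.0);
  int n_groups = 1;
  // include the core site's alleles in the strings
  {
    std::vector<int> col(n);
    for (int i = 0; i < n; ++i) col[i] = H(i, core);
    n_groups = refine(g, col.data(), n, n_groups, remap);
  }
  int x = core + dir;
  std::vector<int> col(n);
  while (x >= 0 && x < S) {
    double d = std::abs(pos[x] - pos[core]);
    if (d > max_span) break;
    for (int i = 0; i < n; ++i) col[i] = H(i, x);
    n_groups = refine(g, col.data(), n, n_groups, remap);
    double e = homozygosity(g, n, n_groups, cnt);
    offs.push_back(d);
    ehh.push_back(e);
    if (e < cutoff) break;
    x += dir;
  }
  // trapezoidal integral over bp
  double ihh = 0.0;
  for (size_t k = 1; k < offs.size(); ++k)
    ihh += 0.5 * (ehh[k] + ehh[k - 1]) * (offs[k] - offs[k - 1]);
  return List::create(_["offsets"] = offs, _["ehh"] = ehh, _["ihh"] = ihh);
}

// XP-EHH raw scores at a set of core sites.
// HA, HB: haplotype matrices of populations A and B over the SAME sites;
// both curves are stepped together and truncated at the union of their
// spans: stepping stops only when BOTH populations' EHH has fallen below
// the cutoff (or max_span is reached); a population whose EHH has dropped
// below the cutoff carries its last value forward while the other
// continues.  iHH = left + right trapezoidal integrals; raw = ln(iHH_A /
// iHH_B), NA_REAL when either iHH is zero.
// [[Rcpp::export]]
NumericVector cpp_xpehh_raw(IntegerMatrix HA, IntegerMatrix HB,
                            NumericVector pos, IntegerVector cores,
                            double cutoff, double max_span) {
  int nA = HA.nrow(), nB = HB.nrow(), S = HA.ncol();
  NumericVector out(cores.size(), NA_REAL);
  std::vector<int> gA, gB, remap, cnt, colA(nA), colB(nB);
  for (int ci = 0; ci < cores.size(); ++ci) {
    int core = cores[ci];
    double ihhA = 0.0, ihhB = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      gA.assign(nA, 0);
      gB.assign(nB, 0);
      int ngA = 1, ngB = 1;
      for (int i = 0; i < nA; ++i) colA[i] = HA(i, core);
      for (int i = 0; i < nB; ++i) colB[i] = HB(i, core);
      ngA = refine(gA, colA.data(), nA, ngA, remap);
      ngB = refine(gB, colB.data(), nB, ngB, remap);
      double prev_d = 0.0, eA = 1.0, eB = 1.0;
      bool liveA = true, liveB = true;
      int x = core + dir;
      while ((liveA || liveB) && x >= 0 && x < S) {
        double d = std::abs(pos[x] - pos[core]);
        if (d > max_span) break;
        double eA_new = eA, eB_new = eB;
        if (liveA) {
          for (int i = 0; i < nA; ++i) colA[i] = HA(i, x);
          ngA = refine(gA, colA.data(), nA, ngA, remap);
          eA_new = homozygosity(gA, nA, ngA, cnt);
        }
        if (liveB) {
          for (int i = 0; i < nB; ++i) colB[i] = HB(i, x);
          ngB = refine(gB, colB.data(), nB, ngB, remap);
          eB_new = homozygosity(gB, nB, ngB, cnt);
        }
        ihhA += 0.5 * (eA + eA_new) * (d - prev_d);
        ihhB += 0.5 * (eB + eB_new) * (d - prev_d);
        eA = eA_new;
        eB = eB_new;
        if (eA < cutoff) liveA = false;
        if (eB < cutoff) liveB = false;
        prev_d = d;
        x += dir;
      }
    }
    if (ihhA > 0.0 && ihhB > 0.0) out[ci] = std::log(ihhA / ihhB);
  }
  return out;
}
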