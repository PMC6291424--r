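#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Enrichment score from sorted (ascending, 1-based) hit positions.
//
// The running sum increases by w_j = aw[p_j]/NR at each hit and decreases by
// 1/(N-k) at each miss, so between hits it is linear: its extrema over the
// whole list are attained immediately before or after a hit (the value at the
// final rank is exactly 0 and never exceeds the post-hit candidates). This
// gives an O(k) evaluation identical to the O(N) walk.
static double es_from_sorted_hits(const NumericVector &aw,
                                  const int *hits, int k, int N) {
  double NR = 0.0;
  for (int j = 0; j < k; ++j) NR += aw[hits[j] - 1];
  const double miss = 1.0 / (double)(N - k);
  const bool equal = (NR <= 0.0); // all-zero hit weights: fall back to equal
  double cum = 0.0, maxP = R_NegInf, minP = R_PosInf;
  for (int j = 0; j < k; ++j) {
    const double pen = (double)(hits[j] - (j + 1)) * miss;
    const double before = cum - pen;
    if (before < minP) minP = before;
    cum += equal ? 1.0 / (double)k : aw[hits[j] - 1] / NR;
    const double after = cum - pen;
    if (after > maxP) maxP = after;
  }
  // magnitude ties resolve to 0, with an epsilon against rounding noise
  if (maxP + minP > 1e-9) return maxP;
  if (maxP + minP < -1e-9) return minP;
  return 0.0;
}

// [[Rcpp::export]]
double es_hits_cpp(NumericVector aw, IntegerVector hits) {
  const int N = aw.size(), k = hits.size();
  if (k < 1 || k >= N) stop("gene set must be a non-empty proper subset");
  std::vector<int> h(hits.begin(), hits.end());
  std::sort(h.begin(), h.end());
  return es_from_sorted_hits(aw, h.data(), k, N);
}

// Draw `nperm` random size-k subsets of 1..N (without replacement, uniform,
// using R's RNG so set.seed() governs reproducibility) and return their ES.
// [[Rcpp::export]]
NumericVector null_es_gene_set_cpp(NumericVector aw, int k, int nperm) {
  const int N = aw.size();
  if (k < 1 || k >= N) stop("subset size must satisfy 1 <= k < N");
  if (nperm < 1) stop("nperm must be >= 1");
  NumericVector out(nperm);
  std::vector<int> pool(N);
  std::vector<int> picked(k);
  for (int i = 0; i < N; ++i) pool[i] = i + 1;
  for (int b = 0; b < nperm; ++b) {
    // partial Fisher-Yates; restore the prefix afterwards
    for (int j = 0; j < k; ++j) {
      int idx = j + (int)(unif_rand() * (double)(N - j));
      if (idx >= N) idx = N - 1;
      std::swap(pool[j], pool[idx]);
      picked[j] = pool[j];
    }
    std::sort(picked.begin(), picked.end());
    out[b] = es_from_sorted_hits(aw, picked.data(), k, N);
  }
  return out;
}
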