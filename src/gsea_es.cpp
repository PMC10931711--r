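#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted KS running-sum enrichment score.
// w: per-position weights (already |stat|^exponent), in rank order, length N.
// pos: sorted 1-based hit positions.
// Hits step up by w/sum(w_hits) (equal steps 1/k when all hit weights are 0);
// misses step down by 1/(N-k). ES is the running-sum value of maximum
// absolute deviation from zero, signed.
static double es_core(const std::vector<int>& pos, const NumericVector& w, int N) {
  const int k = (int)pos.size();
  if (k == 0) return 0.0;
  double W = 0.0;
  for (int i = 0; i < k; ++i) W += w[pos[i] - 1];
  const double miss = (N > k) ? 1.0 / (double)(N - k) : 0.0;
  double cum = 0.0, best = 0.0;
  for (int j = 0; j < k; ++j) {
    const double drop = (double)(pos[j] - (j + 1)) * miss;
    const double before = cum - drop;
    if (std::fabs(before) > std::fabs(best)) best = before;
    cum += (W > 0.0) ? w[pos[j] - 1] / W : 1.0 / (double)k;
    const double at = cum - drop;
    if (std::fabs(at) > std::fabs(best)) best = at;
  }
  return best;
}

// [[Rcpp::export]]
double gsea_es_cpp(NumericVector w, IntegerVector hit_pos) {
  std::vector<int> pos(hit_pos.begin(), hit_pos.end());
  std::sort(pos.begin(), pos.end());
  return es_core(pos, w, w.size());
}

// Null ES by gene-label permutation: B uniform k-subsets of 1..N.
// Uses R's RNG (reproducible under set.seed()).
// [[Rcpp::export]]
NumericVector gsea_null_es_cpp(NumericVector w, int k, int B) {
  const int N = w.size();
  if (k > N) stop("set size exceeds universe");
  NumericVector out(B);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i + 1;
  std::vector<int> pos(k);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (double)(N - i));
      if (j >= N) j = N - 1;
      std::swap(idx[i], idx[j]);
      pos[i] = idx[i];
    }
    std::sort(pos.begin(), pos.end());
    out[b] = es_core(pos, w, N);
  }
  return out;
}
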