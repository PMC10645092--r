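#include <Rcpp.h>
using namespace Rcpp;

// Uniform integer on [0, n), using R's RNG so set.seed() controls the chain.
static inline int runif_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k < n ? k : n - 1;
}

// One curveball trade on m (modified in place): pick two distinct rows,
// pool the columns where exactly one of them is present, and re-partition
// the pool uniformly at random, keeping each row's count of exclusive
// columns. Row and column totals are invariant.
static void curveball_trade_inplace(IntegerMatrix &m, std::vector<int> &pool) {
  const int nr = m.nrow(), nc = m.ncol();
  int i = runif_int(nr);
  int j = runif_int(nr - 1);
  if (j >= i) ++j;
  int np = 0, ka = 0;
  for (int c = 0; c < nc; ++c) {
    const int a = m(i, c), b = m(j, c);
    if (a != b) {
      pool[np++] = c;
      ka += a;
    }
  }
  if (np == 0 || ka == 0 || ka == np) return;
  // partial Fisher-Yates: the first ka pool entries become row i's columns
  for (int t = 0; t < ka; ++t) {
    const int r = t + runif_int(np - t);
    std::swap(pool[t], pool[r]);
  }
  for (int t = 0; t < np; ++t) {
    const int c = pool[t];
    const int v = (t < ka) ? 1 : 0;
    m(i, c) = v;
    m(j, c) = 1 - v;
  }
}

// [[Rcpp::export]]
IntegerMatrix curveball_steps_cpp(IntegerMatrix m0, int n_steps) {
  IntegerMatrix m = clone(m0);
  std::vector<int> pool(m.ncol());
  for (int s = 0; s < n_steps; ++s) curveball_trade_inplace(m, pool);
  return m;
}

// Run the chain and return n_samples states as a (nr x nc x n_samples)
// integer array: burn_in trades first, then one state every thin trades.
// [[Rcpp::export]]
IntegerVector curveball_sample_cpp(IntegerMatrix m0, int n_samples,
                                   int burn_in, int thin) {
  IntegerMatrix m = clone(m0);
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<int> pool(nc);
  IntegerVector out(static_cast<R_xlen_t>(nr) * nc * n_samples);
  out.attr("dim") = IntegerVector::create(nr, nc, n_samples);
  for (int s = 0; s < burn_in; ++s) curveball_trade_inplace(m, pool);
  for (int k = 0; k < n_samples; ++k) {
    for (int s = 0; s < thin; ++s) curveball_trade_inplace(m, pool);
    std::copy(m.begin(), m.end(),
              out.begin() + static_cast<R_xlen_t>(k) * nr * nc);
  }
  return out;
}

// As above, but instead of returning matrices, return the n_pairs x
// n_samples matrix of pairwise C-scores, pairs in column-major upper
// triangle order ((1,2),(1,3),(2,3),...), to avoid materializing the
// null ensemble when only pair statistics are needed.
// [[Rcpp::export]]
NumericMatrix curveball_pair_cscores_cpp(IntegerMatrix m0, int n_samples,
                                         int burn_in, int thin) {
  IntegerMatrix m = clone(m0);
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<int> pool(nc);
  const R_xlen_t n_pairs = static_cast<R_xlen_t>(nr) * (nr - 1) / 2;
  NumericMatrix out(n_pairs, n_samples);
  std::vector<int> rsum(nr);
  for (int s = 0; s < burn_in; ++s) curveball_trade_inplace(m, pool);
  for (int k = 0; k < n_samples; ++k) {
    for (int s = 0; s < thin; ++s) curveball_trade_inplace(m, pool);
    for (int i = 0; i < nr; ++i) {
      int r = 0;
      for (int c = 0; c < nc; ++c) r += m(i, c);
      rsum[i] = r;
    }
    R_xlen_t p = 0;
    for (int j = 1; j < nr; ++j) {
      for (int i = 0; i < j; ++i) {
        int shared = 0;
        for (int c = 0; c < nc; ++c) shared += m(i, c) & m(j, c);
        out(p++, k) = static_cast<double>(rsum[i] - shared) * (rsum[j] - shared);
      }
    }
  }
  return out;
}
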