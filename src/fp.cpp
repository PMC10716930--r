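// Fingerprint kernels: bit packing, bulk Tanimoto scans, banded MinHash
// LSH index, and exact Jaccard k-NN used to feed the UMAP embedding.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Pack 0-based on-bit index sets into 64 x n uint32 words (stored in an
// IntegerMatrix; bit b of molecule j lives in word b/32, bit b%32).
// [[Rcpp::export]]
IntegerMatrix cpp_pack_bits(List fps, int n_bits = 2048) {
  const int words = n_bits / 32;
  const int n = fps.size();
  IntegerMatrix out(words, n);
  for (int j = 0; j < n; ++j) {
    if (Rf_isNull(fps[j])) continue;
    IntegerVector bits = fps[j];
    uint32_t *col = reinterpret_cast<uint32_t *>(&out(0, j));
    for (int i = 0; i < bits.size(); ++i) {
      int b = bits[i];
      if (b < 0 || b >= n_bits) stop("bit index out of range");
      col[b / 32] |= (1u << (b % 32));
    }
  }
  return out;
}

static inline double tanimoto_packed(const uint32_t *a, const uint32_t *b,
                                     int words) {
  int inter = 0, uni = 0;
  int w = 0;
  for (; w + 1 < words; w += 2) {
    uint64_t aw, bw;
    std::memcpy(&aw, a + w, 8);
    std::memcpy(&bw, b + w, 8);
    inter += __builtin_popcountll(aw & bw);
    uni += __builtin_popcountll(aw | bw);
  }
  for (; w < words; ++w) {
    inter += __builtin_popcount(a[w] & b[w]);
    uni += __builtin_popcount(a[w] | b[w]);
  }
  return uni == 0 ? 1.0 : static_cast<double>(inter) / uni;
}

// Max Tanimoto of each query column against all reference columns.
// Returns the maximum and the 1-based arg-max reference index.
// [[Rcpp::export]]
List cpp_max_tanimoto(IntegerMatrix refs, IntegerMatrix queries) {
  const int words = refs.nrow();
  if (queries.nrow() != words) stop("packed widths differ");
  const int m = refs.ncol(), n = queries.ncol();
  if (m == 0) stop("empty reference set");
  NumericVector best(n);
  IntegerVector arg(n);
  const uint32_t *R0 = reinterpret_cast<const uint32_t *>(&refs(0, 0));
  const uint32_t *Q0 = reinterpret_cast<const uint32_t *>(&queries(0, 0));
  for (int q = 0; q < n; ++q) {
    const uint32_t *qc = Q0 + static_cast<size_t>(q) * words;
    double mx = -1.0;
    int mi = 0;
    for (int r = 0; r < m; ++r) {
      double s = tanimoto_packed(R0 + static_cast<size_t>(r) * words, qc, words);
      if (s > mx) {
        mx = s;
        mi = r;
      }
    }
    best[q] = mx;
    arg[q] = mi + 1;
  }
  return List::create(_["max_sim"] = best, _["argmax"] = arg);
}

// All pairwise Tanimoto similarities of queries (cols) vs refs (cols).
// [[Rcpp::export]]
NumericMatrix cpp_tanimoto_cross(IntegerMatrix refs, IntegerMatrix queries) {
  const int words = refs.nrow();
  const int m = refs.ncol(), n = queries.ncol();
  NumericMatrix out(m, n);
  const uint32_t *R0 = reinterpret_cast<const uint32_t *>(&refs(0, 0));
  const uint32_t *Q0 = reinterpret_cast<const uint32_t *>(&queries(0, 0));
  for (int q = 0; q < n; ++q)
    for (int r = 0; r < m; ++r)
      out(r, q) = tanimoto_packed(R0 + static_cast<size_t>(r) * words,
                                  Q0 + static_cast<size_t>(q) * words, words);
  return out;
}

// Exact Jaccard k-nearest neighbours (self included, distance 0 first),
// in the format uwot expects for precomputed neighbours.
// [[Rcpp::export]]
List cpp_jaccard_knn(IntegerMatrix packed, int k) {
  const int words = packed.nrow(), n = packed.ncol();
  if (k > n) stop("k larger than number of molecules");
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  const uint32_t *P0 = reinterpret_cast<const uint32_t *>(&packed(0, 0));
  std::vector<std::pair<double, int>> d(n);
  for (int i = 0; i < n; ++i) {
    const uint32_t *a = P0 + static_cast<size_t>(i) * words;
    for (int j = 0; j < n; ++j) {
      double s = tanimoto_packed(a, P0 + static_cast<size_t>(j) * words, words);
      // force self to the front deterministically
      d[j] = {i == j ? -1.0 : 1.0 - s, j};
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = d[j].second + 1;
      dist(i, j) = std::max(d[j].first, 0.0);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// ---- banded MinHash LSH ----------------------------------------------

struct LshIndex {
  int n_bands, rows, n_refs;
  // per band: hashes sorted ascending with the molecule ids in that order
  std::vector<std::vector<uint64_t>> hashes;
  std::vector<std::vector<int>> ids;
};

static inline uint64_t fnv1a(const int *x, int n) {
  uint64_t h = 1469598103934665603ULL;
  const unsigned char *p = reinterpret_cast<const unsigned char *>(x);
  for (int i = 0; i < n * 4; ++i) {
    h ^= p[i];
    h *= 1099511628211ULL;
  }
  return h;
}

// [[Rcpp::export]]
SEXP cpp_lsh_build(IntegerMatrix mh, int n_bands) {
  const int perms = mh.nrow(), n = mh.ncol();
  if (n == 0) stop("empty reference set");
  if (perms % n_bands != 0) stop("n_bands must divide the minhash length");
  LshIndex *ix = new LshIndex();
  ix->n_bands = n_bands;
  ix->rows = perms / n_bands;
  ix->n_refs = n;
  ix->hashes.resize(n_bands);
  ix->ids.resize(n_bands);
  std::vector<std::pair<uint64_t, int>> band(n);
  for (int b = 0; b < n_bands; ++b) {
    for (int j = 0; j < n; ++j)
      band[j] = {fnv1a(&mh(b * ix->rows, j), ix->rows), j};
    std::sort(band.begin(), band.end());
    ix->hashes[b].resize(n);
    ix->ids[b].resize(n);
    for (int j = 0; j < n; ++j) {
      ix->hashes[b][j] = band[j].first;
      ix->ids[b][j] = band[j].second;
    }
  }
  XPtr<LshIndex> ptr(ix, true);
  return ptr;
}

static inline double minhash_sim(const int *a, const int *b, int n) {
  int eq = 0;
  for (int i = 0; i < n; ++i) eq += (a[i] == b[i]);
  return static_cast<double>(eq) / n;
}

// For each query column: candidates = union of band collisions, ranked by
// estimated Jaccard (minhash agreement) descending, ties by id; top k kept.
// [[Rcpp::export]]
List cpp_lsh_query(SEXP ptr_, IntegerMatrix refs_mh, IntegerMatrix queries_mh,
                   int k) {
  XPtr<LshIndex> ptr(ptr_);
  LshIndex *ix = ptr.get();
  const int perms = refs_mh.nrow();
  if (queries_mh.nrow() != perms) stop("minhash widths differ");
  if (refs_mh.ncol() != ix->n_refs) stop("reference set does not match index");
  const int n = queries_mh.ncol();
  List out(n);
  std::vector<int> cand;
  std::vector<char> seen(ix->n_refs, 0);
  for (int q = 0; q < n; ++q) {
    cand.clear();
    for (int b = 0; b < ix->n_bands; ++b) {
      uint64_t h = fnv1a(&queries_mh(b * ix->rows, q), ix->rows);
      const std::vector<uint64_t> &hs = ix->hashes[b];
      size_t lo = std::lower_bound(hs.begin(), hs.end(), h) - hs.begin();
      for (size_t i = lo; i < hs.size() && hs[i] == h; ++i) {
        int id = ix->ids[b][i];
        if (!seen[id]) {
          seen[id] = 1;
          cand.push_back(id);
        }
      }
    }
    std::vector<std::pair<double, int>> ranked(cand.size());
    for (size_t i = 0; i < cand.size(); ++i) {
      seen[cand[i]] = 0;
      ranked[i] = {-minhash_sim(&refs_mh(0, cand[i]), &queries_mh(0, q), perms),
                   cand[i]};
    }
    std::sort(ranked.begin(), ranked.end());
    int keep = std::min<int>(k, ranked.size());
    IntegerVector ids(keep);
    NumericVector sims(keep);
    for (int i = 0; i < keep; ++i) {
      ids[i] = ranked[i].second + 1;
      sims[i] = -ranked[i].first;
    }
    out[q] = List::create(_["ids"] = ids, _["est_jaccard"] = sims);
  }
  return out;
}

// 1-based positions of reference columns identical to `query`; works for
// packed bit columns and minhash vectors alike (verification steps).
// [[Rcpp::export]]
IntegerVector cpp_columns_equal(IntegerMatrix refs, IntegerVector query) {
  const int perms = refs.nrow(), n = refs.ncol();
  if (query.size() != perms) stop("minhash widths differ");
  IntegerVector out;
  for (int j = 0; j < n; ++j) {
    bool eq = true;
    for (int i = 0; i < perms && eq; ++i) eq = refs(i, j) == query[i];
    if (eq) out.push_back(j + 1);
  }
  return out;
}
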