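#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Rows are integer-encoded match columns: 0 = gap, 1..20 = amino acids,
// 21 = X. Pairwise identity between two rows counts identical residues over
// the columns where both rows carry a residue (so exact duplicates score 1
// regardless of shared gaps); 'X' never certifies a match but does occupy a
// column. Rows are copied into contiguous int8 buffers up front so the
// pairwise scans stream through memory.

typedef std::vector<int8_t> Row;

static std::vector<Row> to_rows(const IntegerMatrix &M) {
  const int n = M.nrow(), L = M.ncol();
  std::vector<Row> rows(n, Row(L));
  for (int c = 0; c < L; ++c) {
    for (int i = 0; i < n; ++i) rows[i][c] = static_cast<int8_t>(M(i, c));
  }
  return rows;
}

static inline double row_identity(const Row &a, const Row &b) {
  const int L = static_cast<int>(a.size());
  int m = 0, d = 0;
  for (int c = 0; c < L; ++c) {
    const int8_t x = a[c], y = b[c];
    const int both = (x != 0) & (y != 0);
    d += both;
    m += both & (x >= 1) & (x <= 20) & (x == y);
  }
  if (d == 0) return 0.0;
  return static_cast<double>(m) / static_cast<double>(d);
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_identity(IntegerMatrix M) {
  const std::vector<Row> rows = to_rows(M);
  const int n = M.nrow();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = row_identity(rows[i], rows[i]);
    for (int j = i + 1; j < n; ++j) {
      const double id = row_identity(rows[i], rows[j]);
      out(i, j) = id;
      out(j, i) = id;
    }
  }
  return out;
}

// Greedy scan in input (priority) order: keep a row iff its identity to every
// already-kept row is <= threshold. Returns 1-based indices of kept rows.
// [[Rcpp::export]]
IntegerVector cpp_greedy_max_seq_id(IntegerMatrix M, double threshold) {
  const std::vector<Row> rows = to_rows(M);
  const int n = M.nrow();
  std::vector<int> kept;
  kept.reserve(n);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (size_t k = 0; k < kept.size(); ++k) {
      if (row_identity(rows[i], rows[kept[k]]) > threshold) { ok = false; break; }
    }
    if (ok) kept.push_back(i);
  }
  IntegerVector out(kept.size());
  for (size_t k = 0; k < kept.size(); ++k) out[k] = kept[k] + 1;
  return out;
}

// Deterministic farthest-point selection: seed = first row; repeatedly add the
// row with the largest minimum distance (1 - identity) to the selected set,
// ties broken by input order (strict > keeps the earliest maximiser).
// Returns 1-based indices in selection order.
// [[Rcpp::export]]
IntegerVector cpp_farthest_point_select(IntegerMatrix M, int k) {
  const int n = M.nrow();
  if (k >= n) {
    IntegerVector all(n);
    for (int i = 0; i < n; ++i) all[i] = i + 1;
    return all;
  }
  const std::vector<Row> rows = to_rows(M);
  std::vector<double> mindist(n);
  std::vector<bool> selected(n, false);
  std::vector<int> order;
  order.reserve(k);
  selected[0] = true;
  order.push_back(0);
  for (int i = 1; i < n; ++i) mindist[i] = 1.0 - row_identity(rows[i], rows[0]);
  for (int s = 1; s < k; ++s) {
    int best = -1;
    double bestd = -1.0;
    for (int i = 0; i < n; ++i) {
      if (!selected[i] && mindist[i] > bestd) { bestd = mindist[i]; best = i; }
    }
    if (best < 0) break;
    selected[best] = true;
    order.push_back(best);
    const Row &br = rows[best];
    for (int i = 0; i < n; ++i) {
      if (!selected[i]) {
        const double d = 1.0 - row_identity(rows[i], br);
        if (d < mindist[i]) mindist[i] = d;
      }
    }
  }
  IntegerVector out(order.size());
  for (size_t s = 0; s < order.size(); ++s) out[s] = order[s] + 1;
  return out;
}
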