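#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <vector>

using namespace Rcpp;

// BiBit enumeration on a binary matrix.
//
// Rows are packed into 64-bit words (little-endian bit order within a word:
// column j lives in word j/64, bit j%64). Every unordered row pair (a, b)
// seeds a candidate column pattern P = row_a AND row_b; a pattern with
// popcount >= mnc that has not been seen before is extended to the full set
// of rows containing it, and emitted when at least mnr rows support it.
// Deduplication is keyed on the complete packed pattern, so distinct
// patterns can never collide; the supporting row set is a deterministic
// function of the pattern, which makes the result independent of pair
// iteration order.
//
// [[Rcpp::export(name = ".bibit_enumerate")]]
List bibit_enumerate(LogicalMatrix mat, int mnr, int mnc) {
  const int n = mat.nrow();
  const int m = mat.ncol();
  const int W = (m + 63) / 64;

  std::vector<std::vector<uint64_t> > rows(n, std::vector<uint64_t>(W, 0));
  std::vector<int> pc(n, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (mat(i, j) == TRUE) {
        rows[i][j >> 6] |= (uint64_t)1 << (j & 63);
        ++pc[i];
      }
    }
  }

  std::map<std::vector<uint64_t>, char> seen;
  std::vector<std::vector<int> > out_rows, out_cols;
  std::vector<uint64_t> pat(W);

  for (int a = 0; a < n; ++a) {
    if (pc[a] < mnc) continue;  // cannot seed a pattern wide enough
    for (int b = a + 1; b < n; ++b) {
      if (pc[b] < mnc) continue;
      int popc = 0;
      for (int w = 0; w < W; ++w) {
        pat[w] = rows[a][w] & rows[b][w];
#if defined(__GNUC__) || defined(__clang__)
        popc += __builtin_popcountll(pat[w]);
#else
        uint64_t v = pat[w];
        while (v) { v &= v - 1; ++popc; }
#endif
      }
      if (popc < mnc) continue;
      if (!seen.insert(std::make_pair(pat, 1)).second) continue;

      std::vector<int> support;
      for (int r = 0; r < n; ++r) {
        bool contains = true;
        for (int w = 0; w < W; ++w) {
          if ((rows[r][w] & pat[w]) != pat[w]) { contains = false; break; }
        }
        if (contains) support.push_back(r + 1);
      }
      if ((int)support.size() < mnr) continue;

      std::vector<int> cols;
      cols.reserve(popc);
      for (int j = 0; j < m; ++j) {
        if (pat[j >> 6] & ((uint64_t)1 << (j & 63))) cols.push_back(j + 1);
      }
      out_rows.push_back(support);
      out_cols.push_back(cols);
    }
  }

  List tr(out_rows.size()), ge(out_cols.size());
  for (size_t i = 0; i < out_rows.size(); ++i) {
    tr[i] = wrap(out_rows[i]);
    ge[i] = wrap(out_cols[i]);
  }
  return List::create(_["traits"] = tr, _["genes"] = ge);
}
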