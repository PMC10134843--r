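#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Banded local alignment for nucleotide sequences, guided by shared k-mer
// anchors. Sequences must be uppercase ACGT. Linear gap penalty.
//
// The band is chosen from the diagonals of exact shared k-mers: within the
// densest diagonal window (width <= band_window) the band is extended by
// band_pad on each side. A pair sharing no k-mer is reported as unaligned;
// at the identity levels relevant for dereplication (>= 90%) a shared
// 15-mer is effectively guaranteed, so the prefilter cannot split pairs
// that the thresholds would merge.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".align_band_cpp")]]
List align_band_cpp(std::string a, std::string b,
                    int k = 15, int band_pad = 48, int band_window = 200,
                    int match = 1, int mismatch = -1, int gap = -2) {
  const int n = (int)a.size(), m = (int)b.size();
  List nores = List::create(_["found"] = false);
  if (n < k || m < k) return nores;

  // hash k-mers of a (2-bit encoding)
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::unordered_map<uint64_t, std::vector<int> > idx;
  {
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(a[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) idx[h].push_back(i - k + 1);
    }
  }

  // collect anchor diagonals (diag = i - j)
  std::unordered_map<int, int> diag_count;
  {
    uint64_t h = 0; int run = 0;
    for (int j = 0; j < m; ++j) {
      int c = base_code(b[j]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto it = idx.find(h);
        if (it != idx.end()) {
          int jj = j - k + 1;
          for (int i : it->second) diag_count[i - jj] += 1;
        }
      }
    }
  }
  if (diag_count.empty()) return nores;

  // densest diagonal window of width band_window
  std::vector<std::pair<int, int> > diags(diag_count.begin(), diag_count.end());
  std::sort(diags.begin(), diags.end());
  size_t lo = 0; long cur = 0, best = -1; int dlo = 0, dhi = 0;
  for (size_t hi = 0; hi < diags.size(); ++hi) {
    cur += diags[hi].second;
    while (diags[hi].first - diags[lo].first > band_window) {
      cur -= diags[lo].second; ++lo;
    }
    if (cur > best) { best = cur; dlo = diags[lo].first; dhi = diags[hi].first; }
  }
  dlo -= band_pad; dhi += band_pad;
  if (dhi - dlo + 1 > 1024) { // cap band width
    int mid = (dlo + dhi) / 2;
    dlo = mid - 512; dhi = mid + 511;
  }
  const int w = dhi - dlo + 1;

  // banded Smith-Waterman, score matrix kept for traceback
  // cell (i, j): i in 1..n over a, j in 1..m over b, j - i in [-dhi, -dlo]
  // column index c = j - i + dhi in [0, w-1]
  std::vector<int> H((size_t)(n + 1) * w, 0);
  int best_sc = 0, bi = 0, bc = 0;
  for (int i = 1; i <= n; ++i) {
    int jmin = std::max(1, i - dhi), jmax = std::min(m, i - dlo);
    if (jmin > jmax) continue;
    const size_t row = (size_t)i * w, prow = (size_t)(i - 1) * w;
    for (int j = jmin; j <= jmax; ++j) {
      int c = j - i + dhi;
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int v = H[prow + c] + s;              // diagonal (i-1, j-1)
      if (c + 1 < w) v = std::max(v, H[prow + c + 1] + gap); // (i-1, j)
      if (c - 1 >= 0) v = std::max(v, H[row + c - 1] + gap); // (i, j-1)
      if (v < 0) v = 0;
      H[row + c] = v;
      if (v > best_sc) { best_sc = v; bi = i; bc = c; }
    }
  }
  if (best_sc <= 0) return nores;

  // traceback
  int i = bi, c = bc;
  int matches = 0, mismatches = 0, gaps = 0;
  int a_end = bi, b_end = bc + bi - dhi, a_start = bi, b_start = b_end;
  while (i > 0) {
    int j = c + i - dhi;
    if (j <= 0) break;
    size_t row = (size_t)i * w, prow = (size_t)(i - 1) * w;
    int v = H[row + c];
    if (v == 0) break;
    int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
    if (v == H[prow + c] + s) {
      if (s == match) ++matches; else ++mismatches;
      a_start = i; b_start = j;
      i -= 1; // diagonal: c unchanged
    } else if (c + 1 < w && v == H[prow + c + 1] + gap) {
      ++gaps; a_start = i; i -= 1; c += 1; // gap in b
    } else if (c - 1 >= 0 && v == H[row + c - 1] + gap) {
      ++gaps; b_start = j; c -= 1;         // gap in a
    } else {
      break; // band edge artifact; stop
    }
  }
  return List::create(
    _["found"] = true, _["score"] = best_sc,
    _["matches"] = matches, _["mismatches"] = mismatches, _["gaps"] = gaps,
    _["aligned_cols"] = matches + mismatches + gaps,
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end);
}
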