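#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline int code2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Direct-repeat array scanner (CRT-style seed-and-verify).
//
// Scans left to right; at each position the seed_word-mer is looked up for
// its next exact occurrence at an admissible period d, periodic copies of
// the seed are counted, and the repeat is extended maximally on both sides
// while all copies agree (with at most max_mm mismatches per copy against
// the first copy). The repeat is trimmed on the right to respect the
// repeat-length maximum and the spacer-length minimum. Arrays are accepted
// with >= min_repeats copies, all length constraints met, and every spacer
// pair at most spacer_id_max identical; accepted arrays are reported
// greedily left to right without overlap.
//
// Returns a DataFrame with 0-based half-open coordinates:
// start, end, period, repeat_len, n_repeats.
// [[Rcpp::export]]
DataFrame detect_arrays_cpp(std::string seq, int min_repeats,
                            int rmin, int rmax, int smin, int smax,
                            int k, int max_mm, double spacer_id_max) {
  const int n = (int) seq.size();
  std::vector<int> r_start, r_end, r_period, r_rlen, r_nrep;
  const int dmin = rmin + smin, dmax = rmax + smax;
  const int min_span = 2 * rmin + smin;
  if (n >= min_span && k <= 16) {
    const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    // rolling k-mer codes; kcode[i] = code of seq[i..i+k), valid[i] flags N-free
    std::vector<uint32_t> kcode(n, 0);
    std::vector<char> kvalid(n, 0);
    {
      uint32_t h = 0; int run = 0;
      for (int i = 0; i < n; ++i) {
        int c = code2(seq[i]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint32_t) c) & mask;
        if (++run >= k) { kcode[i - k + 1] = h; kvalid[i - k + 1] = 1; }
      }
    }
    std::unordered_map<uint32_t, std::vector<int> > occ;
    for (int i = 0; i + k <= n; ++i) if (kvalid[i]) occ[kcode[i]].push_back(i);

    int i = 0;
    while (i + min_span <= n) {
      if (!kvalid[i]) { ++i; continue; }
      bool accepted = false;
      const std::vector<int>& pos = occ[kcode[i]];
      // first occurrence after i, ascending
      size_t lo = std::upper_bound(pos.begin(), pos.end(), i) - pos.begin();
      for (size_t pi = lo; pi < pos.size() && !accepted; ++pi) {
        const int d = pos[pi] - i;
        if (d < dmin) continue;
        if (d > dmax) break;
        // count periodic copies of the seed word
        int m = 1;
        while (i + m * d + k <= n && kvalid[i + m * d] &&
               kcode[i + m * d] == kcode[i]) ++m;
        if (m < min_repeats) continue;
        // maximal agreement interval [i + el, i + er) across all m copies,
        // consensus = first copy, <= max_mm mismatches per copy
        std::vector<int> mm(m, 0);
        int el = 0, er = k;
        const int cap = std::min(rmax, d - smin);
        // right extension
        while (er - el < cap && i + er + (m - 1) * d < n) {
          const char c = seq[i + er];
          bool ok = true;
          for (int t = 1; t < m; ++t) {
            if (seq[i + er + t * d] != c && mm[t] + 1 > max_mm) { ok = false; break; }
          }
          if (!ok) break;
          for (int t = 1; t < m; ++t) if (seq[i + er + t * d] != c) mm[t]++;
          ++er;
        }
        // left extension
        while (er - el < cap && i + el > 0) {
          const char c = seq[i + el - 1];
          bool ok = true;
          for (int t = 1; t < m; ++t) {
            if (seq[i + el - 1 + t * d] != c && mm[t] + 1 > max_mm) { ok = false; break; }
          }
          if (!ok) break;
          for (int t = 1; t < m; ++t) if (seq[i + el - 1 + t * d] != c) mm[t]++;
          --el;
        }
        const int r = er - el;
        if (r < rmin) continue;
        const int spacer = d - r;
        if (spacer < smin || spacer > smax) continue;
        const int start = i + el, end = start + (m - 1) * d + r;
        if (end > n) continue;
        // spacer mutual-similarity guard (equal lengths by construction)
        bool too_similar = false;
        for (int a = 0; a < m - 1 && !too_similar; ++a) {
          for (int b = a + 1; b < m - 1 && !too_similar; ++b) {
            int same = 0;
            const int sa = start + r + a * d, sb = start + r + b * d;
            for (int x = 0; x < spacer; ++x) if (seq[sa + x] == seq[sb + x]) ++same;
            if ((double) same / (double) spacer > spacer_id_max) too_similar = true;
          }
        }
        if (too_similar) continue;
        r_start.push_back(start); r_end.push_back(end);
        r_period.push_back(d); r_rlen.push_back(r); r_nrep.push_back(m);
        i = end;
        accepted = true;
      }
      if (!accepted) ++i;
    }
  }
  return DataFrame::create(_["start"] = r_start, _["end"] = r_end,
                           _["period"] = r_period, _["repeat_len"] = r_rlen,
                           _["n_repeats"] = r_nrep,
                           _["stringsAsFactors"] = false);
}
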