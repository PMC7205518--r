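#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}
static inline int code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Local alignment with affine gaps (Gotoh). Scores: match > 0 > mismatch;
// a gap of length L costs gap_open + L * gap_extend. N never scores as a
// match (any column touching N takes the mismatch score and is not counted
// in `matches`). Returns a list: score, qstart, qend, tstart, tend
// (1-based inclusive), matches, columns. score 0 means no local alignment
// with positive score exists.
// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int m = (int) query.size(), n = (int) target.size();
  List none = List::create(_["score"] = 0.0, _["qstart"] = NA_INTEGER,
                           _["qend"] = NA_INTEGER, _["tstart"] = NA_INTEGER,
                           _["tend"] = NA_INTEGER, _["matches"] = 0,
                           _["columns"] = 0);
  if (m == 0 || n == 0) return none;

  const double go = gap_open + gap_extend; // cost of opening a 1-base gap
  const size_t sz = (size_t)(m + 1) * (size_t)(n + 1);
  std::vector<double> H(sz, 0.0), E(sz, R_NegInf), F(sz, R_NegInf);
  // traceback: for H 0=stop,1=diag,2=E(gap in query row),3=F; for E/F: 1 if
  // opened from H, 0 if extended
  std::vector<uint8_t> tbH(sz, 0), tbE(sz, 0), tbF(sz, 0);

  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    const char qc = query[i - 1];
    const size_t row = (size_t) i * (n + 1), prow = (size_t)(i - 1) * (n + 1);
    for (int j = 1; j <= n; ++j) {
      const char tc = target[j - 1];
      const double s = (is_base(qc) && qc == tc) ? match : mismatch;
      // E: gap consuming target (query pauses)
      double eOpen = H[row + j - 1] - go, eExt = E[row + j - 1] - gap_extend;
      E[row + j] = eOpen >= eExt ? eOpen : eExt;
      tbE[row + j] = eOpen >= eExt ? 1 : 0;
      // F: gap consuming query
      double fOpen = H[prow + j] - go, fExt = F[prow + j] - gap_extend;
      F[row + j] = fOpen >= fExt ? fOpen : fExt;
      tbF[row + j] = fOpen >= fExt ? 1 : 0;
      double diag = H[prow + j - 1] + s;
      double h = 0.0; uint8_t tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[row + j] > h) { h = E[row + j]; tb = 2; }
      if (F[row + j] > h) { h = F[row + j]; tb = 3; }
      H[row + j] = h; tbH[row + j] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return none;

  // traceback from (bi, bj)
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  int matches = 0, columns = 0;
  int qend = bi, tend = bj, qstart = bi, tstart = bj;
  while (true) {
    const size_t row = (size_t) i * (n + 1);
    if (state == 0) {
      uint8_t tb = tbH[row + j];
      if (tb == 0) break;
      if (tb == 1) {
        columns++;
        if (is_base(query[i - 1]) && query[i - 1] == target[j - 1]) matches++;
        qstart = i; tstart = j;
        i--; j--;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      columns++;
      tstart = j;
      state = tbE[row + j] ? 0 : 1;
      j--;
    } else {
      columns++;
      qstart = i;
      state = tbF[row + j] ? 0 : 2;
      i--;
    }
  }
  return List::create(_["score"] = best, _["qstart"] = qstart,
                      _["qend"] = qend, _["tstart"] = tstart,
                      _["tend"] = tend, _["matches"] = matches,
                      _["columns"] = columns);
}

// 1-based start positions in `target` where any exact w-mer of `query`
// occurs (w <= 16, N-containing words skipped).
// [[Rcpp::export]]
IntegerVector find_seeds_cpp(std::string query, std::string target, int w) {
  const int m = (int) query.size(), n = (int) target.size();
  std::vector<int> out;
  if (w < 1 || w > 16 || m < w || n < w) return IntegerVector(0);
  const uint32_t mask = (w == 16) ? 0xFFFFFFFFu : ((1u << (2 * w)) - 1u);
  std::unordered_set<uint32_t> words;
  uint32_t h = 0; int run = 0;
  for (int i = 0; i < m; ++i) {
    int c = code(query[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t) c) & mask;
    if (++run >= w) words.insert(h);
  }
  if (words.empty()) return IntegerVector(0);
  h = 0; run = 0;
  for (int i = 0; i < n; ++i) {
    int c = code(target[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t) c) & mask;
    if (++run >= w && words.count(h)) out.push_back(i - w + 2); // 1-based start
  }
  return wrap(out);
}
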