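#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Gotoh local alignment with affine gaps.  A gap of length L costs
// gap_open + L * gap_extend (NCBI convention: the first gapped position
// pays both the opening and the extension penalty).
//
// q, t: 1-based integer codes into the rows/cols of `sub`.
// Returns the single best-scoring local alignment with a full traceback so
// the caller gets exact match counts and both coordinate spans.
//
// Traceback byte layout per cell:
//   bits 0-1: source of H (0 = stop, 1 = diagonal, 2 = E, 3 = F)
//   bit  2  : E extends a previous E (otherwise opens from H)
//   bit  3  : F extends a previous F (otherwise opens from H)

// [[Rcpp::export(name = ".sw_align_core")]]
List sw_align_core(IntegerVector q, IntegerVector t, NumericMatrix sub,
                   double gap_open, double gap_extend) {
  const int n = q.size(), m = t.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0, _["n_match"] = 0,
                        _["aln_len"] = 0);
  const double NEG = -1e18;
  const int K = sub.nrow();
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  std::vector<uint8_t> tb((size_t)n * m, 0);
  std::vector<int> tj(m);
  for (int j = 0; j < m; ++j) tj[j] = t[j] - 1;
  const double *subp = REAL(sub);
  const double go_ge = gap_open + gap_extend, ge = gap_extend;

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const double *srow = subp + (size_t)(q[i - 1] - 1); // + K*tj indexes
    uint8_t *tbrow = tb.data() + (size_t)(i - 1) * m;
    double *hp = Hprev.data(), *hc = Hcur.data();
    double *fp = Fprev.data(), *fc = Fcur.data();
    hc[0] = 0.0;
    double e = NEG;
    for (int j = 1; j <= m; ++j) {
      uint8_t code = 0;
      // E: gap in query (consumes target)
      double e_open = hc[j - 1] - go_ge;
      double e_ext = e - ge;
      e = e_open;
      if (e_ext > e_open) { e = e_ext; code |= 0x4; }
      // F: gap in target (consumes query)
      double f_open = hp[j] - go_ge;
      double f_ext = fp[j] - ge;
      double f = f_open;
      if (f_ext > f_open) { f = f_ext; code |= 0x8; }
      fc[j] = f;
      // H
      double diag = hp[j - 1] + srow[(size_t)K * tj[j - 1]];
      double h = 0.0;
      uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      hc[j] = h;
      tbrow[j - 1] = code | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0, _["n_match"] = 0,
                        _["aln_len"] = 0);

  // traceback from (bi, bj)
  int i = bi, j = bj, n_match = 0, aln_len = 0;
  int state = 0; // 0 = in H, 2 = in E, 3 = in F
  int qe = bi, te = bj, qs = bi, ts = bj;
  while (i > 0 && j > 0) {
    uint8_t c = tb[(size_t)(i - 1) * m + (j - 1)];
    if (state == 0) {
      uint8_t src = c & 0x3;
      if (src == 0) break;
      if (src == 1) {
        if (q[i - 1] == t[j - 1]) ++n_match;
        ++aln_len;
        qs = i; ts = j;
        --i; --j;
      } else {
        state = src; // enter E or F without consuming
      }
    } else if (state == 2) { // E: consumes target
      ++aln_len;
      ts = j;
      bool ext = (c & 0x4) != 0;
      --j;
      if (!ext) state = 0;
    } else { // F: consumes query
      ++aln_len;
      qs = i;
      bool ext = (c & 0x8) != 0;
      --i;
      if (!ext) state = 0;
    }
  }

  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = qe,
                      _["t_start"] = ts, _["t_end"] = te,
                      _["n_match"] = n_match, _["aln_len"] = aln_len);
}
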