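#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise aligners used by the homology scanner and the
// tandem-duplication pair statistics.  Gap of length L costs
// gap_open + L * gap_extend (Biostrings convention), penalties passed
// as positive numbers.

namespace {

const double NEG_INF = -1e18;

inline double submatch(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch; // conservative: N never matches
  return (a == b) ? match : mismatch;
}

struct AlnResult {
  double score;
  int a_start, a_end, b_start, b_end; // 1-based, inclusive
  int matches, columns;
};

// traceback codes: 0 = stop, 1 = diagonal (H), 2 = gap in b (E: consume a),
// 3 = gap in a (F: consume b)
enum { TB_STOP = 0, TB_DIAG = 1, TB_UP = 2, TB_LEFT = 3 };

AlnResult align_core(const std::string& a, const std::string& b,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     bool local) {
  const int m = a.size(), n = b.size();
  const size_t W = n + 1;
  std::vector<double> Hp(W), Hc(W), Ep(W), Ec(W), Fp(W), Fc(W);
  // traceback matrices: which matrix we were in, and where we came from
  std::vector<unsigned char> tbH((size_t)(m + 1) * W, TB_STOP);
  std::vector<unsigned char> tbE((size_t)(m + 1) * W, 0); // 1 = open (from H), 0 = extend
  std::vector<unsigned char> tbF((size_t)(m + 1) * W, 0);

  for (int j = 0; j <= n; ++j) {
    Hp[j] = 0.0;            // free leading gaps (overlap) / local start
    Ep[j] = NEG_INF;
    Fp[j] = NEG_INF;
  }

  double best = local ? 0.0 : NEG_INF;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    Hc[0] = 0.0;
    Ec[0] = NEG_INF;
    Fc[0] = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      // E: gap in b (vertical, consume a[i])
      double e_open = Hp[j] - gap_open - gap_extend;
      double e_ext  = Ep[j] - gap_extend;
      if (e_open >= e_ext) { Ec[j] = e_open; tbE[(size_t)i * W + j] = 1; }
      else                 { Ec[j] = e_ext;  tbE[(size_t)i * W + j] = 0; }
      // F: gap in a (horizontal, consume b[j])
      double f_open = Hc[j - 1] - gap_open - gap_extend;
      double f_ext  = Fc[j - 1] - gap_extend;
      if (f_open >= f_ext) { Fc[j] = f_open; tbF[(size_t)i * W + j] = 1; }
      else                 { Fc[j] = f_ext;  tbF[(size_t)i * W + j] = 0; }

      double diag = Hp[j - 1] + submatch(a[i - 1], b[j - 1], match, mismatch);
      double h = diag;
      unsigned char tb = TB_DIAG;
      if (Ec[j] > h) { h = Ec[j]; tb = TB_UP; }
      if (Fc[j] > h) { h = Fc[j]; tb = TB_LEFT; }
      if (local && h <= 0.0) { h = 0.0; tb = TB_STOP; }
      Hc[j] = h;
      tbH[(size_t)i * W + j] = tb;
      if (local) {
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (!local) {
      // overlap: free trailing gaps -> candidates on last column
      if (Hc[n] > best) { best = Hc[n]; bi = i; bj = n; }
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  if (!local) {
    // last row (Hp holds row m after the swap)
    for (int j = 0; j <= n; ++j) {
      if (Hp[j] > best) { best = Hp[j]; bi = m; bj = j; }
    }
    if (m == 0 || n == 0) { best = 0.0; bi = m; bj = n; }
  }

  // traceback; we did not keep full H/E/F values, so re-derive the path from
  // the traceback codes alone (they fully determine the moves)
  AlnResult res;
  res.score = best;
  res.matches = 0; res.columns = 0;
  int i = bi, j = bj;
  res.a_end = i; res.b_end = j;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char tb = tbH[(size_t)i * W + j];
      if (tb == TB_STOP) break;           // local alignment start
      if (tb == TB_DIAG) {
        ++res.columns;
        if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++res.matches;
        --i; --j;
      } else if (tb == TB_UP) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char open = tbE[(size_t)i * W + j];
      ++res.columns; --i;
      if (open) state = 0;
    } else {
      unsigned char open = tbF[(size_t)i * W + j];
      ++res.columns; --j;
      if (open) state = 0;
    }
  }
  res.a_start = i + 1; res.b_start = j + 1;
  if (res.a_end < res.a_start) { res.a_start = res.a_end = 0; }
  if (res.b_end < res.b_start) { res.b_start = res.b_end = 0; }
  return res;
}

List wrap_result(const AlnResult& r) {
  return List::create(
    _["score"] = r.score,
    _["a_start"] = r.a_start, _["a_end"] = r.a_end,
    _["b_start"] = r.b_start, _["b_end"] = r.b_end,
    _["matches"] = r.matches, _["columns"] = r.columns,
    _["identity_pct"] = r.columns > 0 ? 100.0 * r.matches / r.columns : 0.0);
}

} // namespace

// [[Rcpp::export]]
List cpp_align_local(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  return wrap_result(align_core(a, b, match, mismatch, gap_open, gap_extend, true));
}

// [[Rcpp::export]]
List cpp_align_overlap(std::string a, std::string b,
                       double match, double mismatch,
                       double gap_open, double gap_extend) {
  return wrap_result(align_core(a, b, match, mismatch, gap_open, gap_extend, false));
}
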