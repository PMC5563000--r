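// Batch Smith-Waterman local alignment with affine gaps.
//
// Scores follow the BLAST convention: a gap of length g costs
// gap_open + g * gap_extend. Traceback is deterministic: at each cell the
// diagonal move is preferred, then the vertical (gap in the subject), then
// the horizontal (gap in the query); the maximal cell chosen as the HSP
// end is the first one encountered in row-major order.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const int NEG_INF = -1000000000;

// [[Rcpp::export(name = ".sw_batch")]]
DataFrame sw_batch(CharacterVector a, CharacterVector b,
                   NumericMatrix submat, CharacterVector alphabet,
                   double gap_open, double gap_extend) {
  int npair = a.size();
  if (b.size() != npair) stop("length mismatch");

  // char -> matrix index lookup
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < alphabet.size(); ++i) {
    const char *s = CHAR(STRING_ELT(alphabet, i));
    lut[(unsigned char)s[0]] = i;
  }
  int nalpha = alphabet.size();
  // integer-scaled scores (substitution matrices here are integral)
  std::vector<int> S(nalpha * nalpha);
  for (int i = 0; i < nalpha; ++i)
    for (int j = 0; j < nalpha; ++j)
      S[i * nalpha + j] = (int)std::lround(submat(i, j));
  int go = (int)std::lround(gap_open), ge = (int)std::lround(gap_extend);
  int open1 = go + ge;  // cost of opening a gap of length 1

  IntegerVector score(npair), nmatch(npair), hsp_len(npair);
  IntegerVector q_start(npair), q_end(npair), s_start(npair), s_end(npair);

  for (int p = 0; p < npair; ++p) {
    const char *qa = CHAR(STRING_ELT(a, p));
    const char *sb = CHAR(STRING_ELT(b, p));
    int m = (int)std::strlen(qa), n = (int)std::strlen(sb);
    std::vector<int> qi(m), si(n);
    for (int i = 0; i < m; ++i) {
      qi[i] = lut[(unsigned char)qa[i]];
      if (qi[i] < 0) stop("character not in scoring alphabet");
    }
    for (int j = 0; j < n; ++j) {
      si[j] = lut[(unsigned char)sb[j]];
      if (si[j] < 0) stop("character not in scoring alphabet");
    }

    // H, E (gap in query / horizontal), F (gap in subject / vertical)
    std::vector<int> Hrow(n + 1, 0), Frow(n + 1, NEG_INF);
    // packed direction byte per cell:
    //   bits 0-1: H origin (0 stop, 1 diag, 2 up/F, 3 left/E)
    //   bit 2: E extends E; bit 3: F extends F
    std::vector<unsigned char> dir((size_t)(m + 1) * (n + 1), 0);
    int best = 0, bi = 0, bj = 0;
    int *Hp = Hrow.data();
    int *Fp = Frow.data();
    for (int i = 1; i <= m; ++i) {
      const int *Srow = &S[qi[i - 1] * nalpha];
      unsigned char *drow = &dir[(size_t)i * (n + 1)];
      int Hdiag = Hp[0];  // H[i-1][j-1]
      int Hleft = 0;      // H[i][j-1]
      int E = NEG_INF;    // E[i][j-1] running
      for (int j = 1; j <= n; ++j) {
        int f_open = Hp[j] - open1, f_ext = Fp[j] - ge;
        int F = f_open >= f_ext ? f_open : f_ext;
        int e_open = Hleft - open1, e_ext = E - ge;
        E = e_open >= e_ext ? e_open : e_ext;
        int diag = Hdiag + Srow[si[j - 1]];
        unsigned char d = (unsigned char)((e_open >= e_ext ? 0 : 4) |
                                          (f_open >= f_ext ? 0 : 8));
        int H = 0;
        if (diag >= H) { H = diag; d |= 1; }
        if (F > H) { H = F; d = (d & 12) | 2; }
        if (E > H) { H = E; d = (d & 12) | 3; }
        if (H == 0) d &= 12;
        Hdiag = Hp[j];
        Hp[j] = H;  // row i now
        Fp[j] = F;
        Hleft = H;
        drow[j] = d;
        if (H > best) { best = H; bi = i; bj = j; }
      }
    }

    int matches = 0, cols = 0;
    int qe = 0, se = 0, qs = 0, ss = 0;
    if (best > 0) {
      qe = bi; se = bj;
      int i = bi, j = bj;
      int state = 0;  // 0 in H, 2 in F, 3 in E
      while (i > 0 && j > 0) {
        unsigned char d = dir[(size_t)i * (n + 1) + j];
        if (state == 0) {
          unsigned char h = d & 3;
          if (h == 0) break;
          if (h == 1) {
            ++cols;
            if (qi[i - 1] == si[j - 1]) ++matches;
            --i; --j;
          } else {
            state = h;  // 2 -> F, 3 -> E
          }
        } else if (state == 2) {  // vertical gap run (consumes query)
          ++cols;
          bool ext = (d & 8) != 0;
          --i;
          if (!ext) state = 0;
        } else {  // horizontal gap run (consumes subject)
          ++cols;
          bool ext = (d & 4) != 0;
          --j;
          if (!ext) state = 0;
        }
      }
      qs = i + 1; ss = j + 1;
    }
    score[p] = best;
    nmatch[p] = matches;
    hsp_len[p] = cols;
    q_start[p] = qs; q_end[p] = qe;
    s_start[p] = ss; s_end[p] = se;
  }
  return DataFrame::create(_["raw_score"] = score, _["nmatch"] = nmatch,
                           _["hsp_length"] = hsp_len,
                           _["q_start"] = q_start, _["q_end"] = q_end,
                           _["s_start"] = s_start, _["s_end"] = s_end);
}

// Hamming mismatch counts between equal-length string pairs (mapper verify).
// [[Rcpp::export(name = ".hamming_batch")]]
IntegerVector hamming_batch(CharacterVector a, CharacterVector b) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (int p = 0; p < n; ++p) {
    const char *x = CHAR(STRING_ELT(a, p));
    const char *y = CHAR(STRING_ELT(b, p));
    int lx = (int)std::strlen(x), ly = (int)std::strlen(y);
    int L = lx < ly ? lx : ly, mm = lx == ly ? 0 : 1000000;
    for (int i = 0; i < L; ++i) if (x[i] != y[i]) ++mm;
    out[p] = mm;
  }
  return out;
}
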