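// Affine-gap pairwise alignment kernels.
//
// Gap cost convention matches protein-search practice: a gap of length L
// costs gap_open + L * gap_extend (so opening a 1-residue gap costs
// gap_open + gap_extend).  Local alignments never start or end with a gap.
// Tie-break for the optimal local cell: highest score, then smallest
// subject index, then smallest query index; traceback prefers diagonal,
// then a gap in the subject, then a gap in the query.
//
// Scores propagate over rolling rows; one packed direction byte per cell
// (2 bits M origin, 1 bit Ix origin, 1 bit Iy origin) drives traceback.

#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

// residues that never count as identities (ambiguity codes + selenocysteine)
static inline bool ambiguous_residue(char c) {
  return c == 'X' || c == 'B' || c == 'Z' || c == 'U';
}

struct ScoreTable {
  int tab[128][128];
  void build(const IntegerMatrix &m, const CharacterVector &rows,
             const CharacterVector &cols) {
    int xx = 0;
    int n = rows.size(), p = cols.size();
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < p; ++j)
        if (CHAR(STRING_ELT(rows, i))[0] == 'X' &&
            CHAR(STRING_ELT(cols, j))[0] == 'X') xx = m(i, j);
    for (int i = 0; i < 128; ++i)
      for (int j = 0; j < 128; ++j) tab[i][j] = xx;  // unknown chars act as X
    for (int i = 0; i < n; ++i) {
      char a = CHAR(STRING_ELT(rows, i))[0];
      for (int j = 0; j < p; ++j)
        tab[(int)a][(int)CHAR(STRING_ELT(cols, j))[0]] = m(i, j);
    }
  }
};

enum { FROM_M = 0, FROM_IX = 1, FROM_IY = 2, FROM_START = 3 };

struct AlnResult {
  int score, n_identical, qs, qe, ss, se;
  std::string aq, as;
};

// ---------------------------------------------------------------- local ----
static void sw_core(const std::string &q, const std::string &s,
                    const ScoreTable &tab, int gap_open, int gap_ext,
                    bool want_strings, AlnResult &r) {
  const int n = q.size(), m = s.size();
  const int oe = gap_open + gap_ext;
  std::vector<int> Mp(m + 1, 0), Mc(m + 1, 0);
  std::vector<int> Ixp(m + 1, NEG_INF), Ixc(m + 1, NEG_INF);
  std::vector<int> Iyp(m + 1, NEG_INF), Iyc(m + 1, NEG_INF);
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int *srow = tab.tab[(int)(unsigned char)q[i - 1]];
    unsigned char *drow = &dir[(size_t)i * (m + 1)];
    Mc[0] = 0; Ixc[0] = NEG_INF; Iyc[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      unsigned char d = 0;
      int openx = Mp[j] - oe, extx = Ixp[j] - gap_ext;
      int ix;
      if (openx >= extx) ix = openx; else { ix = extx; d |= 4; }
      int openy = Mc[j - 1] - oe, exty = Iyc[j - 1] - gap_ext;
      int iy;
      if (openy >= exty) iy = openy; else { iy = exty; d |= 8; }
      int bestprev = Mp[j - 1]; unsigned char from = FROM_M;
      if (Ixp[j - 1] > bestprev) { bestprev = Ixp[j - 1]; from = FROM_IX; }
      if (Iyp[j - 1] > bestprev) { bestprev = Iyp[j - 1]; from = FROM_IY; }
      if (bestprev < 0) { bestprev = 0; from = FROM_START; }
      int mm = bestprev + srow[(int)(unsigned char)s[j - 1]];
      if (mm < 0) { mm = 0; from = FROM_START; }
      Mc[j] = mm; Ixc[j] = ix; Iyc[j] = iy;
      drow[j] = d | from;
      if (mm > best) { best = mm; bi = i; bj = j; }
      else if (mm == best && best > 0 && (j < bj || (j == bj && i < bi))) {
        bi = i; bj = j;
      }
    }
    std::swap(Mp, Mc); std::swap(Ixp, Ixc); std::swap(Iyp, Iyc);
  }
  r.score = best; r.n_identical = 0; r.qs = r.qe = r.ss = r.se = 0;
  r.aq.clear(); r.as.clear();
  if (best > 0) {
    int i = bi, j = bj, st = FROM_M;
    r.qe = bi; r.se = bj;
    while (i > 0 && j > 0) {
      unsigned char d = dir[(size_t)i * (m + 1) + j];
      if (st == FROM_M) {
        char a = q[i - 1], b = s[j - 1];
        if (want_strings) { r.aq.push_back(a); r.as.push_back(b); }
        if (a == b && !ambiguous_residue(a)) ++r.n_identical;
        r.qs = i; r.ss = j;
        unsigned char from = d & 3;
        --i; --j;
        if (from == FROM_START) break;
        st = from;
      } else if (st == FROM_IX) {
        if (want_strings) { r.aq.push_back(q[i - 1]); r.as.push_back('-'); }
        st = (d & 4) ? FROM_IX : FROM_M;
        --i;
      } else {
        if (want_strings) { r.aq.push_back('-'); r.as.push_back(s[j - 1]); }
        st = (d & 8) ? FROM_IY : FROM_M;
        --j;
      }
    }
    if (want_strings) {
      std::reverse(r.aq.begin(), r.aq.end());
      std::reverse(r.as.begin(), r.as.end());
    }
  }
}

// [[Rcpp::export]]
List cpp_align_local(std::string query, std::string subject,
                     IntegerMatrix score_matrix, CharacterVector row_letters,
                     CharacterVector col_letters, int gap_open, int gap_ext,
                     bool want_strings = true) {
  ScoreTable tab;
  tab.build(score_matrix, row_letters, col_letters);
  AlnResult r;
  sw_core(query, subject, tab, gap_open, gap_ext, want_strings, r);
  return List::create(_["score"] = r.score, _["n_identical"] = r.n_identical,
                      _["query_start"] = r.qs, _["query_end"] = r.qe,
                      _["subject_start"] = r.ss, _["subject_end"] = r.se,
                      _["aligned_query"] = r.aq,
                      _["aligned_subject"] = r.as);
}

// [[Rcpp::export]]
DataFrame cpp_align_local_batch(std::string query, CharacterVector subjects,
                                IntegerMatrix score_matrix,
                                CharacterVector row_letters,
                                CharacterVector col_letters, int gap_open,
                                int gap_ext) {
  ScoreTable tab;
  tab.build(score_matrix, row_letters, col_letters);
  int k = subjects.size();
  IntegerVector score(k), nid(k), qs(k), qe(k), ss(k), se(k);
  AlnResult r;
  for (int t = 0; t < k; ++t) {
    std::string s = as<std::string>(subjects[t]);
    sw_core(query, s, tab, gap_open, gap_ext, false, r);
    score[t] = r.score; nid[t] = r.n_identical;
    qs[t] = r.qs; qe[t] = r.qe; ss[t] = r.ss; se[t] = r.se;
  }
  return DataFrame::create(_["score"] = score, _["n_identical"] = nid,
                           _["query_start"] = qs, _["query_end"] = qe,
                           _["subject_start"] = ss, _["subject_end"] = se,
                           _["stringsAsFactors"] = false);
}

// -------------------------------------------------------------- overlap ----
// Global alignment of reference vs subject with free end gaps on both
// sequences.  Returns, for every reference position, the aligned subject
// position (0 = aligned to a gap / outside the aligned region).
// [[Rcpp::export]]
List cpp_align_overlap(std::string ref, std::string subject,
                       IntegerMatrix score_matrix, CharacterVector row_letters,
                       CharacterVector col_letters, int gap_open, int gap_ext) {
  ScoreTable tab;
  tab.build(score_matrix, row_letters, col_letters);
  const int n = ref.size(), m = subject.size();
  const int oe = gap_open + gap_ext;
  std::vector<int> Mp(m + 1, NEG_INF), Mc(m + 1, NEG_INF);
  std::vector<int> Ixp(m + 1, NEG_INF), Ixc(m + 1, NEG_INF);
  std::vector<int> Iyp(m + 1, NEG_INF), Iyc(m + 1, NEG_INF);
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> lastColM(n + 1, NEG_INF);
  for (int i = 1; i <= n; ++i) {
    const int *srow = tab.tab[(int)(unsigned char)ref[i - 1]];
    unsigned char *drow = &dir[(size_t)i * (m + 1)];
    Mc[0] = NEG_INF; Ixc[0] = NEG_INF; Iyc[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      unsigned char d = 0;
      int openx = Mp[j] - oe, extx = Ixp[j] - gap_ext;
      int ix;
      if (openx >= extx) ix = openx; else { ix = extx; d |= 4; }
      int openy = Mc[j - 1] - oe, exty = Iyc[j - 1] - gap_ext;
      int iy;
      if (openy >= exty) iy = openy; else { iy = exty; d |= 8; }
      int bestprev = Mp[j - 1]; unsigned char from = FROM_M;
      if (Ixp[j - 1] > bestprev) { bestprev = Ixp[j - 1]; from = FROM_IX; }
      if (Iyp[j - 1] > bestprev) { bestprev = Iyp[j - 1]; from = FROM_IY; }
      if ((i == 1 || j == 1) && 0 > bestprev) {
        bestprev = 0; from = FROM_START;   // free leading end gaps
      }
      Mc[j] = bestprev + srow[(int)(unsigned char)subject[j - 1]];
      Ixc[j] = ix; Iyc[j] = iy;
      drow[j] = d | from;
    }
    lastColM[i] = Mc[m];
    std::swap(Mp, Mc); std::swap(Ixp, Ixc); std::swap(Iyp, Iyc);
  }
  // after the swap, Mp holds row n
  int best = NEG_INF, bi = 0, bj = 0;
  for (int j = 1; j <= m; ++j)
    if (Mp[j] > best) { best = Mp[j]; bi = n; bj = j; }
  for (int i = 1; i <= n; ++i)
    if (lastColM[i] > best) { best = lastColM[i]; bi = i; bj = m; }
  IntegerVector map(n, 0);
  int n_ident = 0, n_aligned = 0;
  std::string aq, as;
  if (n > 0 && m > 0 && best > NEG_INF) {
    int i = bi, j = bj, st = FROM_M;
    while (i > 0 && j > 0) {
      unsigned char d = dir[(size_t)i * (m + 1) + j];
      if (st == FROM_M) {
        char a = ref[i - 1], b = subject[j - 1];
        aq.push_back(a); as.push_back(b);
        map[i - 1] = j;
        ++n_aligned;
        if (a == b && !ambiguous_residue(a)) ++n_ident;
        unsigned char from = d & 3;
        --i; --j;
        if (from == FROM_START) break;
        st = from;
      } else if (st == FROM_IX) {
        aq.push_back(ref[i - 1]); as.push_back('-');
        st = (d & 4) ? FROM_IX : FROM_M;
        --i;
      } else {
        aq.push_back('-'); as.push_back(subject[j - 1]);
        st = (d & 8) ? FROM_IY : FROM_M;
        --j;
      }
    }
    std::reverse(aq.begin(), aq.end());
    std::reverse(as.begin(), as.end());
  }
  return List::create(_["score"] = (n > 0 && m > 0) ? best : 0,
                      _["map"] = map, _["n_identical"] = n_ident,
                      _["n_aligned"] = n_aligned, _["aligned_ref"] = aq,
                      _["aligned_subject"] = as);
}
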