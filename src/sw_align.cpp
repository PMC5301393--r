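#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Affine-gap Smith-Waterman with BLAST-style gap costs: a gap of length L
// costs gap_open + L * gap_extend. Three-state DP (M = aligned pair,
// X = gap in b / consumes a, Y = gap in a / consumes b).
//
// Tie-breaks are fixed so that an independent re-implementation can agree
// exactly: the best cell is the first maximum in row-major order (i outer,
// j inner), the predecessor of an M cell prefers M, then X, then Y, and a
// fresh start is taken only when max(M, X, Y) < 0; X prefers opening from M
// over extending, as does Y.

struct SwStats {
  double score;
  int matches, columns, alen_a, alen_b, mismatches, gap_opens;
  int a_start, a_end, b_start, b_end; // 1-based inclusive
  bool traced;
};

static const double NEG_INF = -1e30;

// score-only pass: tight rolling-row DP without traceback bookkeeping
static double sw_score_only(const std::vector<int>& a, const std::vector<int>& b,
                            const double* subflat, int nalpha,
                            double go, double ge) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<double> Mprev(m + 1, 0.0), Xprev(m + 1, NEG_INF),
      Yprev(m + 1, NEG_INF);
  std::vector<double> Mrow(m + 1, 0.0), Xrow(m + 1, NEG_INF),
      Yrow(m + 1, NEG_INF);
  double best = 0.0;
  const double goe = go + ge;
  const int* bp = b.data();
  for (int i = 1; i <= n; ++i) {
    const double* srow = subflat + (size_t)a[i - 1] * nalpha;
    Mrow[0] = 0.0; Xrow[0] = NEG_INF; Yrow[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double xv = std::max(Mprev[j] - goe, Xprev[j] - ge);
      double yv = std::max(Mrow[j - 1] - goe, Yrow[j - 1] - ge);
      double pred = std::max(std::max(Mprev[j - 1], Xprev[j - 1]),
                             std::max(Yprev[j - 1], 0.0));
      double mv = srow[bp[j - 1]] + pred;
      Mrow[j] = mv; Xrow[j] = xv; Yrow[j] = yv;
      if (mv > best) best = mv;
    }
    std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev);
  }
  return best;
}

static SwStats sw_one(const std::vector<int>& a, const std::vector<int>& b,
                      const NumericMatrix& sub, double go, double ge,
                      bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  SwStats st;
  st.score = 0.0;
  st.matches = st.columns = st.alen_a = st.alen_b = 0;
  st.mismatches = st.gap_opens = 0;
  st.a_start = st.a_end = st.b_start = st.b_end = 0;
  st.traced = traceback;

  std::vector<double> Mrow(m + 1, 0.0), Xrow(m + 1, NEG_INF), Yrow(m + 1, NEG_INF);
  std::vector<double> Mprev(m + 1, 0.0), Xprev(m + 1, NEG_INF), Yprev(m + 1, NEG_INF);

  // traceback pointers: pM in {0 fresh, 1 M, 2 X, 3 Y}; pX/pY in {1 from M, 2 extend}
  std::vector<unsigned char> pM, pX, pY;
  if (traceback) {
    pM.assign((size_t)(n + 1) * (m + 1), 0);
    pX.assign((size_t)(n + 1) * (m + 1), 0);
    pY.assign((size_t)(n + 1) * (m + 1), 0);
  }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    Mrow[0] = 0.0; Xrow[0] = NEG_INF; Yrow[0] = NEG_INF;
    const double* subrow = &sub(a[i - 1], 0);
    for (int j = 1; j <= m; ++j) {
      // X: gap in b (consume a): come from row i-1, same j
      double openX = Mprev[j] - go - ge;
      double extX  = Xprev[j] - ge;
      double xv; unsigned char xp;
      if (openX >= extX) { xv = openX; xp = 1; } else { xv = extX; xp = 2; }
      Xrow[j] = xv;

      // Y: gap in a (consume b): come from same row, j-1
      double openY = Mrow[j - 1] - go - ge;
      double extY  = Yrow[j - 1] - ge;
      double yv; unsigned char yp;
      if (openY >= extY) { yv = openY; yp = 1; } else { yv = extY; yp = 2; }
      Yrow[j] = yv;

      // M: aligned pair
      double s = subrow[(size_t)b[j - 1] * sub.nrow()];
      double mp = Mprev[j - 1], xpv = Xprev[j - 1], ypv = Yprev[j - 1];
      double pred = mp; unsigned char mptr = 1;
      if (xpv > pred) { pred = xpv; mptr = 2; }
      if (ypv > pred) { pred = ypv; mptr = 3; }
      if (pred < 0) { pred = 0.0; mptr = 0; }
      double mv = s + pred;
      Mrow[j] = mv;

      if (traceback) {
        size_t off = (size_t)i * (m + 1) + j;
        pM[off] = mptr; pX[off] = xp; pY[off] = yp;
      }
      if (mv > best) { best = mv; bi = i; bj = j; }
    }
    std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev);
  }

  st.score = best;
  if (!traceback || best <= 0.0) return st;

  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 1; // 1=M, 2=X, 3=Y
  st.a_end = bi; st.b_end = bj;
  while (i > 0 && j > 0) {
    size_t off = (size_t)i * (m + 1) + j;
    if (state == 1) {
      st.columns++; st.alen_a++; st.alen_b++;
      if (a[i - 1] == b[j - 1]) st.matches++; else st.mismatches++;
      st.a_start = i; st.b_start = j;
      unsigned char p = pM[off];
      i--; j--;
      if (p == 0) break;
      state = p;
    } else if (state == 2) { // X: consumes a
      st.columns++; st.alen_a++;
      unsigned char p = pX[off];
      i--;
      if (p == 1) { st.gap_opens++; state = 1; }
    } else { // Y: consumes b
      st.columns++; st.alen_b++;
      unsigned char p = pY[off];
      j--;
      if (p == 1) { st.gap_opens++; state = 1; }
    }
  }
  return st;
}

static std::vector<int> encode_seq(const char* s, const std::vector<int>& lut) {
  size_t n = std::strlen(s);
  std::vector<int> v(n);
  for (size_t k = 0; k < n; ++k) {
    int code = lut[(unsigned char)s[k]];
    if (code < 0)
      stop("residue '%c' not present in the substitution matrix alphabet", s[k]);
    v[k] = code;
  }
  return v;
}

// [[Rcpp::export]]
DataFrame sw_align_batch(CharacterVector seqs, IntegerMatrix pairs,
                         NumericMatrix submat, std::string alphabet,
                         double gap_open, double gap_extend,
                         NumericVector min_score) {
  const int np = pairs.nrow();
  if (min_score.size() != np && min_score.size() != 1)
    stop("min_score must have length 1 or nrow(pairs)");

  std::vector<int> lut(256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k)
    lut[(unsigned char)alphabet[k]] = (int)k;

  std::vector<std::vector<int> > enc(seqs.size());
  for (int k = 0; k < seqs.size(); ++k)
    enc[k] = encode_seq(CHAR(STRING_ELT(seqs, k)), lut);

  const int nalpha = submat.nrow();
  std::vector<double> subflat((size_t)nalpha * nalpha);
  for (int r = 0; r < nalpha; ++r)
    for (int c = 0; c < nalpha; ++c)
      subflat[(size_t)r * nalpha + c] = submat(r, c);

  NumericVector score(np);
  IntegerVector matches(np, NA_INTEGER), columns(np, NA_INTEGER),
      alen_a(np, NA_INTEGER), alen_b(np, NA_INTEGER),
      mism(np, NA_INTEGER), gopen(np, NA_INTEGER),
      a_start(np, NA_INTEGER), a_end(np, NA_INTEGER),
      b_start(np, NA_INTEGER), b_end(np, NA_INTEGER);

  for (int p = 0; p < np; ++p) {
    int ia = pairs(p, 0) - 1, ib = pairs(p, 1) - 1;
    if (ia < 0 || ib < 0 || ia >= (int)enc.size() || ib >= (int)enc.size())
      stop("pair index out of range");
    double ms = min_score.size() == 1 ? min_score[0] : min_score[p];
    double sc = sw_score_only(enc[ia], enc[ib], subflat.data(), nalpha,
                              gap_open, gap_extend);
    score[p] = sc;
    if (sc >= ms && sc > 0) {
      SwStats st = sw_one(enc[ia], enc[ib], submat, gap_open, gap_extend, true);
      matches[p] = st.matches; columns[p] = st.columns;
      alen_a[p] = st.alen_a; alen_b[p] = st.alen_b;
      mism[p] = st.mismatches; gopen[p] = st.gap_opens;
      a_start[p] = st.a_start; a_end[p] = st.a_end;
      b_start[p] = st.b_start; b_end[p] = st.b_end;
    }
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(
      _["score"] = score, _["matches"] = matches, _["columns"] = columns,
      _["alen_a"] = alen_a, _["alen_b"] = alen_b, _["mismatches"] = mism,
      _["gap_opens"] = gopen, _["a_start"] = a_start, _["a_end"] = a_end,
      _["b_start"] = b_start, _["b_end"] = b_end);
}
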