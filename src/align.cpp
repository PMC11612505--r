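#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman). Convention: the first base of a
// gap costs gap_open + gap_extend, each further base gap_extend. 'N' never
// matches anything (scored as a mismatch).

static inline int subst(char a, char b, int m, int mm) {
  if (a == 'N' || b == 'N') return mm;
  return (a == b) ? m : mm;
}

struct AlnCoord {
  int score, qs, qe, ts, te;
};

// Full DP with traceback over query q (rows) and target t (cols).
// Returns optimal local alignment; among score ties prefers the smallest
// (ref_start, query_start, ref_end, query_end), examining up to 64 tied ends.
static AlnCoord local_align_core(const char *q, int n, const char *t, int m,
                                 int sm, int smm, int go, int ge) {
  const int NEG = -1000000000;
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> E((size_t)(n + 1) * (m + 1), NEG);
  std::vector<int> F((size_t)(n + 1) * (m + 1), NEG);
  // traceback codes for H: 0 stop, 1 diag, 2 from F (gap in target/up), 3 from E (gap in query/left)
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = opened (from H), 0 = extended
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);

  int best = 0;
  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      int eo = H[row + j - 1] + go + ge, ee = E[row + j - 1] + ge;
      if (eo >= ee) { E[row + j] = eo; tbE[row + j] = 1; } else { E[row + j] = ee; tbE[row + j] = 0; }
      int fo = H[prow + j] + go + ge, fe = F[prow + j] + ge;
      if (fo >= fe) { F[row + j] = fo; tbF[row + j] = 1; } else { F[row + j] = fe; tbF[row + j] = 0; }
      int diag = H[prow + j - 1] + subst(q[i - 1], t[j - 1], sm, smm);
      int h = 0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (F[row + j] > h) { h = F[row + j]; tb = 2; }
      if (E[row + j] > h) { h = E[row + j]; tb = 3; }
      H[row + j] = h; tbH[row + j] = tb;
      if (h > best) best = h;
    }
  }
  AlnCoord res; res.score = best; res.qs = res.qe = res.ts = res.te = 0;
  if (best == 0) return res;

  bool have = false;
  AlnCoord chosen; chosen.score = best;
  int seen = 0;
  for (int j = 1; j <= m && seen < 64; ++j) {
    for (int i = 1; i <= n && seen < 64; ++i) {
      if (H[(size_t)i * (m + 1) + j] != best) continue;
      ++seen;
      // traceback
      int ci = i, cj = j;
      int state = 0; // 0 = in H, 1 = in E, 2 = in F
      while (true) {
        size_t idx = (size_t)ci * (m + 1) + cj;
        if (state == 0) {
          unsigned char tb = tbH[idx];
          if (tb == 0) break;
          if (tb == 1) { --ci; --cj; }
          else if (tb == 2) state = 2;
          else state = 1;
        } else if (state == 1) {
          unsigned char tb = tbE[idx];
          --cj;
          if (tb == 1) state = 0;
        } else {
          unsigned char tb = tbF[idx];
          --ci;
          if (tb == 1) state = 0;
        }
      }
      AlnCoord cand; cand.score = best;
      cand.qs = ci; cand.qe = i; cand.ts = cj; cand.te = j;
      if (!have ||
          cand.ts < chosen.ts ||
          (cand.ts == chosen.ts && (cand.qs < chosen.qs ||
          (cand.qs == chosen.qs && (cand.te < chosen.te ||
          (cand.te == chosen.te && cand.qe < chosen.qe)))))) {
        chosen = cand; have = true;
      }
    }
  }
  return chosen;
}

// [[Rcpp::export]]
IntegerVector cpp_local_align(std::string query, std::string target,
                              int match, int mismatch, int gap_open, int gap_extend) {
  AlnCoord a = local_align_core(query.c_str(), (int)query.size(),
                                target.c_str(), (int)target.size(),
                                match, mismatch, gap_open, gap_extend);
  return IntegerVector::create(a.score, a.qs, a.qe, a.ts, a.te);
}

// Best local alignment score of every query prefix q[1..i] against the target,
// in one DP pass: a prefix alignment is any local alignment ending at a query
// row <= i, so out[i] is the running maximum of row maxima.
// [[Rcpp::export]]
IntegerVector cpp_prefix_best(std::string query, std::string target,
                              int match, int mismatch, int gap_open, int gap_extend) {
  int n = (int)query.size(), m = (int)target.size();
  const char *q = query.c_str(), *t = target.c_str();
  const int NEG = -1000000000;
  std::vector<int> H(m + 1, 0), E(m + 1, NEG), Hp(m + 1, 0), F(m + 1, NEG);
  IntegerVector out(n);
  int run = 0;
  for (int i = 1; i <= n; ++i) {
    std::swap(H, Hp);
    H[0] = 0; E[0] = NEG;
    int rowmax = 0;
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[j - 1] + gap_open + gap_extend, E[j - 1] + gap_extend);
      E[j] = e;
      int f = std::max(Hp[j] + gap_open + gap_extend, F[j] + gap_extend);
      F[j] = f;
      int h = Hp[j - 1] + subst(q[i - 1], t[j - 1], match, mismatch);
      if (h < 0) h = 0;
      if (f > h) h = f;
      if (e > h) h = e;
      H[j] = h;
      if (h > rowmax) rowmax = h;
    }
    if (rowmax > run) run = rowmax;
    out[i - 1] = run;
  }
  return out;
}

// Per-read differences with the reference: mismatched aligned bases plus the
// number of indel events (an indel of any length counts 1). pos is 0-based.
// Returns -1 for a read whose cigar walks outside the reference.
// [[Rcpp::export]]
IntegerVector cpp_count_differences(IntegerVector pos, CharacterVector cigar,
                                    CharacterVector seq, std::string ref) {
  int nr = pos.size();
  int reflen = (int)ref.size();
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) {
    const char *cg = CHAR(STRING_ELT(cigar, r));
    const char *sq = CHAR(STRING_ELT(seq, r));
    int qi = 0, ti = pos[r], diffs = 0;
    bool bad = (ti < 0);
    int len = 0;
    for (const char *p = cg; *p && !bad; ++p) {
      char c = *p;
      if (c >= '0' && c <= '9') { len = len * 10 + (c - '0'); continue; }
      switch (c) {
      case 'M': case '=': case 'X':
        if (ti + len > reflen) { bad = true; break; }
        for (int k = 0; k < len; ++k) {
          char a = sq[qi + k], b = ref[ti + k];
          if (a == 'N' || b == 'N' || a != b) ++diffs;
        }
        qi += len; ti += len; break;
      case 'I': ++diffs; qi += len; break;
      case 'D': ++diffs; ti += len; if (ti > reflen) bad = true; break;
      case 'S': qi += len; break;
      case 'H': break;
      default: bad = true;
      }
      len = 0;
    }
    out[r] = bad ? -1 : diffs;
  }
  return out;
}

// Per-cigar summary: reference span, query length consumed, left clip, right clip.
// [[Rcpp::export]]
IntegerMatrix cpp_cigar_stats(CharacterVector cigar) {
  int nr = cigar.size();
  IntegerMatrix out(nr, 4);
  for (int r = 0; r < nr; ++r) {
    const char *cg = CHAR(STRING_ELT(cigar, r));
    int refspan = 0, qlen = 0, lclip = 0, rclip = 0, len = 0;
    bool first = true;
    int lastclip = 0;
    for (const char *p = cg; *p; ++p) {
      char c = *p;
      if (c >= '0' && c <= '9') { len = len * 10 + (c - '0'); continue; }
      if (c == 'M' || c == '=' || c == 'X') { refspan += len; qlen += len; first = false; lastclip = 0; }
      else if (c == 'I') { qlen += len; first = false; lastclip = 0; }
      else if (c == 'D') { refspan += len; first = false; lastclip = 0; }
      else if (c == 'S' || c == 'H') {
        if (first) lclip += len; else lastclip += len;
        if (c == 'S') qlen += len;
        first = false;
      }
      len = 0;
    }
    rclip = lastclip;
    out(r, 0) = refspan; out(r, 1) = qlen; out(r, 2) = lclip; out(r, 3) = rclip;
  }
  return out;
}

// Hamming distance between equal-length strings ('N' counts as mismatch).
// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  int n = (int)std::min(a.size(), b.size());
  int d = (int)std::max(a.size(), b.size()) - n;
  for (int i = 0; i < n; ++i)
    if (a[i] == 'N' || b[i] == 'N' || a[i] != b[i]) ++d;
  return d;
}

// Plurality consensus of sequences placed at integer offsets (0-based) within a
// common window. Ties broken by A < C < G < T < N. Returns the consensus over
// the covered span (assumed contiguous).
// [[Rcpp::export]]
List cpp_pileup_consensus(CharacterVector seqs, IntegerVector offsets) {
  int nr = seqs.size();
  int lo = 1 << 30, hi = 0;
  for (int r = 0; r < nr; ++r) {
    int o = offsets[r], l = (int)std::strlen(CHAR(STRING_ELT(seqs, r)));
    if (o < lo) lo = o;
    if (o + l > hi) hi = o + l;
  }
  if (nr == 0 || hi <= lo) return List::create(_["seq"] = "", _["start"] = 0);
  int w = hi - lo;
  std::vector<int> cnt((size_t)w * 5, 0);
  const char bases[5] = {'A', 'C', 'G', 'T', 'N'};
  for (int r = 0; r < nr; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int o = offsets[r] - lo, l = (int)std::strlen(s);
    for (int k = 0; k < l; ++k) {
      int b;
      switch (s[k]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: b = 4;
      }
      ++cnt[(size_t)(o + k) * 5 + b];
    }
  }
  std::string cons(w, 'N');
  int covlo = -1, covhi = -1;
  for (int k = 0; k < w; ++k) {
    int bi = -1, bc = 0;
    for (int b = 0; b < 5; ++b) {
      int c = cnt[(size_t)k * 5 + b];
      if (c > bc) { bc = c; bi = b; }
    }
    if (bi >= 0) {
      cons[k] = bases[bi];
      if (covlo < 0) covlo = k;
      covhi = k;
    }
  }
  if (covlo < 0) return List::create(_["seq"] = "", _["start"] = 0);
  return List::create(_["seq"] = cons.substr(covlo, covhi - covlo + 1),
                      _["start"] = lo + covlo);
}

// Best suffix(a)-prefix(b) overlap of length >= min_len with identity >= min_id.
// Score per overlap = matches - 5*mismatches; returns c(len, mismatches) or c(0, 0).
// [[Rcpp::export]]
IntegerVector cpp_best_overlap(std::string a, std::string b, int min_len, double min_id) {
  int la = (int)a.size(), lb = (int)b.size();
  int maxo = std::min(la, lb);
  int bestlen = 0, bestmm = 0, bestscore = -1000000000;
  for (int o = min_len; o <= maxo; ++o) {
    int mm = 0;
    const char *pa = a.c_str() + (la - o), *pb = b.c_str();
    for (int k = 0; k < o; ++k)
      if (pa[k] == 'N' || pb[k] == 'N' || pa[k] != pb[k]) ++mm;
    if ((double)(o - mm) / o < min_id) continue;
    int score = (o - mm) - 5 * mm;
    if (score > bestscore) { bestscore = score; bestlen = o; bestmm = mm; }
  }
  return IntegerVector::create(bestlen, bestmm);
}
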