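#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;

// Symbol codes used throughout: $=0 A=1 C=2 G=3 N=4 T=5 (ASCII order, so the
// generic byte-level suffix array and the coded DNA alphabet sort alike).

// ---------------------------------------------------------------------------
// Suffix array by prefix doubling, O(n log^2 n).  Adequate for the desk-scale
// references this package targets (the R layer enforces a capacity guard).
static std::vector<int> sa_prefix_doubling(const std::vector<int>& s) {
  const int n = (int)s.size();
  std::vector<int> sa(n), rk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rk[i] = s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rk[a] != rk[b]) return rk[a] < rk[b];
      const int ra = a + k < n ? rk[a + k] : -1;
      const int rb = b + k < n ? rk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rk = tmp;
    if (rk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// [[Rcpp::export]]
IntegerVector sa_build_cpp(RawVector text) {
  const int n = text.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = (int)text[i];
  std::vector<int> sa = sa_prefix_doubling(s);
  return IntegerVector(sa.begin(), sa.end());  // 0-based positions
}

// bwt[i] = text[sa[i] - 1], wrapping so that row of the terminator picks up
// the last character.
// [[Rcpp::export]]
RawVector bwt_from_sa_cpp(RawVector text, IntegerVector sa) {
  const int n = text.size();
  if (sa.size() != n) stop("text and suffix array lengths differ");
  RawVector b(n);
  for (int i = 0; i < n; ++i) {
    const int p = sa[i];
    if (p < 0 || p >= n) stop("suffix array entry out of range");
    b[i] = text[p == 0 ? n - 1 : p - 1];
  }
  return b;
}

// Checkpointed rank: row r holds, per symbol, its count in bwt[0 .. r*step).
// [[Rcpp::export]]
IntegerMatrix occ_build_cpp(IntegerVector bwt, int nsym, int step) {
  const int n = bwt.size();
  const int rows = n / step + 1;
  IntegerMatrix ck(rows, nsym);
  std::vector<int> cur(nsym, 0);
  for (int i = 0; i < n; ++i) {
    if (i % step == 0)
      for (int c = 0; c < nsym; ++c) ck(i / step, c) = cur[c];
    const int b = bwt[i];
    if (b < 0 || b >= nsym) stop("BWT symbol code out of range");
    cur[b]++;
  }
  if (n % step == 0)
    for (int c = 0; c < nsym; ++c) ck(n / step, c) = cur[c];
  return ck;
}

struct FM {
  const int* bwt;
  const int* ck;  // column-major, rows x nsym
  int rows, step, nsym, n;
  const int* counts;  // per symbol: number of text characters strictly smaller

  inline int rank(int c, int i) const {
    const int r = i / step;
    int cnt = ck[(size_t)c * rows + r];
    for (int j = r * step; j < i; ++j)
      if (bwt[j] == c) ++cnt;
    return cnt;
  }
  // Backward-search interval update; returns false when the interval empties.
  inline bool extend(int c, int& l, int& r) const {
    l = counts[c] + rank(c, l);
    r = counts[c] + rank(c, r);
    return l < r;
  }
};

static FM make_fm(const IntegerVector& bwt, const IntegerMatrix& ck, int step,
                  const IntegerVector& counts) {
  FM f;
  f.bwt = INTEGER(bwt);
  f.ck = INTEGER(ck);
  f.rows = ck.nrow();
  f.step = step;
  f.nsym = ck.ncol();
  f.n = bwt.size();
  f.counts = INTEGER(counts);
  return f;
}

static int count_exact(const FM& f, const std::vector<int>& pat) {
  int l = 0, r = f.n;
  for (int i = (int)pat.size() - 1; i >= 0; --i) {
    const int c = pat[i];
    if (c < 0 || c >= f.nsym) return 0;
    if (!f.extend(c, l, r)) return 0;
  }
  return r - l;
}

// [[Rcpp::export]]
int bs_count_cpp(IntegerVector bwt, IntegerMatrix ck, int step,
                 IntegerVector counts, IntegerVector pat) {
  const FM f = make_fm(bwt, ck, step, counts);
  std::vector<int> p(pat.begin(), pat.end());
  return count_exact(f, p);
}

static const int SUBS[4] = {1, 2, 3, 5};  // A, C, G, T

// One orientation: record whether an exact occurrence exists and (optionally)
// every position at which a single ACGT substitution yields an occurrence.
// N in the reference never matches because substitutions range over ACGT only.
static void scan_strand(const FM& f, const std::vector<int>& pat, bool branch,
                        bool& exact, std::set<int>& mism) {
  const int m = (int)pat.size();
  std::vector<int> L(m + 1, 0), R(m + 1, 0);
  L[m] = 0;
  R[m] = f.n;
  for (int j = m - 1; j >= 0; --j) {  // intervals of pat[j..m-1] matched exactly
    int l = L[j + 1], r = R[j + 1];
    if (l < r)
      f.extend(pat[j], l, r);
    else {
      l = 0;
      r = 0;
    }
    L[j] = l;
    R[j] = r;
  }
  if (L[0] < R[0]) exact = true;
  if (!branch) return;
  for (int j = 0; j < m; ++j) {
    if (L[j + 1] >= R[j + 1]) continue;  // suffix right of j already absent
    if (mism.count(j)) continue;
    for (int ci = 0; ci < 4; ++ci) {
      const int c = SUBS[ci];
      if (c == pat[j]) continue;
      int l = L[j + 1], r = R[j + 1];
      if (!f.extend(c, l, r)) continue;
      bool ok = true;
      for (int i = j - 1; i >= 0; --i)
        if (!f.extend(pat[i], l, r)) {
          ok = false;
          break;
        }
      if (ok) {
        mism.insert(j);
        break;  // one witness per position suffices
      }
    }
  }
}

static inline int rc_code(int c) {
  switch (c) {
    case 1: return 5;
    case 5: return 1;
    case 2: return 3;
    case 3: return 2;
    default: return c;
  }
}

// Membership with up to `maxmm` (0 or 1) substitutions, optionally on both
// strands.  `mism` comes back in the ORIGINAL k-mer's coordinates.
static void membership_full(const FM& f, const std::vector<int>& pat, int maxmm,
                            bool both, bool& valid, bool& found, bool& exact,
                            std::set<int>& mism) {
  const int m = (int)pat.size();
  valid = true;
  found = exact = false;
  mism.clear();
  for (int i = 0; i < m; ++i)
    if (pat[i] != 1 && pat[i] != 2 && pat[i] != 3 && pat[i] != 5) {
      valid = false;
      return;
    }
  std::vector<int> rc(m);
  for (int i = 0; i < m; ++i) rc[i] = rc_code(pat[m - 1 - i]);

  // Pass 1: exact only.  An exact hit is the minimum-distance qualifying
  // occurrence, so no substitution branching is needed.
  std::set<int> dummy;
  scan_strand(f, pat, false, exact, dummy);
  if (!exact && both) scan_strand(f, rc, false, exact, dummy);
  if (exact) {
    found = true;
    return;
  }
  if (maxmm > 0) {
    bool e2 = false;
    scan_strand(f, pat, true, e2, mism);
    if (both) {
      std::set<int> m2;
      scan_strand(f, rc, true, e2, m2);
      for (std::set<int>::iterator it = m2.begin(); it != m2.end(); ++it)
        mism.insert(m - 1 - *it);  // mirror back to original coordinates
    }
  }
  found = !mism.empty();
}

// Concordant positions: union, over all minimum-distance qualifying
// occurrences, of the positions matched without substitution.  With an exact
// hit that is every position; with only 1-mismatch hits each occurrence
// contributes all positions but its single substituted one, so a position is
// excluded only when every occurrence substitutes at the same place.
static IntegerVector concordant_from(int m, bool found, bool exact,
                                     const std::set<int>& mism) {
  if (!found) return IntegerVector(0);
  if (exact || mism.size() > 1) {
    IntegerVector all(m);
    for (int i = 0; i < m; ++i) all[i] = i;
    return all;
  }
  const int excl = *mism.begin();
  IntegerVector out(m - 1);
  int j = 0;
  for (int i = 0; i < m; ++i)
    if (i != excl) out[j++] = i;
  return out;
}

// [[Rcpp::export]]
List membership_cpp(IntegerVector bwt, IntegerMatrix ck, int step,
                    IntegerVector counts, IntegerVector pat, int maxmm,
                    bool both) {
  const FM f = make_fm(bwt, ck, step, counts);
  std::vector<int> p(pat.begin(), pat.end());
  bool valid, found, exact;
  std::set<int> mism;
  membership_full(f, p, maxmm, both, valid, found, exact, mism);
  if (!valid)
    return List::create(_["found"] = false, _["exact"] = false,
                        _["concordant"] = IntegerVector(0));
  return List::create(
      _["found"] = found, _["exact"] = exact,
      _["concordant"] = concordant_from((int)p.size(), found, exact, mism));
}

// ---------------------------------------------------------------------------
// Per-read smoothing.  Rule precedence per base:
//   1 fast path (q > HT)  2 low keep (q < LT)  3 uncovered keep
//   4 smooth (all covering queried k-mers found & position concordant)
//   5 discordant keep.
// Label codes returned: 1..5 in that order.
// [[Rcpp::export]]
List smooth_reads_cpp(IntegerVector bwt, IntegerMatrix ck, int step,
                      IntegerVector counts, CharacterVector seqs,
                      CharacterVector quals, int k, int maxmm, bool both,
                      int lt, int ht, int repl, int offset, bool want_labels) {
  const FM f = make_fm(bwt, ck, step, counts);
  int code[256];
  std::fill(code, code + 256, -1);
  code[(unsigned char)'A'] = code[(unsigned char)'a'] = 1;
  code[(unsigned char)'C'] = code[(unsigned char)'c'] = 2;
  code[(unsigned char)'G'] = code[(unsigned char)'g'] = 3;
  code[(unsigned char)'N'] = code[(unsigned char)'n'] = 4;
  code[(unsigned char)'T'] = code[(unsigned char)'t'] = 5;

  const int nreads = seqs.size();
  if (quals.size() != nreads) stop("sequence and quality vectors differ in length");
  CharacterVector out(nreads);
  List labels(want_labels ? nreads : 0);
  double smoothed = 0, kept_low = 0, kept_disc = 0, kept_unc = 0, fast = 0;
  double kq = 0, ks = 0, kf = 0, total = 0;

  for (int ri = 0; ri < nreads; ++ri) {
    const char* s = CHAR(STRING_ELT(seqs, ri));
    std::string q = Rcpp::as<std::string>(quals[ri]);
    const int n = (int)q.size();
    if ((int)std::char_traits<char>::length(s) != n)
      stop("sequence/quality length mismatch in read %d", ri + 1);
    total += n;
    std::vector<int> bc(n), qv(n);
    for (int i = 0; i < n; ++i) {
      bc[i] = code[(unsigned char)s[i]];
      qv[i] = (int)(unsigned char)q[i] - offset;
    }
    const int W = n - k + 1;  // number of k-mer windows (may be <= 0)
    std::vector<signed char> wst;  // 0 skipped, 1 found, 2 not found
    std::vector<int> wex;          // absolute non-concordant position, or -1
    if (W > 0) {
      wst.assign(W, 0);
      wex.assign(W, -1);
      std::vector<int> bad(n + 1, 0);  // prefix counts of disqualified bases
      for (int i = 0; i < n; ++i)
        bad[i + 1] = bad[i] +
                     ((qv[i] >= lt && (bc[i] == 1 || bc[i] == 2 || bc[i] == 3 ||
                                       bc[i] == 5))
                          ? 0
                          : 1);
      for (int w = 0; w < W; ++w) {
        if (bad[w + k] - bad[w] != 0) {
          ks += 1;
          continue;
        }
        kq += 1;
        std::vector<int> pat(bc.begin() + w, bc.begin() + w + k);
        bool valid, found, exact;
        std::set<int> mism;
        membership_full(f, pat, maxmm, both, valid, found, exact, mism);
        if (valid && found) {
          kf += 1;
          wst[w] = 1;
          if (!exact && mism.size() == 1) wex[w] = w + *mism.begin();
        } else {
          wst[w] = 2;
        }
      }
    }
    std::string outq = q;
    IntegerVector lab(want_labels ? n : 0);
    for (int p = 0; p < n; ++p) {
      int rule;
      if (qv[p] > ht) {
        outq[p] = (char)(repl + offset);
        rule = 1;
        fast += 1;
      } else if (qv[p] < lt) {
        rule = 2;
        kept_low += 1;
      } else {
        int i0 = p - k + 1;
        if (i0 < 0) i0 = 0;
        const int i1 = p < W - 1 ? p : W - 1;
        bool any = false, allok = true;
        for (int w = i0; w <= i1; ++w) {
          if (wst[w] == 0) continue;
          any = true;
          if (wst[w] == 2 || wex[w] == p) {
            allok = false;
            break;
          }
        }
        if (!any) {
          rule = 3;
          kept_unc += 1;
        } else if (allok) {
          outq[p] = (char)(repl + offset);
          rule = 4;
          smoothed += 1;
        } else {
          rule = 5;
          kept_disc += 1;
        }
      }
      if (want_labels) lab[p] = rule;
    }
    out[ri] = outq;
    if (want_labels) labels[ri] = lab;
  }

  return List::create(
      _["quality"] = out,
      _["counters"] = NumericVector::create(
          _["reads_processed"] = (double)nreads, _["bases_total"] = total,
          _["bases_smoothed"] = smoothed,
          _["bases_kept_low_quality"] = kept_low,
          _["bases_kept_discordant"] = kept_disc,
          _["bases_kept_uncovered"] = kept_unc, _["bases_fastpathed"] = fast,
          _["kmers_queried"] = kq, _["kmers_skipped"] = ks,
          _["kmers_found"] = kf),
      _["labels"] = labels);
}
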