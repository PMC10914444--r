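// Alignment core: bounded Levenshtein distance, semi-global (infix) search of a
// wildcard-bearing pattern, variable-region localisation by traceback, and
// whitelist barcode assignment.
//
// Alphabet conventions (enforced at the R level, assumed here):
//   - reads/patterns are uppercase over {A,C,G,T,N}
//   - '?' is the pattern wildcard: substitutes against A/C/G/T/N at cost 0,
//     but indels touching it cost 1 like any other symbol
//   - 'X' is the mask sentinel: it mismatches everything, including itself,
//     so a masked interval can never be re-matched cheaply

#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

static const char SENTINEL = 'X';

// substitution cost with wildcard semantics ('?' only meaningful in pattern)
static inline int wsub(char p, char t) {
  if (p == '?') return t == SENTINEL ? 1 : 0;
  if (p == SENTINEL || t == SENTINEL) return 1;
  return p == t ? 0 : 1;
}

// plain substitution cost: symmetric, no wildcard; sentinel mismatches itself
static inline int psub(char a, char b) {
  if (a == SENTINEL || b == SENTINEL) return 1;
  return a == b ? 0 : 1;
}

static int lev_full(const std::string &a, const std::string &b) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int d = prev[j - 1] + psub(a[i - 1], b[j - 1]);
      int u = prev[j] + 1;
      int l = cur[j - 1] + 1;
      cur[j] = std::min(d, std::min(u, l));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// banded computation; returns -1 when the distance exceeds maxd
static int lev_banded(const std::string &a, const std::string &b, int maxd) {
  const int m = (int)a.size(), n = (int)b.size();
  if (std::abs(m - n) > maxd) return -1;
  const int INF = maxd + 1;
  std::vector<int> prev(n + 1, INF), cur(n + 1, INF);
  for (int j = 0; j <= std::min(n, maxd); ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int lo = std::max(1, i - maxd), hi = std::min(n, i + maxd);
    int rowmin = INF;
    if (i - maxd <= 0) { cur[0] = i <= maxd ? i : INF; rowmin = cur[0]; }
    for (int j = lo; j <= hi; ++j) {
      int best = prev[j - 1] + psub(a[i - 1], b[j - 1]);
      if (prev[j] + 1 < best) best = prev[j] + 1;
      if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
      if (best > INF) best = INF;
      cur[j] = best;
      if (best < rowmin) rowmin = best;
    }
    if (rowmin > maxd) return -1;
    std::swap(prev, cur);
  }
  return prev[n] <= maxd ? prev[n] : -1;
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size(), n = std::max(na, nb);
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i % na]);
    std::string sb = as<std::string>(b[i % nb]);
    out[i] = lev_full(sa, sb);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_bounded_levenshtein(CharacterVector a, CharacterVector b,
                                      int max_d) {
  R_xlen_t na = a.size(), nb = b.size(), n = std::max(na, nb);
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i % na]);
    std::string sb = as<std::string>(b[i % nb]);
    out[i] = lev_banded(sa, sb, max_d);
  }
  return out;
}

// Semi-global search: best match of `pattern` against any substring of `text`
// (both substring ends free).  Ties at equal distance resolve to the smallest
// start, then the smallest end.  The S matrix carries, for every DP cell, the
// minimal substring start over all optimal paths into that cell, which makes
// the leftmost rule exact.  Coordinates are 0-based half-open; dist = -1 means
// no substring achieves <= max_d.
// [[Rcpp::export]]
List cpp_infix_search(std::string pattern, std::string text, int max_d) {
  const int m = (int)pattern.size(), n = (int)text.size();
  std::vector<int> dprev(n + 1), dcur(n + 1), sprev(n + 1), scur(n + 1);
  for (int j = 0; j <= n; ++j) { dprev[j] = 0; sprev[j] = j; }
  for (int i = 1; i <= m; ++i) {
    dcur[0] = i; scur[0] = 0;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int dd = dprev[j - 1] + wsub(pc, text[j - 1]);
      int du = dprev[j] + 1;
      int dl = dcur[j - 1] + 1;
      int best = std::min(dd, std::min(du, dl));
      int s = INT_MAX;
      if (dd == best && sprev[j - 1] < s) s = sprev[j - 1];
      if (du == best && sprev[j] < s) s = sprev[j];
      if (dl == best && scur[j - 1] < s) s = scur[j - 1];
      dcur[j] = best; scur[j] = s;
    }
    std::swap(dprev, dcur); std::swap(sprev, scur);
  }
  int bd = INT_MAX, bs = -1, be = -1;
  for (int j = 0; j <= n; ++j) {
    if (dprev[j] < bd || (dprev[j] == bd && sprev[j] < bs)) {
      bd = dprev[j]; bs = sprev[j]; be = j;
    }
  }
  if (bd > max_d)
    return List::create(_["start"] = -1, _["end"] = -1, _["dist"] = -1);
  return List::create(_["start"] = bs, _["end"] = be, _["dist"] = bd);
}

// Global (Needleman-Wunsch, unit costs, wildcard-aware) alignment of `pattern`
// against `sub` (the matched substring), followed by a traceback that reports
// the 0-based half-open interval of `sub` aligned to pattern positions
// [q_lo, q_hi).  Traceback preference: diagonal, then up (pattern gap), then
// left, which is deterministic and keeps the variable region tight.
// [[Rcpp::export]]
IntegerVector cpp_locate_variable(std::string pattern, std::string sub,
                                  int q_lo, int q_hi) {
  const int m = (int)pattern.size(), n = (int)sub.size();
  if (q_lo < 0 || q_hi > m || q_lo >= q_hi)
    stop("variable span out of pattern bounds");
  std::vector<int> D((m + 1) * (n + 1));
  auto at = [&](int i, int j) -> int & { return D[i * (n + 1) + j]; };
  for (int j = 0; j <= n; ++j) at(0, j) = j;
  for (int i = 1; i <= m; ++i) {
    at(i, 0) = i;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int d = at(i - 1, j - 1) + wsub(pc, sub[j - 1]);
      int u = at(i - 1, j) + 1;
      int l = at(i, j - 1) + 1;
      at(i, j) = std::min(d, std::min(u, l));
    }
  }
  int i = m, j = n;
  int lo = INT_MAX, hi = -1;
  int row_entry = n;  // column at which the traceback first reaches row q_hi
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        at(i, j) == at(i - 1, j - 1) + wsub(pattern[i - 1], sub[j - 1])) {
      if (i - 1 >= q_lo && i - 1 < q_hi) {
        if (j - 1 < lo) lo = j - 1;
        if (j > hi) hi = j;
      }
      --i; --j;
    } else if (i > 0 && at(i, j) == at(i - 1, j) + 1) {
      --i;
    } else {
      --j;
    }
    if (i == q_hi) row_entry = j;
  }
  if (hi < 0) { lo = row_entry; hi = row_entry; }  // fully deleted region
  return IntegerVector::create(lo, hi);
}

// Semi-global distance of `b` inside `window`, capped at max_d (returns
// max_d + 1 when exceeded); row minima are monotone non-decreasing, which
// permits early abandonment.
static int semiglobal_capped(const std::string &b, const std::string &w,
                             int max_d) {
  const int m = (int)b.size(), n = (int)w.size();
  const int INF = max_d + 1;
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = 0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = std::min(i, INF);
    int rowmin = cur[0];
    const char bc = b[i - 1];
    for (int j = 1; j <= n; ++j) {
      int d = prev[j - 1] + wsub(bc, w[j - 1]);
      if (prev[j] + 1 < d) d = prev[j] + 1;
      if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
      if (d > INF) d = INF;
      cur[j] = d;
      if (d < rowmin) rowmin = d;
    }
    if (rowmin >= INF) return INF;
    std::swap(prev, cur);
  }
  int best = INF;
  for (int j = 0; j <= n; ++j) if (prev[j] < best) best = prev[j];
  return best;
}

// Error-correct one extraction window against a whitelist.  Returns the
// 0-based index of the unique lowest-distance barcode (idx = -1 when the
// minimum exceeds max_d), the number of barcodes attaining the minimum, and
// the matched interval of the best barcode inside the window (leftmost-
// shortest tie rule, as in cpp_infix_search).  The result is independent of
// whitelist order by construction.
// [[Rcpp::export]]
List cpp_assign_barcode(std::string window, CharacterVector whitelist,
                        int max_d) {
  const int INF = max_d + 1;
  int bestd = INF, besti = -1, nmin = 0;
  for (R_xlen_t k = 0; k < whitelist.size(); ++k) {
    std::string b = as<std::string>(whitelist[k]);
    int d = semiglobal_capped(b, window, max_d);
    if (d < bestd) { bestd = d; besti = (int)k; nmin = 1; }
    else if (d == bestd && d < INF) ++nmin;
  }
  if (bestd >= INF)
    return List::create(_["idx"] = -1, _["dist"] = -1, _["nmin"] = 0,
                        _["start"] = -1, _["end"] = -1);
  List h = cpp_infix_search(as<std::string>(whitelist[besti]), window, max_d);
  return List::create(_["idx"] = besti, _["dist"] = bestd, _["nmin"] = nmin,
                      _["start"] = h["start"], _["end"] = h["end"]);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    std::string s = as<std::string>(x[k]);
    std::string r(s.size(), ' ');
    for (size_t i = 0; i < s.size(); ++i) {
      char c = s[s.size() - 1 - i], rc;
      switch (c) {
        case 'A': rc = 'T'; break;
        case 'C': rc = 'G'; break;
        case 'G': rc = 'C'; break;
        case 'T': rc = 'A'; break;
        case 'N': rc = 'N'; break;
        case 'X': rc = 'X'; break;
        default:
          stop("cannot reverse-complement unknown character '%s' at position %d",
               std::string(1, c).c_str(), (int)(s.size() - i));
      }
      r[i] = rc;
    }
    out[k] = r;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_strrev(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    std::string s = as<std::string>(x[k]);
    std::reverse(s.begin(), s.end());
    out[k] = s;
  }
  return out;
}
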