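#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

// Suffix-array machinery for exact substring lookup over a concatenated
// reference text. Sequences are joined with a 0x01 sentinel byte; queries are
// restricted to A,C,G,T upstream, so a match can never span a sentinel.

// [[Rcpp::export]]
IntegerVector sa_build_cpp(std::string text) {
  const char* s = text.c_str();
  size_t n = text.size();
  std::vector<int> sa;
  sa.reserve(n);
  for (size_t i = 0; i < n; ++i) {
    if (s[i] != '\x01') sa.push_back((int)i);
  }
  // std::sort with full suffix comparison: fine at desk scale (<= a few
  // hundred kb); shorter-is-prefix ties are resolved by strcmp on the
  // NUL-terminated buffer, so ordering is total and deterministic.
  std::sort(sa.begin(), sa.end(), [s](int a, int b) {
    return std::strcmp(s + a, s + b) < 0;
  });
  IntegerVector out(sa.size());
  for (size_t i = 0; i < sa.size(); ++i) out[i] = sa[i];
  return out;
}

static int cmp_at(const char* s, size_t n, int pos, const char* q, size_t m) {
  // compare suffix starting at pos against query prefix of length m
  size_t avail = n - pos;
  size_t k = std::min(avail, m);
  int c = std::memcmp(s + pos, q, k);
  if (c != 0) return c;
  if (avail < m) return -1;  // suffix is a proper prefix of query
  return 0;                  // query is a prefix of the suffix: a match
}

static void sa_range(const char* s, size_t n, const int* sa, size_t nsa,
                     const char* q, size_t m, size_t& lo_out, size_t& hi_out) {
  // lower bound
  size_t lo = 0, hi = nsa;
  while (lo < hi) {
    size_t mid = (lo + hi) / 2;
    if (cmp_at(s, n, sa[mid], q, m) < 0) lo = mid + 1; else hi = mid;
  }
  size_t first = lo;
  lo = first; hi = nsa;
  while (lo < hi) {
    size_t mid = (lo + hi) / 2;
    if (cmp_at(s, n, sa[mid], q, m) <= 0) lo = mid + 1; else hi = mid;
  }
  lo_out = first;
  hi_out = lo;
}

// [[Rcpp::export]]
IntegerVector sa_find_cpp(std::string text, IntegerVector sa,
                          std::string query) {
  const char* s = text.c_str();
  size_t n = text.size();
  size_t lo, hi;
  sa_range(s, n, INTEGER(sa), (size_t)sa.size(), query.c_str(), query.size(),
           lo, hi);
  IntegerVector out(hi - lo);
  for (size_t i = lo; i < hi; ++i) out[i - lo] = sa[i];
  std::sort(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
List sa_find_batch_cpp(std::string text, IntegerVector sa,
                       CharacterVector queries) {
  const char* s = text.c_str();
  size_t n = text.size();
  List out(queries.size());
  for (R_xlen_t i = 0; i < queries.size(); ++i) {
    const char* q = CHAR(STRING_ELT(queries, i));
    size_t m = std::strlen(q);
    size_t lo, hi;
    sa_range(s, n, INTEGER(sa), (size_t)sa.size(), q, m, lo, hi);
    IntegerVector hits(hi - lo);
    for (size_t j = lo; j < hi; ++j) hits[j - lo] = sa[j];
    std::sort(hits.begin(), hits.end());
    out[i] = hits;
  }
  return out;
}

static bool valid_acgt(const char* q, size_t m) {
  for (size_t i = 0; i < m; ++i) {
    char c = q[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  }
  return true;
}

static void collect_hits(const char* s, size_t n, const int* sa, size_t nsa,
                         const char* q, size_t m, std::vector<int>& out) {
  out.clear();
  if (!valid_acgt(q, m)) return;  // N or other bases never match
  size_t lo, hi;
  sa_range(s, n, sa, nsa, q, m, lo, hi);
  for (size_t i = lo; i < hi; ++i) out.push_back(sa[i]);
  std::sort(out.begin(), out.end());
}

static void revcomp(const std::string& in, std::string& out) {
  size_t m = in.size();
  out.resize(m);
  for (size_t i = 0; i < m; ++i) {
    char c = in[m - 1 - i];
    switch (c) {
      case 'A': out[i] = 'T'; break;
      case 'C': out[i] = 'G'; break;
      case 'G': out[i] = 'C'; break;
      case 'T': out[i] = 'A'; break;
      default:  out[i] = 'N'; break;
    }
  }
}

// Batch placer: trims 2 nt per end, splits into three k-mers, looks each part
// up on both strands and reconciles collinear candidates at spacing k.
// Status codes: 0 unique, 1 multi, 2 unmapped, 3 discordant, 4 geometry_skipped.
// On unique: start = global 0-based offset of the trimmed span, strand +/-.
// [[Rcpp::export]]
List map_reads_cpp(std::string text, IntegerVector sa, CharacterVector reads,
                   int min_part, bool multi_keep_first) {
  const char* s = text.c_str();
  size_t n = text.size();
  const int* sap = INTEGER(sa);
  size_t nsa = (size_t)sa.size();
  R_xlen_t nr = reads.size();
  IntegerVector status(nr), start(nr);
  CharacterVector strand(nr);
  std::vector<int> h[3], candidates;
  std::string part, rc;
  for (R_xlen_t r = 0; r < nr; ++r) {
    const char* rd = CHAR(STRING_ELT(reads, r));
    int L = (int)std::strlen(rd);
    start[r] = NA_INTEGER;
    strand[r] = NA_STRING;
    if (L < 4 || (L - 4) % 3 != 0 || (L - 4) / 3 < min_part) {
      status[r] = 4;
      continue;
    }
    int k = (L - 4) / 3;
    std::string trimmed(rd + 2, (size_t)(3 * k));
    revcomp(trimmed, rc);
    bool part_dead = false;   // some part has zero hits on both strands
    candidates.clear();
    std::vector<int> cand_fwd, cand_rev;
    for (int pass = 0; pass < 2; ++pass) {
      const std::string& src = (pass == 0) ? trimmed : rc;
      bool any_zero_both = false;
      for (int p = 0; p < 3; ++p) {
        part.assign(src, (size_t)(p * k), (size_t)k);
        collect_hits(s, n, sap, nsa, part.c_str(), (size_t)k, h[p]);
      }
      // collinear reconciliation: part p at pos c + p*k
      std::vector<int>& cand = (pass == 0) ? cand_fwd : cand_rev;
      for (int pos : h[0]) {
        bool ok1 = std::binary_search(h[1].begin(), h[1].end(), pos + k);
        bool ok2 = std::binary_search(h[2].begin(), h[2].end(), pos + 2 * k);
        if (ok1 && ok2) cand.push_back(pos);
      }
      (void)any_zero_both;
    }
    // unmapped test: part i (of the read) has zero hits on both strands.
    // Part i forward corresponds to part (2 - i) of the reverse complement.
    {
      bool dead = false;
      for (int p = 0; p < 3 && !dead; ++p) {
        part.assign(trimmed, (size_t)(p * k), (size_t)k);
        std::vector<int> hf;
        collect_hits(s, n, sap, nsa, part.c_str(), (size_t)k, hf);
        std::string prc;
        revcomp(part, prc);
        std::vector<int> hr;
        collect_hits(s, n, sap, nsa, prc.c_str(), (size_t)k, hr);
        if (hf.empty() && hr.empty()) dead = true;
      }
      part_dead = dead;
    }
    int ncand = (int)(cand_fwd.size() + cand_rev.size());
    if (ncand == 1 || (ncand > 1 && multi_keep_first)) {
      bool fwd = !cand_fwd.empty();
      status[r] = (ncand == 1) ? 0 : 1;
      start[r] = fwd ? cand_fwd[0] : cand_rev[0];
      strand[r] = fwd ? "+" : "-";
    } else if (ncand > 1) {
      status[r] = 1;
    } else if (part_dead) {
      status[r] = 2;
    } else {
      status[r] = 3;
    }
  }
  return List::create(_["status"] = status, _["start"] = start,
                      _["strand"] = strand);
}
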