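#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstring>
#include <climits>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Adapter trimming
//
// For a read and a 3' adapter, candidate placements at a start position p are
//   (a) the full adapter aligned against read[p..j) for some j (trailing read
//       bases are free), admissible when the unit-cost edit distance
//       e <= floor(rate * |adapter|);
//   (b) an adapter prefix of length l >= min_overlap aligned against the
//       entire read suffix read[p..n) (flush with the 3' end), admissible
//       when e <= floor(rate * l).
// Among all admissible placements over all starts, the winner has the most
// matched bases; ties go to fewer errors, then to the smallest start (the
// semantics of the standard 3' adapter trimmer). 'N' in the read matches
// nothing (unit substitution cost).
// ---------------------------------------------------------------------------

struct Placement { int matches, errors, start; bool found; };

// DP cell: minimal cost alignment; among minimal-cost, maximal matches.
struct Cell { int cost, match; };

static inline void relax(Cell &c, int cost, int match) {
  if (cost < c.cost || (cost == c.cost && match > c.match)) {
    c.cost = cost; c.match = match;
  }
}

// Evaluate all placements with aligned text starting exactly at p and offer
// them to the running best.
static void placements_at(const char *read, int n, int p,
                          const char *adapter, int m,
                          int min_overlap, double rate, Placement &best) {
  int len = n - p;
  int full_budget = (int)std::floor(rate * m + 1e-9);
  // D[i][j]: adapter[0..i) vs read[p..p+j)
  std::vector<Cell> prev(len + 1), cur(len + 1);
  for (int j = 0; j <= len; ++j) { prev[j].cost = j; prev[j].match = 0; }
  auto offer = [&best](int matches, int errors, int start) {
    if (!best.found || matches > best.matches ||
        (matches == best.matches && errors < best.errors)) {
      // smaller start wins remaining ties implicitly: starts scanned
      // ascending and equal (matches, errors) never replaces the incumbent
      best.found = true; best.matches = matches; best.errors = errors;
      best.start = start;
    }
  };
  for (int i = 1; i <= m; ++i) {
    cur[0].cost = i; cur[0].match = 0;
    for (int j = 1; j <= len; ++j) {
      char rc = read[p + j - 1];
      bool eq = (rc != 'N' && rc == adapter[i - 1]);
      Cell c; c.cost = INT_MAX; c.match = -1;
      relax(c, prev[j - 1].cost + (eq ? 0 : 1), prev[j - 1].match + (eq ? 1 : 0));
      relax(c, prev[j].cost + 1, prev[j].match);
      relax(c, cur[j - 1].cost + 1, cur[j - 1].match);
      cur[j] = c;
    }
    if (i == m) {
      // placement (a): full adapter, trailing read free
      for (int j = 0; j <= len; ++j)
        if (cur[j].cost <= full_budget) offer(cur[j].match, cur[j].cost, p);
    }
    if (i >= min_overlap) {
      // placement (b): adapter prefix of length i flush with the 3' end
      int budget = (int)std::floor(rate * i + 1e-9);
      if (cur[len].cost <= budget) offer(cur[len].match, cur[len].cost, p);
    }
    std::swap(prev, cur);
  }
}

// [[Rcpp::export]]
DataFrame cpp_trim_reads(CharacterVector reads, std::string adapter,
                         int min_overlap, double max_error_rate) {
  int nr = reads.size();
  IntegerVector start(nr), errors(nr);
  LogicalVector found(nr);
  const char *ad = adapter.c_str();
  int m = (int)adapter.size();
  for (int r = 0; r < nr; ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    int n = (int)std::strlen(rd);
    Placement best; best.found = false; best.matches = -1; best.errors = 0;
    best.start = -1;
    for (int p = 0; p < n; ++p) {
      if (best.found && best.matches >= m && best.errors == 0) break; // unbeatable
      if (best.found && n - p < best.matches) break; // cannot tie on matches
      placements_at(rd, n, p, ad, m, min_overlap, max_error_rate, best);
    }
    if (best.found) {
      found[r] = true; start[r] = best.start; errors[r] = best.errors;
    } else {
      found[r] = false; start[r] = NA_INTEGER; errors[r] = NA_INTEGER;
    }
  }
  return DataFrame::create(_["adapter_found"] = found,
                           _["adapter_start"] = start,
                           _["n_errors"] = errors);
}

// ---------------------------------------------------------------------------
// Maximal exact matches (MEMs)
//
// A MEM of the read against a reference is an interval [p, p+L) such that
// read[p..p+L) occurs in the reference and neither the left-extended (p > 0)
// nor the right-extended (p+L < n) substring occurs anywhere in it.
// With Lmax(p) = longest match starting at p, the interval [p, Lmax(p)) is a
// MEM iff p == 0 or Lmax(p-1) < Lmax(p) + 1.
// ---------------------------------------------------------------------------

static void longest_match(const char *read, int n, const char *ref, int m,
                          std::vector<int> &L) {
  L.assign(n, 0);
  for (int p = 0; p < n; ++p) {
    int best = 0;
    for (int q = 0; q < m; ++q) {
      int l = 0;
      while (p + l < n && q + l < m && read[p + l] == ref[q + l]) ++l;
      if (l > best) best = l;
    }
    L[p] = best;
  }
}

static void collect_mems(const std::vector<int> &L, int n, int min_len,
                         std::vector<std::pair<int,int> > &mems) {
  mems.clear();
  for (int p = 0; p < n; ++p) {
    if (L[p] < min_len) continue;
    if (p > 0 && L[p - 1] >= L[p] + 1) continue; // left-extendable
    mems.push_back(std::make_pair(p, L[p]));
  }
}

static int union_size(std::vector<std::pair<int,int> > &iv) {
  if (iv.empty()) return 0;
  std::sort(iv.begin(), iv.end());
  int tot = 0, cs = iv[0].first, ce = iv[0].first + iv[0].second;
  for (size_t i = 1; i < iv.size(); ++i) {
    int s = iv[i].first, e = iv[i].first + iv[i].second;
    if (s > ce) { tot += ce - cs; cs = s; ce = e; }
    else if (e > ce) ce = e;
  }
  tot += ce - cs;
  return tot;
}

// [[Rcpp::export]]
IntegerMatrix cpp_find_mems(std::string read, std::string ref, int min_len) {
  int n = (int)read.size(), m = (int)ref.size();
  std::vector<int> L;
  longest_match(read.c_str(), n, ref.c_str(), m, L);
  std::vector<std::pair<int,int> > mems;
  collect_mems(L, n, min_len, mems);
  IntegerMatrix out((int)mems.size(), 2);
  for (size_t i = 0; i < mems.size(); ++i) {
    out(i, 0) = mems[i].first;
    out(i, 1) = mems[i].second;
  }
  colnames(out) = CharacterVector::create("start", "length");
  return out;
}

// q-gram seeded assignment of many reads against a catalog.
// Refs prefiltered by shared min_mem_len-grams (a MEM of length >= k implies a
// shared k-gram), then exact MEM coverage computed per surviving candidate.
// [[Rcpp::export]]
List cpp_assign_reads(CharacterVector reads, CharacterVector refs,
                      CharacterVector ref_names, int min_mem_len,
                      int min_coverage) {
  int nref = refs.size(), nread = reads.size();
  int k = min_mem_len;
  // seed index: k-gram (2-bit encoded) -> ref ids
  std::unordered_map<uint64_t, std::vector<int> > index;
  std::vector<std::string> refstr(nref);
  for (int i = 0; i < nref; ++i) refstr[i] = as<std::string>(refs[i]);
  auto code = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < nref; ++i) {
    const std::string &s = refstr[i];
    uint64_t h = 0; int run = 0;
    std::vector<uint64_t> seen;
    for (size_t q = 0; q < s.size(); ++q) {
      int c = code(s[q]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        std::vector<int> &v = index[h];
        if (v.empty() || v.back() != i) v.push_back(i);
      }
    }
  }
  IntegerVector ref_idx(nread);
  IntegerVector covered(nread);
  LogicalVector tie(nread);
  std::vector<int> L;
  std::vector<std::pair<int,int> > mems;
  std::vector<int> cand;
  std::vector<unsigned char> in_cand(nref, 0);
  for (int r = 0; r < nread; ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    int n = (int)std::strlen(rd);
    cand.clear();
    uint64_t h = 0; int run = 0;
    for (int q = 0; q < n; ++q) {
      int c = code(rd[q]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto it = index.find(h);
        if (it != index.end())
          for (int id : it->second)
            if (!in_cand[id]) { in_cand[id] = 1; cand.push_back(id); }
      }
    }
    int best_cov = 0, best_id = -1; bool best_tie = false;
    for (int id : cand) {
      in_cand[id] = 0;
      const std::string &s = refstr[id];
      std::vector<int> Lv;
      longest_match(rd, n, s.c_str(), (int)s.size(), Lv);
      collect_mems(Lv, n, min_mem_len, mems);
      int cov = union_size(mems);
      if (cov < min_coverage) continue;
      if (cov > best_cov) { best_cov = cov; best_id = id; best_tie = false; }
      else if (cov == best_cov && best_id >= 0) {
        best_tie = true;
        // lexicographically smallest reference name wins
        if (std::strcmp(CHAR(STRING_ELT(ref_names, id)),
                        CHAR(STRING_ELT(ref_names, best_id))) < 0)
          best_id = id;
      }
    }
    ref_idx[r] = (best_id >= 0) ? best_id + 1 : NA_INTEGER;
    covered[r] = best_cov;
    tie[r] = best_tie;
  }
  return List::create(_["ref_idx"] = ref_idx, _["covered_bp"] = covered,
                      _["tie_flag"] = tie);
}
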