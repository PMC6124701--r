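#include "dna.h"
#include <set>
#include <tuple>
using namespace Rcpp;

std::string cpp_revcomp(std::string s); // align.cpp

// Build word -> positions index (words containing non-ACGT skipped).
static void index_words(const std::string &s, int k,
                        std::unordered_map<uint64_t, std::vector<int>> &idx) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t v = 0;
  int run = 0;
  for (int i = 0; i < (int)s.size(); i++) {
    int c = base2code(s[i]);
    if (c < 0) { run = 0; v = 0; continue; }
    v = ((v << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[v].push_back(i - k + 1);
  }
}

// All maximal exact repeated pairs >= min_len within a linear sequence,
// both orientations. Maximality is per diagonal: a pair is reported once,
// extended as far as equality holds on both sides.
// [[Rcpp::export]]
DataFrame cpp_exact_repeats(std::string s, int min_len) {
  const int n = (int)s.size();
  const int k0 = std::min(min_len, 31);
  std::vector<int> a1, a2, b1, b2;
  std::vector<std::string> ori;
  std::set<std::tuple<int, int, int, int>> seen; // a, b, len, orient(0/1)

  auto record = (
      [&](int ai, int bi, int len, int orient) {
        // canonical order: member a precedes member b
        int xa = ai, xb = bi;
        if (std::make_pair(xb, xb + len) < std::make_pair(xa, xa + len))
          std::swap(xa, xb);
        if (xa == xb) return; // identical interval (self-palindrome)
        auto key = std::make_tuple(xa, xb, len, orient);
        if (!seen.insert(key).second) return;
        a1.push_back(xa); a2.push_back(xa + len);
        b1.push_back(xb); b2.push_back(xb + len);
        ori.push_back(orient == 0 ? "direct" : "inverted");
      });

  // direct repeats: s vs s
  {
    std::unordered_map<uint64_t, std::vector<int>> idx;
    index_words(s, k0, idx);
    for (auto &kv : idx) {
      const std::vector<int> &pos = kv.second;
      if (pos.size() < 2) continue;
      for (size_t x = 0; x < pos.size(); x++) {
        for (size_t y = x + 1; y < pos.size(); y++) {
          int i = pos[x], j = pos[y];
          if (i > 0 && j > 0 && s[i - 1] == s[j - 1]) continue; // not left-maximal
          int l = k0;
          while (j + l < n && s[i + l] == s[j + l]) l++;
          if (l >= min_len) record(i, j, l, 0);
        }
      }
    }
  }
  // inverted repeats: s vs revcomp(s)
  {
    std::string r = cpp_revcomp(s);
    std::unordered_map<uint64_t, std::vector<int>> ridx;
    index_words(r, k0, ridx);
    const uint64_t mask = (1ULL << (2 * k0)) - 1;
    uint64_t v = 0;
    int run = 0;
    for (int i = 0; i < n; i++) {
      int c = base2code(s[i]);
      if (c < 0) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (run + 1 < k0) { run++; continue; }
      run++;
      int qi = i - k0 + 1;
      auto it = ridx.find(v);
      if (it == ridx.end()) continue;
      for (int j : it->second) {
        if (qi > 0 && j > 0 && s[qi - 1] == r[j - 1]) continue; // not left-maximal
        int l = k0;
        while (qi + l < n && j + l < n && s[qi + l] == r[j + l]) l++;
        if (l < min_len) continue;
        // r[j..j+l) is revcomp of s[n-j-l..n-j)
        record(qi, n - j - l, l, 1);
      }
    }
  }
  return DataFrame::create(_["a_start"] = a1, _["a_end"] = a2,
                           _["b_start"] = b1, _["b_end"] = b2,
                           _["orientation"] = ori,
                           _["stringsAsFactors"] = false);
}

// Index of the lexicographically least rotation (Booth-style comparison walk).
// [[Rcpp::export]]
int cpp_min_rotation(std::string s) {
  const int n = (int)s.size();
  if (n == 0) return 0;
  int i = 0, j = 1, k = 0;
  while (i < n && j < n && k < n) {
    char a = s[(i + k) % n], b = s[(j + k) % n];
    if (a == b) { k++; continue; }
    if (a > b) i = i + k + 1; else j = j + k + 1;
    if (i == j) j++;
    k = 0;
  }
  return std::min(i, j);
}
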