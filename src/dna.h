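#pragma once
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>

typedef unsigned __int128 u128;

inline int base2code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

inline char code2base(int v) { return "ACGT"[v & 3]; }

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

struct U128Hash {
  size_t operator()(const u128 &x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL + hi;
    h ^= h >> 33; h *= 0xff51afd7ed558ccdULL; h ^= h >> 33;
    return (size_t)h;
  }
};

// 2-bit encode s[0..k) ; false if any non-ACGT base
inline bool encode_kmer(const char *s, int k, u128 &out) {
  u128 v = 0;
  for (int j = 0; j < k; j++) {
    int c = base2code(s[j]);
    if (c < 0) return false;
    v = (v << 2) | (u128)c;
  }
  out = v;
  return true;
}

inline u128 revcomp_code(u128 v, int k) {
  u128 r = 0;
  for (int j = 0; j < k; j++) { r = (r << 2) | (u128)(3 - (int)(v & 3)); v >>= 2; }
  return r;
}

inline u128 kmer_mask(int k) { return (((u128)1) << (2 * k)) - 1; }

inline std::string decode_kmer(u128 v, int k) {
  std::string s(k, 'A');
  for (int j = k - 1; j >= 0; j--) { s[j] = code2base((int)(v & 3)); v >>= 2; }
  return s;
}
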