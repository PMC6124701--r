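#include "dna.h"
using namespace Rcpp;

// Scan a sequence with a rolling 2-bit k-mer window, resetting on non-ACGT.
// Calls fn(code, pos) for every valid k-mer start position.
template <typename F>
static void for_each_kmer(const std::string &s, int k, F fn) {
  const int n = (int)s.size();
  if (n < k) return;
  const u128 mask = kmer_mask(k);
  u128 v = 0;
  int run = 0;
  for (int i = 0; i < n; i++) {
    int c = base2code(s[i]);
    if (c < 0) { run = 0; v = 0; continue; }
    v = ((v << 2) | (u128)c) & mask;
    if (++run >= k) fn(v, i - k + 1);
  }
}

// [[Rcpp::export]]
LogicalVector cpp_kmer_hits(CharacterVector reads, CharacterVector baits, int k) {
  std::unordered_set<u128, U128Hash> baitset;
  for (R_xlen_t b = 0; b < baits.size(); b++) {
    std::string s = as<std::string>(baits[b]);
    for_each_kmer(s, k, [&](u128 v, int) {
      baitset.insert(v);
      baitset.insert(revcomp_code(v, k));
    });
  }
  LogicalVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); r++) {
    std::string s = as<std::string>(reads[r]);
    bool hit = false;
    for_each_kmer(s, k, [&](u128 v, int) {
      if (!hit && baitset.count(v)) hit = true;
    });
    out[r] = hit;
  }
  return out;
}

// ---- de Bruijn unitigs over canonical k-mers (bidirected graph) ----

struct KmerDB {
  int k;
  u128 mask;
  std::unordered_map<u128, int, U128Hash> cnt; // canonical k-mer -> count

  u128 canon(u128 v) const {
    u128 r = revcomp_code(v, k);
    return v < r ? v : r;
  }
  bool present(u128 v) const { return cnt.count(canon(v)) > 0; }
  int count(u128 v) const {
    auto it = cnt.find(canon(v));
    return it == cnt.end() ? 0 : it->second;
  }
  // oriented successors of oriented k-mer v
  int successors(u128 v, u128 *out) const {
    int m = 0;
    for (int c = 0; c < 4; c++) {
      u128 nxt = ((v << 2) | (u128)c) & mask;
      if (present(nxt)) out[m++] = nxt;
    }
    return m;
  }
  int predecessors(u128 v, u128 *out) const {
    int m = 0;
    for (int c = 0; c < 4; c++) {
      u128 prv = (v >> 2) | (((u128)c) << (2 * (k - 1)));
      if (present(prv)) out[m++] = prv;
    }
    return m;
  }
};

// Build unitigs (maximal unbranched paths) of the assembly de Bruijn graph.
// Returns sequences, per-k-mer coverage along each unitig, and circular flags.
// [[Rcpp::export]]
List cpp_build_unitigs(CharacterVector reads, int k) {
  if (k < 3 || k > 63) stop("assembly k must be in [3, 63]");
  if (k % 2 == 0) stop("assembly k must be odd (avoids palindromic k-mers)");
  KmerDB db;
  db.k = k;
  db.mask = kmer_mask(k);
  for (R_xlen_t r = 0; r < reads.size(); r++) {
    std::string s = as<std::string>(reads[r]);
    for_each_kmer(s, k, [&](u128 v, int) { db.cnt[db.canon(v)]++; });
  }
  std::unordered_set<u128, U128Hash> visited; // canonical
  std::vector<std::string> seqs;
  std::vector<IntegerVector> covs;
  std::vector<bool> circ;

  auto emit = [&](const std::vector<u128> &path, bool circular) {
    std::string s = decode_kmer(path[0], k);
    IntegerVector cv((int)path.size());
    cv[0] = db.count(path[0]);
    for (size_t i = 1; i < path.size(); i++) {
      s.push_back(code2base((int)(path[i] & 3)));
      cv[(int)i] = db.count(path[i]);
    }
    seqs.push_back(s);
    covs.push_back(cv);
    circ.push_back(circular);
  };

  auto walk_right = [&](u128 start, std::vector<u128> &path) -> bool {
    // returns true if the walk closed a cycle back to start
    u128 cur = start, sx[4], px[4];
    while (true) {
      int ns = db.successors(cur, sx);
      if (ns != 1) return false;
      u128 nxt = sx[0];
      if (db.predecessors(nxt, px) != 1) return false;
      if (db.canon(nxt) == db.canon(start)) return true; // closed circle
      if (visited.count(db.canon(nxt))) return false;
      path.push_back(nxt);
      visited.insert(db.canon(nxt));
      cur = nxt;
    }
  };

  u128 sx[4], px[4];
  // pass 1: unitigs with a defined start (branch boundaries)
  for (auto &kv : db.cnt) {
    if (visited.count(kv.first)) continue;
    u128 orients[2] = {kv.first, revcomp_code(kv.first, k)};
    for (int o = 0; o < 2; o++) {
      u128 v = orients[o];
      bool start;
      int np = db.predecessors(v, px);
      if (np != 1) start = true;
      else start = db.successors(px[0], sx) != 1;
      if (!start) continue;
      std::vector<u128> path{v};
      visited.insert(db.canon(v));
      walk_right(v, path);
      emit(path, false);
      break;
    }
  }
  // pass 2: leftover perfect cycles
  for (auto &kv : db.cnt) {
    if (visited.count(kv.first)) continue;
    u128 v = kv.first;
    std::vector<u128> path{v};
    visited.insert(db.canon(v));
    bool closed = walk_right(v, path);
    emit(path, closed);
  }
  return List::create(_["seq"] = wrap(seqs), _["cov"] = wrap(covs),
                      _["circular"] = wrap(circ));
}

// Per-base depth by exact k-mer anchoring of reads onto a genome.
// Multi-mapping reads contribute fractional depth split across anchor sites.
// [[Rcpp::export]]
NumericVector cpp_coverage_profile(std::string genome, CharacterVector reads,
                                   int k, bool circular) {
  int n = (int)genome.size();
  std::unordered_map<u128, std::vector<int>, U128Hash> idx;
  std::string g = circular ? genome + genome.substr(0, std::min(n, k - 1)) : genome;
  for_each_kmer(g, k, [&](u128 v, int pos) {
    if (pos < n) idx[v].push_back(pos);
  });
  NumericVector depth(n);
  for (R_xlen_t r = 0; r < reads.size(); r++) {
    std::string s = as<std::string>(reads[r]);
    int L = (int)s.size();
    const std::vector<int> *hits = nullptr;
    int off = 0;
    bool found = false;
    for (int o = 0; o < 2 && !found; o++) {
      if (o == 1) { // reverse complement
        std::string rc(L, 'N');
        for (int i = 0; i < L; i++) rc[i] = comp_base(s[L - 1 - i]);
        s = rc;
      }
      for_each_kmer(s, k, [&](u128 v, int pos) {
        if (found) return;
        auto it = idx.find(v);
        if (it != idx.end()) { hits = &it->second; off = pos; found = true; }
      });
    }
    if (!found) continue;
    double w = 1.0 / (double)hits->size();
    for (int pos : *hits) {
      int start = pos - off;
      for (int j = 0; j < L; j++) {
        int p = start + j;
        if (circular) p = ((p % n) + n) % n;
        if (p >= 0 && p < n) depth[p] += w;
      }
    }
  }
  return depth;
}

// Does each read (or its reverse complement) match a reference exactly,
// full length, anchored by its first shared k-mer?
// [[Rcpp::export]]
LogicalVector cpp_exact_map(std::string ref, CharacterVector reads, int k,
                            bool circular) {
  int n = (int)ref.size();
  std::unordered_map<u128, std::vector<int>, U128Hash> idx;
  std::string g = circular ? ref + ref.substr(0, std::min(n, k - 1)) : ref;
  for_each_kmer(g, k, [&](u128 v, int pos) {
    if (pos < n) idx[v].push_back(pos);
  });
  auto base_at = [&](int p) -> char {
    if (circular) p = ((p % n) + n) % n;
    if (p < 0 || p >= n) return '\0';
    return ref[p];
  };
  LogicalVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); r++) {
    std::string s = as<std::string>(reads[r]);
    int L = (int)s.size();
    bool mapped = false;
    for (int o = 0; o < 2 && !mapped; o++) {
      if (o == 1) {
        std::string rc(L, 'N');
        for (int i = 0; i < L; i++) rc[i] = comp_base(s[L - 1 - i]);
        s = rc;
      }
      bool anchored = false;
      int aoff = -1;
      u128 av = 0;
      for_each_kmer(s, k, [&](u128 v, int pos) {
        if (!anchored) { anchored = true; aoff = pos; av = v; }
      });
      if (!anchored) continue;
      auto it = idx.find(av);
      if (it == idx.end()) continue;
      for (int pos : it->second) {
        int start = pos - aoff;
        bool ok = true;
        for (int j = 0; j < L; j++) {
          if (base_at(start + j) != s[j]) { ok = false; break; }
        }
        if (ok) { mapped = true; break; }
      }
    }
    out[r] = mapped;
  }
  return out;
}

// Count read pairs placeable concordantly (inward-facing mates, fragment
// length within [min_frag, max_frag]) on a candidate circular sequence,
// requiring full-length exact matches of both mates.
// [[Rcpp::export]]
IntegerVector cpp_concordant_pairs(std::string seq, CharacterVector r1,
                                   CharacterVector r2, int k, int min_frag,
                                   int max_frag, int max_check) {
  int n = (int)seq.size();
  std::unordered_map<u128, std::vector<int>, U128Hash> idx;
  std::string g = seq + seq.substr(0, std::min(n, k - 1));
  for_each_kmer(g, k, [&](u128 v, int pos) {
    if (pos < n) idx[v].push_back(pos);
  });
  auto base_at = [&](int p) -> char { return seq[((p % n) + n) % n]; };
  // full-match positions of a sequence on the circular candidate
  auto match_pos = [&](const std::string &s) {
    std::vector<int> out;
    int L = (int)s.size();
    bool anchored = false;
    int aoff = -1;
    u128 av = 0;
    for_each_kmer(s, k, [&](u128 v, int pos) {
      if (!anchored) { anchored = true; aoff = pos; av = v; }
    });
    if (!anchored) return out;
    auto it = idx.find(av);
    if (it == idx.end()) return out;
    for (int pos : it->second) {
      int start = pos - aoff;
      bool ok = true;
      for (int j = 0; j < L; j++) {
        if (base_at(start + j) != s[j]) { ok = false; break; }
      }
      if (ok) out.push_back(((start % n) + n) % n);
    }
    return out;
  };
  auto rcs = [&](const std::string &s) {
    int L = (int)s.size();
    std::string rc(L, 'N');
    for (int i = 0; i < L; i++) rc[i] = comp_base(s[L - 1 - i]);
    return rc;
  };
  int nch = std::min((int)r1.size(), max_check);
  int conc = 0;
  for (int i = 0; i < nch; i++) {
    std::string a = as<std::string>(r1[i]);
    std::string b = as<std::string>(r2[i]);
    int la = (int)a.size(), lb = (int)b.size();
    bool ok = false;
    // orientation 1: r1 forward, rc(r2) downstream
    std::vector<int> p1 = match_pos(a), p2 = match_pos(rcs(b));
    for (int x : p1) {
      for (int y : p2) {
        int frag = ((y + lb - x) % n + n) % n;
        if (frag >= min_frag && frag <= max_frag) { ok = true; break; }
      }
      if (ok) break;
    }
    if (!ok) { // orientation 2: r2 forward, rc(r1) downstream
      std::vector<int> q1 = match_pos(b), q2 = match_pos(rcs(a));
      for (int x : q1) {
        for (int y : q2) {
          int frag = ((y + la - x) % n + n) % n;
          if (frag >= min_frag && frag <= max_frag) { ok = true; break; }
        }
        if (ok) break;
      }
    }
    if (ok) conc++;
  }
  return IntegerVector::create(conc, nch);
}
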