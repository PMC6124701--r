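#include "dna.h"
using namespace Rcpp;

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  int n = (int)s.size();
  std::string r(n, 'N');
  for (int i = 0; i < n; i++) r[i] = comp_base(s[n - 1 - i]);
  return r;
}

// ---- banded affine-gap extension with X-drop termination ----
//
// Extends an anchored alignment outward from a seed. Sequences are accessed
// through (start, dir) so the same code runs left (dir = -1) and right
// (dir = +1) without copying. Gap of length g costs open + g * extend
// (open charged once, on the first gap column).

struct ExtResult {
  long score = 0;
  int qext = 0, sext = 0;
  int matches = 0, mismatches = 0, gapopens = 0, gapcols = 0;
};

static const long NEG = -(1L << 40);

static ExtResult band_extend(const std::string &q, int qstart, int qlen_avail,
                             const std::string &s, int sstart, int slen_avail,
                             int dir, int match, int mismatch, int gap_open,
                             int gap_extend, int xdrop, int band) {
  ExtResult res;
  const int la = qlen_avail, lb = slen_avail;
  if (la == 0 || lb == 0) return res;
  const int W = 2 * band + 1;
  const long go = (long)gap_open + gap_extend; // first gap column
  const long ge = gap_extend;

  // state arrays indexed by d = c - r + band
  std::vector<long> Gp(W, NEG), Ep(W, NEG), Fp(W, NEG);
  std::vector<long> Gc(W, NEG), Ec(W, NEG), Fc(W, NEG);
  // traceback: bits 0-1 best state (0 H, 1 E, 2 F, 3 invalid), bit2 E open, bit3 F open
  std::vector<uint8_t> tb;
  const int MAXROWS = 1 << 21;

  auto qch = [&](int t) { return q[qstart + dir * t]; };
  auto sch = [&](int t) { return s[sstart + dir * t]; };

  long best = 0;
  int best_r = 0, best_c = 0;

  // row 0
  Gp[band] = 0;
  tb.assign((size_t)W, (uint8_t)3);
  tb[band] = 0;
  for (int c = 1; c <= std::min(lb, band); c++) {
    int d = c + band;
    Ep[d] = (c == 1) ? go : Ep[d - 1] + ge;
    Gp[d] = Ep[d];
    tb[d] = (uint8_t)(1 | (c == 1 ? 4 : 0));
  }

  int r = 0;
  for (r = 1; r <= la && r < MAXROWS; r++) {
    std::fill(Gc.begin(), Gc.end(), NEG);
    std::fill(Ec.begin(), Ec.end(), NEG);
    std::fill(Fc.begin(), Fc.end(), NEG);
    tb.resize((size_t)(r + 1) * W, (uint8_t)3);
    uint8_t *tbrow = &tb[(size_t)r * W];
    long rowmax = NEG;
    int clo = std::max(0, r - band), chi = std::min(lb, r + band);
    if (clo > chi) break;
    for (int c = clo; c <= chi; c++) {
      int d = c - r + band;
      uint8_t code = 3;
      long H = NEG, E = NEG, F = NEG;
      if (c >= 1) {
        long gprev = Gp[d]; // (r-1, c-1) same offset
        if (gprev > NEG / 2) {
          H = gprev + ((qch(r - 1) == sch(c - 1)) ? match : mismatch);
        }
        if (d >= 1) { // from (r, c-1), offset d-1 in this row
          long eopen = (Gc[d - 1] > NEG / 2) ? Gc[d - 1] + go : NEG;
          long eext = (Ec[d - 1] > NEG / 2) ? Ec[d - 1] + ge : NEG;
          E = std::max(eopen, eext);
          if (E > NEG / 2 && eopen >= eext) code |= 4;
        }
      }
      if (d + 1 < W) { // from (r-1, c), offset d+1 in previous row
        long fopen = (Gp[d + 1] > NEG / 2) ? Gp[d + 1] + go : NEG;
        long fext = (Fp[d + 1] > NEG / 2) ? Fp[d + 1] + ge : NEG;
        F = std::max(fopen, fext);
        if (F > NEG / 2 && fopen >= fext) code |= 8;
      }
      long G = std::max(H, std::max(E, F));
      if (G <= NEG / 2) { tbrow[d] = code; continue; }
      int st = (G == H) ? 0 : (G == E ? 1 : 2);
      code = (uint8_t)((code & 12) | st);
      tbrow[d] = code;
      Gc[d] = G; Ec[d] = E; Fc[d] = F;
      if (G > rowmax) rowmax = G;
      if (G > best) { best = G; best_r = r; best_c = c; }
    }
    if (rowmax < best - xdrop) break;
    std::swap(Gp, Gc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }

  if (best <= 0) return res;
  res.score = best;
  res.qext = best_r;
  res.sext = best_c;
  // traceback
  int cr = best_r, cc = best_c;
  int state = 0; // G = take bestState at cell
  bool in_e = false, in_f = false;
  while (cr > 0 || cc > 0) {
    int d = cc - cr + band;
    uint8_t code = tb[(size_t)cr * W + d];
    if (!in_e && !in_f) state = code & 3;
    if (in_e) state = 1;
    if (in_f) state = 2;
    if (state == 0) {
      res.gapcols += 0;
      if (qch(cr - 1) == sch(cc - 1)) res.matches++; else res.mismatches++;
      cr--; cc--;
      in_e = in_f = false;
    } else if (state == 1) {
      res.gapcols++;
      bool open = (code & 4) != 0;
      cc--;
      if (open) { res.gapopens++; in_e = false; }
      else in_e = true;
      in_f = false;
    } else {
      res.gapcols++;
      bool open = (code & 8) != 0;
      cr--;
      if (open) { res.gapopens++; in_f = false; }
      else in_f = true;
      in_e = false;
    }
  }
  return res;
}

// ---- seed-and-extend HSP search (one query strand) ----

struct RawHsp {
  int qstart, qend, sstart, send;
  long score;
  int matches, mismatches, gapopens, gapcols;
  int strand; // 0 = +, 1 = -
};

static void find_hsps_strand(const std::string &q, const std::string &s,
                             const std::unordered_map<uint64_t, std::vector<int>> &sidx,
                             int w, int match, int mismatch, int gap_open,
                             int gap_extend, int xdrop, int band, int strand,
                             std::vector<RawHsp> &out) {
  const int nq = (int)q.size();
  const uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  std::unordered_map<long long, int> diag_end;
  uint64_t v = 0;
  int run = 0;
  for (int i = 0; i < nq; i++) {
    int c = base2code(q[i]);
    if (c < 0) { run = 0; v = 0; continue; }
    v = ((v << 2) | (uint64_t)c) & mask;
    if (++run < w) continue;
    auto it = sidx.find(v);
    if (it == sidx.end()) continue;
    int qpos = i - w + 1;
    for (int spos : it->second) {
      long long diag = (long long)qpos - spos;
      auto de = diag_end.find(diag);
      if (de != diag_end.end() && qpos < de->second) continue;
      ExtResult R = band_extend(q, qpos + w, nq - qpos - w, s, spos + w,
                                (int)s.size() - spos - w, +1, match, mismatch,
                                gap_open, gap_extend, xdrop, band);
      ExtResult L = band_extend(q, qpos - 1, qpos, s, spos - 1, spos, -1, match,
                                mismatch, gap_open, gap_extend, xdrop, band);
      RawHsp h;
      h.qstart = qpos - L.qext;
      h.qend = qpos + w + R.qext;
      h.sstart = spos - L.sext;
      h.send = spos + w + R.sext;
      h.score = (long)w * match + L.score + R.score;
      h.matches = w + L.matches + R.matches;
      h.mismatches = L.mismatches + R.mismatches;
      h.gapopens = L.gapopens + R.gapopens;
      h.gapcols = L.gapcols + R.gapcols;
      h.strand = strand;
      out.push_back(h);
      diag_end[diag] = h.qend;
      long long diag2 = (long long)h.qend - h.send;
      if (diag2 != diag) {
        auto d2 = diag_end.find(diag2);
        if (d2 == diag_end.end() || d2->second < h.qend) diag_end[diag2] = h.qend;
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_find_hsps(std::string query, std::string subject, int word_size,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int xdrop, int band) {
  if (word_size < 4 || word_size > 31) stop("word_size must be in [4, 31]");
  const int nq = (int)query.size();
  // subject word index
  std::unordered_map<uint64_t, std::vector<int>> sidx;
  {
    const uint64_t mask = (1ULL << (2 * word_size)) - 1;
    uint64_t v = 0;
    int run = 0;
    for (int i = 0; i < (int)subject.size(); i++) {
      int c = base2code(subject[i]);
      if (c < 0) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++run >= word_size) sidx[v].push_back(i - word_size + 1);
    }
  }
  std::vector<RawHsp> hsps;
  find_hsps_strand(query, subject, sidx, word_size, match, mismatch, gap_open,
                   gap_extend, xdrop, band, 0, hsps);
  std::string qrc = cpp_revcomp(query);
  std::vector<RawHsp> minus;
  find_hsps_strand(qrc, subject, sidx, word_size, match, mismatch, gap_open,
                   gap_extend, xdrop, band, 1, minus);
  for (auto &h : minus) { // map rc-query coords back to forward query
    int qs = nq - h.qend, qe = nq - h.qstart;
    h.qstart = qs;
    h.qend = qe;
    hsps.push_back(h);
  }
  int n = (int)hsps.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), mt(n), mm(n), gop(n), gcol(n);
  NumericVector sc(n);
  CharacterVector st(n);
  for (int i = 0; i < n; i++) {
    const RawHsp &h = hsps[i];
    qs[i] = h.qstart; qe[i] = h.qend; ss[i] = h.sstart; se[i] = h.send;
    sc[i] = (double)h.score;
    mt[i] = h.matches; mm[i] = h.mismatches;
    gop[i] = h.gapopens; gcol[i] = h.gapcols;
    st[i] = (h.strand == 0) ? "+" : "-";
  }
  return DataFrame::create(
      _["qstart"] = qs, _["qend"] = qe, _["sstart"] = ss, _["send"] = se,
      _["strand"] = st, _["score"] = sc, _["matches"] = mt,
      _["mismatches"] = mm, _["gapopens"] = gop, _["gapcols"] = gcol,
      _["stringsAsFactors"] = false);
}
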