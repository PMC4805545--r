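// Seed-and-extend read mapper used by the pooled-validation pipeline.
//
// k-mer exact seeding over all references, ungapped extension with a
// full-window dynamic-programming fallback (edit distance, traceback) for
// gapped alignments. Because the tag cassette sequence is shared by every
// clone construct, hits that fall entirely inside a construct's tag
// interval are suppressed in favour of a single hit on the shared cassette
// reference ("special" references); pair resolution translates those back
// into clone coordinates.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: break;
    }
  }
  return r;
}

struct SeedIndex {
  int k;
  uint64_t mask;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> map; // kmer -> (ref, pos)
};

static void index_ref(SeedIndex& idx, const std::string& s, int ref) {
  const int k = idx.k;
  const int n = (int)s.size();
  uint64_t h = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base2code(s[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & idx.mask;
    if (++run >= k) idx.map[h].push_back(std::make_pair(ref, i - k + 1));
  }
}

struct Hit {
  int read; int ref; int pos; int strand; int edits; int span;
  std::vector<int> ev_pos;
  std::vector<char> ev_type;          // 'X', 'I', 'D'
  std::vector<std::string> ev_ref;
  std::vector<std::string> ev_alt;
};

// Global-on-read / local-on-window alignment with affine gap penalties
// (mismatch 2, gap open 3, gap extend 2) so a contiguous 2-bp gap is
// preferred over two split 1-bp gaps, and traceback. `edits` is the plain
// edit count (mismatches + gap bases), independent of the internal costs.
static const int SUB_COST = 2, GAP_OPEN = 3, GAP_EXT = 2;
static const int INF_COST = 1 << 28;

static bool dp_align(const std::string& read, const std::string& win,
                     int max_edits, int& edits, int& wstart, int& wend,
                     std::vector<int>& ev_pos, std::vector<char>& ev_type,
                     std::vector<std::string>& ev_ref, std::vector<std::string>& ev_alt) {
  const int m = (int)read.size();
  const int n = (int)win.size();
  if (n == 0) return false;
  // states: 0 = M (diagonal), 1 = I (read base vs gap), 2 = D (ref base vs gap)
  std::vector<int> M((m + 1) * (n + 1)), I((m + 1) * (n + 1)), D((m + 1) * (n + 1));
  auto at = [&](int i, int j) { return i * (n + 1) + j; };
  for (int j = 0; j <= n; ++j) { M[at(0, j)] = 0; I[at(0, j)] = INF_COST; D[at(0, j)] = INF_COST; }
  for (int i = 1; i <= m; ++i) {
    M[at(i, 0)] = INF_COST; D[at(i, 0)] = INF_COST;
    I[at(i, 0)] = GAP_OPEN + GAP_EXT * (i - 1);
    for (int j = 1; j <= n; ++j) {
      int sub = (read[i - 1] == win[j - 1]) ? 0 : SUB_COST;
      int prev = std::min(M[at(i - 1, j - 1)],
                          std::min(I[at(i - 1, j - 1)], D[at(i - 1, j - 1)]));
      M[at(i, j)] = (prev >= INF_COST) ? INF_COST : prev + sub;
      int io = M[at(i - 1, j)] >= INF_COST ? INF_COST : M[at(i - 1, j)] + GAP_OPEN;
      int ie = I[at(i - 1, j)] >= INF_COST ? INF_COST : I[at(i - 1, j)] + GAP_EXT;
      I[at(i, j)] = std::min(io, ie);
      int dopen = M[at(i, j - 1)] >= INF_COST ? INF_COST : M[at(i, j - 1)] + GAP_OPEN;
      int de = D[at(i, j - 1)] >= INF_COST ? INF_COST : D[at(i, j - 1)] + GAP_EXT;
      D[at(i, j)] = std::min(dopen, de);
    }
  }
  // read must be fully aligned; ref end is free; do not end inside a ref gap
  int bj = -1, bstate = 0, bcost = INF_COST;
  for (int j = 0; j <= n; ++j) {
    if (M[at(m, j)] < bcost) { bcost = M[at(m, j)]; bj = j; bstate = 0; }
    if (I[at(m, j)] < bcost) { bcost = I[at(m, j)]; bj = j; bstate = 1; }
  }
  if (bj < 0 || bcost >= INF_COST) return false;
  wend = bj;
  // traceback
  int i = m, j = bj, st = bstate;
  std::vector<int> tpos; std::vector<char> ttyp;
  std::vector<std::string> tref, talt;
  std::string pend_ins, pend_del;
  int pend_ins_at = -1, pend_del_at = -1;
  int n_mm = 0, n_gap = 0;
  auto flush = [&]() {
    if (!pend_ins.empty()) {
      std::reverse(pend_ins.begin(), pend_ins.end());
      tpos.push_back(pend_ins_at); ttyp.push_back('I');
      tref.push_back(""); talt.push_back(pend_ins);
      pend_ins.clear();
    }
    if (!pend_del.empty()) {
      std::reverse(pend_del.begin(), pend_del.end());
      tpos.push_back(pend_del_at); ttyp.push_back('D');
      tref.push_back(pend_del); talt.push_back("");
      pend_del.clear();
    }
  };
  while (i > 0) {
    if (st == 0) {
      flush();
      if (read[i - 1] != win[j - 1]) {
        ++n_mm;
        tpos.push_back(j - 1); ttyp.push_back('X');
        tref.push_back(std::string(1, win[j - 1]));
        talt.push_back(std::string(1, read[i - 1]));
      }
      int sub = (read[i - 1] == win[j - 1]) ? 0 : SUB_COST;
      int want = M[at(i, j)] - sub;
      --i; --j;
      if (M[at(i, j)] == want) st = 0;
      else if (I[at(i, j)] == want) st = 1;
      else st = 2;
    } else if (st == 1) {
      if (!pend_del.empty()) flush();
      pend_ins.push_back(read[i - 1]); pend_ins_at = j;
      ++n_gap;
      int want_open = I[at(i, j)] - GAP_OPEN, want_ext = I[at(i, j)] - GAP_EXT;
      --i;
      if (I[at(i, j)] == want_ext) st = 1;
      else if (M[at(i, j)] == want_open) st = 0;
      else st = 1;
    } else {
      if (!pend_ins.empty()) flush();
      pend_del.push_back(win[j - 1]); pend_del_at = j - 1;
      ++n_gap;
      int want_open = D[at(i, j)] - GAP_OPEN, want_ext = D[at(i, j)] - GAP_EXT;
      --j;
      if (D[at(i, j)] == want_ext) st = 2;
      else if (M[at(i, j)] == want_open) st = 0;
      else st = 2;
    }
  }
  flush();
  wstart = j;
  edits = n_mm + n_gap;
  if (edits > max_edits) return false;
  // reverse event order to left-to-right
  for (int q = (int)tpos.size() - 1; q >= 0; --q) {
    ev_pos.push_back(tpos[q]); ev_type.push_back(ttyp[q]);
    ev_ref.push_back(tref[q]); ev_alt.push_back(talt[q]);
  }
  return true;
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, CharacterVector ref_seqs,
                   IntegerVector tag_lo, IntegerVector tag_hi,
                   LogicalVector is_special,
                   int k = 21, int max_edits = 6, int band = 8,
                   int ungapped_accept = 3) {
  const int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);

  SeedIndex idx; idx.k = k; idx.mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < nref; ++i) index_ref(idx, refs[i], i);

  std::vector<Hit> hits;
  const int nread = reads.size();

  for (int ri = 0; ri < nread; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    const int m = (int)fwd.size();
    if (m < k) continue;
    for (int strand = 0; strand < 2; ++strand) {
      std::string r = strand ? revcomp_str(fwd) : fwd;
      // seed offsets: five across the read
      std::vector<int> offs;
      for (int t = 0; t < 5; ++t) {
        int o = (int)((long long)t * (m - k) / 4);
        if (offs.empty() || o != offs.back()) offs.push_back(o);
      }
      // collect candidate (ref, diag)
      std::vector<std::pair<int,int>> cand;
      for (int o : offs) {
        uint64_t h = 0; bool ok = true;
        for (int q = 0; q < k; ++q) {
          int c = base2code(r[o + q]);
          if (c < 0) { ok = false; break; }
          h = (h << 2) | (uint64_t)c;
        }
        if (!ok) continue;
        auto it = idx.map.find(h & idx.mask);
        if (it == idx.map.end()) continue;
        for (auto& rp : it->second) cand.push_back(std::make_pair(rp.first, rp.second - o));
      }
      if (cand.empty()) continue;
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

      int last_ref = -1, last_pos = -1000000;
      for (auto& cd : cand) {
        int ref = cd.first, diag = cd.second;
        // suppress construct hits fully inside the shared tag interval
        if (!is_special[ref] && tag_lo[ref] >= 0 &&
            diag >= tag_lo[ref] + band && diag + m + band <= tag_hi[ref])
          continue;
        if (ref == last_ref && std::abs(diag - last_pos) <= band) continue;
        const std::string& R = refs[ref];
        const int rn = (int)R.size();
        int edits = -1, hstart = -1, hend = -1;
        std::vector<int> ev_pos; std::vector<char> ev_type;
        std::vector<std::string> ev_ref, ev_alt;
        bool got = false;
        if (diag >= 0 && diag + m <= rn) {
          int mm = 0;
          for (int q = 0; q < m && mm <= max_edits; ++q)
            if (r[q] != R[diag + q]) ++mm;
          if (mm <= ungapped_accept) {
            edits = mm; hstart = diag; hend = diag + m; got = true;
            for (int q = 0; q < m; ++q)
              if (r[q] != R[diag + q]) {
                ev_pos.push_back(diag + q); ev_type.push_back('X');
                ev_ref.push_back(std::string(1, R[diag + q]));
                ev_alt.push_back(std::string(1, r[q]));
              }
          }
        }
        if (!got) {
          int wlo = std::max(0, diag - band);
          int whi = std::min(rn, diag + m + band);
          if (whi - wlo >= m - band) {
            std::string win = R.substr(wlo, whi - wlo);
            int ws = 0, we = 0;
            if (dp_align(r, win, max_edits, edits, ws, we,
                         ev_pos, ev_type, ev_ref, ev_alt)) {
              hstart = wlo + ws; hend = wlo + we; got = true;
              for (auto& p : ev_pos) p += wlo;
            }
          }
        }
        if (!got) continue;
        last_ref = ref; last_pos = diag;
        Hit h;
        h.read = ri + 1; h.ref = ref + 1; h.pos = hstart;
        h.strand = strand ? -1 : 1; h.edits = edits; h.span = hend - hstart;
        h.ev_pos = std::move(ev_pos); h.ev_type = std::move(ev_type);
        h.ev_ref = std::move(ev_ref); h.ev_alt = std::move(ev_alt);
        hits.push_back(std::move(h));
      }
    }
  }

  // flatten
  const int nh = (int)hits.size();
  IntegerVector h_read(nh), h_ref(nh), h_pos(nh), h_strand(nh), h_edits(nh), h_span(nh);
  int nev = 0;
  for (auto& h : hits) nev += (int)h.ev_pos.size();
  IntegerVector e_hit(nev), e_pos(nev);
  CharacterVector e_type(nev), e_ref(nev), e_alt(nev);
  int ei = 0;
  for (int i = 0; i < nh; ++i) {
    const Hit& h = hits[i];
    h_read[i] = h.read; h_ref[i] = h.ref; h_pos[i] = h.pos;
    h_strand[i] = h.strand; h_edits[i] = h.edits; h_span[i] = h.span;
    for (size_t q = 0; q < h.ev_pos.size(); ++q) {
      e_hit[ei] = i + 1; e_pos[ei] = h.ev_pos[q];
      e_type[ei] = std::string(1, h.ev_type[q]);
      e_ref[ei] = h.ev_ref[q]; e_alt[ei] = h.ev_alt[q];
      ++ei;
    }
  }
  return List::create(
    _["hits"] = DataFrame::create(
      _["read"] = h_read, _["ref"] = h_ref, _["pos"] = h_pos,
      _["strand"] = h_strand, _["edits"] = h_edits, _["span"] = h_span,
      _["stringsAsFactors"] = false),
    _["events"] = DataFrame::create(
      _["hit"] = e_hit, _["pos"] = e_pos, _["type"] = e_type,
      _["ref"] = e_ref, _["alt"] = e_alt, _["stringsAsFactors"] = false));
}
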