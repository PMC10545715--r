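// Seed-and-extend read aligner with a glocal (read-global, reference-local)
// affine-gap DP, quality-scaled mismatch penalties, a linear score threshold
// f(L) = A + B*L, and optional SNP/indel-aware matching used by the final
// polished index.  Also houses the pileup accumulator used for variant calling.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static const int NEG = -100000000;

static inline int parse_int(const std::string &s) {
  int v = 0;
  for (size_t i = 0; i < s.size(); ++i)
    if (s[i] >= '0' && s[i] <= '9') v = v * 10 + (s[i] - '0');
  return v;
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct SeqIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > kmers;
  bool has_variants;
  // pos -> bitmask of additional bases accepted as match (bit 0=A,1=C,2=G,3=T)
  std::vector<std::unordered_map<int, int> > altmask;
  // registered deletions indexed by END position (exclusive): end -> starts
  std::vector<std::unordered_map<int, std::vector<int> > > del_by_end;
  // registered insertions: pos (number of ref bases before the insert) -> seqs
  std::vector<std::unordered_map<int, std::vector<std::string> > > ins_at;
  SeqIndex() : k(16), has_variants(false) {}
};

static void index_kmers(SeqIndex &ix) {
  ix.kmers.clear();
  const uint64_t mask = (ix.k >= 32) ? ~0ULL : ((1ULL << (2 * ix.k)) - 1);
  for (size_t s = 0; s < ix.seqs.size(); ++s) {
    const std::string &seq = ix.seqs[s];
    if ((int)seq.size() < ix.k) continue;  // unplaceable; caller warns
    uint64_t code = 0;
    int valid = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int b = base_code(seq[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= ix.k) {
        ix.kmers[code].push_back(std::make_pair((int)s, (int)(i + 1 - ix.k)));
      }
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 8 || k > 31) stop("seed length k must be in [8, 31]");
  SeqIndex *ix = new SeqIndex();
  ix->k = k;
  for (int i = 0; i < names.size(); ++i) {
    ix->names.push_back(as<std::string>(names[i]));
    ix->seqs.push_back(as<std::string>(seqs[i]));
  }
  ix->altmask.resize(ix->seqs.size());
  ix->del_by_end.resize(ix->seqs.size());
  ix->ins_at.resize(ix->seqs.size());
  index_kmers(*ix);
  XPtr<SeqIndex> ptr(ix, true);
  return ptr;
}

// [[Rcpp::export]]
void cpp_register_variants(SEXP idx,
                           IntegerVector snp_sid, IntegerVector snp_pos,
                           CharacterVector snp_alt,
                           IntegerVector del_sid, IntegerVector del_pos,
                           IntegerVector del_len,
                           IntegerVector ins_sid, IntegerVector ins_pos,
                           CharacterVector ins_seq) {
  XPtr<SeqIndex> ix(idx);
  for (int i = 0; i < snp_sid.size(); ++i) {
    std::string a = as<std::string>(snp_alt[i]);
    if (a.size() != 1) stop("SNP alternate must be a single base");
    int b = base_code(a[0]);
    if (b < 0) stop("SNP alternate must be A/C/G/T");
    ix->altmask[snp_sid[i]][snp_pos[i]] |= (1 << b);
  }
  for (int i = 0; i < del_sid.size(); ++i) {
    int p0 = del_pos[i], l = del_len[i];
    if (l < 1) stop("deletion length must be >= 1");
    ix->del_by_end[del_sid[i]][p0 + l].push_back(p0);
  }
  for (int i = 0; i < ins_sid.size(); ++i) {
    ix->ins_at[ins_sid[i]][ins_pos[i]].push_back(as<std::string>(ins_seq[i]));
  }
  ix->has_variants = snp_sid.size() > 0 || del_sid.size() > 0 ||
    ins_sid.size() > 0;
}

// [[Rcpp::export]]
IntegerVector cpp_lookup_kmer(SEXP idx, std::string kmer, int sid) {
  XPtr<SeqIndex> ix(idx);
  if ((int)kmer.size() != ix->k) stop("query length must equal seed length k");
  uint64_t code = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int b = base_code(kmer[i]);
    if (b < 0) return IntegerVector(0);
    code = (code << 2) | (uint64_t)b;
  }
  std::vector<int> out;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::iterator it =
    ix->kmers.find(code);
  if (it != ix->kmers.end()) {
    for (size_t j = 0; j < it->second.size(); ++j)
      if (it->second[j].first == sid) out.push_back(it->second[j].second);
  }
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// [[Rcpp::export]]
CharacterVector cpp_index_seqnames(SEXP idx) {
  XPtr<SeqIndex> ix(idx);
  return wrap(ix->names);
}

struct AlnParams {
  int mm_min, mm_max, gap_open, gap_extend;
  double A, B;
  int seed_step, pad;
};

static inline int mm_penalty(const AlnParams &p, int q) {
  if (q < 0) q = 40;
  if (q > 40) q = 40;
  return p.mm_min +
    (int)std::lround((double)(p.mm_max - p.mm_min) * q / 40.0);
}

struct DPResult {
  int best;
  std::vector<int> ends;  // window-local end columns achieving best
};

// Full-matrix Gotoh DP over one candidate window.  Matrices are kept by the
// caller so the winning window can be traced back without recomputation.
struct DPBuffers {
  std::vector<int> M, Ix, Iy, Bst;
  int m, w;
  inline int idx(int i, int j) const { return i * (w + 1) + j; }
};

static DPResult run_dp(const SeqIndex &ix, int sid, int ws, int we,
                       const std::string &rd, const std::string &qu,
                       const AlnParams &p, DPBuffers &bf) {
  const std::string &ref = ix.seqs[sid];
  int m = (int)rd.size(), w = we - ws;
  bf.m = m; bf.w = w;
  size_t n = (size_t)(m + 1) * (w + 1);
  bf.M.assign(n, NEG); bf.Ix.assign(n, NEG); bf.Iy.assign(n, NEG);
  bf.Bst.assign(n, NEG);
  for (int j = 0; j <= w; ++j) { bf.M[bf.idx(0, j)] = 0; bf.Bst[bf.idx(0, j)] = 0; }
  const int go = p.gap_open, ge = p.gap_extend;
  const bool hv = ix.has_variants;
  for (int i = 1; i <= m; ++i) {
    int rb = base_code(rd[i - 1]);
    int pen = mm_penalty(p, (int)qu[i - 1] - 33);
    for (int j = 0; j <= w; ++j) {
      int id = bf.idx(i, j), up = bf.idx(i - 1, j);
      // Ix: consume read base against a reference gap
      int ix1 = bf.Bst[up] == NEG ? NEG : bf.Bst[up] - go - ge;
      int ix2 = bf.Ix[up] == NEG ? NEG : bf.Ix[up] - ge;
      bf.Ix[id] = std::max(ix1, ix2);
      int best = bf.Ix[id];
      if (j >= 1) {
        int diag = bf.idx(i - 1, j - 1);
        int gb = base_code(ref[ws + j - 1]);
        int sub;
        if (rb >= 0 && rb == gb) sub = 0;
        else if (hv && rb >= 0) {
          std::unordered_map<int, int>::const_iterator am =
            ix.altmask[sid].find(ws + j - 1);
          sub = (am != ix.altmask[sid].end() && (am->second >> rb) & 1) ? 0 : -pen;
        } else sub = -pen;
        bf.M[id] = bf.Bst[diag] == NEG ? NEG : bf.Bst[diag] + sub;
        int lf = bf.idx(i, j - 1);
        int iy1 = bf.Bst[lf] == NEG ? NEG : bf.Bst[lf] - go - ge;
        int iy2 = bf.Iy[lf] == NEG ? NEG : bf.Iy[lf] - ge;
        bf.Iy[id] = std::max(iy1, iy2);
        best = std::max(best, std::max(bf.M[id], bf.Iy[id]));
      }
      if (hv) {
        // registered deletion ending at reference position ws + j
        std::unordered_map<int, std::vector<int> >::const_iterator de =
          ix.del_by_end[sid].find(ws + j);
        if (de != ix.del_by_end[sid].end()) {
          for (size_t t = 0; t < de->second.size(); ++t) {
            int c0 = de->second[t] - ws;
            if (c0 >= 0 && bf.Bst[bf.idx(i, c0)] > best)
              best = bf.Bst[bf.idx(i, c0)];
          }
        }
        // registered insertion located before reference position ws + j
        std::unordered_map<int, std::vector<std::string> >::const_iterator in =
          ix.ins_at[sid].find(ws + j);
        if (in != ix.ins_at[sid].end()) {
          for (size_t t = 0; t < in->second.size(); ++t) {
            int li = (int)in->second[t].size();
            if (li <= i && rd.compare(i - li, li, in->second[t]) == 0) {
              int v = bf.Bst[bf.idx(i - li, j)];
              if (v > best) best = v;
            }
          }
        }
      }
      bf.Bst[id] = best;
    }
  }
  DPResult res; res.best = NEG;
  for (int j = 0; j <= w; ++j) {
    int v = bf.Bst[bf.idx(m, j)];
    if (v > res.best) { res.best = v; res.ends.clear(); res.ends.push_back(j); }
    else if (v == res.best && v > NEG) res.ends.push_back(j);
  }
  return res;
}

// Trace the optimal path ending at window column je back to row 0.
// Returns CIGAR (MID ops, read-oriented) and the window-local start column.
static void traceback(const SeqIndex &ix, int sid, int ws,
                      const std::string &rd, DPBuffers &bf, int je,
                      std::string &cigar, int &start_col) {
  int i = bf.m, j = je;
  std::vector<std::pair<char, int> > ops;
  while (i > 0) {
    int v = bf.Bst[bf.idx(i, j)];
    bool moved = false;
    if (ix.has_variants) {
      std::unordered_map<int, std::vector<int> >::const_iterator de =
        ix.del_by_end[sid].find(ws + j);
      if (de != ix.del_by_end[sid].end()) {
        for (size_t t = 0; t < de->second.size() && !moved; ++t) {
          int c0 = de->second[t] - ws;
          if (c0 >= 0 && c0 < j && bf.Bst[bf.idx(i, c0)] == v) {
            ops.push_back(std::make_pair('D', j - c0));
            j = c0; moved = true;
          }
        }
      }
      if (!moved) {
        std::unordered_map<int, std::vector<std::string> >::const_iterator in =
          ix.ins_at[sid].find(ws + j);
        if (in != ix.ins_at[sid].end()) {
          for (size_t t = 0; t < in->second.size() && !moved; ++t) {
            int li = (int)in->second[t].size();
            if (li <= i && li > 0 && rd.compare(i - li, li, in->second[t]) == 0 &&
                bf.Bst[bf.idx(i - li, j)] == v) {
              ops.push_back(std::make_pair('I', li));
              i -= li; moved = true;
            }
          }
        }
      }
    }
    if (moved) continue;
    if (j >= 1 && bf.M[bf.idx(i, j)] == v) {
      ops.push_back(std::make_pair('M', 1)); --i; --j;
    } else if (bf.Ix[bf.idx(i, j)] == v) {
      ops.push_back(std::make_pair('I', 1)); --i;
    } else if (j >= 1 && bf.Iy[bf.idx(i, j)] == v) {
      ops.push_back(std::make_pair('D', 1)); --j;
    } else {
      stop("internal error: alignment traceback failed");
    }
  }
  start_col = j;
  // compress reversed ops into a CIGAR string
  std::string out;
  int run = 0; char cur = 0;
  for (int t = (int)ops.size() - 1; t >= 0; --t) {
    if (ops[t].first == cur) run += ops[t].second;
    else {
      if (run > 0) { out += std::to_string(run); out += cur; }
      cur = ops[t].first; run = ops[t].second;
    }
  }
  if (run > 0) { out += std::to_string(run); out += cur; }
  cigar = out;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': case 'a': r[i] = 'T'; break;
    case 'C': case 'c': r[i] = 'G'; break;
    case 'G': case 'g': r[i] = 'C'; break;
    case 'T': case 't': r[i] = 'A'; break;
    default: r[i] = 'N';
    }
  }
  return r;
}

// Rolling-row score-only Gotoh DP over one window (no traceback state, no
// variant awareness; variant-aware windows go through the full-matrix DP).
static DPResult run_dp_score(const SeqIndex &ix, int sid, int ws, int we,
                             const std::string &rd, const std::string &qu,
                             const AlnParams &p) {
  const std::string &ref = ix.seqs[sid];
  const int m = (int)rd.size(), w = we - ws;
  const int goe = p.gap_open + p.gap_extend, ge = p.gap_extend;
  static thread_local std::vector<int> best_prev, ix_prev, best_cur, ix_cur;
  static thread_local std::vector<signed char> gcode;
  best_prev.assign(w + 1, 0);
  ix_prev.assign(w + 1, NEG);
  best_cur.resize(w + 1); ix_cur.resize(w + 1);
  gcode.resize(w > 0 ? w : 1);
  for (int j = 0; j < w; ++j) gcode[j] = (signed char)base_code(ref[ws + j]);
  for (int i = 1; i <= m; ++i) {
    const int rb = base_code(rd[i - 1]);
    const int pen = mm_penalty(p, (int)qu[i - 1] - 33);
    int ixv = std::max(best_prev[0] - goe, ix_prev[0] - ge);
    ix_cur[0] = ixv;
    best_cur[0] = ixv;
    int iy_left = NEG;
    const int *bp = best_prev.data();
    const int *ip = ix_prev.data();
    for (int j = 1; j <= w; ++j) {
      const int sub = (rb >= 0 && rb == gcode[j - 1]) ? 0 : -pen;
      const int mv = bp[j - 1] + sub;
      const int ixn = std::max(bp[j] - goe, ip[j] - ge);
      const int iyn = std::max(best_cur[j - 1] - goe, iy_left - ge);
      int b = mv > ixn ? mv : ixn;
      if (iyn > b) b = iyn;
      ix_cur[j] = ixn;
      best_cur[j] = b;
      iy_left = iyn;
    }
    best_prev.swap(best_cur);
    ix_prev.swap(ix_cur);
  }
  DPResult res; res.best = NEG;
  for (int j = 0; j <= w; ++j) {
    int v = best_prev[j];
    if (v > res.best) { res.best = v; res.ends.clear(); res.ends.push_back(j); }
    else if (v == res.best && v > NEG) res.ends.push_back(j);
  }
  return res;
}

struct Candidate { int sid; int strand; int dmin; int dmax; };
struct Locus { int sid; int strand; int endpos; };

// [[Rcpp::export]]
List cpp_align(SEXP idx, CharacterVector reads, CharacterVector quals,
               List params, bool want_cigar) {
  XPtr<SeqIndex> ix(idx);
  AlnParams p;
  p.mm_min = as<int>(params["mismatch_min"]);
  p.mm_max = as<int>(params["mismatch_max"]);
  p.gap_open = as<int>(params["gap_open"]);
  p.gap_extend = as<int>(params["gap_extend"]);
  p.A = as<double>(params["score_A"]);
  p.B = as<double>(params["score_B"]);
  p.seed_step = as<int>(params["seed_step"]);
  p.pad = as<int>(params["pad"]);
  const int k = ix->k;
  int n = reads.size();
  LogicalVector mapped(n);
  IntegerVector sid_out(n), pos_out(n), nloci(n), score_out(n);
  CharacterVector strand_out(n), cigar_out(n);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  DPBuffers bf;
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string qu = quals[r] == NA_STRING ? std::string(fwd.size(), 'I')
      : as<std::string>(quals[r]);
    if (qu.size() != fwd.size()) qu.assign(fwd.size(), 'I');
    int m = (int)fwd.size();
    mapped[r] = false; sid_out[r] = NA_INTEGER; pos_out[r] = NA_INTEGER;
    nloci[r] = 0; score_out[r] = NA_INTEGER;
    strand_out[r] = NA_STRING; cigar_out[r] = NA_STRING;
    if (m < k) continue;
    std::string rev = revcomp(fwd);
    std::string rqu(qu.rbegin(), qu.rend());
    // ---- seeding on both strands ----
    std::vector<std::vector<std::pair<int, int> > > diags(2);  // (sid, diag)
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &s = strand == 0 ? fwd : rev;
      int step = std::max(1, p.seed_step);
      for (int off = 0; off <= m - k; off += step) {
        uint64_t code = 0; bool ok = true;
        for (int t = 0; t < k; ++t) {
          int b = base_code(s[off + t]);
          if (b < 0) { ok = false; break; }
          code = ((code << 2) | (uint64_t)b) & mask;
        }
        if (!ok) continue;
        std::unordered_map<uint64_t,
          std::vector<std::pair<int, int> > >::const_iterator it =
          ix->kmers.find(code);
        if (it == ix->kmers.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h)
          diags[strand].push_back(std::make_pair(it->second[h].first,
                                                 it->second[h].second - off));
        if (off + step > m - k && off != m - k) off = m - k - step;  // tail seed
      }
    }
    // ---- cluster seed diagonals into candidate windows ----
    std::vector<Candidate> cands;
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<std::pair<int, int> > &d = diags[strand];
      if (d.empty()) continue;
      std::sort(d.begin(), d.end());
      int cs = d[0].first, dmin = d[0].second, dmax = d[0].second;
      for (size_t t = 1; t <= d.size(); ++t) {
        if (t < d.size() && d[t].first == cs && d[t].second - dmax <= p.pad) {
          dmax = d[t].second;
        } else {
          Candidate c; c.sid = cs; c.strand = strand;
          c.dmin = dmin; c.dmax = dmax;
          cands.push_back(c);
          if (t < d.size()) { cs = d[t].first; dmin = dmax = d[t].second; }
        }
      }
    }
    if (cands.empty()) continue;
    // ---- fast path: with match score 0 an exact end-to-end hit is optimal
    if (!ix->has_variants) {
      std::vector<Locus> exact;
      for (int strand = 0; strand < 2; ++strand) {
        const std::string &s = strand == 0 ? fwd : rev;
        int psid = -1, pd = -1000000;
        for (size_t t = 0; t < diags[strand].size(); ++t) {
          int esid = diags[strand][t].first, d = diags[strand][t].second;
          if (esid == psid && d == pd) continue;  // already tested
          psid = esid; pd = d;
          if (d < 0 || d + m > (int)ix->seqs[esid].size()) continue;
          if (ix->seqs[esid].compare(d, m, s) == 0) {
            Locus lc; lc.sid = esid; lc.strand = strand; lc.endpos = d + m;
            exact.push_back(lc);
          }
        }
      }
      if (!exact.empty()) {
        std::sort(exact.begin(), exact.end(),
                  [](const Locus &a, const Locus &b) {
                    if (a.sid != b.sid) return a.sid < b.sid;
                    if (a.endpos != b.endpos) return a.endpos < b.endpos;
                    return a.strand < b.strand;
                  });
        int count = 0, last_sid = -1, last_strand = -1, last_end = -1000000;
        for (size_t t = 0; t < exact.size(); ++t) {
          if (exact[t].sid != last_sid || exact[t].strand != last_strand ||
              exact[t].endpos - last_end > m / 2) ++count;
          last_sid = exact[t].sid; last_strand = exact[t].strand;
          last_end = exact[t].endpos;
        }
        nloci[r] = count;
        score_out[r] = 0;
        mapped[r] = true;
        sid_out[r] = exact[0].sid;
        strand_out[r] = exact[0].strand == 0 ? "+" : "-";
        pos_out[r] = exact[0].endpos - m;
        if (want_cigar) cigar_out[r] = std::to_string(m) + "M";
        continue;
      }
    }
    // ---- evaluate candidates ----
    const bool hv = ix->has_variants;
    int gbest = NEG;
    std::vector<std::pair<Locus, int> > loci;  // locus, score
    int best_c = -1, best_je = -1, best_ws = 0, bf_holds = -1;
    for (size_t c = 0; c < cands.size(); ++c) {
      const Candidate &cd = cands[c];
      int L = (int)ix->seqs[cd.sid].size();
      int ws = std::max(0, cd.dmin - p.pad);
      int we = std::min(L, cd.dmax + m + p.pad);
      if (we - ws < 1) continue;
      const std::string &rd = cd.strand == 0 ? fwd : rev;
      const std::string &qv = cd.strand == 0 ? qu : rqu;
      DPResult res;
      if (hv) {
        res = run_dp(*ix, cd.sid, ws, we, rd, qv, p, bf);
        bf_holds = (int)c;
      } else {
        res = run_dp_score(*ix, cd.sid, ws, we, rd, qv, p);
      }
      if (res.best <= NEG) continue;
      for (size_t e = 0; e < res.ends.size(); ++e) {
        Locus lc; lc.sid = cd.sid; lc.strand = cd.strand;
        lc.endpos = ws + res.ends[e];
        loci.push_back(std::make_pair(lc, res.best));
      }
      if (res.best > gbest) {
        gbest = res.best; best_c = (int)c; best_je = res.ends[0]; best_ws = ws;
      } else if (res.best == gbest && best_c >= 0) {
        // deterministic preference: smaller sid, then position, then + strand
        Locus cur; cur.sid = cd.sid; cur.strand = cd.strand;
        cur.endpos = ws + res.ends[0];
        Locus old; old.sid = cands[best_c].sid; old.strand = cands[best_c].strand;
        old.endpos = best_ws + best_je;
        if (cur.sid < old.sid ||
            (cur.sid == old.sid && cur.endpos < old.endpos) ||
            (cur.sid == old.sid && cur.endpos == old.endpos &&
             cur.strand < old.strand)) {
          best_c = (int)c; best_je = res.ends[0]; best_ws = ws;
        }
      }
    }
    if (gbest <= NEG) continue;
    // ---- count distinct loci achieving the global best ----
    std::vector<Locus> at_best;
    for (size_t t = 0; t < loci.size(); ++t)
      if (loci[t].second == gbest) at_best.push_back(loci[t].first);
    std::sort(at_best.begin(), at_best.end(),
              [](const Locus &a, const Locus &b) {
                if (a.sid != b.sid) return a.sid < b.sid;
                if (a.strand != b.strand) return a.strand < b.strand;
                return a.endpos < b.endpos;
              });
    int count = 0, last_sid = -1, last_strand = -1, last_end = -1000000;
    for (size_t t = 0; t < at_best.size(); ++t) {
      const Locus &lc = at_best[t];
      if (lc.sid != last_sid || lc.strand != last_strand ||
          lc.endpos - last_end > m / 2) ++count;
      last_sid = lc.sid; last_strand = lc.strand; last_end = lc.endpos;
    }
    nloci[r] = count;
    score_out[r] = gbest;
    double thr = p.A + p.B * m;
    if ((double)gbest + 1e-9 < thr) continue;  // below score threshold
    mapped[r] = true;
    const Candidate &cd = cands[best_c];
    sid_out[r] = cd.sid;
    strand_out[r] = cd.strand == 0 ? "+" : "-";
    if (want_cigar) {
      const std::string &rd = cd.strand == 0 ? fwd : rev;
      const std::string &qv = cd.strand == 0 ? qu : rqu;
      int L = (int)ix->seqs[cd.sid].size();
      int ws = std::max(0, cd.dmin - p.pad);
      int we = std::min(L, cd.dmax + m + p.pad);
      if (bf_holds != best_c) run_dp(*ix, cd.sid, ws, we, rd, qv, p, bf);
      std::string cg; int sc;
      traceback(*ix, cd.sid, ws, rd, bf, best_je, cg, sc);
      cigar_out[r] = cg;
      pos_out[r] = ws + sc;
    } else {
      pos_out[r] = best_ws + best_je - m;  // approximate leftmost (no gaps)
      if (pos_out[r] < 0) pos_out[r] = 0;
    }
  }
  return List::create(_["mapped"] = mapped, _["sid"] = sid_out,
                      _["pos"] = pos_out, _["strand"] = strand_out,
                      _["score"] = score_out, _["n_loci"] = nloci,
                      _["cigar"] = cigar_out);
}

// ---------------------------------------------------------------------------
// Pileup: project aligned reads through their CIGAR strings onto the genome,
// accumulating per-site base counts and per-genotype log-likelihoods under an
// independent-error model (P(base wrong) = 10^(-Q/10), uniform over the three
// other bases), plus indel evidence keyed to the left anchor site.
// [[Rcpp::export]]
List cpp_pileup(CharacterVector genome_seqs,
                IntegerVector sid, IntegerVector pos, CharacterVector cigar,
                CharacterVector rdseq, CharacterVector rdqual,
                int end_prox) {
  int nseq = genome_seqs.size();
  std::vector<int> lens(nseq);
  std::vector<std::string> refs(nseq);
  for (int s = 0; s < nseq; ++s) {
    refs[s] = as<std::string>(genome_seqs[s]);
    lens[s] = (int)refs[s].size();
  }
  std::vector<std::vector<int> > counts(nseq), internal(nseq);
  std::vector<std::vector<double> > loglik(nseq);
  for (int s = 0; s < nseq; ++s) {
    counts[s].assign((size_t)lens[s] * 4, 0);
    internal[s].assign((size_t)lens[s] * 4, 0);
    loglik[s].assign((size_t)lens[s] * 4, 0.0);
  }
  std::unordered_map<std::string, int> ins_ev, del_ev;
  int n = sid.size();
  for (int r = 0; r < n; ++r) {
    if (sid[r] == NA_INTEGER) continue;
    int s = sid[r];
    if (s < 0 || s >= nseq) stop("alignment references unknown sequence id");
    std::string cg = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(rdseq[r]);
    std::string qv = as<std::string>(rdqual[r]);
    int gp = pos[r], rp = 0;
    size_t ci = 0;
    while (ci < cg.size()) {
      int len = 0;
      while (ci < cg.size() && isdigit(cg[ci])) { len = len * 10 + (cg[ci] - '0'); ++ci; }
      if (ci >= cg.size()) stop("malformed CIGAR");
      char op = cg[ci++];
      if (op == 'M' || op == '=' || op == 'X') {
        int rl = (int)sq.size();
        for (int t = 0; t < len; ++t) {
          int b = base_code(sq[rp]);
          if (b >= 0 && gp >= 0 && gp < lens[s]) {
            int q = (int)qv[rp] - 33;
            if (q < 2) q = 2;
            double e = std::pow(10.0, -q / 10.0);
            if (e > 0.75) e = 0.75;
            counts[s][(size_t)gp * 4 + b] += 1;
            // read-internal observations: at least end_prox bases from
            // both read ends (guards against junction-overhang artifacts)
            if (rp >= end_prox && rl - 1 - rp >= end_prox)
              internal[s][(size_t)gp * 4 + b] += 1;
            double lmatch = std::log(1.0 - e), lmis = std::log(e / 3.0);
            for (int g = 0; g < 4; ++g)
              loglik[s][(size_t)gp * 4 + g] += (g == b) ? lmatch : lmis;
          }
          ++gp; ++rp;
        }
      } else if (op == 'I') {
        std::string inserted = sq.substr(rp, len);
        std::string key = std::to_string(s) + ":" + std::to_string(gp) + ":" + inserted;
        ins_ev[key] += 1;
        rp += len;
      } else if (op == 'D') {
        std::string key = std::to_string(s) + ":" + std::to_string(gp) + ":" +
          std::to_string(len);
        del_ev[key] += 1;
        gp += len;
      } else stop("unsupported CIGAR op");
    }
  }
  // emit covered sites
  std::vector<int> o_sid, o_pos, o_depth;
  std::vector<int> o_counts, o_int;  // 4 per site
  std::vector<double> o_ll;          // 4 per site
  std::vector<char> o_ref;
  for (int s = 0; s < nseq; ++s) {
    for (int ppos = 0; ppos < lens[s]; ++ppos) {
      int d = 0;
      for (int g = 0; g < 4; ++g) d += counts[s][(size_t)ppos * 4 + g];
      if (d == 0) continue;
      o_sid.push_back(s); o_pos.push_back(ppos); o_depth.push_back(d);
      o_ref.push_back(refs[s][ppos]);
      for (int g = 0; g < 4; ++g) {
        o_counts.push_back(counts[s][(size_t)ppos * 4 + g]);
        o_int.push_back(internal[s][(size_t)ppos * 4 + g]);
        o_ll.push_back(loglik[s][(size_t)ppos * 4 + g]);
      }
    }
  }
  int ns = (int)o_sid.size();
  IntegerMatrix cm(ns, 4), im(ns, 4);
  NumericMatrix lm(ns, 4);
  CharacterVector refb(ns);
  for (int i = 0; i < ns; ++i) {
    for (int g = 0; g < 4; ++g) {
      cm(i, g) = o_counts[i * 4 + g];
      im(i, g) = o_int[i * 4 + g];
      lm(i, g) = o_ll[i * 4 + g];
    }
    refb[i] = std::string(1, o_ref[i]);
  }
  // indel evidence tables
  std::vector<int> i_sid, i_pos, i_n; std::vector<std::string> i_seq;
  for (std::unordered_map<std::string, int>::iterator it = ins_ev.begin();
       it != ins_ev.end(); ++it) {
    size_t a = it->first.find(':'), b = it->first.find(':', a + 1);
    i_sid.push_back(parse_int(it->first.substr(0, a)));
    i_pos.push_back(parse_int(it->first.substr(a + 1, b - a - 1)));
    i_seq.push_back(it->first.substr(b + 1));
    i_n.push_back(it->second);
  }
  std::vector<int> d_sid, d_pos, d_len, d_n;
  for (std::unordered_map<std::string, int>::iterator it = del_ev.begin();
       it != del_ev.end(); ++it) {
    size_t a = it->first.find(':'), b = it->first.find(':', a + 1);
    d_sid.push_back(parse_int(it->first.substr(0, a)));
    d_pos.push_back(parse_int(it->first.substr(a + 1, b - a - 1)));
    d_len.push_back(parse_int(it->first.substr(b + 1)));
    d_n.push_back(it->second);
  }
  return List::create(
    _["sid"] = wrap(o_sid), _["pos"] = wrap(o_pos), _["ref"] = refb,
    _["depth"] = wrap(o_depth), _["counts"] = cm, _["internal"] = im,
    _["loglik"] = lm,
    _["ins_sid"] = wrap(i_sid), _["ins_pos"] = wrap(i_pos),
    _["ins_seq"] = wrap(i_seq), _["ins_n"] = wrap(i_n),
    _["del_sid"] = wrap(d_sid), _["del_pos"] = wrap(d_pos),
    _["del_len"] = wrap(d_len), _["del_n"] = wrap(d_n));
}
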