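#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// k-mer hash index over the forward strand of a genome; minus-strand hits are
// found by looking up the reverse complement of the query. Replaces an
// FM-index engine with the same contract: lookup(kmer) returns exactly the
// occurrence positions on both strands.

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  std::unordered_map<uint64_t, std::vector<uint64_t>> map; // code -> (seq<<32|pos)
};

static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) { case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A'; }
  return 'N';
}

static bool encode_kmer(const std::string& s, size_t at, int k, uint64_t& code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[at + i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    out[i] = revcomp_str(s);
  }
  return out;
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector seqs, int k) {
  if (k < 8 || k > 31) stop("k must be between 8 and 31");
  XPtr<KmerIndex> xp(new KmerIndex(), true);
  xp->k = k;
  CharacterVector nm = seqs.names();
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) stop("all sequences must be at least k long");
    xp->seqs.push_back(s);
    xp->names.push_back(nm.size() ? as<std::string>(nm[i]) : std::to_string(i + 1));
    uint64_t code;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      if (encode_kmer(s, p, k, code))
        xp->map[code].push_back(((uint64_t)i << 32) | (uint64_t)p);
    }
  }
  return xp;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp_) { return XPtr<KmerIndex>(xp_)->k; }

// [[Rcpp::export]]
CharacterVector cpp_index_names(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  return wrap(xp->names);
}

// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP xp_, CharacterVector kmers) {
  XPtr<KmerIndex> xp(xp_);
  std::vector<int> q, seq, pos;
  std::vector<std::string> strand;
  for (int i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    if ((int)km.size() != xp->k) stop("k-mer length must equal index k");
    uint64_t code;
    if (encode_kmer(km, 0, xp->k, code)) {
      auto it = xp->map.find(code);
      if (it != xp->map.end())
        for (uint64_t e : it->second) {
          q.push_back(i + 1); seq.push_back((int)(e >> 32) + 1);
          pos.push_back((int)(e & 0xffffffffULL)); strand.push_back("+");
        }
    }
    std::string rc = revcomp_str(km);
    if (rc != km && encode_kmer(rc, 0, xp->k, code)) {
      auto it = xp->map.find(code);
      if (it != xp->map.end())
        for (uint64_t e : it->second) {
          q.push_back(i + 1); seq.push_back((int)(e >> 32) + 1);
          pos.push_back((int)(e & 0xffffffffULL)); strand.push_back("-");
        }
    } else if (rc == km) {
      // palindromic k-mer: forward occurrences double as minus-strand hits
      if (encode_kmer(km, 0, xp->k, code)) {
        auto it = xp->map.find(code);
        if (it != xp->map.end())
          for (uint64_t e : it->second) {
            q.push_back(i + 1); seq.push_back((int)(e >> 32) + 1);
            pos.push_back((int)(e & 0xffffffffULL)); strand.push_back("-");
          }
      }
    }
  }
  return DataFrame::create(_["query"] = q, _["seq"] = seq, _["pos"] = pos,
                           _["strand"] = strand, _["stringsAsFactors"] = false);
}

static inline int hamming_at(const std::string& g, size_t pos, const std::string& q,
                             size_t qfrom, size_t qlen, int cap) {
  if (pos + qlen > g.size()) return cap + 1;
  int mm = 0;
  for (size_t i = 0; i < qlen; ++i) {
    if (g[pos + i] != q[qfrom + i]) { if (++mm > cap) return mm; }
  }
  return mm;
}

// [[Rcpp::export]]
int cpp_mismatch_count(SEXP xp_, int seq_idx, int pos, std::string s, int cap) {
  XPtr<KmerIndex> xp(xp_);
  const std::string& g = xp->seqs[seq_idx - 1];
  if (pos < 0 || pos + (int)s.size() > (int)g.size()) return cap + 1;
  return hamming_at(g, (size_t)pos, s, 0, s.size(), cap);
}

// Full-length ungapped placement of queries by pigeonhole seeding + Hamming
// verification. Seeds are taken at offsets 0, k, 2k, ... and L-k; with
// k <= floor(L/(max_mismatch+1)) this is exhaustive for <= max_mismatch
// substitutions. Both strands are searched (the query's reverse complement is
// placed on the forward genome and reported with strand "-").
// [[Rcpp::export]]
DataFrame cpp_place(SEXP xp_, CharacterVector queries, int max_mismatch, int max_hits) {
  XPtr<KmerIndex> xp(xp_);
  const int k = xp->k;
  std::vector<int> out_q, out_seq, out_pos, out_mm;
  std::vector<std::string> out_strand;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    const int L = (int)fwd.size();
    if (L < k) stop("query shorter than index k");
    std::vector<std::tuple<int,int,int,int>> hits; // mm, seq, pos, strand(0/1)
    for (int sidx = 0; sidx < 2; ++sidx) {
      std::string q = sidx == 0 ? fwd : revcomp_str(fwd);
      std::vector<int> offs;
      for (int o = 0; o + k <= L; o += k) offs.push_back(o);
      if (offs.empty() || offs.back() != L - k) offs.push_back(L - k);
      std::vector<uint64_t> seen;
      for (int o : offs) {
        uint64_t code;
        if (!encode_kmer(q, o, k, code)) continue;
        auto it = xp->map.find(code);
        if (it == xp->map.end()) continue;
        for (uint64_t e : it->second) {
          int seq = (int)(e >> 32);
          long p = (long)(e & 0xffffffffULL) - o;
          if (p < 0) continue;
          uint64_t key = ((uint64_t)seq << 32) | (uint64_t)p;
          bool dup = false;
          for (uint64_t s : seen) if (s == key) { dup = true; break; }
          if (dup) continue;
          seen.push_back(key);
          int mm = hamming_at(xp->seqs[seq], (size_t)p, q, 0, q.size(), max_mismatch);
          if (mm <= max_mismatch)
            hits.emplace_back(mm, seq + 1, (int)p, sidx);
        }
      }
    }
    std::sort(hits.begin(), hits.end());
    int n = std::min((int)hits.size(), max_hits);
    for (int i = 0; i < n; ++i) {
      out_q.push_back(qi + 1);
      out_mm.push_back(std::get<0>(hits[i]));
      out_seq.push_back(std::get<1>(hits[i]));
      out_pos.push_back(std::get<2>(hits[i]));
      out_strand.push_back(std::get<3>(hits[i]) == 0 ? "+" : "-");
    }
  }
  return DataFrame::create(_["query"] = out_q, _["seq"] = out_seq, _["pos"] = out_pos,
                           _["strand"] = out_strand, _["mismatches"] = out_mm,
                           _["stringsAsFactors"] = false);
}

// intron terminal dinucleotide classes; cls 1..3 = GT-AG, GC-AG, AT-AC on the
// junction's + strand, 4..6 the same classes observed reverse-complemented
// (junction on the - strand of the forward genome)
static int dinuc_class(const std::string& g, int istart, int iend) {
  char a = g[istart], b = g[istart + 1], c = g[iend - 2], d = g[iend - 1];
  if (a == 'G' && b == 'T' && c == 'A' && d == 'G') return 1;
  if (a == 'G' && b == 'C' && c == 'A' && d == 'G') return 2;
  if (a == 'A' && b == 'T' && c == 'A' && d == 'C') return 3;
  if (a == 'C' && b == 'T' && c == 'A' && d == 'C') return 4;
  if (a == 'C' && b == 'T' && c == 'G' && d == 'C') return 5;
  if (a == 'G' && b == 'T' && c == 'A' && d == 'T') return 6;
  return 0;
}

struct GapHit { int j, istart, ilen, mm, cls; };

// ---- PSFM scoring (used only for tie-breaking between equal-mismatch
// ---- intron placements; mirrors the R scoring of splice-site windows)

struct PsfmC {
  int order = 0, width = 0;
  std::vector<double> marg;  // 4 x width, [base + 4*pos]
  std::vector<double> cond;  // 4 x 4 x width, [prev + 4*cur + 16*pos]
};

static PsfmC psfm_from_list(List li) {
  PsfmC p;
  p.order = as<int>(li["order"]);
  p.width = as<int>(li["width"]);
  NumericVector m = li["marg"];
  p.marg.assign(m.begin(), m.end());
  if (p.order == 1) {
    NumericVector c = li["cond"];
    p.cond.assign(c.begin(), c.end());
  }
  return p;
}

static double psfm_log2ratio(const std::string& w, const PsfmC& p, const double* bg) {
  double lp = 0, lbg = 0;
  int prev = -1;
  for (int j = 0; j < p.width; ++j) {
    int b = base_code(w[j]);
    if (b < 0) { prev = -1; continue; }  // N: background on both sides, net 0
    double pr;
    if (j == 0 || p.order == 0 || prev < 0) pr = p.marg[b + 4 * j];
    else pr = p.cond[prev + 4 * b + 16 * j];
    lp += std::log2(pr);
    lbg += std::log2(bg[b]);
    prev = b;
  }
  return lp - lbg;
}

// donor+acceptor score of intron [is, ie); class > 3 means the junction lies
// on the minus strand and windows are reverse-complemented
static double intron_score(const std::string& g, int is, int ie, int cls,
                           const PsfmC& donor, const PsfmC& acceptor, const double* bg) {
  const int glen = (int)g.size();
  std::string dw, aw;
  if (cls <= 3) {
    if (is - 3 < 0 || is + 6 > glen || ie - 20 < 0 || ie + 1 > glen) return -1e9;
    dw = g.substr(is - 3, 9);
    aw = g.substr(ie - 20, 21);
  } else {
    if (ie + 3 > glen || ie - 6 < 0 || is - 1 < 0 || is + 20 > glen) return -1e9;
    dw = revcomp_str(g.substr(ie - 6, 9));
    aw = revcomp_str(g.substr(is - 1, 21));
  }
  return psfm_log2ratio(dw, donor, bg) + psfm_log2ratio(aw, acceptor, bg);
}

static void collect_hits(std::vector<GapHit>& hits, int j, int istart, int ilen,
                         int mm, int cls, int& best_mm) {
  if (mm < best_mm) { hits.clear(); best_mm = mm; }
  if (mm == best_mm) hits.push_back({j, istart, ilen, mm, cls});
}

static DataFrame gap_hits_df(const std::vector<GapHit>& hits) {
  std::vector<int> j, is, il, mm, cls;
  for (const auto& h : hits) {
    j.push_back(h.j); is.push_back(h.istart); il.push_back(h.ilen);
    mm.push_back(h.mm); cls.push_back(h.cls);
  }
  return DataFrame::create(_["split"] = j, _["intron_start"] = is, _["intron_len"] = il,
                           _["mismatches"] = mm, _["class"] = cls);
}

// Internal anchor gap: gap string must occupy [gl, gr) around one intron of
// fixed length D = (gr-gl) - m. Returns the minimum-mismatch candidate set.
// left_ctx / right_ctx are exonic lengths already aligned on each side; the
// resulting flanking blocks (ctx + piece) must each reach min_overhang.
static std::vector<GapHit> search_gap_internal(const std::string& g, const std::string& gap,
                                               int gl, int gr, int max_mm, int left_ctx,
                                               int right_ctx, int min_overhang,
                                               bool allow_semi) {
  const int m = (int)gap.size();
  const int D = (gr - gl) - m;
  std::vector<GapHit> hits;
  int best = max_mm;
  if (D >= 4 && gl >= 0 && gr <= (int)g.size()) {
    for (int j = 0; j <= m; ++j) {
      if (left_ctx + j < min_overhang) continue;
      if (right_ctx + (m - j) < min_overhang) continue;
      int is = gl + j, ie = is + D;
      int cls = dinuc_class(g, is, ie);
      if (cls == 0 || (!allow_semi && cls != 1 && cls != 4)) continue;
      int mm = hamming_at(g, gl, gap, 0, (size_t)j, best);
      if (mm > best) continue;
      mm += hamming_at(g, (size_t)ie, gap, (size_t)j, (size_t)(m - j), best - mm);
      if (mm <= best) collect_hits(hits, j, is, D, mm, cls, best);
    }
  }
  return hits;
}

// [[Rcpp::export]]
DataFrame cpp_search_gap(SEXP xp_, int seq_idx, std::string gap, int gl, int gr,
                         int max_mm, int left_ctx, int right_ctx, int min_overhang,
                         bool allow_semi) {
  XPtr<KmerIndex> xp(xp_);
  return gap_hits_df(search_gap_internal(xp->seqs[seq_idx - 1], gap, gl, gr, max_mm,
                                         left_ctx, right_ctx, min_overhang, allow_semi));
}

// dinucleotide codes used by the edge search: intron starts can be
// GT, GC, AT, CT; intron ends can be AG, AC, GC, AT
static inline int start_code(char a, char b) {
  if (a == 'G' && b == 'T') return 0;
  if (a == 'G' && b == 'C') return 1;
  if (a == 'A' && b == 'T') return 2;
  if (a == 'C' && b == 'T') return 3;
  return -1;
}
static inline int end_code(char a, char b) {
  if (a == 'A' && b == 'G') return 0;
  if (a == 'A' && b == 'C') return 1;
  if (a == 'G' && b == 'C') return 2;
  if (a == 'A' && b == 'T') return 3;
  return -1;
}
// class for (start_code, end_code), 0 if not a valid pairing
static const int PAIR_CLASS[4][4] = {
  // end:  AG AC GC AT          start:
  {1, 0, 0, 6},               // GT
  {2, 0, 0, 0},               // GC
  {0, 3, 0, 0},               // AT
  {0, 4, 5, 0}                // CT
};

// Edge gap: only one side is anchored. side = 1: gap is a read prefix ending
// at genome position anchor_pos (right anchor); side = 2: gap is a read
// suffix starting at anchor_pos (left anchor). The intron length is free over
// [min_intron, max_intron); candidate positions are found by pre-indexing
// splice dinucleotides in the search window. Returns the minimum-mismatch
// candidate set.
static std::vector<GapHit> search_edge_internal(const std::string& g, const std::string& gap,
                                                int side, int anchor_pos, int min_intron,
                                                int max_intron, int max_mm, int ctx,
                                                int min_overhang, bool allow_semi) {
  const int m = (int)gap.size();
  const int glen = (int)g.size();
  std::vector<GapHit> hits;
  int best = max_mm;

  // index dinucleotide positions in the window the intron can occupy
  int wlo, whi; // dinucleotide start positions scanned: [wlo, whi)
  if (side == 1) { wlo = std::max(0, anchor_pos - max_intron - m); whi = anchor_pos; }
  else { wlo = anchor_pos; whi = std::min(glen - 1, anchor_pos + max_intron + m); }
  std::vector<int> starts[4], ends[4];
  for (int p = wlo; p < whi; ++p) {
    int sc = start_code(g[p], g[p + 1]);
    if (sc >= 0) starts[sc].push_back(p);
    int ec = end_code(g[p], g[p + 1]);
    if (ec >= 0) ends[ec].push_back(p);
  }

  for (int j = 1; j <= m; ++j) {
    // j = length of the gap piece furthest from the anchor (an intron needs
    // exonic support on its far side, so j >= min_overhang)
    int far_len = j, near_len = m - j;
    if (far_len < min_overhang) continue;
    if (near_len + ctx < min_overhang) continue;
    if (side == 1) { // prefix: far piece is the leftmost block
      int ie = anchor_pos - near_len;       // intron end (one past last intronic base)
      if (ie < 2) continue;
      int ec = end_code(g[ie - 2], g[ie - 1]);
      if (ec < 0) continue;
      int near_mm = hamming_at(g, (size_t)ie, gap, (size_t)j, (size_t)near_len, best);
      if (near_mm > best) continue;
      for (int sc = 0; sc < 4; ++sc) {
        int cls = PAIR_CLASS[sc][ec];
        if (cls == 0 || (!allow_semi && cls != 1 && cls != 4)) continue;
        // intron [is, ie): is in (ie - max_intron, ie - min_intron], is >= far_len
        int lo_is = std::max(far_len, ie - max_intron + 1);
        int hi_is = ie - min_intron;
        auto& v = starts[sc];
        auto it = std::lower_bound(v.begin(), v.end(), lo_is);
        for (; it != v.end() && *it <= hi_is; ++it) {
          int is = *it;
          int mm = near_mm + hamming_at(g, (size_t)(is - far_len), gap, 0,
                                        (size_t)far_len, best - near_mm);
          if (mm <= best) collect_hits(hits, far_len, is, ie - is, mm, cls, best);
        }
      }
    } else {       // suffix: far piece is the rightmost block
      int is = anchor_pos + near_len;       // intron start
      if (is + 1 >= glen) continue;
      int sc = start_code(g[is], g[is + 1]);
      if (sc < 0) continue;
      int near_mm = hamming_at(g, (size_t)anchor_pos, gap, 0, (size_t)near_len, best);
      if (near_mm > best) continue;
      for (int ec = 0; ec < 4; ++ec) {
        int cls = PAIR_CLASS[sc][ec];
        if (cls == 0 || (!allow_semi && cls != 1 && cls != 4)) continue;
        // intron [is, ie): end dinuc at ie-2, ie in [is+min_intron, is+max_intron)
        int lo_e = is + min_intron - 2;
        int hi_e = std::min(is + max_intron - 1, glen - far_len) - 2;
        auto& v = ends[ec];
        auto it = std::lower_bound(v.begin(), v.end(), lo_e);
        for (; it != v.end() && *it <= hi_e; ++it) {
          int ie = *it + 2;
          int mm = near_mm + hamming_at(g, (size_t)ie, gap, (size_t)near_len,
                                        (size_t)far_len, best - near_mm);
          if (mm <= best) collect_hits(hits, far_len, is, ie - is, mm, cls, best);
        }
      }
    }
  }
  return hits;
}

// [[Rcpp::export]]
DataFrame cpp_search_edge(SEXP xp_, int seq_idx, std::string gap, int side,
                          int anchor_pos, int min_intron, int max_intron, int max_mm,
                          int ctx, int min_overhang, bool allow_semi) {
  XPtr<KmerIndex> xp(xp_);
  return gap_hits_df(search_edge_internal(xp->seqs[seq_idx - 1], gap, side, anchor_pos,
                                          min_intron, max_intron, max_mm, ctx,
                                          min_overhang, allow_semi));
}

// ---- pseudo-transcript construction ----------------------------------------

// walk the genome from `from` in direction dir (-1 upstream, +1 downstream)
// collecting `need` exonic nt while splicing out the introns (nd, na);
// appends (start, len) blocks to out (upstream blocks are appended in
// genome order afterwards by reversing)
static void walk_exonic_cpp(int glen, int from, int need, int dir,
                            const std::vector<int>& nd, const std::vector<int>& na,
                            std::vector<std::pair<int,int>>& out) {
  int p = from;
  size_t first = out.size();
  while (need > 0) {
    if (dir < 0) {
      if (p <= 0) break;
      int stop_at = 0, jump_d = -1;
      for (size_t i = 0; i < na.size(); ++i)
        if (na[i] <= p && na[i] > stop_at) { stop_at = na[i]; jump_d = nd[i]; }
      int start = std::max(std::max(0, p - need), stop_at);
      if (p - start > 0) { out.push_back({start, p - start}); need -= p - start; }
      if (need > 0 && jump_d >= 0 && start == stop_at && stop_at > 0) p = jump_d;
      else break;
    } else {
      if (p >= glen) break;
      int stop_at = glen, jump_a = -1;
      for (size_t i = 0; i < nd.size(); ++i)
        if (nd[i] >= p && nd[i] < stop_at) { stop_at = nd[i]; jump_a = na[i]; }
      int end = std::min(std::min(glen, p + need), stop_at);
      if (end - p > 0) { out.push_back({p, end - p}); need -= end - p; }
      if (need > 0 && jump_a >= 0 && end == stop_at && stop_at < glen) p = jump_a;
      else break;
    }
  }
  if (dir < 0) std::reverse(out.begin() + first, out.end());
}

// [[Rcpp::export]]
DataFrame cpp_build_pseudo(std::string g, IntegerVector jd, IntegerVector ja,
                           List nb_d, List nb_a, int L) {
  const int glen = (int)g.size();
  std::vector<int> o_j, o_mask;
  std::vector<std::string> o_blocks, o_seq;
  for (int i = 0; i < jd.size(); ++i) {
    IntegerVector ndv = nb_d[i], nav = nb_a[i];
    int n = (int)ndv.size();
    for (int mask = 0; mask < (1 << n); ++mask) {
      std::vector<int> nd, na;
      for (int b = 0; b < n; ++b)
        if (mask & (1 << b)) { nd.push_back(ndv[b]); na.push_back(nav[b]); }
      std::vector<std::pair<int,int>> blocks;
      walk_exonic_cpp(glen, jd[i], L, -1, nd, na, blocks);
      size_t n_up = blocks.size();
      walk_exonic_cpp(glen, ja[i], L, +1, nd, na, blocks);
      (void)n_up;
      if (blocks.empty()) continue;
      std::string bs, sq;
      for (size_t b = 0; b < blocks.size(); ++b) {
        if (b) bs += ",";
        bs += std::to_string(blocks[b].first) + ":" + std::to_string(blocks[b].second);
        sq += g.substr((size_t)blocks[b].first, (size_t)blocks[b].second);
      }
      o_j.push_back(i + 1);
      o_mask.push_back(mask);
      o_blocks.push_back(bs);
      o_seq.push_back(sq);
    }
  }
  return DataFrame::create(_["junction"] = o_j, _["mask"] = o_mask,
                           _["blocks"] = o_blocks, _["sequence"] = o_seq,
                           _["stringsAsFactors"] = false);
}

// ---- batch anchor-and-extend driver -----------------------------------------

struct Constraints {
  int seg_len, max_mm, min_intron, max_intron, min_overhang, max_hits;
  bool allow_semi;
};

struct Piece { int rpos, gpos, len; };
struct Anchor { int off, len, gpos, mm; };
struct AlnOut { int seq, mm; bool minus; std::vector<Piece> blocks; };

// one placement candidate of a segment: genome seq + position + mismatches
struct SegHit { int seq, pos, mm; };

static void place_segment(const KmerIndex& idx, const std::string& q, int off, int len,
                          int seg_mm, int cap, std::vector<SegHit>& out) {
  const int k = idx.k;
  if (len < k) return;
  std::vector<int> offs;
  for (int o = 0; o + k <= len; o += k) offs.push_back(o);
  if (offs.empty() || offs.back() != len - k) offs.push_back(len - k);
  std::vector<uint64_t> seen;
  for (int o : offs) {
    uint64_t code;
    if (!encode_kmer(q, (size_t)(off + o), k, code)) continue;
    auto it = idx.map.find(code);
    if (it == idx.map.end()) continue;
    for (uint64_t e : it->second) {
      int seq = (int)(e >> 32);
      long p = (long)(e & 0xffffffffULL) - o;
      if (p < 0) continue;
      uint64_t key = ((uint64_t)seq << 32) | (uint64_t)p;
      bool dup = false;
      for (uint64_t s : seen) if (s == key) { dup = true; break; }
      if (dup) continue;
      seen.push_back(key);
      int mm = hamming_at(idx.seqs[seq], (size_t)p, q, (size_t)off, (size_t)len, seg_mm);
      if (mm <= seg_mm && (int)out.size() < cap) out.push_back({seq, (int)p, mm});
    }
  }
}

// pick the best gap candidate: hits are already the minimum-mismatch set;
// break ties by higher donor+acceptor PSFM score, then smaller intron, then
// leftmost intron start
static const GapHit* pick_hit(const std::vector<GapHit>& hits, const std::string& g,
                              const PsfmC& don, const PsfmC& acc, const double* bg,
                              bool use_psfm) {
  if (hits.empty()) return nullptr;
  const GapHit* best = &hits[0];
  double best_sc = use_psfm ? intron_score(g, best->istart, best->istart + best->ilen,
                                           best->cls, don, acc, bg) : 0;
  for (size_t i = 1; i < hits.size(); ++i) {
    const GapHit* h = &hits[i];
    double sc = use_psfm ? intron_score(g, h->istart, h->istart + h->ilen, h->cls,
                                        don, acc, bg) : 0;
    if (sc > best_sc + 1e-12 ||
        (std::abs(sc - best_sc) <= 1e-12 &&
         (h->ilen < best->ilen || (h->ilen == best->ilen && h->istart < best->istart)))) {
      best = h; best_sc = sc;
    }
  }
  return best;
}

// resolve one anchor chain into a spliced alignment; returns false on failure
static bool resolve_chain_cpp(const std::string& g, const std::string& q,
                              const std::vector<Anchor>& chain, const Constraints& cs,
                              const PsfmC& don, const PsfmC& acc, const double* bg,
                              bool use_psfm, int& out_mm, std::vector<Piece>& out_blocks,
                              int& n_introns) {
  const int L = (int)q.size();
  std::vector<Piece> pieces;
  std::vector<GapHit> introns;
  int total_mm = 0;
  for (const auto& a : chain) { pieces.push_back({a.off, a.gpos, a.len}); total_mm += a.mm; }

  // internal gaps
  for (size_t i = 0; i + 1 < chain.size(); ++i) {
    int r0 = chain[i].off + chain[i].len, r1 = chain[i + 1].off;
    int g0 = chain[i].gpos + chain[i].len, g1 = chain[i + 1].gpos;
    int m = r1 - r0, span = g1 - g0;
    std::string gap = q.substr((size_t)r0, (size_t)m);
    if (span == m) {
      int mm = m == 0 ? 0 : hamming_at(g, (size_t)g0, gap, 0, (size_t)m, cs.max_mm);
      if (mm > cs.max_mm) return false;
      total_mm += mm;
      if (m > 0) pieces.push_back({r0, g0, m});
    } else if (span > m) {
      int D = span - m;
      if (D < cs.min_intron || D >= cs.max_intron) return false;
      auto hits = search_gap_internal(g, gap, g0, g1, cs.max_mm, chain[i].len,
                                      chain[i + 1].len, cs.min_overhang, cs.allow_semi);
      const GapHit* b = pick_hit(hits, g, don, acc, bg, use_psfm);
      if (!b) return false;
      total_mm += b->mm;
      if (b->j > 0) pieces.push_back({r0, g0, b->j});
      if (m - b->j > 0) pieces.push_back({r0 + b->j, b->istart + b->ilen, m - b->j});
      introns.push_back(*b);
    } else return false;
  }

  // read prefix before the first anchor
  if (chain.front().off > 0) {
    int m = chain.front().off;
    std::string gap = q.substr(0, (size_t)m);
    int gl_plain = chain.front().gpos - m;
    int mm_plain = gl_plain >= 0 ?
      hamming_at(g, (size_t)gl_plain, gap, 0, (size_t)m, cs.max_mm) : cs.max_mm + 1;
    auto hits = search_edge_internal(g, gap, 1, chain.front().gpos, cs.min_intron,
                                     cs.max_intron, cs.max_mm, chain.front().len,
                                     cs.min_overhang, cs.allow_semi);
    const GapHit* b = pick_hit(hits, g, don, acc, bg, use_psfm);
    if (mm_plain <= cs.max_mm && (!b || mm_plain <= b->mm)) {
      total_mm += mm_plain;
      pieces.push_back({0, gl_plain, m});
    } else if (b) {
      total_mm += b->mm;
      int far = b->j, near = m - far;
      pieces.push_back({0, b->istart - far, far});
      if (near > 0) pieces.push_back({far, b->istart + b->ilen, near});
      introns.push_back(*b);
    } else return false;
  }

  // read suffix after the last anchor
  int tail_off = chain.back().off + chain.back().len;
  if (tail_off < L) {
    int m = L - tail_off;
    std::string gap = q.substr((size_t)tail_off, (size_t)m);
    int gl = chain.back().gpos + chain.back().len;
    int mm_plain = hamming_at(g, (size_t)gl, gap, 0, (size_t)m, cs.max_mm);
    auto hits = search_edge_internal(g, gap, 2, gl, cs.min_intron, cs.max_intron,
                                     cs.max_mm, chain.back().len, cs.min_overhang,
                                     cs.allow_semi);
    const GapHit* b = pick_hit(hits, g, don, acc, bg, use_psfm);
    if (mm_plain <= cs.max_mm && (!b || mm_plain <= b->mm)) {
      total_mm += mm_plain;
      pieces.push_back({tail_off, gl, m});
    } else if (b) {
      total_mm += b->mm;
      int far = b->j, near = m - far;
      if (near > 0) pieces.push_back({tail_off, gl, near});
      pieces.push_back({tail_off + near, b->istart + b->ilen, far});
      introns.push_back(*b);
    } else return false;
  }

  if (total_mm > cs.max_mm) return false;
  if (introns.empty()) return false;  // plain placements are the ungapped stage's job

  std::sort(pieces.begin(), pieces.end(),
            [](const Piece& a, const Piece& b) { return a.rpos < b.rpos; });
  int sum = 0; for (const auto& p : pieces) sum += p.len;
  if (sum != L) return false;
  std::vector<Piece> blocks;
  blocks.push_back(pieces[0]);
  for (size_t i = 1; i < pieces.size(); ++i) {
    Piece& prev = blocks.back();
    if (pieces[i].gpos == prev.gpos + prev.len) prev.len += pieces[i].len;
    else if (pieces[i].gpos > prev.gpos + prev.len) blocks.push_back(pieces[i]);
    else return false;
  }
  if (blocks.size() != introns.size() + 1) return false;
  for (const auto& b : blocks) if (b.len < cs.min_overhang) return false;
  for (size_t i = 1; i < blocks.size(); ++i) {
    int gapg = blocks[i].gpos - (blocks[i - 1].gpos + blocks[i - 1].len);
    if (gapg < cs.min_intron || gapg >= cs.max_intron) return false;
  }
  out_mm = total_mm;
  out_blocks = blocks;
  n_introns = (int)introns.size();
  return true;
}

// Batch anchor-and-extend: segments each read, places the segments ungapped
// (the anchors), chains collinear anchor placements greedily, and resolves
// each anchor gap to at most one intron. donor / acceptor / bg carry the
// PSFM parameters used only for tie-breaking (empty list = no PSFM).
// [[Rcpp::export]]
DataFrame cpp_spliced_align(SEXP xp_, CharacterVector reads, int seg_len, int max_mm,
                            int min_intron, int max_intron, int min_overhang,
                            int max_hits, bool allow_semi, List donor, List acceptor,
                            NumericVector bg_) {
  XPtr<KmerIndex> xp(xp_);
  const KmerIndex& idx = *xp;
  Constraints cs{seg_len, max_mm, min_intron, max_intron, min_overhang, max_hits,
                 allow_semi};
  bool use_psfm = donor.size() > 0;
  PsfmC don, acc;
  double bg[4] = {0.25, 0.25, 0.25, 0.25};
  if (use_psfm) {
    don = psfm_from_list(donor);
    acc = psfm_from_list(acceptor);
    for (int i = 0; i < 4; ++i) bg[i] = bg_[i];
  }
  int seg_mm = std::min(1, max_mm);

  std::vector<int> out_read, out_seq, out_mmv;
  std::vector<std::string> out_strand, out_blocks;

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    std::vector<AlnOut> alns;
    for (int orient = 0; orient < 2; ++orient) {
      std::string q = orient == 0 ? fwd : revcomp_str(fwd);
      const int L = (int)q.size();
      // segmentation: non-overlapping seg_len pieces, remainder on the last
      std::vector<std::pair<int,int>> segs;
      if (L <= seg_len) segs.push_back({0, L});
      else {
        int n = L / seg_len;
        for (int i = 0; i < n; ++i) segs.push_back({i * seg_len, seg_len});
        segs.back().second = L - segs.back().first;
      }
      std::vector<std::vector<SegHit>> plc(segs.size());
      std::vector<int> placed;
      for (size_t si = 0; si < segs.size(); ++si) {
        place_segment(idx, q, segs[si].first, segs[si].second, seg_mm, 50, plc[si]);
        if (!plc[si].empty()) placed.push_back((int)si);
      }
      if (placed.empty()) continue;
      int seed = placed[0];
      for (int si : placed) if (plc[si].size() < plc[seed].size()) seed = si;
      int n_seeds = std::min((int)plc[seed].size(), max_hits);
      for (int s = 0; s < n_seeds; ++s) {
        const SegHit& row = plc[seed][s];
        std::vector<Anchor> chain;
        chain.push_back({segs[seed].first, segs[seed].second, row.pos, row.mm});
        // extend right
        int cer = segs[seed].first + segs[seed].second;
        int ceg = row.pos + segs[seed].second;
        for (int si : placed) {
          if (si <= seed) continue;
          int rgap = segs[si].first - cer;
          const SegHit* pick = nullptr;
          for (const auto& h : plc[si]) {
            if (h.seq != row.seq) continue;
            if (h.pos < ceg + rgap || h.pos > ceg + rgap + max_intron) continue;
            if (!pick || h.pos < pick->pos) pick = &h;
          }
          if (!pick) continue;
          chain.push_back({segs[si].first, segs[si].second, pick->pos, pick->mm});
          cer = segs[si].first + segs[si].second;
          ceg = pick->pos + segs[si].second;
        }
        // extend left
        int csr = segs[seed].first, csg = row.pos;
        for (int pi = (int)placed.size() - 1; pi >= 0; --pi) {
          int si = placed[pi];
          if (si >= seed) continue;
          int rgap = csr - (segs[si].first + segs[si].second);
          int tgt = csg - rgap - segs[si].second;
          const SegHit* pick = nullptr;
          for (const auto& h : plc[si]) {
            if (h.seq != row.seq) continue;
            if (h.pos > tgt || h.pos < tgt - max_intron) continue;
            if (!pick || h.pos > pick->pos) pick = &h;
          }
          if (!pick) continue;
          chain.insert(chain.begin(), {segs[si].first, segs[si].second, pick->pos, pick->mm});
          csr = segs[si].first;
          csg = pick->pos;
        }
        // a segment spanning a junction can acquire a spurious near-match
        // placement that poisons the chain; besides the full chain, try
        // variants with one or two edge anchors dropped (their segments then
        // rejoin the flanking gap) and keep every resolvable alignment --
        // the minimum-mismatch filter below picks the best
        int n_ch = (int)chain.size();
        for (int dropL = 0; dropL <= std::min(2, n_ch - 1); ++dropL) {
          for (int dropR = 0; dropR <= std::min(2, n_ch - 1 - dropL); ++dropR) {
            std::vector<Anchor> sub(chain.begin() + dropL, chain.end() - dropR);
            if (sub.empty()) continue;
            int mm, ni;
            std::vector<Piece> blocks;
            if (resolve_chain_cpp(idx.seqs[row.seq], q, sub, cs, don, acc, bg, use_psfm,
                                  mm, blocks, ni)) {
              alns.push_back({row.seq, mm, orient == 1, blocks});
            }
          }
        }
      }
    }
    if (alns.empty()) continue;
    int best_mm = alns[0].mm;
    for (const auto& a : alns) best_mm = std::min(best_mm, a.mm);
    std::vector<std::string> seen;
    int emitted = 0;
    for (const auto& a : alns) {
      if (a.mm != best_mm || emitted >= max_hits) continue;
      std::string bs;
      for (size_t i = 0; i < a.blocks.size(); ++i) {
        if (i) bs += ",";
        bs += std::to_string(a.blocks[i].gpos) + ":" + std::to_string(a.blocks[i].len);
      }
      std::string key = std::to_string(a.seq) + (a.minus ? "-" : "+") + bs;
      bool dup = false;
      for (const auto& s : seen) if (s == key) { dup = true; break; }
      if (dup) continue;
      seen.push_back(key);
      out_read.push_back(ri + 1);
      out_seq.push_back(a.seq + 1);
      out_strand.push_back(a.minus ? "-" : "+");
      out_blocks.push_back(bs);
      out_mmv.push_back(a.mm);
      ++emitted;
    }
  }
  return DataFrame::create(_["read"] = out_read, _["seq"] = out_seq,
                           _["strand"] = out_strand, _["blocks"] = out_blocks,
                           _["mismatches"] = out_mmv, _["stringsAsFactors"] = false);
}
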