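// Compiled kernels: k-mer occurrence counting, seed-and-extend read mapping,
// word-seeded X-drop homology search, and pileup base counts.
// No indels are ever simulated upstream, so read-to-candidate scoring is
// full-length ungapped (match +1, mismatch -4); see the methods vignette.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// ---------------------------------------------------------------------------
// k-mer occurrence counts (mappability)
// ---------------------------------------------------------------------------

// Counts, for every position admitting a full k-mer, the number of exact
// occurrences of that k-mer in the whole genome on both strands. Positions
// whose k-mer contains a non-ACGT base get count 0.
// [[Rcpp::export]]
List cpp_kmer_counts(CharacterVector seqs, int k) {
  int n = seqs.size();
  std::vector<std::string> genome(n);
  for (int i = 0; i < n; ++i) genome[i] = as<std::string>(seqs[i]);

  std::unordered_map<std::string, int> counts;
  size_t total = 0;
  for (int i = 0; i < n; ++i)
    if ((int)genome[i].size() >= k) total += genome[i].size() - k + 1;
  counts.reserve(total * 2);

  for (int i = 0; i < n; ++i) {
    const std::string& s = genome[i];
    if ((int)s.size() < k) continue;
    int bad = 0;  // positions until the current window is N-free
    for (int j = 0; j < (int)s.size(); ++j) {
      if (base_code(s[j]) < 0) bad = k;
      else if (bad > 0) --bad;
      int start = j - k + 1;
      if (start >= 0 && bad == 0) counts[s.substr(start, k)]++;
    }
  }

  List out(n);
  for (int i = 0; i < n; ++i) {
    const std::string& s = genome[i];
    int len = (int)s.size() - k + 1;
    if (len < 1) { out[i] = IntegerVector(0); continue; }
    IntegerVector v(len);
    int bad = 0;
    for (int j = 0; j < (int)s.size(); ++j) {
      if (base_code(s[j]) < 0) bad = k;
      else if (bad > 0) --bad;
      int start = j - k + 1;
      if (start < 0) continue;
      if (bad != 0) { v[start] = 0; continue; }
      std::string kmer = s.substr(start, k);
      int c = counts[kmer];
      std::string rc = revcomp(kmer);
      auto it = counts.find(rc);
      if (it != counts.end()) c += it->second;  // k odd upstream: no palindromes
      v[start] = c;
    }
    out[i] = v;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}

// ---------------------------------------------------------------------------
// seed index
// ---------------------------------------------------------------------------

struct SeedIndex {
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  int k;
  // 2-bit encoded k-mer -> (contig, position) list
  std::unordered_map<uint64_t, std::vector<std::pair<uint32_t, uint32_t>>> table;
};

static inline bool encode_kmer(const std::string& s, int pos, int k, uint64_t& key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  key = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  if (k < 4 || k > 31) stop("seed length must be in [4, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  int n = seqs.size();
  CharacterVector nm = seqs.attr("names");
  for (int i = 0; i < n; ++i) {
    idx->seqs.push_back(as<std::string>(seqs[i]));
    idx->names.push_back(as<std::string>(nm[i]));
  }
  for (int i = 0; i < n; ++i) {
    const std::string& s = idx->seqs[i];
    if ((int)s.size() < k) continue;
    for (int j = 0; j + k <= (int)s.size(); ++j) {
      uint64_t key;
      if (!encode_kmer(s, j, k, key)) continue;
      idx->table[key].push_back({(uint32_t)i, (uint32_t)j});
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_lookup(SEXP ptr_, std::string kmer) {
  XPtr<SeedIndex> ptr(ptr_);
  if ((int)kmer.size() != ptr->k) stop("k-mer length must equal the index seed length");
  uint64_t key;
  IntegerVector contig, pos;
  if (encode_kmer(kmer, 0, ptr->k, key)) {
    auto it = ptr->table.find(key);
    if (it != ptr->table.end()) {
      for (auto& h : it->second) {
        contig.push_back((int)h.first + 1);
        pos.push_back((int)h.second);
      }
    }
  }
  return List::create(_["contig"] = contig, _["pos"] = pos);
}

// ---------------------------------------------------------------------------
// read mapping
// ---------------------------------------------------------------------------

struct Cand {
  int contig;
  int pos;     // 0-based leftmost on forward genome
  int strand;  // 0 forward, 1 reverse
  int score;
};

static const int MAX_SEED_HITS = 1000;
static const int MAX_CANDIDATES = 30;

static int ungapped_score(const std::string& g, int pos, const std::string& s,
                          int mismatch_pen) {
  int mm = 0;
  for (size_t i = 0; i < s.size(); ++i)
    if (g[pos + i] != s[i]) ++mm;
  return (int)s.size() - (1 + mismatch_pen) * mm;
}

static void gen_candidates(const SeedIndex& idx, const std::string& read,
                           int mismatch_pen, std::vector<Cand>& out) {
  out.clear();
  int k = idx.k;
  int len = (int)read.size();
  if (len < k) return;
  std::string oriented[2] = {read, revcomp(read)};
  std::vector<std::pair<int, std::pair<int, int>>> raw;  // (strand,(contig,start))
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& s = oriented[strand];
    std::vector<int> offs;
    for (int o = 0; o + k <= len; o += k) offs.push_back(o);
    if (offs.empty() || offs.back() != len - k) offs.push_back(len - k);
    for (int o : offs) {
      uint64_t key;
      if (!encode_kmer(s, o, k, key)) continue;
      auto it = idx.table.find(key);
      if (it == idx.table.end()) continue;
      if ((int)it->second.size() > MAX_SEED_HITS) continue;
      for (auto& h : it->second) {
        int start = (int)h.second - o;
        if (start < 0 || start + len > (int)idx.seqs[h.first].size()) continue;
        raw.push_back({strand, {(int)h.first, start}});
      }
    }
  }
  std::sort(raw.begin(), raw.end());
  raw.erase(std::unique(raw.begin(), raw.end()), raw.end());
  for (auto& r : raw) {
    Cand c;
    c.strand = r.first;
    c.contig = r.second.first;
    c.pos = r.second.second;
    c.score = ungapped_score(idx.seqs[c.contig], c.pos, oriented[c.strand],
                             mismatch_pen);
    out.push_back(c);
  }
  // deterministic: best score first, then lowest (contig, coordinate), fwd first
  std::sort(out.begin(), out.end(), [](const Cand& a, const Cand& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.pos != b.pos) return a.pos < b.pos;
    return a.strand < b.strand;
  });
  if ((int)out.size() > MAX_CANDIDATES) out.resize(MAX_CANDIDATES);
}

static inline int mapq_from(int s1, int s2, bool single, int cap) {
  int gap = single ? s1 : s1 - s2;
  if (gap <= 0) return 0;
  int q = 6 * gap;
  return q > cap ? cap : q;
}

struct MateOut {
  IntegerVector contig, pos, strand, mapq, score, score2, ncand;
  IntegerVector alt_contig, alt_pos, alt_strand;
  MateOut(int n)
      : contig(n), pos(n), strand(n), mapq(n), score(n), score2(n), ncand(n),
        alt_contig(n), alt_pos(n), alt_strand(n) {}
  void unmapped(int i) {
    contig[i] = 0; pos[i] = NA_INTEGER; strand[i] = NA_INTEGER; mapq[i] = 0;
    score[i] = NA_INTEGER; score2[i] = NA_INTEGER; ncand[i] = 0;
    alt_contig[i] = 0; alt_pos[i] = NA_INTEGER; alt_strand[i] = NA_INTEGER;
  }
  void fill(int i, const Cand& best, int mq, int s2, int nc, const Cand* alt) {
    contig[i] = best.contig + 1; pos[i] = best.pos; strand[i] = best.strand;
    mapq[i] = mq; score[i] = best.score;
    score2[i] = (nc > 1) ? s2 : NA_INTEGER; ncand[i] = nc;
    if (alt) {
      alt_contig[i] = alt->contig + 1; alt_pos[i] = alt->pos;
      alt_strand[i] = alt->strand;
    } else {
      alt_contig[i] = 0; alt_pos[i] = NA_INTEGER; alt_strand[i] = NA_INTEGER;
    }
  }
  List as_list() {
    return List::create(
        _["contig"] = contig, _["pos"] = pos, _["strand"] = strand,
        _["mapq"] = mapq, _["score"] = score, _["score2"] = score2,
        _["n_cand"] = ncand, _["alt_contig"] = alt_contig,
        _["alt_pos"] = alt_pos, _["alt_strand"] = alt_strand);
  }
};

// [[Rcpp::export]]
List cpp_map_single(SEXP ptr_, CharacterVector reads, int mismatch_pen,
                    int mapq_cap) {
  XPtr<SeedIndex> ptr(ptr_);
  int n = reads.size();
  MateOut out(n);
  std::vector<Cand> cands;
  for (int i = 0; i < n; ++i) {
    gen_candidates(*ptr, as<std::string>(reads[i]), mismatch_pen, cands);
    if (cands.empty()) { out.unmapped(i); continue; }
    int nc = (int)cands.size();
    int s2 = nc > 1 ? cands[1].score : 0;
    int mq = mapq_from(cands[0].score, s2, nc == 1, mapq_cap);
    out.fill(i, cands[0], mq, s2, nc, nc > 1 ? &cands[1] : nullptr);
  }
  return out.as_list();
}

static inline bool proper_pair(const Cand& a, int la, const Cand& b, int lb,
                               double frag_mean, double frag_window) {
  if (a.contig != b.contig || a.strand == b.strand) return false;
  const Cand& f = a.strand == 0 ? a : b;
  const Cand& r = a.strand == 0 ? b : a;
  int lf = a.strand == 0 ? la : lb;
  int lr = a.strand == 0 ? lb : la;
  (void)lf;
  if (f.pos > r.pos) return false;
  int tlen = r.pos + lr - f.pos;
  return std::abs((double)tlen - frag_mean) <= frag_window;
}

// Paired mapping with proper-pair rescue: candidates forming a proper pair
// with the mate's chosen locus receive `pair_bonus`; MAPQ is computed on the
// bonus-adjusted candidate scores.
// [[Rcpp::export]]
List cpp_map_pairs(SEXP ptr_, CharacterVector reads1, CharacterVector reads2,
                   double frag_mean, double frag_window, int pair_bonus,
                   int mismatch_pen, int mapq_cap) {
  XPtr<SeedIndex> ptr(ptr_);
  int n = reads1.size();
  if (reads2.size() != n) stop("read vectors differ in length");
  MateOut out1(n), out2(n);
  LogicalVector proper(n);
  IntegerVector tlen(n);
  std::vector<Cand> A, B;
  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(reads1[i]);
    std::string s2 = as<std::string>(reads2[i]);
    int l1 = (int)s1.size(), l2 = (int)s2.size();
    gen_candidates(*ptr, s1, mismatch_pen, A);
    gen_candidates(*ptr, s2, mismatch_pen, B);
    proper[i] = false;
    tlen[i] = NA_INTEGER;

    if (A.empty() && B.empty()) { out1.unmapped(i); out2.unmapped(i); continue; }
    if (A.empty() || B.empty()) {
      std::vector<Cand>& C = A.empty() ? B : A;
      MateOut& om = A.empty() ? out2 : out1;
      MateOut& ou = A.empty() ? out1 : out2;
      int nc = (int)C.size();
      int s2nd = nc > 1 ? C[1].score : 0;
      int mq = mapq_from(C[0].score, s2nd, nc == 1, mapq_cap);
      om.fill(i, C[0], mq, s2nd, nc, nc > 1 ? &C[1] : nullptr);
      ou.unmapped(i);
      continue;
    }

    // joint pairing totals; each candidate's effective score is the best
    // joint total of any pairing that uses it, so a pair-level tie (e.g.
    // both mates inside an identical duplicated tract) yields MAPQ 0 while
    // a uniquely mapped mate rescues its tied partner by `pair_bonus`.
    // Candidate lists are sorted best-first, coordinate ascending at ties,
    // so the first argmax wins deterministically.
    int na = (int)A.size(), nb = (int)B.size();
    std::vector<int> besta(na, INT32_MIN), bestb(nb, INT32_MIN);
    int bi = 0, bj = 0, btot = INT32_MIN;
    for (int ia = 0; ia < na; ++ia) {
      for (int ib = 0; ib < nb; ++ib) {
        int tot = A[ia].score + B[ib].score +
                  (proper_pair(A[ia], l1, B[ib], l2, frag_mean, frag_window)
                       ? pair_bonus : 0);
        if (tot > btot) { btot = tot; bi = ia; bj = ib; }
        if (tot > besta[ia]) besta[ia] = tot;
        if (tot > bestb[ib]) bestb[ib] = tot;
      }
    }
    const Cand& ca = A[bi];
    const Cand& cb = B[bj];
    bool prop = proper_pair(ca, l1, cb, l2, frag_mean, frag_window);
    proper[i] = prop;
    if (ca.contig == cb.contig) {
      const Cand& f = ca.strand == 0 ? ca : cb;
      const Cand& r = ca.strand == 0 ? cb : ca;
      int lr = ca.strand == 0 ? l2 : l1;
      tlen[i] = r.pos + lr - f.pos;
    }

    for (int mate = 0; mate < 2; ++mate) {
      std::vector<Cand>& C = mate == 0 ? A : B;
      std::vector<int>& joint = mate == 0 ? besta : bestb;
      int chosen = mate == 0 ? bi : bj;
      int s1b = joint[chosen], s2b = INT32_MIN;
      int alt = -1;
      for (int ic = 0; ic < (int)C.size(); ++ic) {
        if (ic == chosen) continue;
        if (joint[ic] > s2b) { s2b = joint[ic]; alt = ic; }
      }
      int nc = (int)C.size();
      // report the mate's own alignment score; MAPQ uses the joint margins
      int mq = mapq_from(s1b, nc > 1 ? s2b : 0, nc == 1, mapq_cap);
      MateOut& om = mate == 0 ? out1 : out2;
      om.fill(i, C[chosen], mq, nc > 1 ? s2b : 0, nc,
              alt >= 0 ? &C[alt] : nullptr);
    }
  }
  return List::create(_["mate1"] = out1.as_list(), _["mate2"] = out2.as_list(),
                      _["proper"] = proper, _["tlen"] = tlen);
}

// ---------------------------------------------------------------------------
// homology search (word-seeded ungapped X-drop extension)
// ---------------------------------------------------------------------------

static const int MAX_WORD_HITS = 200;

// [[Rcpp::export]]
List cpp_homology_search(SEXP ptr_, std::string query, int match_score,
                         int mismatch_pen, int xdrop) {
  XPtr<SeedIndex> ptr(ptr_);
  int w = ptr->k;
  int qlen = (int)query.size();
  IntegerVector contig, sstart, send, qstart, qend, mism;
  CharacterVector strand;
  if (qlen < w)
    return List::create(_["contig"] = contig, _["sstart"] = sstart,
                        _["send"] = send, _["qstart"] = qstart,
                        _["qend"] = qend, _["mismatches"] = mism,
                        _["strand"] = strand);

  std::string oriented[2] = {query, revcomp(query)};
  for (int str = 0; str < 2; ++str) {
    const std::string& q = oriented[str];
    // per (contig, diagonal): query intervals already covered by an extension
    std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> covered;
    for (int o = 0; o + w <= qlen; ++o) {
      uint64_t key;
      if (!encode_kmer(q, o, w, key)) continue;
      auto it = ptr->table.find(key);
      if (it == ptr->table.end()) continue;
      if ((int)it->second.size() > MAX_WORD_HITS) continue;
      for (auto& h : it->second) {
        int c = (int)h.first;
        int diag = (int)h.second - o;
        uint64_t dkey = ((uint64_t)c << 40) ^ (uint64_t)(diag + (1 << 30));
        auto& iv = covered[dkey];
        bool seen = false;
        for (auto& p : iv)
          if (o >= p.first && o < p.second) { seen = true; break; }
        if (seen) continue;
        const std::string& g = ptr->seqs[c];
        int glen = (int)g.size();
        // extend right from o
        int cur = 0, best = 0, qr = o - 1;
        for (int i = o; i < qlen && diag + i < glen; ++i) {
          cur += (q[i] == g[diag + i]) ? match_score : -mismatch_pen;
          if (cur > best) { best = cur; qr = i; }
          if (best - cur > xdrop) break;
        }
        // extend left from o - 1
        cur = 0; best = 0;
        int ql = o;
        for (int i = o - 1; i >= 0 && diag + i >= 0; --i) {
          cur += (q[i] == g[diag + i]) ? match_score : -mismatch_pen;
          if (cur > best) { best = cur; ql = i; }
          if (best - cur > xdrop) break;
        }
        if (qr < ql) continue;
        iv.push_back({ql, qr + 1});
        int mm = 0;
        for (int i = ql; i <= qr; ++i)
          if (q[i] != g[diag + i]) ++mm;
        // report in original-query and forward-subject coordinates
        int oq_start = (str == 0) ? ql : qlen - (qr + 1);
        int oq_end = (str == 0) ? qr + 1 : qlen - ql;
        contig.push_back(c + 1);
        sstart.push_back(diag + ql);
        send.push_back(diag + qr + 1);
        qstart.push_back(oq_start);
        qend.push_back(oq_end);
        mism.push_back(mm);
        strand.push_back(str == 0 ? "+" : "-");
      }
    }
  }
  return List::create(_["contig"] = contig, _["sstart"] = sstart,
                      _["send"] = send, _["qstart"] = qstart,
                      _["qend"] = qend, _["mismatches"] = mism,
                      _["strand"] = strand);
}

// ---------------------------------------------------------------------------
// pileup base counts over a window
// ---------------------------------------------------------------------------

// Alignments are full-length matches (M-only CIGARs); returns a 4 x width
// matrix of A/C/G/T counts for alignments with MAPQ >= mq_min.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup_counts(IntegerVector pos, CharacterVector seq,
                                IntegerVector mapq, int start, int end,
                                int mq_min) {
  int width = end - start;
  if (width < 0) stop("end must be >= start");
  IntegerMatrix out(4, width);
  int n = pos.size();
  for (int i = 0; i < n; ++i) {
    if (mapq[i] < mq_min || pos[i] == NA_INTEGER) continue;
    std::string s = as<std::string>(seq[i]);
    int p = pos[i];
    int lo = std::max(p, start), hi = std::min(p + (int)s.size(), end);
    for (int x = lo; x < hi; ++x) {
      int c = base_code(s[x - p]);
      if (c >= 0) out(c, x - start)++;
    }
  }
  return out;
}
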