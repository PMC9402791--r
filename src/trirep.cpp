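#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// ---- small helpers ----------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) r[j] = comp_base(s[s.size() - 1 - j]);
    out[i] = r;
  }
  return out;
}

// ---- paired-end overlap merging ---------------------------------------
//
// Overlap (glocal) dialect of global alignment: end gaps free, internal
// gaps disallowed (substitution-only error model). Mate 2 must already be
// reverse-complemented. Offset d places the start of read2rc at position d
// of read1's coordinate system (d may be negative). Score over the overlap
// is matches - mismatches; best score wins, ties broken toward the longer
// overlap, then the smaller offset.

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector seq2rc,
                     CharacterVector qual1, CharacterVector qual2rc,
                     int min_overlap, double max_mismatch_rate) {
  R_xlen_t n = seq1.size();
  IntegerVector status(n), ov_len(n), ov_mm(n);
  CharacterVector mseq(n), mqual(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string r1 = as<std::string>(seq1[i]);
    std::string r2 = as<std::string>(seq2rc[i]);
    std::string q1 = as<std::string>(qual1[i]);
    std::string q2 = as<std::string>(qual2rc[i]);
    int L1 = (int)r1.size(), L2 = (int)r2.size();
    if (L1 == 0 || L2 == 0) { status[i] = 2; mseq[i] = ""; mqual[i] = ""; continue; }
    int best_score = INT_MIN, best_d = 0, best_ov = -1, best_mm = 0;
    for (int d = -(L2 - min_overlap); d <= L1 - min_overlap; ++d) {
      int from = std::max(0, d);            // overlap start on read1 coords
      int to = std::min(L1, d + L2);        // overlap end (exclusive)
      int ov = to - from;
      if (ov < min_overlap) continue;
      int mm = 0;
      for (int p = from; p < to; ++p) if (r1[p] != r2[p - d]) ++mm;
      if ((double)mm / (double)ov > max_mismatch_rate) continue;
      int score = ov - 2 * mm;              // matches - mismatches
      if (score > best_score ||
          (score == best_score && (ov > best_ov ||
                                   (ov == best_ov && d < best_d)))) {
        best_score = score; best_d = d; best_ov = ov; best_mm = mm;
      }
    }
    if (best_ov < 0) { status[i] = 1; mseq[i] = ""; mqual[i] = ""; continue; }
    int d = best_d;
    int from = std::max(0, d), to = std::min(L1, d + L2);
    std::string ms, mq;
    ms.reserve(L1 + L2); mq.reserve(L1 + L2);
    // left flank
    if (d > 0) { ms += r1.substr(0, d); mq += q1.substr(0, d); }
    else if (d < 0) { ms += r2.substr(0, -d); mq += q2.substr(0, -d); }
    // overlap consensus: disagreements resolve to the higher-quality base
    // (tie -> read1); agreed bases take the max quality
    for (int p = from; p < to; ++p) {
      char b1 = r1[p], b2 = r2[p - d];
      char c1 = q1[p], c2 = q2[p - d];
      if (b1 == b2) { ms += b1; mq += std::max(c1, c2); }
      else if (c2 > c1) { ms += b2; mq += c2; }
      else { ms += b1; mq += c1; }
    }
    // right flank
    if (d + L2 > L1) { ms += r2.substr(L1 - d); mq += q2.substr(L1 - d); }
    else if (to < L1) { ms += r1.substr(to); mq += q1.substr(to); }
    status[i] = 0; mseq[i] = ms; mqual[i] = mq;
    ov_len[i] = best_ov; ov_mm[i] = best_mm;
  }
  return List::create(_["status"] = status, _["sequence"] = mseq,
                      _["quality"] = mqual, _["overlap_len"] = ov_len,
                      _["overlap_mismatches"] = ov_mm);
}

// ---- seeded gapless local alignment -----------------------------------
//
// Exact k-mer seeds against a small segment library, extension restricted
// to the seeded diagonal (substitution-only), best local block found by
// Kadane's maximum-subarray on the +1/-1 diagonal profile.

struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > map; // kmer -> (seg, pos)
};

static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

static void index_segments(const std::vector<std::string>& segs, int k, SeedIndex& idx) {
  idx.k = k;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t s = 0; s < segs.size(); ++s) {
    const std::string& seg = segs[s];
    if ((int)seg.size() < k) continue;
    uint64_t h = 0; int run = 0;
    for (size_t p = 0; p < seg.size(); ++p) {
      int c = base_code(seg[p]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask; ++run;
      if (run >= k) idx.map[h].emplace_back((int)s, (int)(p - k + 1));
    }
  }
}

struct Hit { int seg, diag, score, rstart, rend, nmatch, nmm; bool ok; };

static Hit align_one(const std::string& read, const std::vector<std::string>& segs,
                     const SeedIndex& idx) {
  Hit best; best.ok = false; best.score = INT_MIN; best.seg = -1;
  best.diag = 0; best.rstart = 0; best.rend = 0; best.nmatch = 0; best.nmm = 0;
  int k = idx.k;
  int Lr = (int)read.size();
  if (Lr < k) return best;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // collect candidate (seg, diag) pairs
  std::unordered_map<uint64_t, char> seen; // (seg<<32)|diag+offset
  std::vector<std::pair<int,int> > cand;
  uint64_t h = 0; int run = 0;
  for (int p = 0; p < Lr; ++p) {
    int c = base_code(read[p]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask; ++run;
    if (run < k) continue;
    auto it = idx.map.find(h);
    if (it == idx.map.end()) continue;
    int rpos = p - k + 1;
    for (auto& sp : it->second) {
      int d = rpos - sp.second; // read_pos = seg_pos + d
      uint64_t key = ((uint64_t)(uint32_t)sp.first << 32) | (uint32_t)(d + 1000000);
      if (seen.emplace(key, 1).second) cand.emplace_back(sp.first, d);
    }
  }
  for (auto& cd : cand) {
    int s = cd.first, d = cd.second;
    const std::string& seg = segs[s];
    int Ls = (int)seg.size();
    int from = std::max(0, d), to = std::min(Lr, Ls + d);
    if (to - from < k) continue;
    // Kadane on +1 match / -1 mismatch
    int cur = 0, cur_start = from, b_score = INT_MIN, b_from = from, b_to = from;
    for (int p = from; p < to; ++p) {
      int v = (read[p] == seg[p - d]) ? 1 : -1;
      if (cur <= 0) { cur = v; cur_start = p; } else cur += v;
      if (cur > b_score) { b_score = cur; b_from = cur_start; b_to = p + 1; }
    }
    if (b_score > best.score ||
        (b_score == best.score && (s < best.seg ||
                                   (s == best.seg && d < best.diag)))) {
      int nm = 0;
      for (int p = b_from; p < b_to; ++p) if (read[p] == seg[p - d]) ++nm;
      best.ok = true; best.score = b_score; best.seg = s; best.diag = d;
      best.rstart = b_from; best.rend = b_to;
      best.nmatch = nm; best.nmm = (b_to - b_from) - nm;
    }
  }
  return best;
}

// [[Rcpp::export]]
DataFrame cpp_align_best(CharacterVector reads, CharacterVector segs, int k) {
  std::vector<std::string> S(segs.size());
  for (R_xlen_t i = 0; i < segs.size(); ++i) S[i] = as<std::string>(segs[i]);
  SeedIndex idx; index_segments(S, k, idx);
  R_xlen_t n = reads.size();
  IntegerVector seg(n), score(n), diag(n), rstart(n), rend(n), nmatch(n), nmm(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    Hit h = align_one(r, S, idx);
    if (!h.ok) {
      seg[i] = NA_INTEGER; score[i] = NA_INTEGER; diag[i] = NA_INTEGER;
      rstart[i] = NA_INTEGER; rend[i] = NA_INTEGER;
      nmatch[i] = NA_INTEGER; nmm[i] = NA_INTEGER;
    } else {
      seg[i] = h.seg + 1; score[i] = h.score; diag[i] = h.diag;
      rstart[i] = h.rstart; rend[i] = h.rend;   // 0-based half-open on read
      nmatch[i] = h.nmatch; nmm[i] = h.nmm;
    }
  }
  return DataFrame::create(_["seg"] = seg, _["score"] = score, _["diag"] = diag,
                           _["rstart"] = rstart, _["rend"] = rend,
                           _["nmatch"] = nmatch, _["nmismatch"] = nmm,
                           _["stringsAsFactors"] = false);
}

// Identity of the gapless diagonal alignment restricted to a read interval
// [from, to) (0-based half-open), clipped to the segment's extent.
// [[Rcpp::export]]
DataFrame cpp_block_identity(CharacterVector reads, CharacterVector segs,
                             IntegerVector seg_index, IntegerVector diag,
                             IntegerVector from, IntegerVector to) {
  R_xlen_t n = reads.size();
  IntegerVector len(n), match(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seg_index[i] == NA_INTEGER) { len[i] = 0; match[i] = 0; continue; }
    std::string r = as<std::string>(reads[i]);
    std::string s = as<std::string>(segs[seg_index[i] - 1]);
    int d = diag[i];
    int a = std::max(std::max(0, d), from[i]);
    int b = std::min(std::min((int)r.size(), (int)s.size() + d), to[i]);
    int m = 0;
    for (int p = a; p < b; ++p) if (r[p] == s[p - d]) ++m;
    len[i] = std::max(0, b - a); match[i] = m;
  }
  return DataFrame::create(_["len"] = len, _["match"] = match,
                           _["stringsAsFactors"] = false);
}

// ---- Hamming-neighbour absorption (sequencing-error filter core) ------
//
// Within one (v_call, j_call, length) group: each clonotype, visited in
// ascending copy order, is absorbed by the highest-copy clonotype within
// Hamming distance <= max_hamming whose (current) copies are >= min_ratio
// times its own. Absorption adds the child's copies to the parent.
// Returns the 1-based parent index per record (0 = kept).

// [[Rcpp::export]]
IntegerVector cpp_absorb_group(CharacterVector junctions, NumericVector copies,
                               int max_hamming, double min_ratio) {
  int n = junctions.size();
  std::vector<std::string> J(n);
  for (int i = 0; i < n; ++i) J[i] = as<std::string>(junctions[i]);
  std::vector<double> cp(copies.begin(), copies.end());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (cp[a] != cp[b]) return cp[a] < cp[b];
    return J[a] < J[b];
  });
  IntegerVector parent(n, 0);
  std::vector<bool> gone(n, false);
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    int best = -1;
    for (int j = 0; j < n; ++j) {
      if (j == i || gone[j]) continue;
      if (cp[j] < min_ratio * cp[i]) continue;
      if (J[j].size() != J[i].size()) continue;
      int h = 0; bool over = false;
      for (size_t p = 0; p < J[i].size(); ++p) {
        if (J[i][p] != J[j][p] && ++h > max_hamming) { over = true; break; }
      }
      if (over) continue;
      if (best < 0 || cp[j] > cp[best] ||
          (cp[j] == cp[best] && J[j] < J[best])) best = j;
    }
    if (best >= 0) {
      parent[i] = best + 1;
      cp[best] += cp[i];
      gone[i] = true;
    }
  }
  return parent;
}

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]), y = as<std::string>(b[i]);
    if (x.size() != y.size()) { out[i] = NA_INTEGER; continue; }
    int h = 0;
    for (size_t p = 0; p < x.size(); ++p) if (x[p] != y[p]) ++h;
    out[i] = h;
  }
  return out;
}

// Substitution injector: applies (position, base) substitutions per string.
// pos is a list of integer vectors (1-based), alt a list of character
// vectors of single bases.
// [[Rcpp::export]]
CharacterVector cpp_apply_subs(CharacterVector seqs, List pos, List alt) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    IntegerVector p = pos[i];
    CharacterVector a = alt[i];
    for (R_xlen_t j = 0; j < p.size(); ++j) {
      int q = p[j] - 1;
      if (q >= 0 && q < (int)s.size()) s[q] = as<std::string>(a[j])[0];
    }
    out[i] = s;
  }
  return out;
}
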