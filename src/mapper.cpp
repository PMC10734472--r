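#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode; -1 for anything that is not ACGT
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline char revcomp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = revcomp_base(r[i]);
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

// exact k-mer index over one strand of the genome
static void build_index(const std::string &g, int k, KmerIndex &idx) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int run = 0; // length of current valid run
  for (size_t i = 0; i < g.size(); ++i) {
    int c = base_code(g[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[key].push_back((int)(i + 1 - k));
  }
}

struct Hit {
  int pos;      // 0-based leftmost genome position
  int matches;
  char strand;
  bool valid;
  Hit() : pos(-1), matches(-1), strand('+'), valid(false) {}
};

// best-scoring contiguous segment of the placed read (Kadane on a
// BLASTn-like +2 match / -3 mismatch score): models the local alignment a
// gapped aligner would report, so partially homologous fragments can be
// rejected by a coverage filter
static void local_segment(const std::string &g, const std::string &r, int p,
                          int &seg_len, int &seg_matches) {
  const double MATCH = 2.0, MISMATCH = -3.0;
  double best = 0.0, cur = 0.0;
  int cur_start = 0, best_s = 0, best_e = -1; // inclusive bounds
  int n = (int)r.size();
  const char *gp = g.data() + p;
  for (int i = 0; i < n; ++i) {
    double s = (gp[i] == r[i]) ? MATCH : MISMATCH;
    if (cur <= 0) { cur = s; cur_start = i; }
    else cur += s;
    if (cur > best) { best = cur; best_s = cur_start; best_e = i; }
  }
  if (best_e < best_s) { seg_len = 0; seg_matches = 0; return; }
  seg_len = best_e - best_s + 1;
  seg_matches = 0;
  for (int i = best_s; i <= best_e; ++i)
    if (gp[i] == r[i]) ++seg_matches;
}

// ungapped full-length comparison of read placed at genome position p
static inline int count_matches(const std::string &g, const std::string &r, int p) {
  int m = 0;
  const char *gp = g.data() + p;
  const char *rp = r.data();
  const size_t n = r.size();
  for (size_t i = 0; i < n; ++i) if (gp[i] == rp[i]) ++m;
  return m;
}

static void try_orientation(const std::string &g, const KmerIndex &idx,
                            const std::string &read, int k, char strand, Hit &best) {
  const int len = (int)read.size();
  const int glen = (int)g.size();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // non-overlapping seeds at offsets 0, k, 2k, ... plus a final seed flush
  // with the read end so the tail is always probed
  std::vector<int> offsets;
  for (int o = 0; o + k <= len; o += k) offsets.push_back(o);
  if (!offsets.empty() && offsets.back() != len - k) offsets.push_back(len - k);
  std::vector<int> seen; // candidate positions already evaluated
  for (size_t oi = 0; oi < offsets.size(); ++oi) {
    int o = offsets[oi];
    uint64_t key = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base_code(read[o + j]);
      if (c < 0) { ok = false; break; }
      key = ((key << 2) | (uint64_t)c) & mask;
    }
    if (!ok) continue;
    KmerIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    const std::vector<int> &poss = it->second;
    for (size_t pi = 0; pi < poss.size(); ++pi) {
      int p = poss[pi] - o; // implied read start on genome
      if (p < 0 || p + len > glen) continue;
      bool dup = false;
      for (size_t si = 0; si < seen.size(); ++si)
        if (seen[si] == p) { dup = true; break; }
      if (dup) continue;
      seen.push_back(p);
      int m = count_matches(g, read, p);
      // best hit: highest identity, tie -> lowest genome coordinate,
      // tie -> forward strand (forward is evaluated first)
      if (!best.valid || m > best.matches ||
          (m == best.matches && p < best.pos)) {
        best.pos = p; best.matches = m; best.strand = strand; best.valid = true;
      }
    }
  }
}

//' @noRd
// [[Rcpp::export]]
List map_reads_cpp(std::string genome, CharacterVector reads, int k,
                   double min_identity, bool both_strands) {
  if (k < 1 || k > 32) stop("seed length k must be in [1, 32]");
  if ((int)genome.size() < k) stop("genome shorter than seed length k");
  KmerIndex idx;
  build_index(genome, k, idx);

  const int n = reads.size();
  std::vector<int> out_read; std::vector<int> out_pos; std::vector<int> out_match;
  std::vector<int> out_len; std::vector<char> out_strand;
  std::vector<int> out_seg_len; std::vector<int> out_seg_match;
  out_read.reserve(n);

  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    if ((int)r.size() < k) continue; // caller validates; unseedable reads unmapped
    Hit best;
    try_orientation(genome, idx, r, k, '+', best);
    if (both_strands) {
      std::string rc = revcomp(r);
      Hit rbest;
      try_orientation(genome, idx, rc, k, '-', rbest);
      if (rbest.valid && (!best.valid || rbest.matches > best.matches ||
                          (rbest.matches == best.matches && rbest.pos < best.pos)))
        best = rbest;
    }
    if (!best.valid) continue;
    double ident = 100.0 * best.matches / (double)r.size();
    if (ident < min_identity) continue;
    const std::string &placed = (best.strand == '-') ? revcomp(r) : r;
    int seg_len = 0, seg_matches = 0;
    local_segment(genome, placed, best.pos, seg_len, seg_matches);
    out_read.push_back(i + 1);
    out_pos.push_back(best.pos);
    out_match.push_back(best.matches);
    out_len.push_back((int)r.size());
    out_strand.push_back(best.strand);
    out_seg_len.push_back(seg_len);
    out_seg_match.push_back(seg_matches);
  }

  int m = (int)out_read.size();
  IntegerVector ri(m), po(m), ma(m), le(m), sl(m), sm(m);
  CharacterVector st(m);
  for (int i = 0; i < m; ++i) {
    ri[i] = out_read[i]; po[i] = out_pos[i]; ma[i] = out_match[i];
    le[i] = out_len[i];  st[i] = std::string(1, out_strand[i]);
    sl[i] = out_seg_len[i]; sm[i] = out_seg_match[i];
  }
  return List::create(_["read_index"] = ri, _["pos0"] = po,
                      _["matches"] = ma, _["read_length"] = le,
                      _["strand"] = st, _["segment_length"] = sl,
                      _["segment_matches"] = sm);
}

// per-position depth from 0-based half-open intervals
// [[Rcpp::export]]
IntegerVector interval_depth_cpp(IntegerVector start0, IntegerVector end0,
                                 int genome_length) {
  IntegerVector diff(genome_length + 1);
  for (int i = 0; i < start0.size(); ++i) {
    int s = start0[i], e = end0[i];
    if (s < 0 || e > genome_length || s >= e)
      stop("alignment interval outside genome bounds");
    diff[s] += 1; diff[e] -= 1;
  }
  IntegerVector depth(genome_length);
  int acc = 0;
  for (int i = 0; i < genome_length; ++i) { acc += diff[i]; depth[i] = acc; }
  return depth;
}
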