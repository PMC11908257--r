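#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or anything else: never matches a seed
  }
}

// Per-position w-mer codes of a sequence, 2 bits per base.  Positions whose
// window contains a non-ACGT character get NA.  w must be <= 15 so the code
// fits a positive 32-bit int.
// [[Rcpp::export(name = ".kmer_codes")]]
IntegerVector kmer_codes_cpp(std::string seq, int w) {
  if (w < 1 || w > 15) stop("word size must be in [1, 15]");
  const int L = (int)seq.size();
  const int n = L - w + 1;
  if (n <= 0) return IntegerVector(0);
  IntegerVector out(n, NA_INTEGER);
  const uint32_t mask = (1u << (2 * w)) - 1u;
  uint32_t code = 0;
  int valid = 0;
  for (int i = 0; i < L; ++i) {
    int b = base2(seq[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++valid >= w) out[i - w + 1] = (int)code;
  }
  return out;
}

// Shared-word prefilter: for each representative (a sorted set of distinct
// w-mer codes) count how many query positions carry a word present in the
// representative, and return the 1-based indices of representatives whose
// count reaches `threshold`.  Indices come back in input (i.e. creation)
// order so the caller's first-fit semantics are preserved.
// [[Rcpp::export(name = ".prefilter_hits")]]
IntegerVector prefilter_hits_cpp(IntegerVector query_codes, List rep_sets,
                                 int w, int threshold) {
  if (w < 1 || w > 12) stop("prefilter word size must be in [1, 12]");
  std::vector<int> mult((size_t)1 << (2 * w), 0);
  for (int i = 0; i < query_codes.size(); ++i) {
    if (query_codes[i] != NA_INTEGER) mult[(size_t)query_codes[i]]++;
  }
  std::vector<int> hits;
  const int nrep = rep_sets.size();
  for (int r = 0; r < nrep; ++r) {
    IntegerVector codes = rep_sets[r];
    long shared = 0;
    for (int j = 0; j < codes.size(); ++j) {
      if (codes[j] != NA_INTEGER) shared += mult[(size_t)codes[j]];
    }
    if (shared >= threshold) hits.push_back(r + 1);
  }
  return wrap(hits);
}

static std::vector<int8_t> encode_seq(const char* s, int L) {
  std::vector<int8_t> v((size_t)L);
  for (int i = 0; i < L; ++i) v[(size_t)i] = (int8_t)base2(s[i]);
  return v;
}

static std::vector<int8_t> revcomp_codes(const std::vector<int8_t>& v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t b = v[v.size() - 1 - i];
    r[i] = (b < 0) ? b : (int8_t)(3 - b);
  }
  return r;
}

struct Hit { int mm, gene, start, strand; };

// End-to-end read mapper against a set of reference genes.
//
// Candidate placements are generated from exact (mismatch-free) seed matches
// of length `seed_len` taken at read offsets 0, stride, 2*stride, ... plus
// the final offset; each candidate diagonal is then scored by full-length
// Hamming comparison (end-to-end, no gaps).  With stride <= seed_len/2 every
// base is covered by at least two seed windows, so any placement of a read
// with at most floor(n_windows/2) substitutions is guaranteed to be found.
// Alignments with identity below `min_identity` are dropped; only the
// best-score stratum is reported, capped at `k_max` alignments per read.
// Returns parallel vectors (read, gene, pos are 1-based; strand +1/-1).
// [[Rcpp::export(name = ".map_reads")]]
List map_reads_cpp(CharacterVector reads, CharacterVector genes, int seed_len,
                   int k_max, double min_identity, bool both_strands,
                   int stride) {
  if (stride < 1) stop("stride must be >= 1");
  if (seed_len < 4 || seed_len > 31) stop("seed length must be in [4, 31]");
  const int ng = genes.size();
  std::vector<std::vector<int8_t> > gseq((size_t)ng);
  const uint64_t mask = (seed_len == 31) ? ((1ULL << 62) - 1ULL)
                                         : ((1ULL << (2 * seed_len)) - 1ULL);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  for (int g = 0; g < ng; ++g) {
    const char* s = CHAR(STRING_ELT(genes, g));
    int L = (int)LENGTH(STRING_ELT(genes, g));
    gseq[(size_t)g] = encode_seq(s, L);
    uint64_t code = 0; int valid = 0;
    for (int i = 0; i < L; ++i) {
      int b = gseq[(size_t)g][(size_t)i];
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= seed_len)
        index[code].push_back(std::make_pair(g, i - seed_len + 1));
    }
  }

  std::vector<int> o_read, o_gene, o_pos, o_strand, o_mm, o_len;
  int n_short = 0;
  const int nr = reads.size();
  std::vector<Hit> hits;
  std::unordered_set<uint64_t> seen;

  for (int r = 0; r < nr; ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    const int len = (int)LENGTH(STRING_ELT(reads, r));
    if (len < seed_len) { n_short++; continue; }
    const int maxmm = (int)((1.0 - min_identity) * len + 1e-9);
    std::vector<int8_t> fwd = encode_seq(s, len);
    hits.clear();
    seen.clear();
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::vector<int8_t> rcv;
      if (strand == 1) rcv = revcomp_codes(fwd);
      const std::vector<int8_t>& read = (strand == 0) ? fwd : rcv;
      // rolling seed codes at every offset (cheap); hash lookups only at
      // strided offsets
      const int n_off = len - seed_len + 1;
      std::vector<uint64_t> codes((size_t)n_off);
      std::vector<char> ok((size_t)n_off, 0);
      uint64_t code = 0; int valid = 0;
      for (int i = 0; i < len; ++i) {
        int b = read[(size_t)i];
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++valid >= seed_len) {
          codes[(size_t)(i - seed_len + 1)] = code;
          ok[(size_t)(i - seed_len + 1)] = 1;
        }
      }
      std::vector<int> offsets;
      for (int off = 0; off < n_off; off += stride) offsets.push_back(off);
      if (offsets.empty() || offsets.back() != n_off - 1)
        offsets.push_back(n_off - 1);
      for (size_t oi = 0; oi < offsets.size(); ++oi) {
        const int off = offsets[oi];
        if (!ok[(size_t)off]) continue;
        std::unordered_map<uint64_t,
            std::vector<std::pair<int, int> > >::const_iterator it =
            index.find(codes[(size_t)off]);
        if (it == index.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          const int g = it->second[h].first;
          const int start = it->second[h].second - off;
          if (start < 0) continue;
          const int gl = (int)gseq[(size_t)g].size();
          if (start + len > gl) continue;
          uint64_t key = ((uint64_t)(unsigned)g << 33) |
                         ((uint64_t)(unsigned)start << 1) |
                         (uint64_t)strand;
          if (!seen.insert(key).second) continue;
          int mm = 0;
          const int8_t* gp = &gseq[(size_t)g][(size_t)start];
          for (int j = 0; j < len; ++j) {
            if (read[(size_t)j] < 0 || read[(size_t)j] != gp[j]) {
              if (++mm > maxmm) break;
            }
          }
          if (mm <= maxmm) {
            Hit ht; ht.mm = mm; ht.gene = g; ht.start = start;
            ht.strand = (strand == 0) ? 1 : -1;
            hits.push_back(ht);
          }
        }
      }
    }
    if (hits.empty()) continue;
    int best = hits[0].mm;
    for (size_t h = 1; h < hits.size(); ++h)
      if (hits[h].mm < best) best = hits[h].mm;
    std::vector<Hit> top;
    for (size_t h = 0; h < hits.size(); ++h)
      if (hits[h].mm == best) top.push_back(hits[h]);
    std::sort(top.begin(), top.end(), [](const Hit& a, const Hit& b) {
      if (a.gene != b.gene) return a.gene < b.gene;
      if (a.start != b.start) return a.start < b.start;
      return a.strand > b.strand;
    });
    const int keep = std::min((int)top.size(), k_max);
    for (int h = 0; h < keep; ++h) {
      o_read.push_back(r + 1);
      o_gene.push_back(top[(size_t)h].gene + 1);
      o_pos.push_back(top[(size_t)h].start + 1);
      o_strand.push_back(top[(size_t)h].strand);
      o_mm.push_back(top[(size_t)h].mm);
      o_len.push_back(len);
    }
  }

  return List::create(_["read"] = wrap(o_read), _["gene"] = wrap(o_gene),
                      _["pos"] = wrap(o_pos), _["strand"] = wrap(o_strand),
                      _["mismatches"] = wrap(o_mm), _["len"] = wrap(o_len),
                      _["n_too_short"] = n_short);
}

// Hamming distance between two equal-length sequences; non-ACGT never matches.
// [[Rcpp::export(name = ".hamming")]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int x = base2(a[i]), y = base2(b[i]);
    if (x < 0 || y < 0 || x != y) mm++;
  }
  return mm;
}
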