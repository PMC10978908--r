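#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; anything but ACGT is -1 and breaks a k-mer.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KmerMap;

// Encode s[pos..pos+k-1]; returns false if the window contains a non-ACGT base.
static bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int j = 0; j < k; ++j) {
    int c = base_code(s[pos + j]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static void build_map(const std::vector<std::string>& refs, int k, KmerMap& map) {
  for (size_t t = 0; t < refs.size(); ++t) {
    const std::string& s = refs[t];
    if ((int)s.size() < k) continue;
    for (size_t pos = 0; pos + k <= s.size(); ++pos) {
      uint64_t key;
      if (!encode_kmer(s, pos, k, key))
        continue;
      map[key].push_back(((uint64_t)t << 32) | (uint64_t)pos);
    }
  }
}

// Ungapped seed-and-extend placement of reads on transcripts.
// Non-overlapping seeds every k bases give the pigeonhole guarantee:
// floor(len/k) seeds tolerate floor(len/k) - 1 mismatches without losing
// the true placement, which covers the default budget (k = 21 on 150 bp
// reads: 7 seeds vs 6 allowed mismatches).
//
// Returns an integer matrix with one row per read:
//   col 0: transcript index (1-based; 0 = unaligned)
//   col 1: 0-based offset
//   col 2: mismatch count
//   col 3: number of candidate placements examined
// [[Rcpp::export]]
IntegerMatrix cpp_align_reads(CharacterVector ref_seqs, CharacterVector read_seqs,
                              int k, double max_mismatch_frac) {
  size_t nref = ref_seqs.size(), nreads = read_seqs.size();
  std::vector<std::string> refs(nref);
  for (size_t i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);

  KmerMap map;
  build_map(refs, k, map);

  IntegerMatrix out(nreads, 4);
  std::vector<uint64_t> cands;

  for (size_t r = 0; r < nreads; ++r) {
    std::string read = as<std::string>(read_seqs[r]);
    int len = (int)read.size();
    out(r, 0) = 0; out(r, 1) = NA_INTEGER; out(r, 2) = NA_INTEGER; out(r, 3) = 0;
    if (len < k) continue;
    int budget = (int)std::floor(max_mismatch_frac * len + 1e-9);

    cands.clear();
    for (int sp = 0; sp + k <= len; sp += k) {
      uint64_t key;
      if (!encode_kmer(read, sp, k, key)) continue;
      KmerMap::const_iterator it = map.find(key);
      if (it == map.end()) continue;
      for (size_t h = 0; h < it->second.size(); ++h) {
        uint64_t hit = it->second[h];
        int t = (int)(hit >> 32);
        long off = (long)(hit & 0xffffffffULL) - sp;
        if (off < 0 || off + len > (long)refs[t].size()) continue;
        cands.push_back(((uint64_t)t << 32) | (uint64_t)off);
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int best_mm = len + 1, second_mm = len + 1, best_t = -1, best_off = -1;
    int cap = budget + 1; // mismatch counts above budget are equivalent
    for (size_t c = 0; c < cands.size(); ++c) {
      int t = (int)(cands[c] >> 32);
      int off = (int)(cands[c] & 0xffffffffULL);
      const std::string& ref = refs[t];
      int mm = 0;
      for (int j = 0; j < len && mm <= cap; ++j)
        if (ref[off + j] != read[j]) ++mm;
      if (mm < best_mm) {
        second_mm = best_mm; best_mm = mm; best_t = t; best_off = off;
      } else if (mm < second_mm) {
        second_mm = mm;
      }
    }
    out(r, 3) = (int)cands.size();
    if (best_mm <= budget && best_mm < second_mm) {
      out(r, 0) = best_t + 1;
      out(r, 1) = best_off;
      out(r, 2) = best_mm;
    }
  }
  return out;
}

// Base-count pileup over placements. Transcript coordinates are flattened
// into one axis using cumulative offsets supplied by the caller.
// Returns a 5 x total_length matrix of A,C,G,T,N counts.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(CharacterVector read_seqs, IntegerVector tx_idx,
                         IntegerVector offsets, IntegerVector tx_start,
                         int total_len) {
  IntegerMatrix counts(5, total_len);
  int n = tx_idx.size();
  for (int i = 0; i < n; ++i) {
    std::string read = as<std::string>(read_seqs[i]);
    int base0 = tx_start[tx_idx[i] - 1] + offsets[i];
    for (size_t j = 0; j < read.size(); ++j) {
      int c = base_code(read[j]);
      if (c < 0) c = 4;
      counts(c, base0 + (int)j) += 1;
    }
  }
  return counts;
}
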