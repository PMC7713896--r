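#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// MurmurHash3 64-bit finalizer: full avalanche on the packed k-mer.
static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

// 2-bit code; 255 marks ambiguous residues (window voided).
static inline uint8_t base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 255;
  }
}

// Bottom-sigma sketch of canonical k-mer hashes.
//
// Canonical form: the lexicographically smaller of the k-mer and its reverse
// complement; with A<C<G<T packed big-endian (first base most significant),
// string order equals numeric order on the packed value.  Hashes are the top
// 53 bits of fmix64(packed ^ scrambled seed) so that every value is exactly
// representable as an R double.  sigma <= 0 keeps the whole distinct set.
// [[Rcpp::export(name = ".sketch_hashes_cpp")]]
NumericVector sketch_hashes_cpp(std::string seq, int k, double sigma,
                                double seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t n = seq.size();
  const uint64_t seed_mix =
      fmix64(static_cast<uint64_t>(seed) * 0x9e3779b97f4a7c15ULL + 1ULL);
  std::vector<uint64_t> hashes;
  if (n >= static_cast<uint64_t>(k)) hashes.reserve(n - k + 1);

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t fwd = 0, rev = 0;
  int filled = 0; // valid residues in the current window
  for (uint64_t i = 0; i < n; ++i) {
    uint8_t c = base_code(seq[i]);
    if (c == 255) { filled = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | c) & mask;
    rev = (rev >> 2) | (static_cast<uint64_t>(3 - c) << (2 * (k - 1)));
    if (++filled >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      hashes.push_back(fmix64(canon ^ seed_mix) >> 11);
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  size_t keep = hashes.size();
  if (sigma > 0 && sigma < static_cast<double>(keep))
    keep = static_cast<size_t>(sigma);
  NumericVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = static_cast<double>(hashes[i]);
  return out;
}
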