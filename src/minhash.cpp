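#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Seed-stable 64-bit hashing for MinHash signatures. Process-randomized
// hashes (as in R environments or C++ std::hash) would break cross-run
// signature stability, so the hash is fixed here: FNV-1a over the k-mer
// bytes, keyed by a splitmix64-mixed seed, with a splitmix64 finalizer
// for avalanche.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t hash_str(const char *s, R_xlen_t n, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL ^ splitmix64(seed);
  for (R_xlen_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return splitmix64(h);
}

// One-bit minwise signature of a k-mer set: for each of L independent
// hash seeds (derived from hash_seed), locate the element with minimal
// hash (ties resolved toward the lexicographically smallest element) and
// emit the parity of an independent secondary hash of that element.
// [[Rcpp::export(name = ".minhash_bits")]]
IntegerVector minhash_bits(CharacterVector kmers, int L, double hash_seed) {
  R_xlen_t n = kmers.size();
  if (n == 0) stop("empty k-mer set");
  uint64_t base = splitmix64((uint64_t)hash_seed);
  IntegerVector bits(L);
  std::vector<const char *> ptrs(n);
  std::vector<R_xlen_t> lens(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    ptrs[i] = CHAR(STRING_ELT(kmers, i));
    lens[i] = LENGTH(STRING_ELT(kmers, i));
  }
  for (int l = 0; l < L; ++l) {
    uint64_t seed_l = splitmix64(base + (uint64_t)l);
    uint64_t best = UINT64_MAX;
    R_xlen_t arg = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      uint64_t h = hash_str(ptrs[i], lens[i], seed_l);
      if (h < best ||
          (h == best && std::strcmp(ptrs[i], ptrs[arg]) < 0)) {
        best = h;
        arg = i;
      }
    }
    // independent secondary hash of the minimal element -> 1 bit
    uint64_t h2 = hash_str(ptrs[arg], lens[arg],
                           seed_l ^ 0xA5A5A5A55A5A5A5AULL);
    bits[l] = (int)(h2 & 1ULL);
  }
  return bits;
}

// Raw 64-bit hash reduced to [0, 1); exposed for diagnostics and tests.
// [[Rcpp::export(name = ".hash_unit")]]
NumericVector hash_unit(CharacterVector x, double seed) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t h = hash_str(CHAR(STRING_ELT(x, i)), LENGTH(STRING_ELT(x, i)),
                          (uint64_t)seed);
    out[i] = (double)(h >> 11) / 9007199254740992.0; // 53-bit mantissa
  }
  return out;
}
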