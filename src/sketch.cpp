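#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

// 64-bit MurmurHash3 (x64_128 variant, first word) so sketches are
// reproducible across platforms and runs for a fixed seed.
static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static uint64_t murmur3_x64(const char *key, int len, uint32_t seed) {
  const uint8_t *data = (const uint8_t *)key;
  const int nblocks = len / 16;
  uint64_t h1 = seed, h2 = seed;
  const uint64_t c1 = 0x87c37b91114253d5ULL;
  const uint64_t c2 = 0x4cf5ad432745937fULL;

  for (int i = 0; i < nblocks; i++) {
    uint64_t k1, k2;
    std::memcpy(&k1, data + i * 16, 8);
    std::memcpy(&k2, data + i * 16 + 8, 8);
    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5;
  }

  const uint8_t *tail = data + nblocks * 16;
  uint64_t k1 = 0, k2 = 0;
  switch (len & 15) {
  case 15: k2 ^= ((uint64_t)tail[14]) << 48;
  case 14: k2 ^= ((uint64_t)tail[13]) << 40;
  case 13: k2 ^= ((uint64_t)tail[12]) << 32;
  case 12: k2 ^= ((uint64_t)tail[11]) << 24;
  case 11: k2 ^= ((uint64_t)tail[10]) << 16;
  case 10: k2 ^= ((uint64_t)tail[9]) << 8;
  case  9: k2 ^= ((uint64_t)tail[8]) << 0;
           k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
  case  8: k1 ^= ((uint64_t)tail[7]) << 56;
  case  7: k1 ^= ((uint64_t)tail[6]) << 48;
  case  6: k1 ^= ((uint64_t)tail[5]) << 40;
  case  5: k1 ^= ((uint64_t)tail[4]) << 32;
  case  4: k1 ^= ((uint64_t)tail[3]) << 24;
  case  3: k1 ^= ((uint64_t)tail[2]) << 16;
  case  2: k1 ^= ((uint64_t)tail[1]) << 8;
  case  1: k1 ^= ((uint64_t)tail[0]) << 0;
           k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }

  h1 ^= len; h2 ^= len;
  h1 += h2; h2 += h1;
  h1 = fmix64(h1); h2 = fmix64(h2);
  h1 += h2;
  return h1;
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Distinct k-mer hashes of one sequence, bottom-s retained. Hash values are
// truncated to 53 bits so they are exactly representable as doubles on the
// R side; the truncation is applied before deduplication so every sequence
// sees the same hash space.
// [[Rcpp::export]]
List sketch_cpp(std::string seq, int k, int s, bool canonical,
                int seed, std::string alphabet) {
  bool allowed[256];
  std::fill(allowed, allowed + 256, false);
  for (char c : alphabet) allowed[(unsigned char)c] = true;

  const int n = (int)seq.size();
  std::unordered_set<uint64_t> seen;
  std::string rc(k, 'N');

  int run = 0;  // length of current run of valid characters
  for (int i = 0; i < n; i++) {
    run = allowed[(unsigned char)seq[i]] ? run + 1 : 0;
    if (run < k) continue;
    const char *kmer = seq.data() + i - k + 1;
    const char *use = kmer;
    if (canonical) {
      for (int j = 0; j < k; j++) rc[j] = complement(kmer[k - 1 - j]);
      if (std::lexicographical_compare(rc.data(), rc.data() + k,
                                       kmer, kmer + k))
        use = rc.data();
    }
    uint64_t h = murmur3_x64(use, k, (uint32_t)seed) >> 11;
    seen.insert(h);
  }

  std::vector<uint64_t> all(seen.begin(), seen.end());
  std::sort(all.begin(), all.end());
  const int keep = std::min((int)all.size(), s);
  NumericVector hashes(keep);
  for (int i = 0; i < keep; i++) hashes[i] = (double)all[i];
  return List::create(_["hashes"] = hashes,
                      _["n_kmers"] = (int)all.size());
}

// Bottom-s union Jaccard estimate from two sorted distinct hash vectors.
// [[Rcpp::export]]
double jaccard_sketch_cpp(NumericVector a, NumericVector b, int s) {
  const int na = a.size(), nb = b.size();
  if (na == 0 || nb == 0) return 0.0;
  int i = 0, j = 0, taken = 0, shared = 0;
  while (taken < s && (i < na || j < nb)) {
    if (i < na && j < nb) {
      if (a[i] == b[j]) { shared++; i++; j++; }
      else if (a[i] < b[j]) i++;
      else j++;
    } else if (i < na) i++;
    else j++;
    taken++;
  }
  return taken > 0 ? (double)shared / (double)taken : 0.0;
}

static inline double mash_d(double j, int k) {
  if (j <= 0.0) return 1.0;
  double d = -std::log(2.0 * j / (1.0 + j)) / (double)k;
  if (d < 0.0) d = 0.0;
  if (d > 1.0) d = 1.0;
  return d;
}

// Full symmetric Mash distance matrix from a list of sketches.
// [[Rcpp::export]]
NumericMatrix mash_matrix_cpp(List sketches, int k, int s) {
  const int n = sketches.size();
  NumericMatrix D(n, n);
  std::vector<NumericVector> hs(n);
  for (int i = 0; i < n; i++) {
    List sk = sketches[i];
    hs[i] = as<NumericVector>(sk["hashes"]);
  }
  for (int i = 0; i < n - 1; i++) {
    for (int j = i + 1; j < n; j++) {
      double d = mash_d(jaccard_sketch_cpp(hs[i], hs[j], s), k);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
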