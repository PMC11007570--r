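#ifndef MITOBAIT_SEQ_UTIL_H
#define MITOBAIT_SEQ_UTIL_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>

// 2-bit base encoding; -1 for anything outside ACGT (N, IUPAC codes).
inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

inline char bits2base(int b) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  return tab[b & 3];
}

inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  case 'N': case 'n': return 'N';
  default: return 'N';
  }
}

inline std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// Reverse complement of a 2-bit packed k-mer, k <= 31.
inline uint64_t revcomp_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

inline uint64_t canonical_kmer(uint64_t x, int k) {
  uint64_t r = revcomp_kmer(x, k);
  return x < r ? x : r;
}

// Enumerate canonical k-mers of `s` (k <= 31); positions with non-ACGT
// bases yield no k-mer. Calls f(pos, canonical, forward) per valid k-mer.
template <typename F>
inline void for_each_kmer(const std::string& s, int k, F f) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t fwd = 0;
  int run = 0;  // length of current valid run
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      uint64_t rc = revcomp_kmer(fwd, k);
      f(i - k + 1, fwd < rc ? fwd : rc, fwd);
    }
  }
}

#endif
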