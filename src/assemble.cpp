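#include "seq_util.h"
using namespace Rcpp;

// De Bruijn graph over k-mers packed into 2-bit code, three 64-bit words
// (k <= 96; the multi-k ladder uses 33/55/77). Word 0 carries the high
// bits, so lexicographic word comparison equals string comparison of the
// k-mers, which keeps seed ordering (and therefore output) identical to a
// string-keyed implementation.

namespace {

struct PK {
  uint64_t w[3];
  bool operator==(const PK& o) const {
    return w[0] == o.w[0] && w[1] == o.w[1] && w[2] == o.w[2];
  }
  bool operator<(const PK& o) const {
    if (w[0] != o.w[0]) return w[0] < o.w[0];
    if (w[1] != o.w[1]) return w[1] < o.w[1];
    return w[2] < o.w[2];
  }
};

struct PKHash {
  size_t operator()(const PK& x) const {
    uint64_t h = 1469598103934665603ULL;
    for (int i = 0; i < 3; ++i) {
      h ^= x.w[i];
      h *= 1099511628211ULL;
    }
    return (size_t)h;
  }
};

struct Ctx {
  int k;
  PK mask;        // low 2k bits set
  int top_word;   // array index holding the (k-1)-th base
  int top_shift;  // bit offset of that base within its word
};

inline Ctx make_ctx(int k) {
  Ctx c;
  c.k = k;
  int bits = 2 * k;
  for (int i = 0; i < 3; ++i) {
    int lo = 64 * (2 - i);  // word i covers bits [64*(2-i), 64*(3-i))
    int have = std::min(64, std::max(0, bits - lo));
    c.mask.w[i] = have >= 64 ? ~0ULL : ((1ULL << have) - 1ULL);
  }
  int off = 2 * (k - 1);
  c.top_word = 2 - off / 64;
  c.top_shift = off % 64;
  return c;
}

inline void shl2(PK& x) {
  x.w[0] = (x.w[0] << 2) | (x.w[1] >> 62);
  x.w[1] = (x.w[1] << 2) | (x.w[2] >> 62);
  x.w[2] <<= 2;
}

inline void shr2(PK& x) {
  x.w[2] = (x.w[2] >> 2) | (x.w[1] << 62);
  x.w[1] = (x.w[1] >> 2) | (x.w[0] << 62);
  x.w[0] >>= 2;
}

inline void apply_mask(PK& x, const Ctx& c) {
  x.w[0] &= c.mask.w[0]; x.w[1] &= c.mask.w[1]; x.w[2] &= c.mask.w[2];
}

// append base at the low end (rightmost position of the k-mer)
inline PK append_base(PK x, int b, const Ctx& c) {
  shl2(x);
  x.w[2] |= (uint64_t)b;
  apply_mask(x, c);
  return x;
}

// drop the low base and insert one at the high (leftmost) position
inline PK prepend_base(PK x, int b, const Ctx& c) {
  shr2(x);
  x.w[c.top_word] |= (uint64_t)b << c.top_shift;
  return x;
}

inline PK canon(const PK& f, const PK& r) { return f < r ? f : r; }

inline int base_at(const PK& x, int pos_from_left, const Ctx& c) {
  int off = 2 * (c.k - 1 - pos_from_left);
  return (int)((x.w[2 - off / 64] >> (off % 64)) & 3ULL);
}

inline std::string decode(const PK& x, const Ctx& c) {
  std::string s(c.k, 'A');
  for (int i = 0; i < c.k; ++i) s[i] = bits2base(base_at(x, i, c));
  return s;
}

typedef std::unordered_map<PK, int, PKHash> PKCounts;

// count canonical k-mers over the valid (ACGT) runs of a sequence
inline void count_kmers(const std::string& s, const Ctx& c, PKCounts& cnt) {
  PK f = {{0, 0, 0}}, r = {{0, 0, 0}};
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; f = {{0, 0, 0}}; r = {{0, 0, 0}}; continue; }
    f = append_base(f, b, c);
    r = prepend_base(r, 3 - b, c);
    if (++run >= c.k) ++cnt[canon(f, r)];
  }
}

struct Oriented { PK f, r; };

inline int lookup(const PKCounts& cnt, const Oriented& o) {
  auto it = cnt.find(canon(o.f, o.r));
  return it == cnt.end() ? 0 : it->second;
}

inline Oriented step_right(const Oriented& o, int b, const Ctx& c) {
  return { append_base(o.f, b, c), prepend_base(o.r, 3 - b, c) };
}

inline Oriented step_left(const Oriented& o, int b, const Ctx& c) {
  return { prepend_base(o.f, b, c), append_base(o.r, 3 - b, c) };
}

inline int out_degree(const PKCounts& cnt, const Oriented& o, const Ctx& c,
                      int min_count, int* the_b) {
  int n = 0;
  for (int b = 0; b < 4; ++b) {
    if (lookup(cnt, step_right(o, b, c)) >= min_count) { *the_b = b; ++n; }
  }
  return n;
}

inline int in_degree(const PKCounts& cnt, const Oriented& o, const Ctx& c,
                     int min_count) {
  int n = 0;
  for (int b = 0; b < 4; ++b)
    if (lookup(cnt, step_left(o, b, c)) >= min_count) ++n;
  return n;
}

}  // namespace

// Maximal non-branching paths (unitigs) of the canonical de Bruijn graph
// over all reads, keeping k-mers seen at least min_count times. Output is
// sorted by decreasing length then sequence for determinism; each unitig
// is reported in its lexicographically smaller orientation. Mean member
// k-mer counts are attached as attribute "coverage".
// [[Rcpp::export(rng = false)]]
CharacterVector cpp_unitigs(CharacterVector seqs, int k, int min_count) {
  if (k < 3 || k > 96) stop("k must be in [3, 96]");
  if (k % 2 == 0) stop("k must be odd");
  Ctx c = make_ctx(k);
  PKCounts cnt;
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    count_kmers(as<std::string>(seqs[i]), c, cnt);

  std::vector<PK> keys;
  keys.reserve(cnt.size());
  for (auto& kv : cnt) if (kv.second >= min_count) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  std::unordered_set<PK, PKHash> visited;
  std::vector<std::string> unitigs;
  std::vector<double> covs;
  for (const auto& start : keys) {
    if (visited.count(start)) continue;
    visited.insert(start);
    // start in canonical orientation; build its reverse complement
    PK rc = {{0, 0, 0}};
    for (int i = 0; i < c.k; ++i)
      rc = append_base(rc, 3 - base_at(start, c.k - 1 - i, c), c);
    Oriented cur = { start, rc };
    std::string path = decode(start, c);
    double covsum = cnt[start];
    long nk = 1;
    for (int dir = 0; dir < 2; ++dir) {
      while (true) {
        int b = -1;
        if (out_degree(cnt, cur, c, min_count, &b) != 1) break;
        Oriented nxt = step_right(cur, b, c);
        if (in_degree(cnt, nxt, c, min_count) != 1) break;
        PK cn = canon(nxt.f, nxt.r);
        if (visited.count(cn)) break;
        visited.insert(cn);
        path.push_back(bits2base(b));
        covsum += cnt[cn];
        ++nk;
        cur = nxt;
      }
      path = revcomp_str(path);
      std::swap(cur.f, cur.r);
      // re-orient cur to the (new) right end of the path
      PK f = {{0, 0, 0}}, r = {{0, 0, 0}};
      for (size_t i = path.size() - c.k; i < path.size(); ++i) {
        int b = base2bits(path[i]);
        f = append_base(f, b, c);
        r = prepend_base(r, 3 - b, c);
      }
      cur = { f, r };
    }
    std::string rcp = revcomp_str(path);
    if (rcp < path) path = rcp;
    unitigs.push_back(path);
    covs.push_back(covsum / nk);
  }
  std::vector<int> ord(unitigs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (unitigs[a].size() != unitigs[b].size())
      return unitigs[a].size() > unitigs[b].size();
    return unitigs[a] < unitigs[b];
  });
  CharacterVector out(ord.size());
  NumericVector cov(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    out[i] = unitigs[ord[i]];
    cov[i] = covs[ord[i]];
  }
  out.attr("coverage") = cov;
  return out;
}
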