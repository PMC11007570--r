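#include "seq_util.h"
using namespace Rcpp;

// Count, per query sequence, how many k-mer positions carry a canonical
// k-mer also present in the panel sequences (both strands via canonical
// form). k must be <= 31 so k-mers pack into 64 bits.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_shared_kmer_counts(CharacterVector seqs, CharacterVector panel,
                                     int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  std::unordered_set<uint64_t> bank;
  for (R_xlen_t i = 0; i < panel.size(); ++i) {
    std::string p = as<std::string>(panel[i]);
    for_each_kmer(p, k, [&](int, uint64_t canon, uint64_t) { bank.insert(canon); });
  }
  IntegerVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int n = 0;
    for_each_kmer(s, k, [&](int, uint64_t canon, uint64_t) {
      if (bank.count(canon)) ++n;
    });
    out[i] = n;
  }
  return out;
}

// k-mer-spectrum error correction. Builds the canonical k-mer count
// spectrum over all reads, then repairs positions supported only by solo
// k-mers (count == 1) when a single-base substitution lifts every covering
// k-mer to solid (count >= solid_min). Ties broken by base order A<C<G<T.
// [[Rcpp::export(rng = false)]]
CharacterVector cpp_correct_reads(CharacterVector seqs, int k, int solid_min) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  std::unordered_map<uint64_t, int> counts;
  std::vector<std::string> reads(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    reads[i] = as<std::string>(seqs[i]);
    for_each_kmer(reads[i], k, [&](int, uint64_t canon, uint64_t) { ++counts[canon]; });
  }
  auto count_of = [&](const std::string& s, int pos) -> int {
    // count of the k-mer starting at pos, or -1 if invalid
    uint64_t x = 0;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[pos + j]);
      if (b < 0) return -1;
      x = (x << 2) | (uint64_t)b;
    }
    auto it = counts.find(canonical_kmer(x, k));
    return it == counts.end() ? 0 : it->second;
  };
  CharacterVector out(seqs.size());
  std::vector<int> pos_cnt;
  for (R_xlen_t i = 0; i < (R_xlen_t)reads.size(); ++i) {
    std::string s = reads[i];
    int n = (int)s.size();
    if (n >= k) {
      // per-start k-mer counts once, then windowed max per position
      pos_cnt.assign(n - k + 1, -1);
      for (int q = 0; q + k <= n; ++q) pos_cnt[q] = count_of(s, q);
      for (int p = 0; p < n; ++p) {
        int lo = std::max(0, p - k + 1), hi = std::min(p, n - k);
        if (lo > hi) continue;
        int best = 0;
        for (int q = lo; q <= hi; ++q) best = std::max(best, pos_cnt[q]);
        if (best != 1) continue;  // only solo-supported positions are suspect
        char orig = s[p];
        char best_base = 0;
        for (int b = 0; b < 4; ++b) {
          char cand = bits2base(b);
          if (cand == orig) continue;
          s[p] = cand;
          int worst = INT32_MAX;
          for (int q = lo; q <= hi; ++q) worst = std::min(worst, count_of(s, q));
          if (worst >= solid_min) { best_base = cand; break; }
        }
        s[p] = best_base ? best_base : orig;
        if (best_base) {  // refresh counts after an applied repair
          for (int q = 0; q + k <= n; ++q) pos_cnt[q] = count_of(s, q);
        }
      }
    }
    out[i] = s;
  }
  return out;
}

// Sliding-window 3' quality trimming plus exact-suffix adapter clipping.
// Qualities are Phred+33. Windows of `window` bases are peeled from the 3'
// end while their mean quality sits below `cutoff`; residual trailing bases
// below `cutoff` are then stripped individually.
// [[Rcpp::export(rng = false)]]
List cpp_trim_reads(CharacterVector seqs, CharacterVector quals,
                    double cutoff, int window,
                    CharacterVector adapters, int min_adapter) {
  R_xlen_t n = seqs.size();
  CharacterVector oseq(n), oqual(n);
  std::vector<std::string> ad;
  for (R_xlen_t a = 0; a < adapters.size(); ++a)
    ad.push_back(as<std::string>(adapters[a]));
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    if (s.size() != q.size()) stop("sequence/quality length mismatch at record %d", (int)i + 1);
    // adapter: clip at the leftmost suffix of s that equals a prefix (>=
    // min_adapter bases) of any adapter
    size_t cut = s.size();
    for (const auto& a : ad) {
      if ((int)a.size() < min_adapter) continue;
      for (size_t p = 0; p + (size_t)min_adapter <= s.size() && p < cut; ++p) {
        size_t len = std::min(s.size() - p, a.size());
        if (len >= (size_t)min_adapter && s.compare(p, len, a, 0, len) == 0) {
          cut = p;
          break;
        }
      }
    }
    s.resize(cut); q.resize(cut);
    int pos = (int)s.size();
    while (pos >= window) {
      double m = 0;
      for (int j = pos - window; j < pos; ++j) m += q[j] - 33;
      if (m / window < cutoff) --pos; else break;
    }
    while (pos > 0 && (q[pos - 1] - 33) < cutoff) --pos;
    s.resize(pos); q.resize(pos);
    oseq[i] = s; oqual[i] = q;
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual);
}
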