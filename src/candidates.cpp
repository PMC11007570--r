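#include "seq_util.h"
using namespace Rcpp;

// One-pass candidate assignment for contig polishing: index the contigs'
// canonical k-mers, scan each read once, and report which contigs share
// at least min_shared k-mers with it. Returns a list (one integer vector
// of 1-based read ids per contig).
// [[Rcpp::export(rng = false)]]
List cpp_candidate_reads(CharacterVector contigs, CharacterVector reads,
                         int k, int min_shared) {
  if (k < 11 || k > 31) stop("k must be in [11, 31]");
  std::unordered_map<uint64_t, std::vector<int>> idx;
  for (R_xlen_t c = 0; c < contigs.size(); ++c) {
    std::string s = as<std::string>(contigs[c]);
    for_each_kmer(s, k, [&](int, uint64_t canon, uint64_t) {
      auto& v = idx[canon];
      if (v.empty() || v.back() != (int)c) v.push_back((int)c);
    });
  }
  std::vector<std::vector<int>> out(contigs.size());
  std::unordered_map<int, int> shared;  // contig -> shared k-mer count
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    shared.clear();
    for_each_kmer(s, k, [&](int, uint64_t canon, uint64_t) {
      auto it = idx.find(canon);
      if (it == idx.end()) return;
      for (int c : it->second) ++shared[c];
    });
    for (auto& kv : shared)
      if (kv.second >= min_shared) out[kv.first].push_back((int)r + 1);
  }
  List res(contigs.size());
  for (R_xlen_t c = 0; c < contigs.size(); ++c) {
    std::sort(out[c].begin(), out[c].end());
    res[c] = IntegerVector(out[c].begin(), out[c].end());
  }
  return res;
}
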