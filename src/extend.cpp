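#include "seq_util.h"
using namespace Rcpp;

// Iterative consensus overlap extension of contigs. Reads are indexed by
// their first `index_k` bases (both orientations). Per iteration and per
// contig end, reads whose prefix k-mer matches inside the terminal region
// and whose full overlap with the contig reaches min_identity vote on the
// appended bases; a base is appended only while the leading base holds at
// least `majority` of the votes. Extension stops at a fork (no majority),
// which marks a haplotype boundary. Ties break toward the alphabetically
// smaller base for determinism.
// [[Rcpp::export(rng = false)]]
List cpp_extend_contigs(CharacterVector contigs, CharacterVector reads,
                        int min_overlap, double min_identity, double majority,
                        int iterations, int index_k) {
  if (index_k < 11 || index_k > 31) stop("index_k must be in [11, 31]");
  std::vector<std::string> rs;
  rs.reserve(2 * reads.size());
  size_t max_rl = 0;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    if ((int)r.size() < std::max(min_overlap + 1, index_k)) continue;
    max_rl = std::max(max_rl, r.size());
    rs.push_back(r);
    rs.push_back(revcomp_str(r));
  }
  // prefix index: packed first index_k bases -> read ids (oriented)
  std::unordered_map<uint64_t, std::vector<int>> pref;
  for (size_t i = 0; i < rs.size(); ++i) {
    uint64_t x = 0;
    bool ok = true;
    for (int j = 0; j < index_k; ++j) {
      int b = base2bits(rs[i][j]);
      if (b < 0) { ok = false; break; }
      x = (x << 2) | (uint64_t)b;
    }
    if (ok) pref[x].push_back((int)i);
  }

  int nct = (int)contigs.size();
  std::vector<std::string> ct(nct);
  for (int i = 0; i < nct; ++i) ct[i] = as<std::string>(contigs[i]);
  IntegerVector iters_used(nct);

  auto extend_right = [&](std::string& c) -> bool {
    int L = (int)c.size();
    if (L < min_overlap) return false;
    // candidate reads: prefix k-mer occurs at position p in the terminal
    // region; overlap = L - p
    int from = std::max(0, L - (int)max_rl + 1);
    std::vector<std::array<int, 4>> votes;
    uint64_t x = 0;
    int run = 0;
    for (int p = from; p + index_k <= L; ++p) {
      if (run == 0) {
        x = 0;
        bool ok = true;
        for (int j = 0; j < index_k; ++j) {
          int b = base2bits(c[p + j]);
          if (b < 0) { ok = false; break; }
          x = (x << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        run = 1;
      } else {
        int b = base2bits(c[p + index_k - 1]);
        if (b < 0) { run = 0; continue; }
        uint64_t mask = (index_k < 32) ? ((1ULL << (2 * index_k)) - 1) : ~0ULL;
        x = ((x << 2) | (uint64_t)b) & mask;
      }
      int ov = L - p;
      if (ov < min_overlap) break;
      auto it = pref.find(x);
      if (it == pref.end()) continue;
      for (int rid : it->second) {
        const std::string& r = rs[rid];
        if ((int)r.size() <= ov) continue;  // must extend past the end
        int mm = 0, allowed = (int)std::floor((1.0 - min_identity) * ov);
        bool pass = true;
        for (int j = 0; j < ov; ++j) {
          if (r[j] != c[p + j] && ++mm > allowed) { pass = false; break; }
        }
        if (!pass) continue;
        int ext = (int)r.size() - ov;
        if ((int)votes.size() < ext) votes.resize(ext, {0, 0, 0, 0});
        for (int j = 0; j < ext; ++j) {
          int b = base2bits(r[ov + j]);
          if (b >= 0) ++votes[j][b];
        }
      }
    }
    bool grew = false;
    for (auto& v : votes) {
      int tot = v[0] + v[1] + v[2] + v[3];
      if (tot == 0) break;
      int best = 0;
      for (int b = 1; b < 4; ++b) if (v[b] > v[best]) best = b;
      if ((double)v[best] < majority * tot) break;  // fork: stop
      c.push_back(bits2base(best));
      grew = true;
    }
    return grew;
  };

  for (int i = 0; i < nct; ++i) {
    for (int it = 0; it < iterations; ++it) {
      bool g1 = extend_right(ct[i]);
      ct[i] = revcomp_str(ct[i]);
      bool g2 = extend_right(ct[i]);
      ct[i] = revcomp_str(ct[i]);
      iters_used[i] = it + 1;
      if (!g1 && !g2) break;
    }
  }
  CharacterVector out(nct);
  for (int i = 0; i < nct; ++i) out[i] = ct[i];
  return List::create(_["seq"] = out, _["iterations"] = iters_used);
}
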