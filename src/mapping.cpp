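#include "seq_util.h"
using namespace Rcpp;

// Ungapped seed-and-verify read mapping against a small set of reference
// sequences (scaffolds or mitogenomes). A read is placed by exact k-mer
// seeds and verified by full-length mismatch counting; circular references
// wrap, linear references clip. 'N' in the reference is a wildcard and is
// excluded from both the mismatch and the compared-site count. Returns the
// best placement per read (fewest mismatches per compared site).
//
// Output matrix columns: ref (1-based, 0 = unmapped), start (1-based, may
// be <= 0 only for circular wrap before normalization — always normalized
// to [1, L]), strand (1/-1), mismatches, compared sites.
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_map_reads(CharacterVector refs, LogicalVector circular,
                            CharacterVector reads, int k, double max_div,
                            int seed_stride) {
  if (k < 11 || k > 31) stop("k must be in [11, 31]");
  if (seed_stride < 1) seed_stride = 1;
  std::vector<std::string> R(refs.size());
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;  // fwd kmers
  for (R_xlen_t i = 0; i < refs.size(); ++i) {
    R[i] = as<std::string>(refs[i]);
    // index the doubled sequence head for circular refs so seeds spanning
    // the origin still hit; positions stay modulo L
    std::string s = R[i];
    int L = (int)s.size();
    if (circular[i] && L > k) s += R[i].substr(0, std::min(L, k - 1));
    for_each_kmer(s, k, [&](int pos, uint64_t, uint64_t fwd) {
      idx[fwd].push_back({(int)i, pos % L});
    });
  }
  R_xlen_t n = reads.size();
  IntegerMatrix out(n, 5);
  colnames(out) = CharacterVector::create("ref", "start", "strand", "mismatches", "sites");
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int rl = (int)rd.size();
    int best_ref = -1, best_start = 0, best_strand = 0, best_mm = 0, best_sites = 0;
    double best_rate = 2.0;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? rd : revcomp_str(rd);
      if ((int)q.size() < k) break;
      std::unordered_set<int64_t> tried;
      for (int p = 0; p + k <= rl; p += seed_stride) {
        uint64_t x = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          int b = base2bits(q[p + j]);
          if (b < 0) { ok = false; break; }
          x = (x << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = idx.find(x);
        if (it == idx.end()) continue;
        for (auto& hit : it->second) {
          int ri = hit.first;
          int L = (int)R[ri].size();
          int start = hit.second - p;  // implied 0-based start on ref
          if (circular[ri]) start = ((start % L) + L) % L;
          int64_t key = ((int64_t)ri << 33) | ((int64_t)(start + L) << 1) | strand;
          if (!tried.insert(key).second) continue;
          int mm = 0, sites = 0;
          for (int j = 0; j < rl; ++j) {
            int rp = start + j;
            if (circular[ri]) rp %= L;
            else if (rp < 0 || rp >= L) continue;
            char rc = R[ri][rp];
            if (rc == 'N' || rc == 'n') continue;
            ++sites;
            if (rc != q[j]) ++mm;
          }
          if (sites < k) continue;
          double rate = (double)mm / sites;
          if (rate < best_rate ||
              (rate == best_rate && (ri < best_ref ||
               (ri == best_ref && start + 1 < best_start)))) {
            best_rate = rate;
            best_ref = ri; best_start = start + 1;
            best_strand = strand == 0 ? 1 : -1;
            best_mm = mm; best_sites = sites;
          }
        }
        if (best_rate == 0.0) break;  // perfect hit, stop seeding
      }
      if (best_rate == 0.0) break;
    }
    if (best_ref >= 0 && best_rate <= max_div) {
      out(i, 0) = best_ref + 1; out(i, 1) = best_start;
      out(i, 2) = best_strand; out(i, 3) = best_mm; out(i, 4) = best_sites;
    }
  }
  return out;
}

// Per-position depth and consensus-disagreement counts from ungapped read
// placements (as produced by cpp_map_reads, filtered to one reference).
// starts are 1-based; strand -1 means the read aligns reverse-complemented.
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_pileup(std::string ref, bool circular, CharacterVector reads,
                         IntegerVector starts, IntegerVector strands) {
  int L = (int)ref.size();
  IntegerMatrix out(L, 2);
  colnames(out) = CharacterVector::create("depth", "disagree");
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string q = as<std::string>(reads[i]);
    if (strands[i] < 0) q = revcomp_str(q);
    int start = starts[i] - 1;
    for (int j = 0; j < (int)q.size(); ++j) {
      int rp = start + j;
      if (circular) rp = ((rp % L) + L) % L;
      else if (rp < 0 || rp >= L) continue;
      char rc = ref[rp];
      if (rc == 'N' || rc == 'n') continue;
      ++out(rp, 0);
      if (rc != q[j]) ++out(rp, 1);
    }
  }
  return out;
}

// Diagonal-offset hits between two sequences from shared forward k-mers;
// used to anchor a contig on a reference before banded alignment. K-mers
// occurring more than max_occ times in b are skipped as repeats.
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_diag_hits(std::string a, std::string b, int k, int max_occ) {
  std::unordered_map<uint64_t, std::vector<int>> ib;
  for_each_kmer(b, k, [&](int pos, uint64_t, uint64_t fwd) { ib[fwd].push_back(pos); });
  std::vector<std::pair<int, int>> hits;
  for_each_kmer(a, k, [&](int pos, uint64_t, uint64_t fwd) {
    auto it = ib.find(fwd);
    if (it == ib.end() || (int)it->second.size() > max_occ) return;
    for (int pb : it->second) hits.push_back({pos, pb});
  });
  IntegerMatrix out((int)hits.size(), 2);
  colnames(out) = CharacterVector::create("pos_a", "pos_b");
  for (size_t i = 0; i < hits.size(); ++i) {
    out((int)i, 0) = hits[i].first;
    out((int)i, 1) = hits[i].second;
  }
  return out;
}
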