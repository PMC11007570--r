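#include "seq_util.h"
using namespace Rcpp;

// Per-position base votes from ungapped read placements on one contig.
// Returns a 4 x L matrix of A/C/G/T counts.
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_base_votes(std::string ref, CharacterVector reads,
                             IntegerVector starts, IntegerVector strands) {
  int L = (int)ref.size();
  IntegerMatrix out(4, L);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string q = as<std::string>(reads[i]);
    if (strands[i] < 0) q = revcomp_str(q);
    int start = starts[i] - 1;
    for (int j = 0; j < (int)q.size(); ++j) {
      int rp = start + j;
      if (rp < 0 || rp >= L) continue;
      int b = base2bits(q[j]);
      if (b >= 0) ++out(b, rp);
    }
  }
  return out;
}
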